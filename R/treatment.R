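## Macrophage-directed immunotherapies and their schedules.
##
## Three strategies: depletion (macrophages of any phenotype are removed),
## recruitment inhibition (fewer macrophages enter the tissue) and PI3K
## inhibition ("reeducation": the PI3K-activity input to the differentiation
## decision is lowered, tipping redifferentiation toward M1). Each can run
## continuously from the start day or cycled (on for `days_on` out of each
## `cycle_duration`-day cycle). Cycled depletion is special: instead of a
## per-step removal probability it removes an exact fraction of all
## macrophages at the start of each cycle.

#' Specify a treatment
#'
#' @param strategy `"depletion"`, `"recruitment_inhibition"` or
#'   `"pi3k_inhibition"`.
#' @param strength Fraction in `[0, 1]`. For continuous depletion this is
#'   the per-step removal probability; for cycled depletion the fraction of
#'   macrophages removed at each cycle start; for the other strategies the
#'   fractional reduction of the targeted parameter.
#' @param schedule `"continuous"` or `"cycled"`.
#' @param start_day Day treatment begins (default 100, after the
#'   no-treatment system has reached its equilibrium).
#' @param cycle_duration,days_on Cycle length and on-time in days (cycled
#'   schedules). `days_on` must be strictly less than `cycle_duration`
#'   (on-time equal to or exceeding the cycle is just continuous treatment
#'   and is rejected); it is ignored for cycled depletion, which acts
#'   instantaneously at each cycle start.
#' @return Object of class `"treatment_spec"`.
#' @export
treatment_spec <- function(strategy = c("depletion", "recruitment_inhibition",
                                        "pi3k_inhibition"),
                           strength, schedule = c("continuous", "cycled"),
                           start_day = 100, cycle_duration = NULL,
                           days_on = NULL) {
  strategy <- match.arg(strategy)
  schedule <- match.arg(schedule)
  stopifnot(length(strength) == 1, strength >= 0, strength <= 1,
            start_day >= 0)
  if (schedule == "cycled") {
    if (is.null(cycle_duration) || cycle_duration <= 0) {
      stop("cycled schedule needs a positive cycle_duration")
    }
    if (strategy == "depletion") {
      days_on <- 0
    } else {
      if (is.null(days_on) || days_on <= 0) {
        stop("cycled schedule needs a positive days_on")
      }
      if (days_on >= cycle_duration) {
        stop("days_on must be < cycle_duration")
      }
    }
  }
  structure(list(strategy = strategy, strength = strength,
                 schedule = schedule, start_day = start_day,
                 cycle_duration = cycle_duration, days_on = days_on),
            class = "treatment_spec")
}

#' @export
print.treatment_spec <- function(x, ...) {
  sched <- if (x$schedule == "continuous") "continuous" else {
    sprintf("cycled (%g d cycle, %g d on)", x$cycle_duration,
            if (x$strategy == "depletion") 0 else x$days_on)
  }
  cat(sprintf("<treatment_spec> %s, strength %g, %s, start day %g\n",
              x$strategy, x$strength, sched, x$start_day))
  invisible(x)
}

#' Is treatment on at time t?
#'
#' A pure function of time: off before the start day; continuous schedules
#' are on forever after; cycled schedules are on while
#' `(t - start_day) mod cycle_duration < days_on`.
#'
#' @param spec A [treatment_spec()].
#' @param t Time(s) in days (>= 0).
#' @return Logical vector.
#' @export
treatment_active <- function(spec, t) {
  stopifnot(inherits(spec, "treatment_spec"), all(t >= 0))
  if (spec$schedule == "continuous") return(t >= spec$start_day)
  phase <- (t - spec$start_day) %% spec$cycle_duration
  t >= spec$start_day & phase < spec$days_on - 1e-9
}

#' Continuous depletion: independent per-step removal
#'
#' While treatment is on, every macrophage (any phenotype, equal
#' probability) is independently removed with probability `p` this step.
#'
#' @param state A `tme_state`.
#' @param p Per-step removal probability.
#' @return Number of macrophages removed (invisibly).
#' @export
deplete_continuous <- function(state, p) {
  live <- which(state$mac$alive)
  if (length(live) == 0 || p <= 0) return(invisible(0L))
  hit <- live[runif(length(live)) < p]
  for (i in hit) {
    state$occ_kind[state$mac$row[i], state$mac$col[i]] <- OCC_EMPTY
    state$occ_id[state$mac$row[i], state$mac$col[i]] <- 0L
    state$mac$alive[i] <- FALSE
  }
  invisible(length(hit))
}

#' Cycled depletion: remove an exact fraction at cycle start
#'
#' Removes `round(frac * N)` macrophages (rounding to nearest, ties up),
#' sampled uniformly without replacement and blind to phenotype.
#'
#' @param state A `tme_state`.
#' @param frac Fraction in `[0, 1]`.
#' @return Number removed (invisibly).
#' @export
deplete_fraction <- function(state, frac) {
  live <- which(state$mac$alive)
  n_remove <- floor(frac * length(live) + 0.5)
  if (n_remove <= 0) return(invisible(0L))
  hit <- live[sample.int(length(live), n_remove)]
  for (i in hit) {
    state$occ_kind[state$mac$row[i], state$mac$col[i]] <- OCC_EMPTY
    state$occ_id[state$mac$row[i], state$mac$col[i]] <- 0L
    state$mac$alive[i] <- FALSE
  }
  invisible(as.integer(n_remove))
}

#' Effective recruitment inhibition at time t
#'
#' @param spec A [treatment_spec()] (or `NULL` for no treatment).
#' @param t Time in days.
#' @return The inhibition fraction forwarded to [recruit_macrophages()]:
#'   `strength` while a recruitment-inhibition treatment is on, else 0.
#' @export
apply_recruitment_inhibition <- function(spec, t) {
  if (is.null(spec) || spec$strategy != "recruitment_inhibition") return(0)
  if (treatment_active(spec, t)) spec$strength else 0
}

#' Effective PI3K activity at time t
#'
#' @param spec A [treatment_spec()] (or `NULL`).
#' @param t Time in days.
#' @return `1 - strength` while a PI3K-inhibition treatment is on, else 1.
#'   This value feeds every macrophage differentiation/redifferentiation
#'   query; the treatment touches nothing else (not survival, not
#'   recruitment).
#' @export
apply_pi3k_inhibition <- function(spec, t) {
  if (is.null(spec) || spec$strategy != "pi3k_inhibition") return(1)
  if (treatment_active(spec, t)) 1 - spec$strength else 1
}
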