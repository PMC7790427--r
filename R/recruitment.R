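## Immune-cell influx.
##
## T cells: cancer-cell deaths (any cause) release tumor antigen; after a
## priming/trafficking delay the death count over a window drives a
## saturating recruitment rate. Macrophages: constant-rate recruitment,
## reducible by recruitment-inhibition therapy. Fractional expected arrivals
## are handled by a deterministic carry accumulator so long-run arrivals
## per unit time match the rate exactly; recruits land on uniformly random
## empty sites.

#' Windowed cancer-death count
#'
#' Sums logged cancer-cell deaths whose times fall in the closed interval
#' `[t - t_delay - t_window/2, t - t_delay + t_window/2]` (days).
#'
#' @param death_log Data frame with columns `time` (days, non-decreasing)
#'   and `count` (>= 1).
#' @param t Current simulation time in days (>= 0).
#' @param params List with `t_delay_day` and `t_window_day`.
#' @return Total death count in the window.
#' @export
windowed_deaths <- function(death_log, t, params) {
  stopifnot(t >= 0)
  if (nrow(death_log) == 0) return(0)
  center <- t - params$t_delay_day
  lo <- center - params$t_window_day / 2
  hi <- center + params$t_window_day / 2
  tol <- 1e-9
  sum(death_log$count[death_log$time >= lo - tol & death_log$time <= hi + tol])
}

#' T-cell recruitment rate
#'
#' `rate = ka * N_death * r1 / (ki + N_death)`: proportional to the mutational
#' burden `ka` and the basal rate `r1`, saturating in the windowed death
#' count with half-saturation `ki` (the neoantigen strength).
#'
#' @param n_death Windowed cancer-death count (>= 0).
#' @param params List with `ka`, `r1_day`, `ki`.
#' @return Recruitment rate in cells/day; bounded by `ka * r1`.
#' @export
tcell_recruitment_rate <- function(n_death, params) {
  stopifnot(all(n_death >= 0), params$ki > 0)
  params$ka * n_death * params$r1_day / (params$ki + n_death)
}

#' Place recruited cells on random empty sites
#'
#' Converts a fractional expected arrival count into integer arrivals with a
#' persistent carry (`arrivals = floor(expected + carry)`, remainder kept
#' for later steps, so nothing is lost in the long run). Each recruit is
#' placed on a uniformly random empty site; if the lattice cannot hold them
#' all, as many as fit are placed and the shortfall is recorded (recruitment
#' declines inherently as the tumor fills the lattice).
#'
#' @param count_expected Expected arrivals this step (>= 0).
#' @param state A `tme_state`.
#' @param kind `"macrophage"` or `"tcell"`.
#' @param carry Fractional carry from previous steps.
#' @param init Named list of extra agent fields for new recruits (e.g.
#'   `kills` for T cells).
#' @return List with `placed` (count), `shortfall`, and updated `carry`.
#' @export
place_recruits <- function(count_expected, state, kind, carry = 0,
                           init = list()) {
  stopifnot(count_expected >= 0)
  total <- count_expected + carry
  arrivals <- floor(total + 1e-9)
  carry <- total - arrivals
  placed <- 0L
  shortfall <- 0L
  if (arrivals > 0) {
    empties <- empty_sites(state)
    n_fit <- min(arrivals, nrow(empties))
    shortfall <- as.integer(arrivals - n_fit)
    if (n_fit > 0) {
      pick <- sample.int(nrow(empties), n_fit)
      for (p in pick) {
        do.call(add_agent, c(list(state, kind, empties[p, 1], empties[p, 2]),
                             init))
      }
      placed <- as.integer(n_fit)
    }
  }
  list(placed = placed, shortfall = shortfall, carry = carry)
}

#' Recruit naive macrophages
#'
#' Arrivals follow `macrophage_recruitment_rate * (1 - inhibition)`; new
#' cells enter in the naive (M0) state with their redifferentiation clock
#' elapsed, so they differentiate as soon as the local activation factor
#' licenses it. Placement is uniform over all empty sites, so most recruits
#' enter far from the tumor.
#'
#' @param params List with `mac_recruitment_rate_day` and `rediff_period_h`.
#' @param state A `tme_state`.
#' @param dt_h Step length in hours.
#' @param inhibition Fraction in `[0, 1]` by which the rate is reduced
#'   (1 = complete inhibition).
#' @return As [place_recruits()].
#' @export
recruit_macrophages <- function(params, state, dt_h, inhibition = 0) {
  stopifnot(inhibition >= 0, inhibition <= 1)
  expected <- params$mac_recruitment_rate_day * (1 - inhibition) * dt_h / 24
  res <- place_recruits(expected, state, "macrophage", carry = state$carry_mac,
                        init = list(phen = 0L,
                                    clock = params$rediff_period_h))
  state$carry_mac <- res$carry
  res
}

#' Recruit T cells from the logged cancer deaths
#'
#' Evaluates the windowed death count and saturating rate at the current
#' simulation time, then places the integer arrivals (carry-accumulated) on
#' random empty sites. New T cells enter naive with a full kill budget.
#'
#' @param params List with the recruitment constants and `tc_max_kills`.
#' @param state A `tme_state`.
#' @param dt_h Step length in hours.
#' @return As [place_recruits()].
#' @export
recruit_tcells <- function(params, state, dt_h) {
  n_death <- windowed_deaths(state$death_log, state$time_h / 24, params)
  rate <- tcell_recruitment_rate(n_death, params)
  expected <- rate * dt_h / 24
  res <- place_recruits(expected, state, "tcell", carry = state$carry_tc,
                        init = list(state = 0L,
                                    kills = as.integer(params$tc_max_kills)))
  state$carry_tc <- res$carry
  res
}
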