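## The simulation loop: parameters, initialization, the 8-phase step
## ordering, stopping rules, RNG discipline and time-course recording.
##
## One RNG stream per run: run_simulation() seeds R's generator once and
## every stochastic draw (R level and compiled phases alike) comes from that
## stream, so (seed, params, treatment) fully determine every output byte.

#' Simulation parameters
#'
#' All rates and constants of the model, with calibrated defaults. Any
#' subset can be overridden via `...`. Time step is `dt_h` hours (per-step
#' probabilities are documented as dt-dependent); per-day rates are
#' converted internally.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return Object of class `"sim_params"` (a validated list).
#'
#' @section Parameters:
#' \describe{
#'   \item{n_row, n_col, site_length_um}{Lattice: 100 x 100 sites of 15 um
#'     (a 1.5 x 1.5 mm tissue slice).}
#'   \item{dt_h}{Step length in hours (1).}
#'   \item{max_days, tumor_cap}{Stopping rules: 200 days, or 5000 cancer
#'     cells (space-saturation cutoff).}
#'   \item{initial_cancer, resident_mac_density}{25 cancer cells in a
#'     centered block; resident M0 macrophages scattered at 2e-3 cells/site.}
#'   \item{proliferation_rate_day}{Cancer divisions per day (0.8; the
#'     division period is 24/rate hours). Variant analyses use 1.2.}
#'   \item{ca_lifespan_mode, ca_max_divisions, ca_lifespan_h}{Cancer
#'     lifespan as a division budget (default, 10) or an age in hours.}
#'   \item{mac_lifespan_h, mac_recruitment_rate_day, act_threshold,
#'     rediff_period_h}{Macrophage lifespan (240 h), influx (cells/day),
#'     the activation-factor level licensing differentiation, and the 24-h
#'     redifferentiation clock.}
#'   \item{chemo_floor, act_sat}{Chemotactic sensing floor and
#'     receptor-saturation ceiling on the activation-factor field
#'     (molecules/site): below the floor cells random-walk instead of homing
#'     onto vanishing field tails; above the ceiling gradients are not
#'     sensed, so cells near the tumor churn locally instead of piling into
#'     a static shell.}
#'   \item{tc_lifespan_h, tc_max_kills, engage_duration_h,
#'     tc_division_period_h}{T-cell lifespan (120 h), kill budget (3),
#'     engagement duration per kill (6 h), active-cell division period
#'     (24 h).}
#'   \item{act_k, act_s}{Activation-sigmoid steepness and shift (4.4, 0.5):
#'     with no macrophage neighbors P is about 0.9 and it drops to 0.1
#'     already at numM2/(numM1+1) = 1, well below 0.1 at ratio 3.}
#'   \item{activation_enabled}{Set `FALSE` to disable T-cell activation
#'     entirely (immune cells present but without function).}
#'   \item{ka, r1_day, ki, t_delay_day, t_window_day}{T-cell recruitment:
#'     mutational burden (1), basal rate (30 cells/day), neoantigen
#'     half-saturation (50 deaths), priming delay (3 d), accumulation
#'     window (1 d).}
#'   \item{D_um2_s, decay_s}{Per-factor diffusivities (um^2/s) and
#'     first-order decay rates (1/s).}
#'   \item{ksec_act_tumor, ksec_il4_tumor, ksec_il4_m2, ksec_ifng_tcell}{
#'     Secretion rates, molecules/s per secreting cell.}
#'   \item{pi3k_activity}{Baseline PI3K activity (1; lowered by
#'     reeducation therapy).}
#'   \item{readout}{Local cytokine readout: `"site"` or
#'     `"neighborhood_mean"`.}
#'   \item{movement_kind}{Neighborhood for movement and contact
#'     interactions.}
#'   \item{record_every_h}{Time-course recording cadence (1 h).}
#'   \item{seed}{Default RNG seed for [run_simulation()].}
#' }
#' @export
sim_params <- function(...) {
  p <- list(
    n_row = 100L, n_col = 100L, site_length_um = 15,
    dt_h = 1, max_days = 200, tumor_cap = 5000L,
    initial_cancer = 25L, resident_mac_density = 2e-3,
    proliferation_rate_day = 0.8,
    ca_lifespan_mode = "hours", ca_max_divisions = 10L,
    ca_lifespan_h = 300,
    mac_lifespan_h = 240, mac_recruitment_rate_day = 6,
    act_threshold = 1, chemo_floor = 1, act_sat = 30,
    rediff_period_h = 24,
    tc_lifespan_h = 120, tc_max_kills = 3L, engage_duration_h = 6,
    tc_division_period_h = 24,
    act_k = 4.4, act_s = 0.5, activation_enabled = TRUE,
    ka = 1, r1_day = 30, ki = 50, t_delay_day = 3, t_window_day = 1,
    D_um2_s = c(act = 3, il4 = 3, ifng = 3),
    decay_s = c(act = 5e-4, il4 = 1e-4, ifng = 1e-4),
    ksec_act_tumor = 0.05, ksec_il4_tumor = 0.02, ksec_il4_m2 = 0.01,
    ksec_ifng_tcell = 0.05,
    pi3k_activity = 1,
    readout = "site",
    movement_kind = "moore_8",
    record_every_h = 1,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p[names(over)] <- over
  stopifnot(p$dt_h > 0, p$max_days > 0, p$tumor_cap >= 1,
            p$resident_mac_density >= 0, p$resident_mac_density <= 1,
            p$proliferation_rate_day > 0, p$ki > 0,
            all(p$D_um2_s >= 0), all(p$decay_s >= 0),
            p$ca_lifespan_mode %in% c("divisions", "hours"),
            p$readout %in% c("site", "neighborhood_mean"),
            p$movement_kind %in% c("moore_8", "von_neumann_4"))
  p$ca_period_h <- 24 / p$proliferation_rate_day
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0("<sim_params> %dx%d lattice, dt %g h, %g d max, ",
                     "proliferation %g/day, mac recruitment %g/day\n"),
              x$n_row, x$n_col, x$dt_h, x$max_days,
              x$proliferation_rate_day, x$mac_recruitment_rate_day))
  invisible(x)
}

#' Initialize the model state
#'
#' Places the initial cancer cells in a compact centered block (a
#' micrometastasis) and scatters resident naive macrophages over the
#' remaining sites, each site independently occupied with probability
#' `resident_mac_density`. Founder cancer cells start at uniformly random
#' cell-cycle phases and ages, and residents at uniformly random ages, so
#' the initial population is desynchronized (no artificial division or
#' death waves). Fields start at zero; no T cells are present. Uses the
#' current RNG stream (seed it, or let [run_simulation()] do so).
#'
#' @param params A [sim_params()].
#' @return A `tme_state`.
#' @export
initialize_state <- function(params) {
  side <- ceiling(sqrt(params$initial_cancer))
  if (side > min(params$n_row, params$n_col)) {
    stop("initial cancer block exceeds lattice")
  }
  st <- new_lattice(params$n_row, params$n_col, params$site_length_um,
                    params$movement_kind)
  r0 <- floor((params$n_row - side) / 2)
  c0 <- floor((params$n_col - side) / 2)
  placed <- 0L
  for (i in seq_len(side)) {
    for (j in seq_len(side)) {
      if (placed >= params$initial_cancer) break
      add_agent(st, "cancer", r0 + i, c0 + j,
                clock = runif(1, 0, params$ca_period_h),
                age = runif(1, 0, params$ca_lifespan_h))
      placed <- placed + 1L
    }
  }
  if (params$resident_mac_density > 0) {
    open <- empty_sites(st)
    hit <- which(runif(nrow(open)) < params$resident_mac_density)
    for (k in hit) {
      add_agent(st, "macrophage", open[k, 1], open[k, 2], phen = 0L,
                clock = params$rediff_period_h,
                age = runif(1, 0, params$mac_lifespan_h))
    }
  }
  st
}

## Internal: secretion source table for the current state. Engaged cells
## undergo no other processes, so they do not secrete.
secretion_sources <- function(state, params) {
  ca_on <- state$ca$alive & state$ca$engaged == 0L
  m2_on <- state$mac$alive & state$mac$phen == 2L
  tc_on <- state$tc$alive & state$tc$state == 1L & state$tc$engaged == 0L
  n <- c(sum(ca_on), sum(ca_on), sum(m2_on), sum(tc_on))
  list(
    row = c(state$ca$row[ca_on], state$ca$row[ca_on],
            state$mac$row[m2_on], state$tc$row[tc_on]),
    col = c(state$ca$col[ca_on], state$ca$col[ca_on],
            state$mac$col[m2_on], state$tc$col[tc_on]),
    factor = rep(c("act", "il4", "il4", "ifng"), n),
    rate = rep(c(params$ksec_act_tumor, params$ksec_il4_tumor,
                 params$ksec_il4_m2, params$ksec_ifng_tcell), n))
}

## Internal: drop dead agents, remapping occupancy indices and engagement
## links (engaged partners are always alive, so links survive compaction).
compact_state <- function(state) {
  keep_map <- list()
  for (tab_name in c("ca", "mac", "tc")) {
    tab <- state[[tab_name]]
    keep <- which(tab$alive)
    map <- integer(length(tab$alive))
    map[keep] <- seq_along(keep)
    keep_map[[tab_name]] <- map
    state[[tab_name]] <- lapply(tab, function(v) v[keep])
  }
  ## remap cross-links
  eng <- state$tc$engaged
  state$tc$engaged <- ifelse(eng > 0L, keep_map$ca[pmax(eng, 1L)], 0L)
  eng <- state$ca$engaged
  state$ca$engaged <- ifelse(eng > 0L, keep_map$tc[pmax(eng, 1L)], 0L)
  ## rebuild occupancy from the tables
  state$occ_kind[] <- OCC_EMPTY
  state$occ_id[] <- 0L
  for (kind_code in c(OCC_CANCER, OCC_MAC, OCC_TCELL)) {
    tab <- state[[agent_table_name(kind_code)]]
    if (length(tab$row) > 0) {
      state$occ_kind[cbind(tab$row, tab$col)] <- kind_code
      state$occ_id[cbind(tab$row, tab$col)] <- seq_along(tab$row)
    }
  }
  invisible(state)
}

## Internal: one time-course record.
record_row <- function(state, treatment_on) {
  cnt <- agent_counts(state)
  c(time_d = state$time_h / 24,
    n_cancer = cnt[["cancer"]], n_m0 = cnt[["m0"]], n_m1 = cnt[["m1"]],
    n_m2 = cnt[["m2"]], n_tcell = cnt[["tcell"]],
    n_tcell_active = cnt[["tcell_active"]],
    il4_mean = mean(state$fields$il4), il4_max = max(state$fields$il4),
    ifng_mean = mean(state$fields$ifng), ifng_max = max(state$fields$ifng),
    treatment_on = as.integer(treatment_on))
}

#' Advance the simulation by one step
#'
#' Phase order: (1) secretion then diffusion/decay of the three fields for
#' `dt_h`; (2) macrophage recruitment (treatment-adjusted); (3) macrophages
#' act in random order; (4) T-cell recruitment from the death log, then T
#' cells act in random order (engagements resolve first); (5) cancer cells
#' act in random order; (6) dead agents are removed; (7) treatment events
#' (continuous depletion draws; cycle-start bulk depletion); (8) record.
#'
#' @param state A `tme_state` (mutated in place).
#' @param params A [sim_params()].
#' @param treatment A [treatment_spec()] or `NULL`.
#' @param surrogate A trained [train_surrogate()] model.
#' @return The state, invisibly.
#' @export
sim_step <- function(state, params, treatment = NULL,
                     surrogate = default_surrogate()) {
  dt_h <- params$dt_h
  dt_s <- dt_h * 3600
  t_day <- state$time_h / 24
  off <- neighborhood_offsets(params$movement_kind)
  on_now <- !is.null(treatment) && treatment_active(treatment, t_day)

  ## (1) secretion + diffusion
  src <- secretion_sources(state, params)
  if (length(src$row) > 0) state$fields <- secrete(state$fields, src, dt_s)
  state$fields <- diffuse_step(state$fields, dt_s, params$D_um2_s,
                               params$decay_s, params$site_length_um)

  ## (2) macrophage recruitment (inhibition applies while that therapy is on)
  inhib <- apply_recruitment_inhibition(treatment, t_day)
  recruit_macrophages(params, state, dt_h, inhib)

  ## (3) macrophage phase
  n_mac <- length(state$mac$row)
  if (n_mac > 0) {
    pi3k <- apply_pi3k_inhibition(treatment, t_day) * params$pi3k_activity
    res <- cpp_macrophage_phase(
      sample.int(n_mac), state$mac, state$occ_kind, state$occ_id,
      state$fields$act, state$fields$il4, state$fields$ifng,
      unclass(surrogate),
      list(dt_h = dt_h, mac_lifespan_h = params$mac_lifespan_h,
           act_threshold = params$act_threshold,
           chemo_floor = params$chemo_floor, act_sat = params$act_sat,
           rediff_period_h = params$rediff_period_h,
           pi3k_activity = pi3k, offsets = off))
    state$mac <- res$mac
    state$occ_kind <- res$occ_kind
    state$occ_id <- res$occ_id
  }

  ## (4) T-cell recruitment then T-cell phase
  recruit_tcells(params, state, dt_h)
  n_tc <- length(state$tc$row)
  n_kills <- 0L
  if (n_tc > 0) {
    res <- cpp_tcell_phase(
      sample.int(n_tc), state$tc, state$ca, state$occ_kind, state$occ_id,
      state$fields$act,
      list(dt_h = dt_h, tc_lifespan_h = params$tc_lifespan_h,
           act_k = params$act_k, act_s = params$act_s,
           engage_duration_h = params$engage_duration_h,
           tc_max_kills = as.integer(params$tc_max_kills),
           tc_p_divide = dt_h / params$tc_division_period_h,
           activation_enabled = isTRUE(params$activation_enabled),
           chemo_floor = params$chemo_floor, act_sat = params$act_sat,
           offsets = off, mac_phen = state$mac$phen))
    state$tc <- res$tc
    state$ca$engaged <- res$ca_engaged
    state$ca$alive <- res$ca_alive
    state$occ_kind <- res$occ_kind
    state$occ_id <- res$occ_id
    n_kills <- res$n_kills
  }

  ## (5) cancer phase
  n_ca_deaths <- 0L
  n_ca <- length(state$ca$row)
  if (n_ca > 0) {
    res <- cpp_cancer_phase(
      sample.int(n_ca), state$ca, state$occ_kind, state$occ_id,
      list(dt_h = dt_h, ca_period_h = params$ca_period_h,
           ca_lifespan_mode = params$ca_lifespan_mode,
           ca_max_divisions = as.integer(params$ca_max_divisions),
           ca_lifespan_h = params$ca_lifespan_h, offsets = off))
    state$ca <- res$ca
    state$occ_kind <- res$occ_kind
    state$occ_id <- res$occ_id
    n_ca_deaths <- res$n_deaths
  }

  ## advance the clock; deaths are logged at the time they occurred
  state$time_h <- state$time_h + dt_h
  deaths <- n_kills + n_ca_deaths
  if (deaths > 0) {
    state$death_log <- rbind(state$death_log,
                             data.frame(time = state$time_h / 24,
                                        count = deaths))
  }

  ## (6) remove dead agents
  compact_state(state)

  ## (7) treatment events
  if (!is.null(treatment) && treatment$strategy == "depletion") {
    t_now <- state$time_h / 24
    if (treatment$schedule == "continuous") {
      if (treatment_active(treatment, t_now)) {
        deplete_continuous(state, treatment$strength)
      }
    } else if (t_now >= treatment$start_day) {
      cycle <- floor((t_now - treatment$start_day) / treatment$cycle_duration)
      if (cycle > state$last_depletion_cycle) {
        state$last_depletion_cycle <- as.integer(cycle)
        deplete_fraction(state, treatment$strength)
      }
    }
    compact_state(state)
  }

  invisible(state)
}

#' Run a full simulation
#'
#' Repeats [sim_step()] until the tumor is eliminated (0 cancer cells),
#' the cell count reaches `tumor_cap`, or `max_days` of simulated time
#' elapse. Seeds the RNG once at the start, so identical
#' (seed, params, treatment) reproduce the run byte for byte.
#'
#' @param params A [sim_params()].
#' @param treatment A [treatment_spec()] or `NULL` for no treatment.
#' @param surrogate A trained surrogate; defaults to the packaged one.
#' @param seed RNG seed (defaults to `params$seed`).
#' @return Object of class `"tme_run"`: `timecourse` (data frame, one row
#'   per recording time), `summary` (outcome `"eliminated"`, `"capped"` or
#'   `"persisted"`; elimination time; maxima of M1, total T and active T
#'   counts over the treatment window), `params`, `treatment`, `seed`.
#' @export
run_simulation <- function(params = sim_params(), treatment = NULL,
                           surrogate = NULL, seed = params$seed) {
  if (is.null(surrogate)) surrogate <- default_surrogate()
  set.seed(seed)
  state <- initialize_state(params)
  n_steps <- ceiling(params$max_days * 24 / params$dt_h)
  rec_every <- max(1L, round(params$record_every_h / params$dt_h))
  rows <- vector("list", n_steps + 1L)
  rows[[1]] <- record_row(state, FALSE)
  n_rec <- 1L
  outcome <- "persisted"
  elim_time <- NA_real_
  for (k in seq_len(n_steps)) {
    sim_step(state, params, treatment, surrogate)
    t_day <- state$time_h / 24
    on_now <- !is.null(treatment) && treatment_active(treatment, t_day)
    if (k %% rec_every == 0L || k == n_steps) {
      n_rec <- n_rec + 1L
      rows[[n_rec]] <- record_row(state, on_now)
    }
    n_cancer <- sum(state$ca$alive)
    if (n_cancer == 0L) {
      outcome <- "eliminated"
      elim_time <- t_day
      if (k %% rec_every != 0L && k != n_steps) {
        n_rec <- n_rec + 1L
        rows[[n_rec]] <- record_row(state, on_now)
      }
      break
    }
    if (n_cancer >= params$tumor_cap) {
      outcome <- "capped"
      break
    }
  }
  tc <- as.data.frame(do.call(rbind, rows[seq_len(n_rec)]))
  win_start <- if (is.null(treatment)) 0 else treatment$start_day
  win <- tc[tc$time_d >= win_start, , drop = FALSE]
  if (nrow(win) == 0) win <- tc[nrow(tc), , drop = FALSE]
  summary <- list(
    outcome = outcome,
    elimination_time_d = elim_time,
    time_from_treatment_d = if (!is.na(elim_time)) {
      max(0, elim_time - win_start)
    } else NA_real_,
    max_m1 = max(win$n_m1), max_tcell = max(win$n_tcell),
    max_tcell_active = max(win$n_tcell_active),
    final_cancer = tc$n_cancer[nrow(tc)])
  structure(list(timecourse = tc, summary = summary, params = params,
                 treatment = treatment, seed = seed, state = state),
            class = "tme_run")
}

#' @export
print.tme_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<tme_run> seed %s: %s (final tumor %d cells; ",
                     "max M1 %d, max T %d, max active T %d)\n"),
              format(x$seed), s$outcome, s$final_cancer, s$max_m1,
              s$max_tcell, s$max_tcell_active))
  if (!is.na(s$elimination_time_d)) {
    cat(sprintf("  eliminated at day %.2f\n", s$elimination_time_d))
  }
  invisible(x)
}
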