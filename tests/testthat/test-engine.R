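test_that("initialization places the tumor block and resident macrophages", {
  p <- sim_params()
  set.seed(1)
  st <- initialize_state(p)
  cnt <- agent_counts(st)
  expect_equal(unname(cnt["cancer"]), 25L)
  expect_equal(unname(cnt["tcell"]), 0L)
  # compact centered 5x5 block
  expect_equal(max(st$ca$row) - min(st$ca$row), 4L)
  expect_equal(max(st$ca$col) - min(st$ca$col), 4L)
  expect_lt(abs(mean(st$ca$row) - 50.5), 3)
  # ~20 resident macrophages (binomial, n ~ 9975, p = 2e-3), all M0
  expect_gt(unname(cnt["m0"]), 5)
  expect_lt(unname(cnt["m0"]), 45)
  expect_true(all(st$mac$phen == 0L))
  expect_true(all(st$fields$act == 0))
  audit_occupancy(st)

  # density 0 -> no macrophages; fixed seed -> identical initial state
  set.seed(2)
  st0 <- initialize_state(sim_params(resident_mac_density = 0))
  expect_equal(sum(st0$mac$alive), 0L)
  set.seed(3); a <- initialize_state(p)
  set.seed(3); b <- initialize_state(p)
  expect_identical(a$occ_kind, b$occ_kind)

  expect_error(initialize_state(sim_params(n_row = 4L, n_col = 4L)),
               "exceeds lattice")
})

test_that("an empty lattice is a fixed point of the step (time advances)", {
  p <- quiet_params(initial_cancer = 1L)
  st <- bare_state(9)
  sur <- test_surrogate()
  set.seed(1)
  before <- list(occ = st$occ_kind, f = st$fields)
  sim_step(st, p, NULL, sur)
  expect_equal(st$time_h, 1)
  expect_identical(st$occ_kind, before$occ)
  expect_equal(st$fields, before$f)
})

test_that("identical seed and params reproduce the run exactly", {
  p <- sim_params(n_row = 30, n_col = 30, max_days = 6)
  sur <- test_surrogate()
  a <- run_simulation(p, NULL, sur, seed = 13)
  b <- run_simulation(p, NULL, sur, seed = 13)
  expect_identical(a$timecourse, b$timecourse)
  expect_identical(a$summary, b$summary)
  c <- run_simulation(p, NULL, sur, seed = 14)
  expect_false(identical(a$timecourse, c$timecourse))
})

test_that("occupancy and engagement invariants hold across engine steps", {
  p <- sim_params(n_row = 30, n_col = 30)
  sur <- test_surrogate()
  set.seed(31)
  st <- initialize_state(p)
  for (k in 1:120) {
    sim_step(st, p, NULL, sur)
    if (k %% 10 == 0) {
      audit_occupancy(st)
      expect_engagement_matching(st)
      expect_true(all(st$tc$kills >= 0L))
      expect_true(all(st$tc$state[st$tc$kills == 0L & st$tc$alive] == 2L))
    }
  }
})

test_that("a lone tumor with immune action disabled grows to the cap", {
  p <- sim_params(n_row = 20, n_col = 20, resident_mac_density = 0,
                  mac_recruitment_rate_day = 0, r1_day = 0,
                  tumor_cap = 120L, max_days = 30, ca_lifespan_h = 1e6)
  sur <- test_surrogate()
  run <- run_simulation(p, NULL, sur, seed = 2)
  expect_equal(run$summary$outcome, "capped")
  expect_true(all(diff(run$timecourse$n_cancer) >= 0))  # pure growth
})

test_that("a non-dividing tumor dies out by lifespan", {
  p <- sim_params(n_row = 20, n_col = 20, resident_mac_density = 0,
                  mac_recruitment_rate_day = 0, r1_day = 0,
                  proliferation_rate_day = 1e-6, ca_lifespan_h = 48,
                  initial_cancer = 4L, max_days = 10)
  sur <- test_surrogate()
  run <- run_simulation(p, NULL, sur, seed = 2)
  expect_equal(run$summary$outcome, "eliminated")
  # founders start at random ages, so extinction lands within the lifespan
  expect_lte(run$summary$elimination_time_d, 2)
  expect_gte(run$summary$elimination_time_d, 1)
})

test_that("removing all T cells lets IFN-gamma decay monotonically to zero", {
  p <- quiet_params(decay_s = c(act = 0, il4 = 0, ifng = 5e-4),
                    D_um2_s = c(act = 0, il4 = 0, ifng = 3))
  st <- bare_state(11)
  st$fields$ifng[6, 6] <- 100
  sur <- test_surrogate()
  set.seed(1)
  tot <- numeric(12)
  for (k in 1:12) {
    sim_step(st, p, NULL, sur)
    tot[k] <- sum(st$fields$ifng)
  }
  expect_true(all(diff(tot) < 0))
  expect_lt(tot[12], 100 * exp(-5e-4 * 3600 * 11))
})

test_that("time-course records counts, field statistics and treatment state", {
  p <- sim_params(n_row = 30, n_col = 30, max_days = 3)
  sur <- test_surrogate()
  spec <- treatment_spec("pi3k_inhibition", 0.5, "continuous", start_day = 2)
  run <- run_simulation(p, spec, sur, seed = 4)
  tc <- run$timecourse
  expect_equal(nrow(tc), 3 * 24 + 1)
  expect_true(all(tc$n_cancer == floor(tc$n_cancer) & tc$n_cancer >= 0))
  expect_equal(tc$treatment_on, as.integer(tc$time_d >= 2))
  expect_true(all(tc$il4_max >= tc$il4_mean))

  # serialization round-trips
  f <- tempfile(fileext = ".csv")
  write_timecourse(run, f)
  back <- read.csv(f)
  expect_equal(back$n_cancer, tc$n_cancer)
  js <- tempfile(fileext = ".json")
  write_summary_json(run, js)
  expect_equal(jsonlite::read_json(js)$outcome, run$summary$outcome)
})

test_that("lattice snapshots code every agent kind", {
  st <- bare_state(5)
  add_agent <- tmesim:::add_agent
  add_agent(st, "cancer", 1, 1)
  add_agent(st, "macrophage", 2, 2, phen = 1L)
  add_agent(st, "macrophage", 2, 3, phen = 2L)
  add_agent(st, "tcell", 3, 3, state = 1L)
  add_agent(st, "tcell", 4, 4)
  g <- snapshot_grid(st)
  expect_equal(g[1, 1], "C")
  expect_equal(g[2, 2], "1")
  expect_equal(g[2, 3], "2")
  expect_equal(g[3, 3], "A")
  expect_equal(g[4, 4], "T")
  expect_equal(sum(g != "."), 5)
  f <- tempfile(fileext = ".csv")
  write_snapshot_csv(st, f)
  expect_equal(nrow(read.csv(f, header = FALSE)), 5)
})
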