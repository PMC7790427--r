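test_that("activation probability follows the macrophage-weighted sigmoid", {
  # multiplicative antigen gate
  expect_equal(activation_probability(0, 0, 5), 0)
  expect_equal(activation_probability(0, 10, 0), 0)

  # closed form with no macrophage neighbors
  k <- 4.4; s <- 0.5
  expect_equal(activation_probability(1, 0, 0, k, s),
               1 / (1 + exp(-k * (1 - s))))
  # shipped defaults give ~0.9 with no macrophages, < 0.1 at ratio >= 1
  expect_gt(activation_probability(1, 0, 0), 0.85)
  expect_lt(activation_probability(1, 0, 1), 0.11)
  expect_lt(activation_probability(1, 1, 6), 0.1)

  # strictly non-increasing in numM2 at fixed numM1
  p <- activation_probability(1, 2, 0:10)
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 1))

  expect_error(activation_probability(1, 0, 0, k = -1))
})

test_that("cancer cells divide at the period set by the proliferation rate", {
  # 0.8 divisions/day -> 30 h period
  expect_equal(sim_params(proliferation_rate_day = 0.8)$ca_period_h, 30)
  expect_equal(sim_params(proliferation_rate_day = 1.2)$ca_period_h, 20)

  p <- quiet_params(ca_lifespan_h = 1e6)
  set.seed(5)
  st <- bare_state(11)
  tmesim:::add_agent(st, "cancer", 6, 6)  # cycle phase zero
  sur <- test_surrogate()
  for (k in 1:29) sim_step(st, p, NULL, sur)
  expect_equal(sum(st$ca$alive), 1L)
  sim_step(st, p, NULL, sur)   # clock reaches 30 h
  expect_equal(sum(st$ca$alive), 2L)
  audit_occupancy(st)
})

test_that("surrounded cells go quiescent and resume when space opens", {
  p <- quiet_params(ca_lifespan_h = 1e6)
  st <- bare_state(11)
  add_agent <- tmesim:::add_agent
  # center cell about to divide, ring of fresh cancer cells blocking it
  center <- add_agent(st, "cancer", 6, 6, clock = 29.5)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr != 0 || dc != 0) add_agent(st, "cancer", 6 + dr, 6 + dc)
  }
  sur <- test_surrogate()
  set.seed(8)
  sim_step(st, p, NULL, sur)
  i <- st$occ_id[6, 6]
  expect_true(st$ca$quiescent[i])
  expect_equal(sum(st$ca$alive), 9L)

  # open a site next to the center: the quiescent cell divides on a later step
  j <- st$occ_id[5, 5]
  st$ca$alive[j] <- FALSE
  tmesim:::compact_state(st)
  # freeze the ring so only the center can act
  st$ca$clock[st$occ_id[6, 6]] <- 40   # already past period; stays frozen
  others <- setdiff(seq_along(st$ca$row), st$occ_id[6, 6])
  st$ca$clock[others] <- -1e5
  sim_step(st, p, NULL, sur)
  expect_equal(sum(st$ca$alive), 9L)       # 8 ring - 1 + center + daughter
  expect_false(st$ca$quiescent[st$occ_id[6, 6]])
  audit_occupancy(st)
})

test_that("engagement freezes the pair, kills on expiry, and exhausts at zero budget", {
  p <- quiet_params(ca_lifespan_h = 1e6, engage_duration_h = 2,
                    tc_max_kills = 1L, tc_division_period_h = 1e9,
                    tc_lifespan_h = 1e6)
  st <- bare_state(11)
  add_agent <- tmesim:::add_agent
  add_agent(st, "cancer", 6, 6, clock = -1e5)
  add_agent(st, "tcell", 6, 7, state = 1L, kills = 1L)
  sur <- test_surrogate()
  set.seed(3)

  sim_step(st, p, NULL, sur)   # T cell initiates killing
  expect_equal(st$tc$engaged[1], 1L)
  expect_equal(st$ca$engaged[1], 1L)
  expect_engagement_matching(st)
  pos <- c(st$tc$row[1], st$tc$col[1])

  sim_step(st, p, NULL, sur)   # timer 2 -> 1: still engaged, both frozen
  expect_equal(st$tc$engaged[1], 1L)
  expect_equal(c(st$tc$row[1], st$tc$col[1]), pos)
  expect_equal(sum(st$ca$alive), 1L)

  sim_step(st, p, NULL, sur)   # timer expires: kill lands
  expect_equal(sum(st$ca$alive), 0L)
  expect_equal(st$tc$engaged[1], 0L)
  expect_equal(st$tc$kills[1], 0L)
  expect_equal(st$tc$state[1], 2L)          # exhausted exactly at zero budget
  expect_equal(sum(st$death_log$count), 1)  # kill recorded in the death log
  audit_occupancy(st)

  # exhausted T cells never re-engage
  add_agent(st, "cancer", st$tc$row[1] + 1L, st$tc$col[1], clock = -1e5)
  for (k in 1:3) sim_step(st, p, NULL, sur)
  expect_equal(sum(st$ca$alive), 1L)
  expect_true(all(st$tc$kills >= 0L))
})

test_that("naive T cells need antigen and activation enabled to activate", {
  p <- quiet_params(ca_lifespan_h = 1e6, activation_enabled = FALSE,
                    tc_lifespan_h = 1e6)
  st <- bare_state(11)
  add_agent <- tmesim:::add_agent
  add_agent(st, "cancer", 6, 6, clock = -1e5)
  add_agent(st, "tcell", 6, 7)
  sur <- test_surrogate()
  set.seed(2)
  for (k in 1:10) sim_step(st, p, NULL, sur)
  expect_equal(sum(st$tc$state == 1L), 0L)   # function disabled: never active
  expect_equal(sum(st$ca$alive), 1L)         # and never any killing

  # with activation enabled and certain activation, the same fixture activates
  p2 <- quiet_params(ca_lifespan_h = 1e6, act_k = 50, tc_lifespan_h = 1e6,
                     tc_division_period_h = 1e9)
  st2 <- bare_state(11)
  add_agent(st2, "cancer", 6, 6, clock = -1e5)
  add_agent(st2, "tcell", 6, 7)
  set.seed(2)
  sim_step(st2, p2, NULL, sur)
  expect_equal(st2$tc$state[1], 1L)
})

test_that("macrophages differentiate only when licensed by activation factor", {
  sur <- test_surrogate()
  p <- quiet_params(act_threshold = 5, mac_lifespan_h = 1e6, initial_cancer = 1L)
  st <- bare_state(11)
  add_agent <- tmesim:::add_agent
  add_agent(st, "macrophage", 3, 3, clock = 24)
  # below threshold everywhere: stays M0 despite high IL-4
  st$fields$il4[] <- 50
  set.seed(6)
  sim_step(st, p, NULL, sur)
  expect_equal(st$mac$phen[1], 0L)

  # above threshold with strong IL-4: the surrogate sends it to M2
  st$fields$act[] <- 10
  sim_step(st, p, NULL, sur)
  expect_equal(st$mac$phen[1], 2L)

  # high IFN-gamma, no IL-4, licensed: goes M1 at the next 24-h evaluation
  st2 <- bare_state(11)
  add_agent(st2, "macrophage", 3, 3, clock = 24)
  st2$fields$act[] <- 10
  st2$fields$ifng[] <- 100
  sim_step(st2, p, NULL, sur)
  expect_equal(st2$mac$phen[1], 1L)
})

test_that("macrophages die at their lifespan and are removed", {
  p <- quiet_params(mac_lifespan_h = 3)
  st <- bare_state(11)
  tmesim:::add_agent(st, "macrophage", 2, 2)
  sur <- test_surrogate()
  set.seed(1)
  sim_step(st, p, NULL, sur); sim_step(st, p, NULL, sur)
  expect_equal(sum(st$mac$alive), 1L)
  sim_step(st, p, NULL, sur)
  expect_equal(sum(st$mac$alive), 0L)
  expect_equal(sum(st$occ_kind != 0L), 0L)
})

test_that("agents climb the activation-factor gradient", {
  p <- quiet_params(mac_lifespan_h = 1e6)
  st <- bare_state(11)
  tmesim:::add_agent(st, "macrophage", 2, 2)
  # strictly increasing field toward (11, 11)
  st$fields$act <- outer(1:11, 1:11, "+") * 1.0
  sur <- test_surrogate()
  set.seed(9)
  for (k in 1:25) sim_step(st, p, NULL, sur)
  # motile agents hover at the field maximum rather than freezing on it
  expect_gte(st$mac$row[1] + st$mac$col[1], 20L)
})
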