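# Shared fixtures: a small cached surrogate for engine tests and builders
# for hand-laid lattice states.

test_surrogate <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      ds <- generate_training_set(5000, seed = 424242L)
      model <<- train_surrogate(ds, seed = 424242L)
    }
    model
  }
})

# Parameters that silence every process except the ones a fixture exercises.
quiet_params <- function(...) {
  defaults <- list(n_row = 11L, n_col = 11L,
                   resident_mac_density = 0,
                   mac_recruitment_rate_day = 0,
                   r1_day = 0,
                   initial_cancer = 1L,
                   D_um2_s = c(act = 0, il4 = 0, ifng = 0),
                   decay_s = c(act = 0, il4 = 0, ifng = 0),
                   ksec_act_tumor = 0, ksec_il4_tumor = 0, ksec_il4_m2 = 0,
                   ksec_ifng_tcell = 0)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

# A bare state without engine initialization (no tumor block).
bare_state <- function(n = 11L) {
  new_lattice(n, n)
}

# Engagement links must always form a perfect mutual matching.
expect_engagement_matching <- function(state) {
  eng_t <- which(state$tc$engaged > 0L)
  for (i in eng_t) {
    j <- state$tc$engaged[i]
    expect_true(state$ca$alive[j])
    expect_identical(state$ca$engaged[j], i)
  }
  eng_c <- which(state$ca$engaged > 0L)
  for (j in eng_c) {
    i <- state$ca$engaged[j]
    expect_true(state$tc$alive[i])
    expect_identical(state$tc$engaged[i], j)
  }
  invisible(TRUE)
}
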