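## Agent behavior rules.
##
## The per-agent update loops (macrophage, T-cell and cancer-cell phases)
## run in compiled code (src/phases.cpp) for speed; this file holds the
## closed-form pieces of the behavior rules that are meaningful on their
## own, chiefly the macrophage-weighted T-cell activation probability.
##
## Behavior summary (one engine step, dt hours):
##  * Macrophages age and die at their lifespan; once the local activation
##    factor passes the licensing threshold and the 24-h redifferentiation
##    clock has elapsed, they read local IL-4/IFN-gamma (plus the current
##    PI3K activity) and commit to M1 or M2 via the surrogate; M2 cells
##    secrete IL-4; all migrate one site up the activation-factor gradient
##    (ties broken uniformly at random; blocked cells stay).
##  * T cells age and die at their lifespan; naive cells adjacent to antigen
##    (a cancer cell or an M1 macrophage) draw full activation with the
##    probability below; active cells secrete IFN-gamma, may proliferate
##    into an empty adjacent site, and initiate killing of an adjacent
##    unengaged cancer cell; engaged pairs are frozen until the engagement
##    timer expires, when the cancer cell dies and the T cell spends one
##    unit of its kill budget (exhausting at zero); unengaged cells migrate
##    up the activation-factor gradient.
##  * Cancer cells advance a proliferation clock (frozen while quiescent or
##    engaged) and divide into a uniformly random empty adjacent site at the
##    division period, becoming quiescent when surrounded (re-checking for
##    space each step); they secrete IL-4 and activation factor every step
##    and die after a maximum number of divisions (or, configurably, at an
##    age limit).

#' T-cell activation probability
#'
#' Probability that a T cell in contact with antigen becomes fully active,
#' promoted by neighboring M1 macrophages and suppressed by neighboring M2
#' macrophages:
#'
#' `P = antigen * sigmoid(k * ((antigen - numM2 / (numM1 + 1)) - s))`
#'
#' where `antigen` is 1 if a cancer cell or M1 macrophage is adjacent and 0
#' otherwise (a multiplicative gate: no antigen, no activation).
#'
#' @param antigen_present 0 or 1.
#' @param numM1,numM2 Counts of neighboring M1 and M2 macrophages (>= 0).
#' @param k Sigmoid steepness (> 0).
#' @param s Sigmoid shift.
#' @return Probability in `[0, 1]`; vectorized over its arguments.
#' @export
activation_probability <- function(antigen_present, numM1, numM2,
                                   k = 4.4, s = 0.5) {
  stopifnot(all(k > 0), all(numM1 >= 0), all(numM2 >= 0),
            all(antigen_present %in% c(0, 1)))
  antigen_present *
    stats::plogis(k * ((antigen_present - numM2 / (numM1 + 1)) - s))
}
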