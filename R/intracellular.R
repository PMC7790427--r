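## Macrophage differentiation decision.
##
## A macrophage reads IL-4 and IFN-gamma in its local environment (plus the
## current PI3K activity, which reeducation therapy lowers) and commits to an
## M1 or M2 phenotype. The decision chain is:
##
##   mechanistic model -> M1/M2 product-ratio score -> binary label
##
## and, inside the simulation engine, the mechanistic call is replaced by a
## small neural-network surrogate trained on Monte-Carlo samples of the
## mechanistic model, which is orders of magnitude cheaper per query.
##
## The mechanistic component shipped here is an algebraic stand-in with the
## same input/output contract as an intracellular signaling ODE model: five
## M1 marker channels (standing in for iNOS, TNF-alpha, CXCL9, CXCL10,
## IL-12) rise saturably with IFN-gamma, and three M2 marker channels
## (IL-10, Arg-1, VEGF) rise saturably with IL-4 scaled by PI3K activity.
## All channels are normalized to a baseline of 1, and the stand-in is at
## steady state, so the 24-h time average of the score equals its
## instantaneous value. A full time-course-returning ODE model can be
## plugged in through the same interface.

#' Constants of the stand-in differentiation model
#'
#' `alpha` are the saturating fold-increases of the five M1 channels with
#' IFN-gamma, `beta` those of the three M2 channels with IL-4 (scaled by
#' PI3K activity), and `K_ifng` / `K_il4` the half-saturation constants
#' (molecules/site). Defaults are chosen so the M1/M2 decision boundary is a
#' nontrivial curve across the cytokine range realized in the lattice model.
#'
#' @param alpha,beta Named non-negative saturation amplitudes.
#' @param K_il4,K_ifng Half-saturation constants (> 0).
#' @return List of constants.
#' @export
standin_constants <- function(alpha = c(iNOS = 0.60, TNFa = 0.50,
                                        CXCL9 = 0.45, CXCL10 = 0.40,
                                        IL12 = 0.35),
                              beta = c(IL10 = 1.20, Arg1 = 1.00,
                                       VEGF = 0.80),
                              K_il4 = 10, K_ifng = 10) {
  stopifnot(all(alpha >= 0), all(beta >= 0), K_il4 > 0, K_ifng > 0)
  list(alpha = alpha, beta = beta, K_il4 = K_il4, K_ifng = K_ifng)
}

hill1 <- function(x, K) x / (x + K)

#' Stand-in mechanistic differentiation model
#'
#' Each M1 channel responds as `1 + alpha_j * ifng / (ifng + K_ifng)`, each
#' M2 channel as `1 + beta_j * pi3k * il4 / (il4 + K_il4)`. Baseline inputs
#' (`il4 = ifng = 0`) give all channels 1; full PI3K inhibition
#' (`pi3k = 0`) abolishes the M2 drive entirely.
#'
#' @param il4,ifng Cytokine concentrations (molecules/site, >= 0); vectors
#'   are recycled to a common length.
#' @param pi3k PI3K activity in `[0, 1]` (1 = untreated).
#' @param constants See [standin_constants()].
#' @return List with matrices `m1` (n x 5) and `m2` (n x 3) of channel
#'   values, one row per input.
#' @export
standin_mechanistic <- function(il4, ifng, pi3k = 1,
                                constants = standin_constants()) {
  n <- max(length(il4), length(ifng), length(pi3k))
  il4 <- rep_len(il4, n); ifng <- rep_len(ifng, n); pi3k <- rep_len(pi3k, n)
  if (any(il4 < 0) || any(ifng < 0) || any(pi3k < 0)) {
    stop("inputs must be non-negative")
  }
  if (any(pi3k > 1)) stop("pi3k activity must be <= 1")
  h_i <- hill1(ifng, constants$K_ifng)
  h_4 <- pi3k * hill1(il4, constants$K_il4)
  m1 <- 1 + outer(h_i, constants$alpha)
  m2 <- 1 + outer(h_4, constants$beta)
  list(m1 = m1, m2 = m2)
}

#' M1/M2 score and phenotype label
#'
#' The score is the product of the M1 channels divided by the product of the
#' M2 channels, time-averaged over the 24-h evaluation window (for the
#' steady-state stand-in the average equals the instantaneous value). A
#' score strictly greater than one labels the macrophage M1; a score of one
#' or less labels it M2 (ties fall to M2, the environment's default
#' attractor).
#'
#' @param channels Output of [standin_mechanistic()] (all channels > 0).
#' @return Data frame with columns `score` and `label` (factor `M1`/`M2`).
#' @export
m1m2_score <- function(channels) {
  if (any(channels$m1 <= 0) || any(channels$m2 <= 0)) {
    stop("channel values must be positive")
  }
  score <- apply(channels$m1, 1, prod) / apply(channels$m2, 1, prod)
  data.frame(score = score,
             label = factor(ifelse(score > 1, "M1", "M2"),
                            levels = c("M1", "M2")))
}

#' Phenotype decided by the mechanistic oracle
#'
#' Convenience composition `standin_mechanistic` then [m1m2_score()]; this is
#' the labeling oracle used to generate surrogate training data and to audit
#' surrogate predictions.
#'
#' @inheritParams standin_mechanistic
#' @return Factor vector of `M1`/`M2` labels.
#' @export
mechanistic_label <- function(il4, ifng, pi3k = 1,
                              constants = standin_constants()) {
  m1m2_score(standin_mechanistic(il4, ifng, pi3k, constants))$label
}

#' Default sampling ranges for surrogate training
#'
#' The cytokine ranges cover the per-site concentrations realized in
#' baseline lattice simulations (observed field extrema, with headroom);
#' PI3K activity covers the full treatment range.
#'
#' @return Named list of `c(lo, hi)` ranges for `il4`, `ifng`, `pi3k`.
#' @export
default_input_ranges <- function() {
  list(il4 = c(0, 60), ifng = c(0, 120), pi3k = c(0, 1))
}

#' Monte-Carlo labeled training set
#'
#' Samples inputs uniformly over `ranges` and labels each with the
#' mechanistic oracle, mirroring the Monte-Carlo labeling used to train the
#' in-simulation surrogate.
#'
#' @param n_samples Number of rows (>= 1).
#' @param ranges See [default_input_ranges()].
#' @param seed Optional integer seed for reproducibility.
#' @param constants Stand-in constants.
#' @return Data frame `(il4, ifng, pi3k, label)`.
#' @export
generate_training_set <- function(n_samples, ranges = default_input_ranges(),
                                  seed = NULL,
                                  constants = standin_constants()) {
  stopifnot(n_samples >= 1)
  for (nm in c("il4", "ifng", "pi3k")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2 || r[2] < r[1]) {
      stop("invalid range for ", nm)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  il4 <- runif(n_samples, ranges$il4[1], ranges$il4[2])
  ifng <- runif(n_samples, ranges$ifng[1], ranges$ifng[2])
  pi3k <- runif(n_samples, ranges$pi3k[1], ranges$pi3k[2])
  data.frame(il4 = il4, ifng = ifng, pi3k = pi3k,
             label = mechanistic_label(il4, ifng, pi3k, constants))
}

#' Train the neural-network surrogate
#'
#' Fits a network with one hidden layer of four sigmoid neurons (inputs:
#' IL-4, IFN-gamma, PI3K activity; one sigmoid output unit) on a random
#' train/test split of the labeled dataset, by entropy (binary
#' cross-entropy) fitting with weight decay. Inputs are min-max normalized
#' to `[0, 1]`; at prediction time out-of-range queries are clamped to the
#' training range edges rather than extrapolated.
#'
#' @param dataset Data frame from [generate_training_set()].
#' @param split_fraction Fraction of rows used for training (rest held out).
#' @param seed Optional integer seed (controls the split and the weight
#'   initialization; a fixed seed gives an identical model).
#' @param maxit,decay Optimizer iteration cap and weight-decay penalty
#'   passed to [nnet::nnet()].
#' @param n_restarts Number of random weight initializations; the fit with
#'   the lowest final penalized training deviance is kept (the optimizer
#'   occasionally stalls in a poor local optimum; selection uses only
#'   training-set loss, never the held-out data).
#' @return Object of class `"tme_surrogate"`: weight matrices, input
#'   normalization ranges, held-out accuracy and split sizes. If the dataset
#'   contains a single class a warning state is recorded
#'   (`single_class = TRUE`) and the accuracy is trivially 1.
#' @export
train_surrogate <- function(dataset, split_fraction = 0.8, seed = NULL,
                            maxit = 500, decay = 1e-4, n_restarts = 5) {
  stopifnot(all(c("il4", "ifng", "pi3k", "label") %in% names(dataset)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dataset)
  x <- as.matrix(dataset[, c("il4", "ifng", "pi3k")])
  in_lo <- apply(x, 2, min)
  in_hi <- apply(x, 2, max)
  rng <- pmax(in_hi - in_lo, .Machine$double.eps)
  xn <- sweep(sweep(x, 2, in_lo), 2, rng, "/")
  y <- as.integer(dataset$label == "M1")

  single_class <- length(unique(y)) < 2
  idx_train <- sample.int(n, size = max(1, floor(split_fraction * n)))
  idx_test <- setdiff(seq_len(n), idx_train)

  if (single_class) {
    warning("training set contains a single class; surrogate is degenerate")
    ## constant model: output saturated toward the lone class
    const <- if (y[1] == 1) 20 else -20
    model <- list(W1 = matrix(0, 4, 3), b1 = rep(0, 4), w2 = rep(0, 4),
                  b2 = const)
  } else {
    fit <- NULL
    for (r in seq_len(max(1, n_restarts))) {
      cand <- nnet::nnet(x = xn[idx_train, , drop = FALSE], y = y[idx_train],
                         size = 4, entropy = TRUE, maxit = maxit,
                         decay = decay, trace = FALSE)
      if (is.null(fit) || cand$value < fit$value) fit <- cand
    }
    ## nnet weight layout for 3-4-1: per hidden unit (b, w_in1..3), then
    ## output unit (b, w_h1..4)
    w <- fit$wts
    W1 <- matrix(0, 4, 3); b1 <- numeric(4)
    for (j in 1:4) {
      blk <- w[((j - 1) * 4 + 1):(j * 4)]
      b1[j] <- blk[1]
      W1[j, ] <- blk[2:4]
    }
    out <- w[17:21]
    model <- list(W1 = W1, b1 = b1, w2 = out[2:5], b2 = out[1])
  }

  model$in_lo <- in_lo
  model$in_hi <- in_hi
  model$single_class <- single_class
  model$n_train <- length(idx_train)
  model$n_test <- length(idx_test)
  if (length(idx_test) > 0) {
    pred <- surrogate_prob(model, x[idx_test, 1], x[idx_test, 2],
                           x[idx_test, 3]) > 0.5
    model$held_out_accuracy <- mean(pred == (y[idx_test] == 1))
  } else {
    model$held_out_accuracy <- NA_real_
  }
  class(model) <- "tme_surrogate"
  model
}

## Internal: M1 probability from the surrogate (same arithmetic as the
## engine's C++ forward pass; cross-checked in tests).
surrogate_prob <- function(model, il4, ifng, pi3k) {
  n <- max(length(il4), length(ifng), length(pi3k))
  cpp_nn_forward(rep_len(as.numeric(il4), n), rep_len(as.numeric(ifng), n),
                 rep_len(as.numeric(pi3k), n), unclass(model))
}

#' Predict macrophage phenotype with the surrogate
#'
#' Deterministic given the trained weights. Inputs outside the training
#' ranges are clamped to the range edges.
#'
#' @param model A `"tme_surrogate"` from [train_surrogate()].
#' @param il4,ifng,pi3k Query inputs (recycled to a common length).
#' @return Factor vector of `M1`/`M2` labels.
#' @export
predict_phenotype <- function(model, il4, ifng, pi3k = 1) {
  if (!inherits(model, "tme_surrogate")) {
    stop("`model` must be a trained tme_surrogate")
  }
  p <- surrogate_prob(model, il4, ifng, pi3k)
  factor(ifelse(p > 0.5, "M1", "M2"), levels = c("M1", "M2"))
}

#' @export
print.tme_surrogate <- function(x, ...) {
  cat(sprintf(paste0("<tme_surrogate> 3-4-1 sigmoid network; held-out ",
                     "accuracy %.2f%% (train n=%d, test n=%d)%s\n"),
              100 * x$held_out_accuracy, x$n_train, x$n_test,
              if (isTRUE(x$single_class)) " [single-class]" else ""))
  invisible(x)
}

#' Serialize / restore a surrogate as JSON
#'
#' Round-trips all weights and normalization ranges at full precision so
#' predictions are bit-reproducible across sessions.
#'
#' @param model A `"tme_surrogate"`.
#' @param path File path.
#' @return `surrogate_from_json` returns the restored `"tme_surrogate"`.
#' @export
surrogate_to_json <- function(model, path) {
  obj <- unclass(model)
  obj$W1 <- as.vector(obj$W1)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname surrogate_to_json
#' @export
surrogate_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$W1 <- matrix(obj$W1, 4, 3)
  obj$in_lo <- setNames(as.numeric(obj$in_lo), c("il4", "ifng", "pi3k"))
  obj$in_hi <- setNames(as.numeric(obj$in_hi), c("il4", "ifng", "pi3k"))
  class(obj) <- "tme_surrogate"
  obj
}

## Internal: package-default surrogate used by the engine when the caller
## does not supply one. Trained once per session on a moderate Monte-Carlo
## sample under a fixed seed and cached.
the <- new.env(parent = emptyenv())

default_surrogate <- function() {
  if (is.null(the$surrogate)) {
    ds <- generate_training_set(20000, seed = 20201223L)
    the$surrogate <- train_surrogate(ds, split_fraction = 0.8,
                                     seed = 20201223L)
  }
  the$surrogate
}
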