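## Reaction-diffusion layer for the three diffusible factors:
## the tumor-secreted macrophage activation factor (primarily HMG-B1),
## IL-4 and IFN-gamma. Concentrations are per-site molecule counts.
##
## Each factor obeys dC/dt = D * laplacian(C) + sources - decay * C, solved
## by operator splitting per macro time step: point-wise secretion first,
## then an explicit 5-point finite-difference diffusion/decay pass with
## zero-flux boundaries (a closed tissue slice; mass is conserved exactly up
## to decay). The explicit pass sub-cycles automatically to respect the
## stability bound D*dt/h^2 <= 1/4. The decay term is an extension over the
## plain diffusion+secretion formulation (without it the fields grow without
## bound); setting the decay rates to zero recovers the undamped equations.

FACTORS <- c("act", "il4", "ifng")

#' Create zeroed cytokine fields
#'
#' @param n_row,n_col Grid dimensions (must match the lattice).
#' @return Named list of numeric matrices (`act`, `il4`, `ifng`).
#' @export
cytokine_fields <- function(n_row, n_col) {
  setNames(lapply(FACTORS, function(f) matrix(0, n_row, n_col)), FACTORS)
}

#' Add secretion from point sources
#'
#' Forward-Euler source term: each source site's factor grid is incremented
#' by `rate * dt`. Multiple sources on the same site are additive.
#'
#' @param fields Named list of factor matrices (see [cytokine_fields()]).
#' @param sources Data frame (or list of equal-length vectors) with
#'   components `row`, `col`, `factor` (one of `"act"`, `"il4"`, `"ifng"`)
#'   and `rate` (molecules/s, >= 0).
#' @param dt Time step in seconds (> 0).
#' @return Updated fields list.
#' @export
secrete <- function(fields, sources, dt) {
  stopifnot(dt > 0)
  if (length(sources$row) == 0) return(fields)
  if (any(sources$rate < 0)) stop("secretion rates must be non-negative")
  if (!all(sources$factor %in% FACTORS)) {
    stop("unknown factor: ",
         paste(setdiff(unique(sources$factor), FACTORS), collapse = ", "))
  }
  for (f in unique(sources$factor)) {
    idx <- which(sources$factor == f)
    fields[[f]] <- cpp_add_at(fields[[f]], as.integer(sources$row[idx]),
                              as.integer(sources$col[idx]),
                              sources$rate[idx] * dt)
  }
  fields
}

#' Advance diffusion and decay for one macro step
#'
#' @param fields Named list of factor matrices.
#' @param dt Macro time step in seconds.
#' @param D Named vector of diffusivities (um^2/s) per factor.
#' @param decay Named vector of first-order decay rates (1/s) per factor.
#' @param h Site length in micrometers.
#' @return Updated fields list.
#' @export
diffuse_step <- function(fields, dt, D, decay, h) {
  for (f in names(fields)) {
    fields[[f]] <- cpp_diffuse(fields[[f]], D[[f]], decay[[f]], h, dt)
  }
  fields
}

#' Local concentration readout for an agent
#'
#' By default an agent reads the factor value at its own site; the
#' `"neighborhood_mean"` mode averages the 3x3 patch centered on the site
#' (truncated at boundaries).
#'
#' @param fields Named list of factor matrices.
#' @param site `c(row, col)`, 1-based.
#' @param factor One of `"act"`, `"il4"`, `"ifng"`.
#' @param mode `"site"` (default) or `"neighborhood_mean"`.
#' @return Scalar concentration.
#' @export
local_concentration <- function(fields, site, factor,
                                mode = c("site", "neighborhood_mean")) {
  mode <- match.arg(mode)
  if (!factor %in% names(fields)) stop("unknown factor: ", factor)
  grid <- fields[[factor]]
  if (site[1] < 1 || site[1] > nrow(grid) || site[2] < 1 ||
      site[2] > ncol(grid)) {
    stop("site out of bounds")
  }
  if (mode == "site") return(grid[site[1], site[2]])
  rr <- max(1, site[1] - 1):min(nrow(grid), site[1] + 1)
  cc <- max(1, site[2] - 1):min(ncol(grid), site[2] + 1)
  mean(grid[rr, cc])
}
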