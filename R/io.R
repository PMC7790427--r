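## Serialization and plotting: time-course CSV, run-summary JSON, lattice
## snapshots (plain-text grid and raster plot) and field snapshots.

#' Write a run's time course as CSV
#'
#' One row per recording time with population counts, field statistics and
#' the treatment-state column.
#'
#' @param run A `"tme_run"` from [run_simulation()].
#' @param path Output file.
#' @export
write_timecourse <- function(run, path) {
  write.csv(run$timecourse, path, row.names = FALSE)
  invisible(path)
}

#' Write a run summary as JSON
#'
#' @param run A `"tme_run"`.
#' @param path Output file.
#' @export
write_summary_json <- function(run, path) {
  s <- run$summary
  s$seed <- run$seed
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Character-coded lattice snapshot
#'
#' Codes: `.` empty, `C` cancer cell, `T` T cell, `A` active T cell,
#' `X` exhausted T cell, `0`/`1`/`2` macrophage phenotypes.
#'
#' @param state A `tme_state`.
#' @return Character matrix of codes.
#' @export
snapshot_grid <- function(state) {
  g <- matrix(".", state$n_row, state$n_col)
  ca <- state$ca
  g[cbind(ca$row[ca$alive], ca$col[ca$alive])] <- "C"
  mac <- state$mac
  live <- which(mac$alive)
  g[cbind(mac$row[live], mac$col[live])] <- as.character(mac$phen[live])
  tc <- state$tc
  live <- which(tc$alive)
  code <- c("T", "A", "X")[tc$state[live] + 1L]
  g[cbind(tc$row[live], tc$col[live])] <- code
  g
}

#' Write a lattice snapshot as CSV
#'
#' @param state A `tme_state`.
#' @param path Output file.
#' @export
write_snapshot_csv <- function(state, path) {
  utils::write.table(snapshot_grid(state), path, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot the spatial distribution of cells
#'
#' Raster view of the lattice: cancer cells black, T cells yellow, active T
#' cells red, M0 macrophages blue, M1 green, M2 purple (empty sites white;
#' exhausted T cells orange).
#'
#' @param state A `tme_state`.
#' @param main Plot title.
#' @export
plot_state <- function(state, main = sprintf("day %.1f", state$time_h / 24)) {
  g <- snapshot_grid(state)
  codes <- c(".", "C", "T", "A", "X", "0", "1", "2")
  cols <- c("white", "black", "yellow2", "red", "orange", "blue3",
            "green3", "purple3")
  z <- matrix(match(g, codes), nrow(g), ncol(g))
  graphics::image(t(z[nrow(z):1, , drop = FALSE]), col = cols,
                  breaks = 0.5 + 0:8, axes = FALSE, main = main,
                  useRaster = TRUE)
  graphics::box()
  invisible(NULL)
}

#' Plot population time courses
#'
#' @param run A `"tme_run"` (or a list of them, overlaid).
#' @param what Column of the time course to plot.
#' @param col Line color(s).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_timecourse <- function(run, what = "n_cancer", col = "black", ...) {
  runs <- if (inherits(run, "tme_run")) list(run) else run
  xs <- lapply(runs, function(r) r$timecourse$time_d)
  ys <- lapply(runs, function(r) r$timecourse[[what]])
  n <- max(vapply(xs, length, 1L))
  pad <- function(v) c(v, rep(NA, n - length(v)))
  graphics::matplot(vapply(xs, pad, numeric(n)), vapply(ys, pad, numeric(n)),
                    type = "l", lty = 1, col = col, xlab = "time (days)",
                    ylab = what, ...)
  invisible(NULL)
}

#' Write a cytokine field as CSV
#'
#' @param state A `tme_state`.
#' @param factor `"act"`, `"il4"` or `"ifng"`.
#' @param path Output file.
#' @export
write_field_csv <- function(state, factor, path) {
  if (!factor %in% names(state$fields)) stop("unknown factor: ", factor)
  utils::write.table(state$fields[[factor]], path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
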