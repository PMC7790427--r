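## Lattice geometry and occupancy bookkeeping.
##
## The simulation state is an environment (class "tme_state") so that engine
## phases can update it in place. The lattice is a single-occupancy grid:
## `occ_kind` holds 0 (empty), 1 (cancer cell), 2 (macrophage) or 3 (T cell),
## and `occ_id` the 1-based row index into the matching agent table.

OCC_EMPTY <- 0L
OCC_CANCER <- 1L
OCC_MAC <- 2L
OCC_TCELL <- 3L

#' Neighborhood offsets
#'
#' Offsets (drow, dcol) for the two supported lattice neighborhoods. Offsets
#' are unique and exclude (0, 0).
#'
#' @param kind `"moore_8"` (default, all 8 surrounding sites) or
#'   `"von_neumann_4"` (the 4 orthogonal sites).
#' @return Integer matrix with columns `drow`, `dcol`.
#' @export
neighborhood_offsets <- function(kind = c("moore_8", "von_neumann_4")) {
  kind <- match.arg(kind)
  if (kind == "moore_8") {
    off <- expand.grid(drow = -1:1, dcol = -1:1)
    off <- off[!(off$drow == 0 & off$dcol == 0), ]
  } else {
    off <- data.frame(drow = c(-1L, 1L, 0L, 0L), dcol = c(0L, 0L, -1L, 1L))
  }
  m <- as.matrix(off)
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

empty_agents <- function(kind) {
  base <- list(row = integer(0), col = integer(0), age = numeric(0),
               alive = logical(0))
  extra <- switch(kind,
    mac = list(phen = integer(0), clock = numeric(0)),
    tc = list(state = integer(0), kills = integer(0), engaged = integer(0),
              timer = numeric(0)),
    ca = list(clock = numeric(0), divisions = integer(0),
              quiescent = logical(0), engaged = integer(0)))
  c(base, extra)
}

#' Create an empty lattice state
#'
#' Builds the container shared by all modules: the occupancy grid, the three
#' cytokine fields (macrophage activation factor, IL-4, IFN-gamma, all zero)
#' and empty agent tables. Returned as an environment so engine phases can
#' update it in place.
#'
#' @param n_row,n_col Lattice dimensions in sites.
#' @param site_length_um Side of one lattice site in micrometers (15 um, one
#'   cell diameter, so the default 100 x 100 grid spans 1.5 x 1.5 mm).
#' @param movement_kind Neighborhood used for movement and contact
#'   interactions.
#' @return An environment of class `"tme_state"`.
#' @export
new_lattice <- function(n_row = 100, n_col = 100, site_length_um = 15,
                        movement_kind = c("moore_8", "von_neumann_4")) {
  movement_kind <- match.arg(movement_kind)
  stopifnot(n_row >= 1, n_col >= 1, site_length_um > 0)
  st <- new.env(parent = emptyenv())
  st$n_row <- as.integer(n_row)
  st$n_col <- as.integer(n_col)
  st$site_length_um <- site_length_um
  st$movement_kind <- movement_kind
  st$occ_kind <- matrix(OCC_EMPTY, n_row, n_col)
  st$occ_id <- matrix(0L, n_row, n_col)
  st$fields <- list(act = matrix(0, n_row, n_col),
                    il4 = matrix(0, n_row, n_col),
                    ifng = matrix(0, n_row, n_col))
  st$mac <- empty_agents("mac")
  st$tc <- empty_agents("tc")
  st$ca <- empty_agents("ca")
  st$death_log <- data.frame(time = numeric(0), count = numeric(0))
  st$carry_mac <- 0
  st$carry_tc <- 0
  st$shortfall <- 0
  st$time_h <- 0
  st$last_depletion_cycle <- -1L
  class(st) <- "tme_state"
  st
}

in_bounds <- function(state, site) {
  site[1] >= 1 && site[1] <= state$n_row && site[2] >= 1 && site[2] <= state$n_col
}

#' List all empty lattice sites
#'
#' @param state A `tme_state`.
#' @return Two-column integer matrix (`row`, `col`) of unoccupied sites in
#'   row-major order (row varies slowest).
#' @export
empty_sites <- function(state) {
  idx <- which(t(state$occ_kind) == OCC_EMPTY)
  if (length(idx) == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  }
  row <- (idx - 1L) %/% state$n_col + 1L
  col <- (idx - 1L) %% state$n_col + 1L
  cbind(row = row, col = col)
}

#' Occupied neighbors of a site
#'
#' @param state A `tme_state`.
#' @param site Integer vector `c(row, col)` (1-based); must be in bounds.
#' @param kind Neighborhood kind; defaults to the state's movement
#'   neighborhood.
#' @return Data frame with one row per occupied in-bounds neighbor: `row`,
#'   `col`, `kind` (`"cancer"`, `"macrophage"`, `"tcell"`) and `id` (row index
#'   into the matching agent table). Boundary sites return truncated lists.
#' @export
neighbors_of <- function(state, site, kind = NULL) {
  if (!in_bounds(state, site)) stop("site out of bounds")
  off <- neighborhood_offsets(if (is.null(kind)) state$movement_kind else kind)
  rr <- site[1] + off[, 1]
  cc <- site[2] + off[, 2]
  ok <- rr >= 1 & rr <= state$n_row & cc >= 1 & cc <= state$n_col
  rr <- rr[ok]; cc <- cc[ok]
  kinds <- state$occ_kind[cbind(rr, cc)]
  occ <- kinds != OCC_EMPTY
  data.frame(row = rr[occ], col = cc[occ],
             kind = c("cancer", "macrophage", "tcell")[kinds[occ]],
             id = state$occ_id[cbind(rr[occ], cc[occ])])
}

agent_table_name <- function(kind_code) {
  switch(kind_code, "ca", "mac", "tc")
}

#' Move an agent to an adjacent empty site
#'
#' The move is refused (a no-op, returning `FALSE`) when the destination is
#' occupied: contention between agents is expected, not an error. Calling
#' with an empty source site or a non-adjacent destination signals a caller
#' bug and errors.
#'
#' @param state A `tme_state`.
#' @param from,to Integer vectors `c(row, col)`.
#' @return `TRUE` if the agent moved, `FALSE` if the destination was occupied
#'   (invisibly).
#' @export
move_agent <- function(state, from, to) {
  if (!in_bounds(state, from) || !in_bounds(state, to)) {
    stop("site out of bounds")
  }
  kind <- state$occ_kind[from[1], from[2]]
  if (kind == OCC_EMPTY) stop("no agent at `from`")
  off <- neighborhood_offsets(state$movement_kind)
  if (!any(off[, 1] == to[1] - from[1] & off[, 2] == to[2] - from[2])) {
    stop("`to` is not adjacent to `from` under the movement neighborhood")
  }
  if (state$occ_kind[to[1], to[2]] != OCC_EMPTY) {
    return(invisible(FALSE))
  }
  id <- state$occ_id[from[1], from[2]]
  state$occ_kind[to[1], to[2]] <- kind
  state$occ_id[to[1], to[2]] <- id
  state$occ_kind[from[1], from[2]] <- OCC_EMPTY
  state$occ_id[from[1], from[2]] <- 0L
  tab <- agent_table_name(kind)
  state[[tab]]$row[id] <- as.integer(to[1])
  state[[tab]]$col[id] <- as.integer(to[2])
  invisible(TRUE)
}

## Internal: append one agent to its table and mark the lattice.
add_agent <- function(st, kind = c("cancer", "macrophage", "tcell"),
                      row, col, ...) {
  kind <- match.arg(kind)
  if (!in_bounds(st, c(row, col))) stop("site out of bounds")
  if (st$occ_kind[row, col] != OCC_EMPTY) stop("site already occupied")
  dots <- list(...)
  tab_name <- switch(kind, cancer = "ca", macrophage = "mac", tcell = "tc")
  code <- switch(kind, cancer = OCC_CANCER, macrophage = OCC_MAC,
                 tcell = OCC_TCELL)
  tab <- st[[tab_name]]
  defaults <- switch(tab_name,
    mac = list(age = 0, alive = TRUE, phen = 0L, clock = 0),
    tc = list(age = 0, alive = TRUE, state = 0L, kills = 0L, engaged = 0L,
              timer = 0),
    ca = list(age = 0, alive = TRUE, clock = 0, divisions = 0L,
              quiescent = FALSE, engaged = 0L))
  rec <- c(list(row = as.integer(row), col = as.integer(col)),
           utils::modifyList(defaults, dots))
  for (nm in names(tab)) tab[[nm]] <- c(tab[[nm]], rec[[nm]])
  st[[tab_name]] <- tab
  id <- length(tab$row)
  st$occ_kind[row, col] <- code
  st$occ_id[row, col] <- id
  invisible(id)
}

#' Counts of live agents by type and phenotype/state
#'
#' @param state A `tme_state`.
#' @return Named integer vector: `cancer`, `m0`, `m1`, `m2`, `tcell`,
#'   `tcell_active`.
#' @export
agent_counts <- function(state) {
  ma <- state$mac$alive
  ta <- state$tc$alive
  c(cancer = sum(state$ca$alive),
    m0 = sum(ma & state$mac$phen == 0L),
    m1 = sum(ma & state$mac$phen == 1L),
    m2 = sum(ma & state$mac$phen == 2L),
    tcell = sum(ta),
    tcell_active = sum(ta & state$tc$state == 1L))
}

#' Audit the occupancy bijection
#'
#' Checks that every live agent's stored position matches exactly one
#' occupancy entry and that every occupied site points back at a live agent
#' (at most one agent per site is implied by the representation). Used as the
#' full-audit routine after engine steps.
#'
#' @param state A `tme_state`.
#' @return `TRUE` invisibly; stops with a description on any breach.
#' @export
audit_occupancy <- function(state) {
  seen <- 0L
  for (kind_code in c(OCC_CANCER, OCC_MAC, OCC_TCELL)) {
    tab <- state[[agent_table_name(kind_code)]]
    live <- which(tab$alive)
    for (i in live) {
      r <- tab$row[i]; c <- tab$col[i]
      if (state$occ_kind[r, c] != kind_code || state$occ_id[r, c] != i) {
        stop(sprintf("agent %d of kind %d not on lattice at (%d,%d)",
                     i, kind_code, r, c))
      }
    }
    seen <- seen + length(live)
  }
  n_occ <- sum(state$occ_kind != OCC_EMPTY)
  if (n_occ != seen) {
    stop(sprintf("occupancy count %d != live agent count %d", n_occ, seen))
  }
  invisible(TRUE)
}

#' @export
print.tme_state <- function(x, ...) {
  cnt <- agent_counts(x)
  cat(sprintf("<tme_state> %dx%d lattice (%.1f um sites), t = %.1f h\n",
              x$n_row, x$n_col, x$site_length_um, x$time_h))
  cat("  ", paste(names(cnt), cnt, sep = "=", collapse = " "), "\n")
  invisible(x)
}
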