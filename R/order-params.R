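#' Distance bin table for the order parameters
#'
#' The arm-target distances are discretized into half-open intervals
#' `[e_i, e_{i+1})` plus a final unbounded interval `[e_last, Inf)`; the
#' number of intervals equals the number of edges. The default table has 11
#' intervals so the order parameters run from 0 to 10: the printed edges
#' 0, 1.7, 3.4, 5.1, 8.5, 12.8, 17.0, 34.1, 68.1, 102.2 nm enumerate only 10
#' intervals against a stated count of 11, so the default inserts one edge at
#' 85.2 nm between 68.1 and 102.2, keeping every printed edge (see the
#' methods vignette).
#'
#' @param edges Strictly ascending numeric vector of interval edges in nm,
#'   starting at 0.
#' @return Object of class `bin_table`.
#' @export
bin_table <- function(edges = default_bin_edges()) {
  if (!is.numeric(edges) || length(edges) < 2L || anyNA(edges)) {
    stop_lasso("`edges` must be a numeric vector with at least two entries", "invalid_bins")
  }
  if (edges[1] != 0) stop_lasso("the first bin edge must be 0", "invalid_bins")
  if (any(diff(edges) <= 0)) stop_lasso("bin edges must be strictly ascending", "invalid_bins")
  structure(list(edges = as.numeric(edges)), class = "bin_table")
}

default_bin_edges <- function() {
  c(0, 1.7, 3.4, 5.1, 8.5, 12.8, 17.0, 34.1, 68.1, 85.2, 102.2)
}

#' @rdname bin_table
#' @export
default_bin_table <- function() bin_table(default_bin_edges())

#' @rdname bin_table
#' @param bins A `bin_table`.
#' @export
n_intervals <- function(bins) {
  stopifnot(inherits(bins, "bin_table"))
  length(bins$edges)
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("<bin_table> %d intervals, edges (nm): %s, last interval [%g, Inf)\n",
              n_intervals(x), paste(x$edges, collapse = ", "),
              x$edges[length(x$edges)]))
  invisible(x)
}

#' Discretize a distance into an order-parameter value
#'
#' Returns the index (0-based) of the half-open interval containing `d`; a
#' distance of exactly an edge value falls into the upper interval, and any
#' distance at or beyond the last edge maps to the final unbounded interval.
#' Monotone non-decreasing in `d`. Vectorized over `d`.
#'
#' @param d Distance(s) in nm, non-negative.
#' @param bins A [bin_table()].
#' @return Integer order parameter(s) in `0 .. n_intervals(bins) - 1`.
#' @examples
#' discretize(1.0, default_bin_table())   # 0
#' discretize(150, default_bin_table())   # 10
#' @export
discretize <- function(d, bins = default_bin_table()) {
  stopifnot(inherits(bins, "bin_table"))
  if (!is.numeric(d) || anyNA(d)) stop_lasso("`d` must be numeric", "invalid_distance")
  if (any(d < 0)) stop_lasso("distances must be non-negative", "invalid_distance")
  q <- findInterval(d, bins$edges, left.open = FALSE) - 1L
  as.integer(q)
}

#' Arm-target distance
#'
#' The distance between one probe arm and its target site: the minimum over
#' the designed complementary pairs of the minimum-image Euclidean bead-bead
#' distance.
#'
#' @param system A [capture_system()].
#' @param arm Either `"extension"` / `"ligation"` (using the system's pair
#'   lists) or an explicit two-column matrix of 0-based global bead indices.
#' @return Distance in nm.
#' @export
arm_distance <- function(system, arm = c("extension", "ligation")) {
  stopifnot(inherits(system, "capture_system"))
  pairs <- if (is.matrix(arm) || is.data.frame(arm)) {
    p <- as.matrix(arm)
    storage.mode(p) <- "integer"
    p
  } else {
    switch(match.arg(arm), extension = system$ext_pairs, ligation = system$lig_pairs)
  }
  if (nrow(pairs) == 0L) {
    stop_lasso("no designed pairs for this arm; cannot define an arm distance", "empty_pairs")
  }
  cg_arm_distance(system$positions, system$box_side, pairs)
}

#' Order-parameter state of a configuration
#'
#' Discretizes the two arm distances into `(Q_ex, Q_lig)`.
#'
#' @param system A [capture_system()].
#' @param bins A [bin_table()].
#' @return A named integer vector `c(q_ex, q_lig)` of class `op_state`, with
#'   the bin count attached as attribute `max_q`.
#' @export
op_state <- function(system, bins = default_bin_table()) {
  q <- c(
    q_ex = discretize(arm_distance(system, "extension"), bins),
    q_lig = discretize(arm_distance(system, "ligation"), bins)
  )
  structure(q, max_q = n_intervals(bins) - 1L, class = "op_state")
}

#' Classify an order-parameter state
#'
#' The configuration is an interaction state when both order parameters are
#' zero (both arms engaged with their sites), a non-interaction state when
#' both sit in the final unbounded interval, and intermediate otherwise.
#'
#' @param op An [op_state()], or a length-2 integer vector (then `max_q`
#'   must be supplied).
#' @param max_q Largest order-parameter value (defaults to the attribute).
#' @return One of `"interaction"`, `"non_interaction"`, `"intermediate"`.
#' @export
classify_state <- function(op, max_q = attr(op, "max_q")) {
  if (is.null(max_q)) stop_lasso("`max_q` is required when `op` is a bare vector", "invalid_argument")
  q <- as.integer(op)
  if (length(q) != 2L || anyNA(q) || any(q < 0L) || any(q > max_q)) {
    stop_lasso("`op` must be two integers in [0, max_q]", "invalid_argument")
  }
  if (all(q == 0L)) return("interaction")
  if (all(q == max_q)) return("non_interaction")
  "intermediate"
}
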