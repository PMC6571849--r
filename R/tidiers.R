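# broom-style tidiers and ggplot2 autoplot methods for the result objects

#' @export
tidy.capture_histogram <- function(x, ...) {
  grid_tibble(x$counts, "count")
}

#' @export
tidy.weight_table <- function(x, ...) {
  grid_tibble(x$weights, "weight")
}

#' @export
tidy.unbiased_distribution <- function(x, ...) {
  grid_tibble(x$p, "p")
}

grid_tibble <- function(mat, value_name) {
  nq <- nrow(mat)
  out <- tibble(
    q_ex = rep(0:(nq - 1L), times = nq),
    q_lig = rep(0:(nq - 1L), each = nq),
    value = as.numeric(mat)
  )
  names(out)[3] <- value_name
  out
}

#' Tidy the diagonal free-energy profile
#'
#' @param x A `capture_fe` from [interaction_free_energy()].
#' @param ... Unused.
#' @return The diagonal profile tibble (`q`, `p`, `dg`).
#' @export
tidy.capture_fe <- function(x, ...) x$profile

#' One-row summary of a free-energy result
#'
#' @inheritParams tidy.capture_fe
#' @return Tibble with `dg_int`, `se`, `n_samples`.
#' @export
glance.capture_fe <- function(x, ...) {
  tibble(dg_int = x$dg_int, se = x$se, n_samples = x$n_samples)
}

#' @export
tidy.capture_enrichment <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.capture_enrichment <- function(x, ...) {
  tibble(n_probes = nrow(x),
         best_probe = x$probe_id[which.min(x$dg_rel)],
         max_enrichment = max(x$enrichment_ratio))
}

#' Plot an order-parameter grid
#'
#' Heatmap of the sampled histogram (or unbiased distribution) on the
#' `(Q_ex, Q_lig)` grid; unvisited states are blank.
#'
#' @param object A `capture_histogram` or `unbiased_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.capture_histogram <- function(object, ...) {
  d <- tidy(object)
  d$count[d$count == 0] <- NA
  ggplot2::ggplot(d, ggplot2::aes(.data$q_ex, .data$q_lig, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10", na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(Q[ex]), y = expression(Q[lig]),
                  fill = "counts", title = "Biased sampling frequency")
}

#' @rdname autoplot.capture_histogram
#' @export
autoplot.unbiased_distribution <- function(object, ...) {
  d <- tidy(object)
  d$p[d$p == 0] <- NA
  ggplot2::ggplot(d, ggplot2::aes(.data$q_ex, .data$q_lig, fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10", na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(Q[ex]), y = expression(Q[lig]),
                  fill = "P", title = "Unbiased distribution")
}

#' Plot the diagonal free-energy profile
#'
#' Free energy along `Q_ex = Q_lig`, zeroed at the non-interaction corner;
#' the value at `q = 0` is `dG_int`.
#'
#' @param object A `capture_fe`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.capture_fe <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d[!is.na(d$dg), ], ggplot2::aes(.data$q, .data$dg)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(Q[ex] == Q[lig]), y = "free energy (RT)",
                  title = sprintf("Diagonal profile; dG_int = %.2f RT", object$dg_int))
}

#' Plot per-probe relative free energies
#'
#' @param object A `capture_enrichment` from [enrich_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.capture_enrichment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$probe_id, .data$dg_rel)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "probe", y = "relative free energy (RT)",
                  title = "Capture free energy relative to the best probe")
}

#' @importFrom rlang .data
NULL
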