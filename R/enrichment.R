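#' Reads per kilobase per million mapped reads
#'
#' `rpkm = reads_target * 1e9 / (reads_lib * length_nt)`: the read count for
#' a sequence normalized by library depth (per million) and sequence length
#' (per kilobase). Vectorized over all arguments. Every downstream use
#' (enrichment ratios, free-energy differences) is invariant to the 1e9
#' constant, which only fixes the conventional scale.
#'
#' @param reads_target Read count(s) for the sequence(s).
#' @param reads_lib Total mapped reads of the library; must be positive.
#' @param length_nt Sequence length(s) in nt; must be positive.
#' @return RPKM value(s).
#' @examples
#' rpkm(10, 1e6, 1000) # 10
#' @export
rpkm <- function(reads_target, reads_lib, length_nt) {
  if (any(!is.finite(reads_lib)) || any(reads_lib <= 0)) {
    stop_lasso("`reads_lib` must be positive", "invalid_counts")
  }
  if (any(!is.finite(length_nt)) || any(length_nt <= 0)) {
    stop_lasso("`length_nt` must be positive", "invalid_counts")
  }
  if (any(reads_target < 0)) stop_lasso("`reads_target` must be non-negative", "invalid_counts")
  reads_target * 1e9 / (reads_lib * length_nt)
}

check_read_table <- function(tbl) {
  need <- c("sequence_id", "length_nt", "reads", "is_target", "probe_id")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    stop_lasso(paste0("read-count table is missing column(s): ",
                      paste(missing, collapse = ", ")), "invalid_table")
  }
  if (any(tbl$length_nt <= 0)) stop_lasso("all lengths must be positive", "invalid_table")
  if (any(tbl$reads < 0)) stop_lasso("read counts must be non-negative", "invalid_table")
  invisible(tbl)
}

#' Add per-row RPKM to a read-count table
#'
#' @param tbl Tibble with columns `sequence_id`, `length_nt`, `reads`,
#'   `is_target`, `probe_id`.
#' @param reads_lib Library size; defaults to the table's total reads,
#'   computed per probe (each probe's capture is a separate library).
#' @param pseudocount Added to every read count before normalizing (use 0.5
#'   to make zero-count rows usable in log transforms); default 0.
#' @return The table with an `rpkm` column appended.
#' @export
add_rpkm <- function(tbl, reads_lib = NULL, pseudocount = 0) {
  check_read_table(tbl)
  tbl <- dplyr::group_by(tbl, .data$probe_id)
  tbl <- dplyr::mutate(
    tbl,
    rpkm = rpkm(.data$reads + pseudocount,
                reads_lib %||% sum(.data$reads + pseudocount),
                .data$length_nt))
  dplyr::ungroup(tbl)
}

#' Capture enrichment ratio
#'
#' The ratio of the median RPKM of target sequences to the median RPKM of
#' off-target sequences (medians of even-length sets are the mean of the
#' central pair, R's default). Invariant to row order.
#'
#' @param tbl Read-count table (see [add_rpkm()]); an `rpkm` column is added
#'   if absent.
#' @param pseudocount Passed to [add_rpkm()] when RPKM must be computed.
#' @return The enrichment ratio (single number).
#' @export
enrichment_ratio <- function(tbl, pseudocount = 0) {
  if (!"rpkm" %in% names(tbl)) tbl <- add_rpkm(tbl, pseudocount = pseudocount)
  if (!any(tbl$is_target) || !any(!tbl$is_target)) {
    stop_lasso("need at least one target and one off-target row", "invalid_table")
  }
  m_t <- median(tbl$rpkm[tbl$is_target])
  m_o <- median(tbl$rpkm[!tbl$is_target])
  if (m_o <= 0) {
    stop_lasso("off-target median RPKM is zero; consider a pseudocount (add_rpkm(pseudocount = 0.5))",
               "zero_offtarget")
  }
  m_t / m_o
}

#' Free-energy difference between two probes from their RPKMs
#'
#' `dG(A - B) = -ln(RPKM_A / RPKM_B)` in RT units: a probe that captures
#' better (larger RPKM) sits at lower free energy. Antisymmetric under
#' swapping the arguments and additive along chains of comparisons.
#'
#' @param rpkm_a,rpkm_b Positive RPKM values (vectorized).
#' @return Free-energy difference(s) in RT units.
#' @export
dg_from_rpkm <- function(rpkm_a, rpkm_b) {
  if (any(!is.finite(rpkm_a)) || any(!is.finite(rpkm_b)) ||
      any(rpkm_a <= 0) || any(rpkm_b <= 0)) {
    stop_lasso("RPKM values must be positive; use a pseudocount for zero counts",
               "invalid_rpkm")
  }
  -log(rpkm_a / rpkm_b)
}

#' Relative free energies across a probe panel
#'
#' Assigns each probe the free energy `-ln(RPKM_p / max(RPKM))` so the probe
#' with the largest RPKM (the most efficient capture) defines the zero level;
#' all values are >= 0 and the minimum is exactly 0. Probes tied for the
#' maximum are all assigned 0.
#'
#' @param rpkms Named numeric vector of per-probe RPKMs, or a tibble with
#'   columns `probe_id` and `rpkm`.
#' @return Tibble with columns `probe_id`, `rpkm`, `dg_rel` (RT units).
#' @export
relative_dg <- function(rpkms) {
  if (is.data.frame(rpkms)) {
    if (!all(c("probe_id", "rpkm") %in% names(rpkms))) {
      stop_lasso("tibble input needs columns `probe_id` and `rpkm`", "invalid_table")
    }
    ids <- as.character(rpkms$probe_id)
    v <- rpkms$rpkm
  } else {
    v <- as.numeric(rpkms)
    ids <- names(rpkms) %||% as.character(seq_along(v))
  }
  if (length(v) < 2L) stop_lasso("need at least two probes", "invalid_table")
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop_lasso("all RPKM values must be positive", "invalid_rpkm")
  }
  dg <- -log(v / max(v))
  dg[v == max(v)] <- 0  # exact zero for ties at the maximum
  tibble(probe_id = ids, rpkm = v, dg_rel = dg)
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation between experimental and simulated free
#' energies (or any paired series), with the domain checks the comparison
#' needs: equal lengths of at least 3 and non-degenerate variance.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_lasso("`x` and `y` must have equal length", "invalid_argument")
  if (length(x) < 3L) stop_lasso("need at least 3 paired observations", "invalid_argument")
  if (anyNA(x) || anyNA(y)) stop_lasso("missing values are not allowed", "invalid_argument")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_lasso("correlation is undefined when a series has zero variance", "zero_variance")
  }
  cor(x, y, method = "pearson")
}

#' Per-probe enrichment summary
#'
#' Tidy summary of a read-count table: per probe, the median target and
#' off-target RPKM, the enrichment ratio, and the relative free energy
#' across the probe panel (zero at the probe with the largest median target
#' RPKM).
#'
#' @inheritParams enrichment_ratio
#' @return Tibble of class `capture_enrichment`, one row per probe:
#'   `probe_id`, `n_target`, `n_offtarget`, `median_rpkm_target`,
#'   `median_rpkm_offtarget`, `enrichment_ratio`, `dg_rel`.
#' @export
enrich_summary <- function(tbl, pseudocount = 0) {
  if (!"rpkm" %in% names(tbl)) tbl <- add_rpkm(tbl, pseudocount = pseudocount)
  out <- dplyr::summarise(
    dplyr::group_by(tbl, .data$probe_id),
    n_target = sum(.data$is_target),
    n_offtarget = sum(!.data$is_target),
    median_rpkm_target = median(.data$rpkm[.data$is_target]),
    median_rpkm_offtarget = median(.data$rpkm[!.data$is_target]),
    .groups = "drop"
  )
  out$enrichment_ratio <- out$median_rpkm_target / out$median_rpkm_offtarget
  rel <- relative_dg(tibble(probe_id = out$probe_id, rpkm = out$median_rpkm_target))
  out <- dplyr::left_join(out, rel[, c("probe_id", "dg_rel")], by = "probe_id")
  class(out) <- c("capture_enrichment", class(out))
  out
}
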