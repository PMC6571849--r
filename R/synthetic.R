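#' Synthetic-data configuration
#'
#' Parameters for generating scaled-down capture systems and read-count
#' tables with known ground truth. The defaults are an explicit desk-scale
#' reduction of the experimental setting: 8-nt arms, a 40-nt target, and
#' adapters of 10-120 nt standing in for the experimental 54-788 nt range;
#' read tables emulate a capture library with negative-binomial
#' overdispersion (`dispersion = 0.3`) and sequence lengths of 400-1500 nt.
#'
#' @param seed Integer seed governing all generation.
#' @param target_len Target length, nt.
#' @param arm_len Arm length, nt (both arms).
#' @param adapter_lens Integer vector of adapter lengths, nt.
#' @param n_targets,n_offtargets Rows per stratum in read tables.
#' @param true_enrichment Ground-truth target/off-target mean-count ratio.
#' @param dispersion Negative-binomial dispersion `alpha`
#'   (`var = mu + alpha * mu^2`); 0 selects Poisson counts.
#' @param mean_depth Mean off-target read count per kilobase.
#' @param propensities Optional positive per-probe capture propensities
#'   (recycled/named over `adapter_lens`); default all 1.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, target_len = 40L, arm_len = 8L,
                         adapter_lens = c(10L, 30L, 60L, 120L),
                         n_targets = 30L, n_offtargets = 120L,
                         true_enrichment = 10, dispersion = 0.3,
                         mean_depth = 100, propensities = NULL) {
  seed <- check_count(seed, "seed")
  target_len <- check_count(target_len, "target_len", min = 2L)
  arm_len <- check_count(arm_len, "arm_len", min = 1L)
  adapter_lens <- vapply(adapter_lens, check_count, integer(1),
                         name = "adapter_lens", min = 0L)
  check_number(true_enrichment, "true_enrichment")
  check_number(dispersion, "dispersion", allow_zero = TRUE)
  check_number(mean_depth, "mean_depth")
  if (is.null(propensities)) {
    propensities <- rep(1, length(adapter_lens))
  }
  if (length(propensities) != length(adapter_lens) || any(propensities <= 0)) {
    stop_lasso("`propensities` must be positive, one per adapter length", "invalid_argument")
  }
  structure(
    list(seed = seed, target_len = target_len, arm_len = arm_len,
         adapter_lens = adapter_lens,
         n_targets = check_count(n_targets, "n_targets", min = 1L),
         n_offtargets = check_count(n_offtargets, "n_offtargets", min = 1L),
         true_enrichment = true_enrichment, dispersion = dispersion,
         mean_depth = mean_depth, propensities = propensities),
    class = "synth_config"
  )
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Generate probe/target systems for an adapter sweep
#'
#' Draws one random target whose two ends serve as the arm sites
#' (extension site at the 5' end, ligation site at the 3' end) and builds
#' one probe per adapter length, all sharing identical arms - mirroring a
#' library experiment where probes differ only in their adapter. The arms
#' are exact reverse complements of their sites by construction, so every
#' generated pair passes [find_arm_complements()] with zero mismatches.
#'
#' @param cfg A [synth_config()].
#' @return Tibble with one row per adapter length: `adapter_length`,
#'   `probe` (list of [probe_spec()]), `target` (list of [target_spec()]).
#' @export
gen_capture_system <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$target_len < 2L * cfg$arm_len) {
    stop_lasso("target_len must be at least 2 * arm_len", "invalid_argument")
  }
  if (cfg$arm_len < 4L) {
    stop_lasso("arm_len must be at least 4 for a meaningful arm", "invalid_argument")
  }
  with_seed(cfg$seed, {
    tseq <- random_dna(cfg$target_len)
    ext_site <- c(0L, cfg$arm_len)
    lig_site <- c(cfg$target_len - cfg$arm_len, cfg$target_len)
    ext_arm <- reverse_complement(substr(tseq, ext_site[1] + 1L, ext_site[2]))
    lig_arm <- reverse_complement(substr(tseq, lig_site[1] + 1L, lig_site[2]))
    target <- target_spec(tseq, ext_site, lig_site, id = "synthetic_target")
    rows <- lapply(cfg$adapter_lens, function(al) {
      adapter <- if (al > 0) random_dna(al) else ""
      tibble(
        adapter_length = al,
        probe = list(probe_spec(ext_arm, lig_arm, adapter,
                                id = sprintf("AL%d", al))),
        target = list(target)
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate a synthetic read-count table with known enrichment
#'
#' Emulates the sequencing readout of a capture library: per probe,
#' `n_targets` target rows and `n_offtargets` off-target rows with lengths
#' uniform in 400-1500 nt and counts drawn from a negative binomial with
#' mean `mean_depth * length/1000`, multiplied by
#' `true_enrichment * propensity` for target rows. The same multiplicative
#' noise acts on both strata, so the median-ratio enrichment estimator
#' recovers `true_enrichment` without bias.
#'
#' @param cfg A [synth_config()].
#' @return A read-count tibble (`sequence_id`, `length_nt`, `reads`,
#'   `is_target`, `probe_id`) ready for [add_rpkm()] and friends.
#' @export
gen_read_table <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    rows <- lapply(seq_along(cfg$adapter_lens), function(k) {
      probe_id <- sprintf("AL%d", cfg$adapter_lens[k])
      n <- cfg$n_targets + cfg$n_offtargets
      is_target <- rep(c(TRUE, FALSE), c(cfg$n_targets, cfg$n_offtargets))
      len <- sample(400:1500, n, replace = TRUE)
      mu <- cfg$mean_depth * len / 1000 *
        ifelse(is_target, cfg$true_enrichment * cfg$propensities[k], 1)
      reads <- if (cfg$dispersion > 0) {
        rnbinom(n, size = 1 / cfg$dispersion, mu = mu)
      } else {
        rpois(n, mu)
      }
      tibble(
        sequence_id = sprintf("%s_%s%03d", probe_id,
                              ifelse(is_target, "tgt", "off"),
                              c(seq_len(cfg$n_targets), seq_len(cfg$n_offtargets))),
        length_nt = len, reads = reads, is_target = is_target,
        probe_id = probe_id
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Freely-jointed reference chains
#'
#' Samples ideal chains with fixed bond length (no bending, no excluded
#' volume). The exact mean squared end-to-end distance is
#' `(n_beads - 1) * bond_r0^2`, which makes these chains a closed-form
#' oracle for polymer-statistics checks.
#'
#' @param n_beads Beads per chain (>= 2).
#' @param bond_r0 Bond length, nm.
#' @param n_samples Number of independent chains.
#' @param seed Integer seed.
#' @return Array of dimension `c(n_samples, n_beads, 3)`.
#' @export
gen_ideal_chain <- function(n_beads, bond_r0 = 0.65, n_samples = 1L, seed = 1L) {
  n_beads <- check_count(n_beads, "n_beads", min = 2L)
  n_samples <- check_count(n_samples, "n_samples", min = 1L)
  check_number(bond_r0, "bond_r0")
  seed <- check_count(seed, "seed")
  with_seed(seed, {
    out <- array(0, dim = c(n_samples, n_beads, 3))
    for (s in seq_len(n_samples)) {
      v <- matrix(rnorm(3 * (n_beads - 1L)), ncol = 3)
      v <- v / sqrt(rowSums(v^2)) * bond_r0
      out[s, , ] <- rbind(c(0, 0, 0), apply(v, 2, cumsum))
    }
    out
  })
}
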