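#' Coarse-grained system state
#'
#' Bundles the bead coordinates of all chains (one bead per nucleotide) in a
#' periodic cubic box with the designed arm/site pair lists. Coordinates are
#' wrapped into `[0, box_side)^3`. Most users build a system with
#' [init_configuration()]; this low-level constructor accepts explicit
#' coordinates (and optionally more than two chains, e.g. for extensivity
#' checks). Pair indices are 0-based global bead indices, with the probe
#' chain first.
#'
#' @param chains List of n_i x 3 coordinate matrices (nm), one per chain;
#'   the first is taken as the probe, the second as the target.
#' @param box_side Box edge length, nm.
#' @param ext_pairs,lig_pairs Integer matrices with two columns (probe bead,
#'   target bead) of 0-based global indices; may have zero rows.
#' @param sequence Optional character vector of per-bead bases.
#' @return Object of class `capture_system`.
#' @export
capture_system <- function(chains, box_side, ext_pairs = NULL, lig_pairs = NULL,
                           sequence = NULL) {
  check_number(box_side, "box_side")
  if (!is.list(chains) || length(chains) < 1L) {
    stop_lasso("`chains` must be a non-empty list of coordinate matrices", "invalid_system")
  }
  chains <- lapply(chains, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L || nrow(m) < 1L || !is.numeric(m) || anyNA(m)) {
      stop_lasso("each chain must be a numeric n x 3 matrix", "invalid_system")
    }
    m %% box_side
  })
  n_per <- vapply(chains, nrow, integer(1))
  n <- sum(n_per)
  chain_id <- rep(seq_along(chains) - 1L, n_per)
  positions <- do.call(rbind, chains)
  dimnames(positions) <- NULL

  as_pairs <- function(p, name) {
    if (is.null(p)) return(matrix(integer(0), 0, 2))
    p <- as.matrix(p)
    storage.mode(p) <- "integer"
    if (ncol(p) != 2L) stop_lasso(sprintf("`%s` must have two columns", name), "invalid_system")
    if (nrow(p) > 0 && (min(p) < 0L || max(p) >= n)) {
      stop_lasso(sprintf("`%s` contains bead indices outside [0, %d)", name, n), "invalid_system")
    }
    p
  }
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (length(sequence) != n) {
      stop_lasso("`sequence` must have one base per bead", "invalid_system")
    }
  }
  structure(
    list(positions = positions, chain_id = chain_id, n_per_chain = n_per,
         box_side = box_side,
         ext_pairs = as_pairs(ext_pairs, "ext_pairs"),
         lig_pairs = as_pairs(lig_pairs, "lig_pairs"),
         sequence = sequence),
    class = "capture_system"
  )
}

#' @export
print.capture_system <- function(x, ...) {
  cat(sprintf("<capture_system> %d chain(s), %d beads, box %.1f nm, %d+%d designed pairs\n",
              length(x$n_per_chain), sum(x$n_per_chain), x$box_side,
              nrow(x$ext_pairs), nrow(x$lig_pairs)))
  invisible(x)
}

#' Bead coordinates as a tibble
#'
#' @param x A `capture_system`.
#' @param ... Unused.
#' @return Tibble with columns `chain`, `bead` (0-based within system),
#'   `x`, `y`, `z`, and `base` when sequences are attached.
#' @export
as_tibble.capture_system <- function(x, ...) {
  out <- tibble(
    chain = x$chain_id,
    bead = seq_len(nrow(x$positions)) - 1L,
    x = x$positions[, 1], y = x$positions[, 2], z = x$positions[, 3]
  )
  if (!is.null(x$sequence)) out$base <- x$sequence
  out
}

chain_positions <- function(system, chain) {
  system$positions[system$chain_id == chain, , drop = FALSE]
}

# grow one self-avoiding chain; returns an n x 3 matrix (unwrapped start point
# inside the box, steps of length r0, overlap checked against `occupied`)
grow_saw <- function(n_beads, r0, box, occupied, min_dist, max_tries = 200L,
                     max_restarts = 60L) {
  for (restart in seq_len(max_restarts)) {
    pos <- matrix(NA_real_, n_beads, 3)
    pos[1, ] <- runif(3, 0, box)
    ok <- TRUE
    for (i in seq_len(n_beads - 1L)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        v <- rnorm(3)
        v <- v / sqrt(sum(v^2))
        cand <- pos[i, ] + r0 * v
        prev <- rbind(occupied, pos[seq_len(max(i - 1L, 0L)), , drop = FALSE])
        if (nrow(prev) > 0 && min_dist > 0) {
          d <- sweep(prev, 2, cand)
          d <- d - box * round(d / box)
          if (min(rowSums(d^2)) < min_dist^2) next
        }
        pos[i + 1L, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pos %% box)
  }
  stop_lasso("failed to place a self-avoiding initial configuration; box too crowded",
             "configuration_error")
}

#' Initial configuration for a probe/target pair
#'
#' Places probe and target as independent self-avoiding random walks inside a
#' periodic box sized to contain both strands. Reproducible given `seed`.
#'
#' @param probe A [probe_spec()].
#' @param target A [target_spec()].
#' @param params An [energy_params()] (used for bond length and bead size).
#' @param box_side Box edge, nm. Default `1.2 x` the longer chain's contour
#'   length. Must be at least the longer contour length.
#' @param seed Integer seed; the same seed gives identical coordinates.
#' @return A [capture_system()] with the designed pair lists attached.
#' @export
init_configuration <- function(probe, target, params = energy_params(),
                               box_side = NULL, seed = 1L) {
  pairs <- find_arm_complements(probe, target)   # validates complementarity
  full_probe <- build_probe(probe)
  n_p <- nchar(full_probe$seq)
  n_t <- nchar(target$sequence)
  contour <- (max(n_p, n_t) - 1L) * params$bond_r0
  box_side <- box_side %||% (1.2 * contour)
  check_number(box_side, "box_side")
  if (box_side < contour) {
    stop_lasso(sprintf(
      "box_side %.2f nm is smaller than the longest contour length %.2f nm",
      box_side, contour), "configuration_error")
  }
  seed <- check_count(seed, "seed")
  min_dist <- if (params$ev_on) 0.7 * params$ev_sigma else 0
  chains <- with_seed(seed, {
    p <- grow_saw(n_p, params$bond_r0, box_side,
                  matrix(numeric(0), 0, 3), min_dist)
    t <- grow_saw(n_t, params$bond_r0, box_side, p, min_dist)
    list(probe = p, target = t)
  })
  ext <- pairs[pairs$arm == "extension", ]
  lig <- pairs[pairs$arm == "ligation", ]
  sys <- capture_system(
    chains, box_side,
    ext_pairs = cbind(ext$probe_index, n_p + ext$target_index),
    lig_pairs = cbind(lig$probe_index, n_p + lig$target_index),
    sequence = c(strsplit(full_probe$seq, "")[[1]],
                 strsplit(target$sequence, "")[[1]])
  )
  sys$seed <- seed
  sys
}
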