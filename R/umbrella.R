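#' Umbrella weight table
#'
#' Positive per-state weights on the `(Q_ex, Q_lig)` grid. Weights are stored
#' normalized so the minimum entry is 1 (only ratios matter for the biased
#' acceptance rule). The table carries a content hash so histograms sampled
#' under it can be matched back to it when unbiasing.
#'
#' @param w Positive numeric matrix, `n x n` with `n = n_intervals(bins)`,
#'   rows indexed by `Q_ex`, or a single number for a uniform table.
#' @param bins The [bin_table()] the grid refers to.
#' @return Object of class `weight_table`.
#' @export
weight_table <- function(w = 1, bins = default_bin_table()) {
  nq <- n_intervals(bins)
  if (length(w) == 1L) w <- matrix(as.numeric(w), nq, nq)
  w <- as.matrix(w)
  if (nrow(w) != nq || ncol(w) != nq) {
    stop_lasso(sprintf("weight table must be %d x %d for this bin table", nq, nq),
               "invalid_weights")
  }
  if (!is.numeric(w) || anyNA(w) || any(w <= 0)) {
    stop_lasso("all weights must be positive and finite", "invalid_weights")
  }
  w <- w / min(w)
  dimnames(w) <- list(q_ex = 0:(nq - 1L), q_lig = 0:(nq - 1L))
  structure(list(weights = w, edges = bins$edges, hash = table_hash(w)),
            class = "weight_table")
}

#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf("<weight_table> %d x %d grid, weight range [1, %.3g], hash %s\n",
              nrow(x$weights), ncol(x$weights), max(x$weights),
              substr(x$hash, 1, 8)))
  invisible(x)
}

as_weight_matrix <- function(weights, bins) {
  if (inherits(weights, "weight_table")) {
    if (!isTRUE(all.equal(weights$edges, bins$edges))) {
      stop_lasso("weight table was built for a different bin table", "invalid_weights")
    }
    return(weights$weights)
  }
  weight_table(weights, bins)$weights
}

#' Iteratively adapt umbrella weights to a flat histogram
#'
#' First stage of the umbrella pipeline: run a sampling block under the
#' current weights, divide each visited state's weight by its visit count
#' while leaving unvisited states untouched (`w <- w / max(counts, 1)`, a
#' multiplicative Wang-Landau-flavoured update), renormalize, and repeat
#' until converged or the iteration budget is exhausted. Two stabilizations
#' make the bare rule usable: block counts are first normalized by their
#' geometric mean over visited states, so the overall block size does not
#' swing the weights, and the per-block update factor of every state is
#' clamped to `exp(+-damping)`, so a single noisy block cannot shift any
#' weight by orders of magnitude. Leaving zero-count states untouched is
#' what keeps effectively-unreachable states from accumulating runaway
#' weights that would turn them into traps; exploration pressure arises
#' because the weights of well-visited states keep falling relative to the
#' frontier. In the converged limit the weights approach `1 / p(q)`, which
#' is what makes every state equally easy to visit.
#'
#' Convergence requires, within a single block, (a) histogram flatness
#' `min(count) / mean(count) >= flatness_target` over the states the block
#' visited, and (b) at least two round trips between the interaction corner
#' `(0, 0)` and the non-interaction corner `(max, max)` - the direct
#' certificate that a production run of several block lengths will sample
#' both corners, which is what the free-energy estimate needs.
#'
#' @param system A [capture_system()]; sampling continues from block to block.
#' @param params An [energy_params()].
#' @param move A [move_params()].
#' @param bins A [bin_table()].
#' @param flatness_target Required `min/mean` count ratio over visited
#'   states, in `(0, 1]`.
#' @param iteration_budget Maximum number of adaptation blocks.
#' @param block_steps Sampler steps per block.
#' @param init Starting [weight_table()] (uniform by default).
#' @param seed Integer seed (per-block seeds are derived from it).
#' @param engine Sampler engine, see [run_sampler()].
#' @param damping Cap (in log units) on the per-block weight change of any
#'   state.
#' @param require_cells Optional integer matrix of `(q_ex, q_lig)` states
#'   (one row each, 0-based) that must have been visited before convergence
#'   can be declared; flatness over already-visited states alone can
#'   otherwise stop the adaptation before rare corner states have ever been
#'   reached. The pipeline passes the two corner states.
#' @return A [weight_table()] with attributes `converged` (logical),
#'   `warning` (TRUE when the budget ran out before reaching flatness),
#'   `log` (per-iteration tibble: flatness, states visited, acceptance) and
#'   `system` (the evolved system, so later stages can continue from it).
#' @export
adapt_weights <- function(system, params, move, bins = default_bin_table(),
                          flatness_target = 0.6, iteration_budget = 30,
                          block_steps = 2e5, init = NULL, seed = NULL,
                          engine = c("vmmc", "metropolis"), damping = 2,
                          require_cells = NULL) {
  engine <- match.arg(engine)
  check_number(flatness_target, "flatness_target")
  if (flatness_target > 1) stop_lasso("`flatness_target` must be in (0, 1]", "invalid_argument")
  iteration_budget <- check_count(iteration_budget, "iteration_budget")
  block_steps <- check_count(block_steps, "block_steps", min = 1L)
  seed <- resolve_seed(seed, move)
  check_number(damping, "damping")
  wt <- init %||% weight_table(1, bins)
  wt <- weight_table(as_weight_matrix(wt, bins), bins)
  nq <- n_intervals(bins)
  log <- list()
  converged <- FALSE
  for (it in seq_len(iteration_budget)) {
    run <- run_sampler(system, params, move, n_steps = block_steps,
                       weights = wt, bins = bins,
                       stride = max(block_steps %/% 5000L, 1L),
                       seed = seed + it, engine = engine)
    system <- run$system
    counts <- run$histogram
    visited <- counts > 0
    flat <- if (any(visited)) min(counts[visited]) / mean(counts[visited]) else 0
    trips <- corner_round_trips(run$trajectory, nq)
    required_ok <- is.null(require_cells) ||
      all(counts[cbind(require_cells[, 1] + 1L, require_cells[, 2] + 1L)] > 0)
    log[[it]] <- tibble(iteration = it, flatness = flat,
                        n_visited = sum(visited), round_trips = trips,
                        acceptance = run$accepted / run$n_steps)
    if (flat >= flatness_target && trips >= 2 && required_ok) {
      converged <- TRUE
      break
    }
    gmean <- exp(mean(log(counts[visited])))
    fac <- counts / gmean
    fac[counts == 0] <- 1  # unvisited states are left untouched
    fac <- pmin(pmax(fac, exp(-damping)), exp(damping))
    wt <- weight_table(wt$weights / fac, bins)
  }
  structure(wt, converged = converged, warning = !converged,
            log = dplyr::bind_rows(log), system = system,
            class = class(wt))
}

# number of completed transitions between the (0,0) and (max,max) corners
# along a recorded OP trajectory
corner_round_trips <- function(trajectory, nq) {
  at00 <- trajectory$q_ex == 0L & trajectory$q_lig == 0L
  atMM <- trajectory$q_ex == nq - 1L & trajectory$q_lig == nq - 1L
  lab <- ifelse(at00, 1L, ifelse(atMM, 2L, NA_integer_))
  lab <- lab[!is.na(lab)]
  if (length(lab) < 2L) return(0L)
  sum(diff(lab) != 0L)
}

#' Sample a biased order-parameter histogram
#'
#' Second and third stage of the umbrella pipeline: equilibrate for
#' `n_equilibration` steps under the fixed weights, then accumulate the
#' `(Q_ex, Q_lig)` occupancy histogram over `n_steps` production steps.
#'
#' @inheritParams adapt_weights
#' @param weights A [weight_table()] (typically from [adapt_weights()]).
#' @param n_steps Production steps.
#' @param n_equilibration Discarded equilibration steps.
#' @param stride Trajectory recording interval (used for error bars).
#' @return Object of class `capture_histogram`: `counts` matrix,
#'   `n_samples`, the `weight_table` used (and its hash), the recorded
#'   trajectory, seed and acceptance statistics.
#' @export
sample_biased <- function(system, params, move, weights,
                          bins = default_bin_table(), n_steps = 1e6,
                          n_equilibration = 1e5, stride = 100, seed = NULL,
                          engine = c("vmmc", "metropolis")) {
  engine <- match.arg(engine)
  wt <- if (inherits(weights, "weight_table")) weights else weight_table(weights, bins)
  seed <- resolve_seed(seed, move)
  run <- run_sampler(system, params, move, n_steps = n_steps, weights = wt,
                     bins = bins, n_equil = n_equilibration, stride = stride,
                     seed = seed, engine = engine)
  structure(
    list(counts = run$histogram, n_samples = sum(run$histogram),
         weight_table = wt, weight_hash = wt$hash,
         trajectory = run$trajectory, edges = bins$edges,
         acceptance = run$accepted / run$n_steps,
         capped_rejections = run$capped_rejections,
         system = run$system, seed = seed, engine = engine),
    class = "capture_histogram"
  )
}

#' @export
print.capture_histogram <- function(x, ...) {
  cat(sprintf("<capture_histogram> %d x %d grid, %g samples, %d states visited, weight hash %s\n",
              nrow(x$counts), ncol(x$counts), x$n_samples, sum(x$counts > 0),
              substr(x$weight_hash, 1, 8)))
  invisible(x)
}

#' Remove the umbrella bias from a sampled histogram
#'
#' Transforms biased counts into the unbiased state distribution:
#' `p(q) proportional to counts(q) / w(q)`, normalized to 1. The histogram
#' must have been sampled under the supplied weight table (hashes are
#' compared) so that runs and tables cannot be mixed up. States never visited
#' get `p = 0` and are reported as gaps downstream, not as evidence of zero
#' probability.
#'
#' @param hist A `capture_histogram` from [sample_biased()].
#' @param weights The [weight_table()] the histogram was sampled under
#'   (defaults to the one stored in the histogram).
#' @return Object of class `unbiased_distribution` with matrix `p` summing
#'   to 1 (within 1e-12).
#' @export
unbias <- function(hist, weights = hist$weight_table) {
  stopifnot(inherits(hist, "capture_histogram"))
  wt <- if (inherits(weights, "weight_table")) weights else {
    weight_table(weights, bin_table(hist$edges))
  }
  if (!identical(wt$hash, hist$weight_hash)) {
    stop_lasso("weight-table hash does not match the one this histogram was sampled under",
               "hash_mismatch")
  }
  if (hist$n_samples == 0) {
    stop_lasso("histogram is empty; nothing to unbias", "empty_histogram")
  }
  p <- hist$counts / wt$weights
  p <- p / sum(p)
  structure(list(p = p, edges = hist$edges, n_samples = hist$n_samples,
                 weight_hash = wt$hash),
            class = "unbiased_distribution")
}

#' @export
print.unbiased_distribution <- function(x, ...) {
  nq <- nrow(x$p) - 1L
  cat(sprintf("<unbiased_distribution> %d x %d grid; P(0,0) = %.3g, P(%d,%d) = %.3g\n",
              nrow(x$p), ncol(x$p), x$p[1, 1], nq, nq, x$p[nq + 1L, nq + 1L]))
  invisible(x)
}

corner_ratio_dg <- function(p) {
  nq <- nrow(p)
  p00 <- p[1, 1]
  pmm <- p[nq, nq]
  if (p00 <= 0 || pmm <= 0) {
    stop_lasso(paste0(
      "a corner state was never visited (P(0,0) or P(max,max) is zero); ",
      "the free energy is unbounded on this sample - run longer or adapt weights further"),
      "unbounded_estimate")
  }
  -log(p00 / pmm)
}

#' Probe-target interaction free energy
#'
#' The interaction free energy in units of RT,
#' `dG_int / RT = -ln( P(0,0) / P(max,max) )`, i.e. minus the log-ratio of
#' the unbiased probabilities of the fully bound corner (both arms engaged)
#' and the fully free corner. A statistical error is attached by block
#' bootstrap over the recorded trajectory when a histogram with a trajectory
#' is supplied.
#'
#' @param p An [unbias()]ed distribution.
#' @param hist Optional `capture_histogram` (the one `p` came from); enables
#'   the block-bootstrap error estimate.
#' @param n_blocks Number of contiguous trajectory blocks.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap resampling.
#' @return Object of class `capture_fe` with fields `dg_int` (RT units),
#'   `se` (RT; `NA` without a trajectory), and the diagonal free-energy
#'   `profile` tibble (see [diagonal_profile()]).
#' @export
interaction_free_energy <- function(p, hist = NULL, n_blocks = 20,
                                    n_boot = 200, seed = 1L) {
  stopifnot(inherits(p, "unbiased_distribution"))
  dg <- corner_ratio_dg(p$p)
  se <- NA_real_
  if (!is.null(hist) && nrow(hist$trajectory) >= n_blocks * 2) {
    se <- block_bootstrap_se(hist, n_blocks = n_blocks, n_boot = n_boot, seed = seed)
  }
  structure(
    list(dg_int = dg, se = se, profile = diagonal_profile(p),
         p = p, n_samples = p$n_samples),
    class = "capture_fe"
  )
}

# block bootstrap over the recorded OP trajectory: resample contiguous blocks,
# rebuild the histogram, unbias, recompute the corner ratio
block_bootstrap_se <- function(hist, n_blocks = 20, n_boot = 200, seed = 1L) {
  tr <- hist$trajectory
  nq <- nrow(hist$counts)
  n <- nrow(tr)
  blk <- rep(seq_len(n_blocks), each = ceiling(n / n_blocks))[seq_len(n)]
  cell <- tr$q_ex + nq * tr$q_lig  # 0-based flat index
  w <- as.numeric(hist$weight_table$weights)
  per_block <- lapply(seq_len(n_blocks), function(b) {
    tabulate(cell[blk == b] + 1L, nbins = nq * nq)
  })
  dgs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      pick <- sample.int(n_blocks, n_blocks, replace = TRUE)
      counts <- Reduce(`+`, per_block[pick])
      pp <- counts / w
      s <- sum(pp)
      if (s <= 0 || pp[1] <= 0 || pp[nq * nq] <= 0) return(NA_real_)
      -log(pp[1] / pp[nq * nq])
    }, numeric(1))
  })
  dgs <- dgs[is.finite(dgs)]
  if (length(dgs) < 2) return(NA_real_)
  sd(dgs)
}

#' Free-energy profile along the diagonal
#'
#' The free energy `-ln P(q, q)` of the diagonal states `Q_ex = Q_lig = q`,
#' shifted so the non-interaction corner `q = max` sits at zero. States with
#' zero counts are reported as gaps (`NA`), not as zeros. The end-to-end
#' difference of the profile equals `dg_int` exactly.
#'
#' @param p An [unbias()]ed distribution.
#' @return Tibble with columns `q`, `p`, `dg` (RT units).
#' @export
diagonal_profile <- function(p) {
  stopifnot(inherits(p, "unbiased_distribution"))
  nq <- nrow(p$p)
  pd <- diag(p$p)
  ref <- pd[nq]
  dg <- ifelse(pd > 0, -log(pd), NA_real_)
  if (ref > 0) dg <- dg - (-log(ref))
  tibble(q = 0:(nq - 1L), p = pd, dg = dg)
}

#' @export
print.capture_fe <- function(x, ...) {
  cat(sprintf("<capture_fe> dG_int = %.3f RT (se %.3f), %g samples\n",
              x$dg_int, x$se, x$n_samples))
  invisible(x)
}
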