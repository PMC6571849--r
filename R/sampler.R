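#' Monte Carlo move parameters
#'
#' Step sizes for the samplers. Defaults (0.25 nm translation, 0.2 rad
#' rotation) target a 30-50% acceptance rate on the reference systems.
#' `cluster_size_cap` limits how many beads a VMMC cluster may recruit;
#' moves exceeding the cap are auto-rejected and counted. The default cap
#' `Inf` resolves to the total bead count at run time (no cap).
#'
#' @param max_translation Maximum per-axis displacement, nm.
#' @param max_rotation Maximum rotation about the seed bead, radians.
#' @param cluster_size_cap Maximum VMMC cluster size (beads).
#' @param seed Optional default seed used by the samplers.
#' @return Object of class `move_params`.
#' @export
move_params <- function(max_translation = 0.25, max_rotation = 0.2,
                        cluster_size_cap = Inf, seed = NULL) {
  check_number(max_translation, "max_translation")
  check_number(max_rotation, "max_rotation")
  if (!(is.numeric(cluster_size_cap) && length(cluster_size_cap) == 1L &&
        (is.infinite(cluster_size_cap) || (cluster_size_cap >= 1 &&
                                           cluster_size_cap == round(cluster_size_cap))))) {
    stop_lasso("`cluster_size_cap` must be a whole number >= 1 or Inf", "invalid_argument")
  }
  if (!is.null(seed)) seed <- check_count(seed, "seed")
  structure(list(max_translation = max_translation, max_rotation = max_rotation,
                 cluster_size_cap = cluster_size_cap, seed = seed),
            class = "move_params")
}

move_for_cpp <- function(move, n_beads) {
  cap <- move$cluster_size_cap
  if (is.infinite(cap)) cap <- n_beads
  list(max_translation = move$max_translation, max_rotation = move$max_rotation,
       cluster_size_cap = as.integer(cap))
}

resolve_seed <- function(seed, move) {
  seed <- seed %||% move$seed
  if (is.null(seed)) stop_lasso("a `seed` is required (argument or move_params$seed)",
                                "invalid_argument")
  check_count(seed, "seed")
}

#' Run a Monte Carlo sampler over a capture system
#'
#' Advances the system by `n_steps + n_equil` elementary moves with either
#' the single-bead Metropolis sampler or the Virtual Move Monte Carlo
#' (VMMC) cluster sampler, optionally under a 2D umbrella bias: when a
#' `weights` table is supplied the acceptance of every move is multiplied by
#' `w_new / w_old`, the weights evaluated on the order-parameter state
#' before and after the move, so that rare states can be visited. The
#' trajectory of `(Q_ex, Q_lig)` is recorded every `stride` steps after
#' equilibration, and a full 2D histogram accumulates every post-equilibration
#' step.
#'
#' @param system A [capture_system()].
#' @param params An [energy_params()].
#' @param move A [move_params()].
#' @param n_steps Number of recorded (production) steps.
#' @param weights Optional [weight_table()] for umbrella biasing.
#' @param bins A [bin_table()].
#' @param n_equil Discarded equilibration steps before recording.
#' @param stride Trajectory recording interval.
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param engine `"vmmc"` or `"metropolis"`.
#' @return A list of class `sampler_run`: the final `system`, the `histogram`
#'   count matrix (rows `q_ex`, columns `q_lig`), a trajectory tibble, and
#'   acceptance bookkeeping (`accepted + rejected == n_steps + n_equil`).
#' @export
run_sampler <- function(system, params, move, n_steps,
                        weights = NULL, bins = default_bin_table(),
                        n_equil = 0, stride = 1, seed = NULL,
                        engine = c("vmmc", "metropolis")) {
  stopifnot(inherits(system, "capture_system"), inherits(params, "energy_params"),
            inherits(move, "move_params"), inherits(bins, "bin_table"))
  engine <- match.arg(engine)
  n_steps <- check_count(n_steps, "n_steps")
  n_equil <- check_count(n_equil, "n_equil")
  stride <- check_count(stride, "stride", min = 1L)
  seed <- resolve_seed(seed, move)
  wmat <- NULL
  if (!is.null(weights)) {
    wmat <- as_weight_matrix(weights, bins)
    if (any(wmat <= 0)) {
      stop_lasso("umbrella weights must be strictly positive for every state",
                 "invalid_weights")
    }
  }
  res <- cg_run_sampler(system$positions, system$chain_id, system$box_side,
                        params_for_cpp(params), system$ext_pairs, system$lig_pairs,
                        bin_table_edges(bins), wmat,
                        move_for_cpp(move, nrow(system$positions)),
                        n_steps, n_equil, stride, seed,
                        engine = if (engine == "vmmc") 1L else 0L)
  out_sys <- system
  out_sys$positions <- res$positions
  nq <- n_intervals(bins)
  hist <- res$hist
  dimnames(hist) <- list(q_ex = 0:(nq - 1L), q_lig = 0:(nq - 1L))
  structure(
    list(
      system = out_sys,
      histogram = hist,
      trajectory = tibble(
        step = if (length(res$traj_qex)) seq(0L, by = stride,
                                             length.out = length(res$traj_qex)) else integer(0),
        q_ex = res$traj_qex, q_lig = res$traj_qlig,
        ree2_probe = res$traj_ree2
      ),
      accepted = res$accepted,
      rejected = res$n_steps - res$accepted,
      n_steps = res$n_steps,
      capped_rejections = res$capped,
      final_op = c(q_ex = res$q_ex, q_lig = res$q_lig),
      engine = engine, seed = seed, stride = stride
    ),
    class = "sampler_run"
  )
}

#' @export
print.sampler_run <- function(x, ...) {
  cat(sprintf("<sampler_run> %s, %d steps, acceptance %.1f%%, final (Qex,Qlig) = (%d,%d)\n",
              x$engine, x$n_steps, 100 * x$accepted / max(x$n_steps, 1),
              x$final_op[1], x$final_op[2]))
  invisible(x)
}

bin_table_edges <- function(bins) bins$edges

#' Single Metropolis or VMMC step
#'
#' One elementary move of the corresponding sampler; rejected moves return
#' the input state unchanged. These are thin single-step wrappers around
#' [run_sampler()], mainly for tests and didactics.
#'
#' @inheritParams run_sampler
#' @return List with elements `system` and `accepted`.
#' @export
metropolis_step <- function(system, params, move, seed = NULL,
                            weights = NULL, bins = default_bin_table()) {
  r <- run_sampler(system, params, move, n_steps = 1L, weights = weights,
                   bins = bins, seed = seed, engine = "metropolis")
  list(system = r$system, accepted = r$accepted == 1)
}

#' @rdname metropolis_step
#' @export
vmmc_step <- function(system, params, move, seed = NULL,
                      weights = NULL, bins = default_bin_table()) {
  r <- run_sampler(system, params, move, n_steps = 1L, weights = weights,
                   bins = bins, seed = seed, engine = "vmmc")
  list(system = r$system, accepted = r$accepted == 1)
}
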