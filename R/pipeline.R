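#' Capture-pipeline configuration
#'
#' Collects everything a full umbrella run needs: energy parameters, move
#' sizes, bin table, box, seed, and the step counts of the three stages
#' (weight adaptation, equilibration, production). Unknown keys are
#' rejected so typos cannot silently change a run.
#'
#' @param params [energy_params()].
#' @param move [move_params()].
#' @param bins [bin_table()].
#' @param box_side Box edge in nm, or `NULL` for the default sizing rule of
#'   [init_configuration()].
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param engine `"vmmc"` or `"metropolis"`.
#' @param adapt_blocks,block_steps,flatness_target Weight-adaptation stage.
#' @param equil_steps,production_steps,stride Equilibration/production stage.
#' @param out_dir Optional directory; when set, every intermediate (weights,
#'   histogram, unbiased distribution, result JSON) is persisted there.
#' @return List of class `capture_config`.
#' @export
capture_config <- function(params = energy_params(), move = move_params(),
                           bins = default_bin_table(), box_side = NULL,
                           seed = 1L, engine = c("vmmc", "metropolis"),
                           adapt_blocks = 25, block_steps = 2e5,
                           flatness_target = 0.6,
                           equil_steps = 1e5, production_steps = 1e6,
                           stride = 100, out_dir = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "energy_params"), inherits(move, "move_params"),
            inherits(bins, "bin_table"))
  cfg <- list(
    params = params, move = move, bins = bins, box_side = box_side,
    seed = check_count(seed, "seed"), engine = engine,
    adapt_blocks = check_count(adapt_blocks, "adapt_blocks"),
    block_steps = check_count(block_steps, "block_steps", min = 1L),
    flatness_target = check_number(flatness_target, "flatness_target"),
    equil_steps = check_count(equil_steps, "equil_steps"),
    production_steps = check_count(production_steps, "production_steps", min = 1L),
    stride = check_count(stride, "stride", min = 1L),
    out_dir = out_dir
  )
  structure(cfg, class = "capture_config")
}

required_config_keys <- function() {
  c("params", "move", "bins", "box_side", "seed", "engine", "adapt_blocks",
    "block_steps", "flatness_target", "equil_steps", "production_steps",
    "stride", "out_dir")
}

validate_config <- function(config) {
  if (!inherits(config, "capture_config")) {
    if (!is.list(config)) stop_lasso("`config` must be a capture_config", "invalid_config")
    missing <- setdiff(setdiff(required_config_keys(), c("box_side", "out_dir")),
                       names(config))
    if (length(missing)) {
      stop_lasso(paste0("config is missing required key(s): ",
                        paste(missing, collapse = ", ")), "invalid_config")
    }
    unknown <- setdiff(names(config), required_config_keys())
    if (length(unknown)) {
      stop_lasso(paste0("config has unknown key(s): ", paste(unknown, collapse = ", ")),
                 "invalid_config")
    }
    config <- do.call(capture_config, config)
  }
  config
}

config_hash <- function(config) {
  keep <- config[setdiff(required_config_keys(), "out_dir")]
  rlang::hash(lapply(keep, function(x) if (is.list(x)) unclass(x) else x))
}

#' Run the full three-stage capture free-energy pipeline
#'
#' End-to-end umbrella-sampling estimate of the probe-target interaction
#' free energy for one probe/target pair: (1) adapt the umbrella weights
#' until the order-parameter histogram is flat, (2) equilibrate under the
#' final weights, (3) production sampling, then unbias the histogram and
#' compute `dG_int` with a block-bootstrap error bar. All intermediates are
#' returned (and persisted when `config$out_dir` is set) together with the
#' config hash and seed for provenance.
#'
#' @param probe A [probe_spec()].
#' @param target A [target_spec()].
#' @param config A [capture_config()].
#' @param system Optional pre-built [capture_system()] to start from
#'   (default: [init_configuration()] under the config seed).
#' @return A `capture_fe` result (see [interaction_free_energy()]) with
#'   attributes `weights`, `histogram`, `distribution`, `config`, `timings`.
#' @export
run_capture_pipeline <- function(probe, target, config = capture_config(),
                                 system = NULL) {
  config <- validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what, expr) {
    t1 <- proc.time()[["elapsed"]]
    message(sprintf("[lassocapture] stage %s ...", what))
    val <- force(expr)
    message(sprintf("[lassocapture] stage %s done (%.1f s)", what,
                    proc.time()[["elapsed"]] - t1))
    val
  }
  if (is.null(system)) {
    system <- stage("init", init_configuration(probe, target, config$params,
                                               box_side = config$box_side,
                                               seed = config$seed))
  }
  wt <- stage("adapt-weights", adapt_weights(
    system, config$params, config$move, config$bins,
    flatness_target = config$flatness_target,
    iteration_budget = config$adapt_blocks,
    block_steps = config$block_steps,
    seed = config$seed * 1000L, engine = config$engine,
    require_cells = rbind(c(0L, 0L),
                          rep(n_intervals(config$bins) - 1L, 2L))))
  if (isTRUE(attr(wt, "warning"))) {
    warning("weight adaptation exhausted its budget before reaching flatness; ",
            "continuing with the best table", call. = FALSE)
  }
  hist <- stage("production", sample_biased(
    attr(wt, "system"), config$params, config$move, wt, config$bins,
    n_steps = config$production_steps, n_equilibration = config$equil_steps,
    stride = config$stride, seed = config$seed * 1000L + 777L,
    engine = config$engine))
  p <- unbias(hist, wt)
  fe <- interaction_free_energy(p, hist, seed = config$seed)
  attr(fe, "weights") <- wt
  attr(fe, "histogram") <- hist
  attr(fe, "distribution") <- p
  attr(fe, "config") <- config
  attr(fe, "config_hash") <- config_hash(config)
  attr(fe, "timings") <- proc.time()[["elapsed"]] - t0
  if (!is.null(config$out_dir)) persist_pipeline(fe, config)
  fe
}

persist_pipeline <- function(fe, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- attr(fe, "weights")
  hist <- attr(fe, "histogram")
  p <- attr(fe, "distribution")
  hdr <- c(seed = config$seed, config_hash = attr(fe, "config_hash"))
  write_grid_csv(wt$weights, file.path(config$out_dir, "weights.csv"),
                 c(hdr, weight_hash = wt$hash, edges = paste(config$bins$edges, collapse = " ")))
  write_grid_csv(hist$counts, file.path(config$out_dir, "histogram.csv"),
                 c(hdr, weight_hash = hist$weight_hash,
                   n_samples = hist$n_samples,
                   edges = paste(config$bins$edges, collapse = " ")))
  write_grid_csv(p$p, file.path(config$out_dir, "unbiased.csv"),
                 c(hdr, weight_hash = p$weight_hash,
                   edges = paste(config$bins$edges, collapse = " ")))
  jsonlite::write_json(
    list(dg_int = fe$dg_int, se = fe$se, n_samples = fe$n_samples,
         seed = config$seed, config_hash = attr(fe, "config_hash"),
         elapsed_s = attr(fe, "timings"),
         diagonal = attr(fe, "profile") %||% fe$profile),
    file.path(config$out_dir, "free_energy.json"),
    auto_unbox = TRUE, digits = NA, na = "null", dataframe = "columns")
  invisible(NULL)
}
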