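test_that("unbias divides counts by weights and normalizes", {
  bins <- bin_table(c(0, 1))  # 2x2 grid
  wt <- weight_table(rbind(c(9, 1), c(1, 1)), bins)
  h <- structure(list(counts = rbind(c(90, 0), c(0, 10)), n_samples = 100,
                      weight_table = wt, weight_hash = wt$hash,
                      trajectory = tibble::tibble(step = integer(0), q_ex = integer(0),
                                                  q_lig = integer(0)),
                      edges = bins$edges),
                 class = "capture_histogram")
  p <- unbias(h, wt)
  expect_equal(sum(p$p), 1, tolerance = 1e-12)
  expect_equal(p$p[1, 1], 0.5)   # counts 90 / weight 9 == counts 10 / weight 1
  expect_equal(p$p[2, 2], 0.5)
  expect_equal(p$p[1, 2], 0)     # unvisited cell stays an exact zero

  # uniform weights leave the counts' proportions untouched
  wu <- weight_table(1, bins)
  hu <- h; hu$weight_table <- wu; hu$weight_hash <- wu$hash
  pu <- unbias(hu, wu)
  expect_equal(pu$p[1, 1], 0.9)

  # cell-wise counts == weights cancels exactly to the uniform distribution
  wc <- weight_table(rbind(c(4, 2), c(2, 8)), bins)
  hc <- h; hc$counts <- wc$weights; hc$n_samples <- sum(wc$weights)
  hc$weight_table <- wc; hc$weight_hash <- wc$hash
  expect_true(all(abs(unbias(hc, wc)$p - 0.25) < 1e-12))

  # histogram sampled under a different table must be refused
  expect_error(unbias(h, weight_table(rbind(c(2, 1), c(1, 1)), bins)),
               class = "lassocapture_hash_mismatch")
})

test_that("interaction free energy is the corner log-ratio", {
  bins <- bin_table(c(0, 1, 2))
  mk <- function(p00, pmm) {
    p <- matrix((1 - p00 - pmm) / 7, 3, 3)
    p[1, 1] <- p00; p[3, 3] <- pmm
    structure(list(p = p, edges = bins$edges, n_samples = 1000,
                   weight_hash = "x"),
              class = "unbiased_distribution")
  }
  expect_equal(interaction_free_energy(mk(0.2, 0.2))$dg_int, 0)
  expect_equal(interaction_free_energy(mk(0.1 * exp(-2), 0.1))$dg_int, 2,
               tolerance = 1e-12)
  bad <- mk(0.3, 0.3); bad$p[1, 1] <- 0
  expect_error(interaction_free_energy(bad), class = "lassocapture_unbounded_estimate")

  # diagonal profile: flat for uniform p, end-to-end difference equals dG
  unif <- structure(list(p = matrix(1 / 9, 3, 3), edges = bins$edges,
                         n_samples = 1, weight_hash = "x"),
                    class = "unbiased_distribution")
  expect_true(all(abs(diagonal_profile(unif)$dg) < 1e-12))
  pf <- diagonal_profile(mk(0.05, 0.2))
  expect_equal(pf$dg[1] - pf$dg[3], interaction_free_energy(mk(0.05, 0.2))$dg_int)
})

test_that("weight adaptation handles degenerate budgets and flat systems", {
  p <- toy_pair_params(hyb_epsilon = 0)
  sys <- toy_pair_system()
  bins <- bin_table(c(0, 2.2))
  mv <- move_params(0.3, 0.3)
  none <- adapt_weights(sys, p, mv, bins, iteration_budget = 0, seed = 1)
  expect_true(attr(none, "warning"))
  expect_true(all(none$weights == 1))

  # a system already flat over its two states converges immediately
  # (the 4.4 nm edge splits the toy box into two equal-probability cells)
  flat <- adapt_weights(sys, p, mv, bin_table(c(0, 4.4)), flatness_target = 0.3,
                        iteration_budget = 5, block_steps = 2e4, seed = 2)
  expect_true(attr(flat, "converged"))
  expect_equal(nrow(attr(flat, "log")), 1L)
})

test_that("adaptation inverts a known two-state probability ratio", {
  p <- toy_pair_params(hyb_epsilon = 5)
  sys <- toy_pair_system()
  bins <- bin_table(c(0, 1.2))
  z <- oracle_cell_weights(p, bins$edges, sys$box_side)
  true_ratio <- z[2] / z[1]  # p(far)/p(near), the converged w(near)/w(far)
  # a two-cell histogram with min/mean >= 0.85 pins the weights within ~35%
  wt <- adapt_weights(sys, p, move_params(0.3, 0.3), bins, flatness_target = 0.85,
                      iteration_budget = 60, block_steps = 1e5, seed = 31,
                      engine = "metropolis")
  expect_true(attr(wt, "converged"))
  got <- wt$weights[1, 1] / wt$weights[2, 2]
  expect_lt(abs(log(got / true_ratio)), log(1.35))
})

test_that("biased sampling under converged weights is nearly flat", {
  p <- toy_pair_params(hyb_epsilon = 6)
  sys <- toy_pair_system()
  bins <- toy_pair_bins()
  mv <- move_params(0.3, 0.4)
  wt <- adapt_weights(sys, p, mv, bins, flatness_target = 0.55,
                      iteration_budget = 30, block_steps = 5e4, seed = 101)
  expect_true(attr(wt, "converged"))
  h <- sample_biased(attr(wt, "system"), p, mv, wt, bins, n_steps = 4e5,
                     n_equilibration = 4e4, seed = 102)
  diagc <- diag(h$counts)  # the toy lives on the diagonal
  expect_true(all(diagc > 0))
  expect_lt(max(diagc) / min(diagc), 3)
  expect_equal(sum(h$counts), h$n_samples)

  # empty production: defined empty histogram
  h0 <- sample_biased(sys, p, mv, wt, bins, n_steps = 0, n_equilibration = 0,
                      seed = 1)
  expect_equal(h0$n_samples, 0)
  expect_error(unbias(h0, wt), class = "lassocapture_empty_histogram")

  # fixed seed reproduces the histogram exactly
  h2 <- sample_biased(sys, p, mv, wt, bins, n_steps = 5e4,
                      n_equilibration = 1e4, seed = 77)
  h3 <- sample_biased(sys, p, mv, wt, bins, n_steps = 5e4,
                      n_equilibration = 1e4, seed = 77)
  expect_identical(h2$counts, h3$counts)
})

test_that("pipeline runs end to end, persists artifacts, and is deterministic", {
  cfg_syn <- synth_config(seed = 5, arm_len = 4L, target_len = 16L,
                          adapter_lens = 8L)
  pair <- gen_capture_system(cfg_syn)
  out <- withr::local_tempdir()
  config <- capture_config(
    params = energy_params(hyb_epsilon = 1.5),
    move = move_params(0.4, 0.7),
    bins = bin_table(c(0, 1.7, 5)),
    seed = 3, adapt_blocks = 12, block_steps = 1e5, flatness_target = 0.15,
    equil_steps = 5e4, production_steps = 4e5, stride = 100,
    out_dir = file.path(out, "run1")
  )
  fe1 <- suppressMessages(suppressWarnings(
    run_capture_pipeline(pair$probe[[1]], pair$target[[1]], config)))
  expect_true(is.finite(fe1$dg_int))
  expect_true(file.exists(file.path(out, "run1", "weights.csv")))
  expect_true(file.exists(file.path(out, "run1", "histogram.csv")))
  expect_true(file.exists(file.path(out, "run1", "free_energy.json")))

  config2 <- config; config2$out_dir <- NULL
  fe2 <- suppressMessages(suppressWarnings(
    run_capture_pipeline(pair$probe[[1]], pair$target[[1]], config2)))
  expect_identical(fe1$dg_int, fe2$dg_int)

  # tidiers expose the result in broom style
  g <- glance(fe1)
  expect_equal(g$dg_int, fe1$dg_int)
  expect_equal(nrow(tidy(fe1)), n_intervals(config$bins))

  # structured config validation
  expect_error(lassocapture:::validate_config(list(seed = 1)),
               class = "lassocapture_invalid_config")
  expect_error(lassocapture:::validate_config(c(unclass(config), list(bogus = 1))),
               class = "lassocapture_invalid_config")
})
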