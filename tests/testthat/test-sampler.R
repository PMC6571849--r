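test_that("trajectories are seed-deterministic and bookkeeping is exact", {
  p <- toy_pair_params()
  sys <- toy_four_bead()
  bins <- bin_table(c(0, 0.9, 1.8, 2.7))
  for (eng in c("metropolis", "vmmc")) {
    r1 <- run_sampler(sys, p, move_params(), n_steps = 5000, bins = bins,
                      seed = 42, engine = eng)
    r2 <- run_sampler(sys, p, move_params(), n_steps = 5000, bins = bins,
                      seed = 42, engine = eng)
    expect_identical(r1$system$positions, r2$system$positions)
    expect_identical(r1$trajectory, r2$trajectory)
    expect_equal(r1$accepted + r1$rejected, r1$n_steps)
    expect_equal(sum(r1$histogram), 5000)
  }
})

test_that("single steps reduce to the documented Metropolis rule", {
  # free single bead: every move has dE = 0 and must be accepted
  p <- energy_params(bend_on = FALSE, ev_on = FALSE, el_on = FALSE, hyb_epsilon = 0)
  lone <- capture_system(list(matrix(c(5, 5, 5), 1)), box_side = 10)
  for (s in 1:10) {
    expect_true(metropolis_step(lone, p, move_params(), seed = s)$accepted)
    # an isolated bead is a VMMC cluster of size one: same rule
    expect_true(vmmc_step(lone, p, move_params(), seed = s)$accepted)
  }
})

test_that("harmonic dimer bond lengths follow the Boltzmann distribution", {
  p <- energy_params(bend_on = FALSE, ev_on = FALSE, el_on = FALSE, hyb_epsilon = 0)
  bins <- bin_table(seq(0, 1.28, by = 0.02))
  dimer <- capture_system(list(rbind(c(5, 5, 5), c(5.65, 5, 5))), box_side = 12,
                          ext_pairs = rbind(c(0L, 1L)), lig_pairs = rbind(c(0L, 1L)))
  edges <- c(seq(0, 1.28, by = 0.02), 3)
  expc <- vapply(seq_len(length(edges) - 1), function(i) {
    integrate(function(x) x^2 * exp(-0.5 * p$bond_k * (x - p$bond_r0)^2),
              edges[i], edges[i + 1])$value
  }, numeric(1))
  expc <- expc / sum(expc)
  for (eng in c("metropolis", "vmmc")) {
    run <- run_sampler(dimer, p, move_params(0.25, 0.3), n_steps = 4e5,
                       n_equil = 2e4, bins = bins, seed = 11, engine = eng)
    obs <- diag(run$histogram)
    obs <- obs / sum(obs)
    # total-variation distance to the exact radial Boltzmann law
    expect_lt(sum(abs(obs - expc)) / 2, 0.03)
  }
})

test_that("cluster moves preserve a bound dimer's internal distribution", {
  p <- toy_pair_params(hyb_epsilon = 8)
  sys <- toy_pair_system()
  bins <- bin_table(seq(0, 3.6, by = 0.06))
  edges <- bins$edges
  expw <- vapply(seq_len(length(edges) - 1), function(i) {
    integrate(function(x) 4 * pi * x^2 * exp(-oracle_pair_u(x, p)),
              edges[i], edges[i + 1], subdivisions = 400L)$value
  }, numeric(1))
  runs <- lapply(1:3, function(s) {
    run_sampler(sys, p, move_params(0.25, 0.3), n_steps = 6e5, n_equil = 5e4,
                bins = bins, seed = 100 + s, engine = "vmmc")
  })
  pooled <- Reduce(`+`, lapply(runs, function(r) diag(r$histogram)))
  keep <- seq_len(length(edges) - 1)  # closed cells only
  obs <- pooled[keep] / sum(pooled[keep])
  expw <- expw / sum(expw)
  expect_lt(sum(abs(obs - expw)) / 2, 0.05)
})

test_that("umbrella weights rescale acceptance by the weight ratio", {
  p <- toy_pair_params(hyb_epsilon = 0)
  sys <- toy_pair_system()
  bins <- bin_table(c(0, 1.2))  # two states: near / far
  mv <- move_params(0.3, 0.3)
  occup <- function(weights, seed) {
    r <- run_sampler(sys, p, mv, n_steps = 2e6, n_equil = 5e4, bins = bins,
                     weights = weights, seed = seed, engine = "metropolis")
    h <- diag(r$histogram)
    unname(h[1] / h[2])
  }
  # uniform weights and doubled uniform weights behave identically (ratios only)
  r0 <- run_sampler(sys, p, mv, n_steps = 1e4, bins = bins,
                    weights = weight_table(1, bins), seed = 5)
  r2 <- run_sampler(sys, p, mv, n_steps = 1e4, bins = bins,
                    weights = weight_table(matrix(2, 2, 2), bins), seed = 5)
  expect_identical(r0$histogram, r2$histogram)

  # boosting the near state by 10 must raise its relative occupancy 10-fold
  w10 <- weight_table(rbind(c(10, 1), c(1, 1)), bins)
  ratio_plain <- occup(NULL, 7)
  ratio_biased <- occup(w10, 8)
  expect_equal(ratio_biased / ratio_plain, 10, tolerance = 0.15)

  zero_w <- weight_table(rbind(c(1, 1), c(1, 1)), bins)
  zero_w$weights[1, 1] <- 0
  expect_error(run_sampler(sys, p, mv, n_steps = 10, bins = bins,
                           weights = zero_w$weights * c(0, 1, 1, 1), seed = 1),
               class = "lassocapture_invalid_weights")
})

test_that("VMMC and Metropolis share a stationary distribution on a 4-bead toy", {
  p <- energy_params(hyb_epsilon = 4)
  sys <- toy_four_bead()
  bins <- bin_table(c(0, 0.9, 1.8, 2.7))
  pv <- run_sampler(sys, p, move_params(0.25, 0.3), n_steps = 1.5e6, n_equil = 1e5,
                    bins = bins, seed = 21, engine = "vmmc")
  pm <- run_sampler(sys, p, move_params(0.25, 0.3), n_steps = 1.5e6, n_equil = 1e5,
                    bins = bins, seed = 22, engine = "metropolis")
  hv <- pv$histogram / sum(pv$histogram)
  hm <- pm$histogram / sum(pm$histogram)
  # compare the well-populated states; SEs from independent replicas below
  expect_lt(max(abs(hv - hm)), 0.08)
  expect_lt(abs(hv[1, 1] - hm[1, 1]), 0.05)
})

test_that("cluster-size caps reject oversized moves and log them", {
  p <- energy_params(hyb_epsilon = 3)
  sys <- capture_system(list(straight_chain(10)), box_side = 15)
  run <- run_sampler(sys, p, move_params(0.4, 0.5, cluster_size_cap = 2),
                     n_steps = 2e4, seed = 3, engine = "vmmc")
  expect_gt(run$capped_rejections, 0)
  expect_equal(run$accepted + run$rejected, run$n_steps)
})
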