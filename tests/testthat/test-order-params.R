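test_that("default bin table has 11 intervals over the printed edges", {
  bins <- default_bin_table()
  expect_equal(n_intervals(bins), 11L)
  expect_true(all(c(0, 1.7, 3.4, 5.1, 8.5, 12.8, 17.0, 34.1, 68.1, 102.2)
                  %in% bins$edges))
  expect_error(bin_table(c(1, 2, 3)), class = "lassocapture_invalid_bins")
  expect_error(bin_table(c(0, 2, 2)), class = "lassocapture_invalid_bins")
})

test_that("discretize maps distances to half-open intervals", {
  bins <- default_bin_table()
  expect_identical(discretize(1.0, bins), 0L)
  expect_identical(discretize(150, bins), 10L)
  expect_identical(discretize(1.7, bins), 1L)   # boundary joins the upper cell
  expect_identical(discretize(50, bins), 7L)
  expect_identical(discretize(0, bins), 0L)
  expect_error(discretize(-1, bins), class = "lassocapture_invalid_distance")
})

test_that("discretize is a monotone step function agreeing with a linear scan", {
  bins <- default_bin_table()
  scan <- function(d) sum(d >= bins$edges) - 1L  # brute-force interval lookup
  set.seed(71)
  d <- c(runif(2e4, 0, 130), bins$edges, bins$edges + 1e-12, bins$edges - 1e-9)
  d <- d[d >= 0]
  expect_identical(discretize(d, bins), vapply(d, scan, integer(1)))
  ds <- sort(runif(1e4, 0, 200))
  expect_true(all(diff(discretize(ds, bins)) >= 0L))
})

test_that("arm distances take the minimum pair under minimum image", {
  sys <- capture_system(
    list(rbind(c(1, 1, 1), c(1, 4, 1)), rbind(c(1, 1, 1), c(1, 8, 1))),
    box_side = 20,
    ext_pairs = rbind(c(0L, 2L)),            # coincident beads
    lig_pairs = rbind(c(0L, 3L), c(1L, 3L))  # separations 7 and 4
  )
  expect_equal(arm_distance(sys, "extension"), 0)
  expect_equal(arm_distance(sys, "ligation"), 4)

  # pair split across the periodic boundary: 19 apart -> 1 via minimum image
  wrap <- capture_system(list(matrix(c(0.5, 1, 1), 1), matrix(c(19.5, 1, 1), 1)),
                         box_side = 20,
                         ext_pairs = rbind(c(0L, 1L)), lig_pairs = rbind(c(0L, 1L)))
  expect_equal(arm_distance(wrap, "extension"), 1, tolerance = 1e-12)

  none <- capture_system(list(matrix(1, 1, 3)), box_side = 10)
  expect_error(arm_distance(none, "extension"), class = "lassocapture_empty_pairs")
})

test_that("op_state discretizes both arms and classify_state names the corners", {
  bins <- default_bin_table()
  sys <- capture_system(
    list(rbind(c(1, 1, 1), c(1, 1, 2)), rbind(c(1.5, 1, 1), c(1, 51, 2))),
    box_side = 120,
    ext_pairs = rbind(c(0L, 2L)),  # 0.5 nm apart -> Q = 0
    lig_pairs = rbind(c(1L, 3L))   # 50 nm apart  -> Q = 7
  )
  op <- op_state(sys, bins)
  expect_equal(unname(op[1]), 0L)
  expect_equal(unname(op[2]), 7L)
  expect_equal(classify_state(op), "intermediate")
  expect_equal(classify_state(c(0L, 0L), max_q = 10), "interaction")
  expect_equal(classify_state(c(10L, 10L), max_q = 10), "non_interaction")
  expect_equal(classify_state(c(0L, 10L), max_q = 10), "intermediate")
})

test_that("op_state is invariant under joint rigid motion", {
  p <- energy_params()
  bins <- bin_table(c(0, 1, 2, 4, 8))
  sys <- toy_four_bead()
  op0 <- op_state(sys, bins)
  moved <- sys
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  moved$positions <- (sys$positions %*% t(R) +
                        matrix(rep(c(1.3, 2.4, -0.7), each = 4), ncol = 3)) %% sys$box_side
  expect_identical(op_state(moved, bins), op0)
})
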