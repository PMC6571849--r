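test_that("probe assembly concatenates arms around the adapter", {
  ps <- probe_spec("ACGT", "TTTT", adapter = "AAA")
  full <- build_probe(ps)
  expect_equal(full$seq, "ACGTAAATTTT")
  expect_equal(nchar(full$seq), 11L)
  expect_equal(probe_length(ps), 11L)

  mip <- build_probe(probe_spec("ACGT", "TTTT", adapter = ""))
  expect_equal(mip$seq, "ACGTTTTT")

  long <- probe_spec(strrep("A", 20), strrep("A", 20), strrep("C", 242))
  expect_equal(probe_length(long), 282L)

  expect_error(probe_spec("", "TTTT"), class = "lassocapture_invalid_sequence")
  expect_error(nt_seq("ACGN"), class = "lassocapture_invalid_sequence")
  expect_error(nt_seq("ACGU"), class = "lassocapture_invalid_sequence")
})

test_that("arm-target pair mapping is antiparallel and validated", {
  # ext arm "AC" should pair with a "GT" site: revcomp("AC") == "GT"
  tg <- target_spec("GTAAAAAAAT", ext_site = c(0, 2), lig_site = c(9, 10))
  pr <- probe_spec("AC", "A", adapter = "")
  pairs <- find_arm_complements(pr, tg)
  ext <- pairs[pairs$arm == "extension", ]
  expect_equal(ext$probe_index, c(0L, 1L))
  expect_equal(ext$target_index, c(1L, 0L))  # (0, site_end-1), (1, site_start)

  tg10 <- target_spec(paste0(strrep("G", 10), "AAAA", strrep("T", 10)),
                      ext_site = c(0, 10), lig_site = c(14, 24))
  pr10 <- probe_spec(strrep("C", 10), strrep("A", 10), adapter = "AA")
  p10 <- find_arm_complements(pr10, tg10)
  expect_equal(sum(p10$arm == "extension"), 10L)
  expect_equal(sum(p10$arm == "ligation"), 10L)

  # single mismatch is reported with its position
  bad <- target_spec("GAAAAAAAAT", ext_site = c(0, 2), lig_site = c(9, 10))
  err <- expect_error(find_arm_complements(pr, bad),
                      class = "lassocapture_arm_mismatch")
  expect_match(conditionMessage(err), "probe\\[0\\]")

  expect_error(target_spec("ACGT", c(0, 3), c(2, 4)), class = "lassocapture_invalid_spec")
  expect_error(target_spec("ACGT", c(0, 2), c(2, 5)), class = "lassocapture_invalid_spec")
})

test_that("energy terms vanish for straight chains at rest geometry", {
  p <- energy_params()
  sys <- capture_system(list(straight_chain(6), straight_chain(6, origin = c(1, 8, 1))),
                        box_side = 30)
  comp <- total_energy(sys, p, by_term = TRUE)
  expect_equal(comp$total, 0, tolerance = 1e-12)

  # single bond stretched by 0.1 nm at bond_k = 100 -> 0.5 kT
  dimer <- capture_system(list(rbind(c(1, 1, 1), c(1.75, 1, 1))), box_side = 30)
  expect_equal(total_energy(dimer, p), 0.5, tolerance = 1e-10)

  # coincident beads: finite capped repulsion, no infinities
  clash <- capture_system(list(matrix(c(2, 2, 2), 1), matrix(c(2, 2, 2), 1)),
                          box_side = 30)
  expect_true(is.finite(total_energy(clash, p)))
  expect_gte(total_energy(clash, p), p$ev_cap)
})

test_that("three-bead energy matches an independent hand summation", {
  p <- energy_params()
  # bead coordinates chosen to engage bond, bend and nonbonded terms
  pos <- rbind(c(2.0, 2.0, 2.0), c(2.7, 2.0, 2.0), c(2.7, 2.6, 2.0))
  sys <- capture_system(list(pos), box_side = 20)
  # hand computation, term by term
  b1 <- 0.7; b2 <- 0.6
  e_bond <- 0.5 * p$bond_k * (b1 - p$bond_r0)^2 + 0.5 * p$bond_k * (b2 - p$bond_r0)^2
  theta <- acos(sum(c(0.7, 0, 0) * c(0, 0.6, 0)) / (b1 * b2))  # 90 degrees
  e_bend <- 0.5 * p$bend_k * theta^2
  r13 <- sqrt(0.7^2 + 0.6^2)
  e_nb <- oracle_pair_u(r13, p, bound_pair = FALSE)
  expect_equal(total_energy(sys, p), e_bond + e_bend + e_nb, tolerance = 1e-8)
})

test_that("total energy is invariant under rigid motion and rewrapping", {
  p <- energy_params()
  box <- 30
  centre <- function(m) sweep(m, 2, colMeans(m)) + box / 2
  # contiguous chains near the box centre (a rigid motion of a configuration
  # is only meaningful on an unwrapped representation of each molecule)
  ch1 <- centre(gen_ideal_chain(12, 0.65, 1, seed = 4)[1, , ])
  ch2 <- centre(gen_ideal_chain(10, 0.65, 1, seed = 5)[1, , ]) +
    matrix(rep(c(0.9, 0.4, 0), each = 10), ncol = 3)
  sys <- capture_system(list(ch1, ch2), box_side = box,
                        ext_pairs = rbind(c(0L, 12L)), lig_pairs = rbind(c(11L, 21L)))
  e0 <- total_energy(sys, p)
  expect_true(is.finite(e0))

  # translation through the periodic boundary
  shift <- sys
  shift$positions <- (sys$positions +
                        matrix(rep(c(13.1, -22.2, 7.9), each = 22), ncol = 3)) %% box
  expect_equal(total_energy(shift, p), e0, tolerance = 1e-9)

  # joint rotation about the box centre
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- sys
  rot$positions <- (sweep(sys$positions, 2, box / 2) %*% t(R) + box / 2) %% box
  expect_equal(total_energy(rot, p), e0, tolerance = 1e-9)

  # re-wrapping by whole box lengths changes nothing
  rewrap <- sys
  rewrap$positions <- sys$positions + box * matrix(rep(c(2, -1, 3), each = 22), ncol = 3)
  rewrap$positions <- rewrap$positions %% box
  expect_equal(total_energy(rewrap, p), e0, tolerance = 1e-12)
})

test_that("energy is extensive for duplicated non-interacting systems", {
  p <- energy_params()
  ch <- straight_chain(8) + 0.13  # slightly perturbed offsets
  ch[3, 2] <- ch[3, 2] + 0.2     # engage bend terms
  one <- capture_system(list(ch, ch + matrix(rep(c(0, 5, 0), each = 8), ncol = 3)),
                        box_side = 20)
  two <- capture_system(list(ch, ch + matrix(rep(c(0, 5, 0), each = 8), ncol = 3),
                             ch + matrix(rep(c(0, 0, 20), each = 8), ncol = 3),
                             ch + matrix(rep(c(0, 5, 20), each = 8), ncol = 3)),
                        box_side = 40)
  expect_equal(total_energy(two, p), 2 * total_energy(one, p), tolerance = 1e-9)
})

test_that("initial configurations are reproducible and respect the box rule", {
  p <- energy_params()
  tg <- target_spec(paste0(strrep("G", 5), "AAAA", strrep("T", 5)),
                    ext_site = c(0, 5), lig_site = c(9, 14))
  pr <- probe_spec(strrep("C", 5), strrep("A", 5), adapter = strrep("A", 40))
  s1 <- init_configuration(pr, tg, p, seed = 9)
  s2 <- init_configuration(pr, tg, p, seed = 9)
  expect_identical(s1$positions, s2$positions)
  expect_equal(nrow(s1$positions), 50L + 14L)
  expect_equal(sum(s1$chain_id == 0L), 50L)  # 50-nt probe -> 50 beads

  expect_error(init_configuration(pr, tg, p, box_side = 10, seed = 1),
               class = "lassocapture_configuration_error")
})

test_that("free chains reproduce the discrete worm-like-chain size", {
  p <- energy_params(ev_on = FALSE, el_on = FALSE, hyb_epsilon = 0)
  for (N in c(20, 50, 100)) {
    box <- 2.2 * (N - 1) * p$bond_r0  # large enough that R never image-folds
    sys <- capture_system(list(straight_chain(N)), box_side = box)
    run <- run_sampler(sys, p, move_params(0.25, 0.6), n_steps = 3e6,
                       n_equil = 4e5, stride = 100, seed = N, engine = "vmmc")
    ree2 <- run$trajectory$ree2_probe
    obs <- mean(ree2)
    se <- batch_se(ree2)
    exact <- oracle_wlc_ree2(N, p)
    expect_lt(abs(obs - exact), max(0.05 * exact, 3 * se))
  }
})

test_that("persistence-length calibration inverts the bending constant", {
  k <- bend_k_for_persistence(1.5, 0.65)
  expect_equal(mean_cos_angle(k), exp(-0.65 / 1.5), tolerance = 1e-8)
  expect_equal(debye_length_nm(300), 0.304 / sqrt(0.3), tolerance = 1e-12)
  expect_error(energy_params(debye_length = 1.0, salt_Na_mM = 300),
               class = "lassocapture_invalid_params")
})
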