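# Small reference systems shared across tests.

# two single-bead chains with one designed pair serving as both arms; the
# exact distribution over distance cells is a radial quadrature
toy_pair_system <- function(box = 9) {
  capture_system(list(matrix(c(4, 4, 4), 1), matrix(c(4.6, 4, 4), 1)),
                 box_side = box,
                 ext_pairs = rbind(c(0L, 1L)), lig_pairs = rbind(c(0L, 1L)))
}

toy_pair_params <- function(hyb_epsilon = 6) {
  energy_params(bend_on = FALSE, ev_on = TRUE, el_on = TRUE,
                hyb_epsilon = hyb_epsilon, hyb_range = 0.85)
}

toy_pair_bins <- function() bin_table(c(0, 0.9, 1.8, 2.7, 3.6))

# 2+2-bead system with one designed pair per arm (cross-sampler checks)
toy_four_bead <- function(box = 8) {
  capture_system(list(rbind(c(4, 4, 4), c(4.65, 4, 4)),
                      rbind(c(4, 5, 4), c(4.65, 5, 4))),
                 box_side = box,
                 ext_pairs = rbind(c(0L, 2L)), lig_pairs = rbind(c(1L, 3L)))
}

# ideal-chain loop-closure system: the probe is N adapter beads whose
# terminal beads carry the arm function; the target is two beads
loop_system <- function(n_adapter, box = 40, seed = 1) {
  pos <- gen_ideal_chain(n_adapter, 0.65, 1, seed)[1, , ] + box / 3
  post <- gen_ideal_chain(2L, 0.65, 1, seed + 500L)[1, , ] + 2 * box / 3
  capture_system(list(pos, post), box_side = box,
                 ext_pairs = rbind(c(0L, n_adapter + 0L)),
                 lig_pairs = rbind(c(n_adapter - 1L, n_adapter + 1L)))
}

ideal_params <- function(hyb_epsilon = 3) {
  energy_params(bend_on = FALSE, ev_on = FALSE, el_on = FALSE,
                hyb_epsilon = hyb_epsilon, hyb_range = 0.85)
}

# straight chain along x at rest bond length, offset into the box
straight_chain <- function(n, b0 = 0.65, origin = c(1, 1, 1)) {
  cbind(origin[1] + seq(0, by = b0, length.out = n), origin[2], origin[3])
}
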