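# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (quadrature, direct sampling, closed
# forms) rather than calling the package's own computational path.

# pair potential of the reduced model between two non-bonded beads, mirrored
# here for radial quadrature oracles
oracle_pair_u <- function(r, params, bound_pair = TRUE) {
  sig <- params$ev_sigma; eps <- params$ev_epsilon; rc <- 2^(1/6) * sig
  e <- ifelse(params$ev_on & r < rc,
              pmin(4 * eps * ((sig / r)^12 - (sig / r)^6) + eps, params$ev_cap), 0)
  lD <- params$debye_length; cut <- params$el_cutoff
  e <- e + ifelse(params$el_on & r < cut,
                  params$el_amp * (exp(-r / lD) / r - exp(-cut / lD) / cut), 0)
  if (bound_pair) e <- e - ifelse(r < params$hyb_range, params$hyb_epsilon, 0)
  e
}

# exact cell weights of the two-bead toy: integral of 4 pi r^2 exp(-u(r))
# over each distance interval, the final open interval taken at u = 0 with
# its exact volume in the periodic box
oracle_cell_weights <- function(params, edges, box) {
  brk_all <- c(2^(1/6) * params$ev_sigma, params$el_cutoff, params$hyb_range)
  n <- length(edges)
  z <- numeric(n)
  for (i in seq_len(n - 1)) {
    lo <- edges[i]; hi <- edges[i + 1]
    brk <- sort(unique(c(lo, hi, brk_all[brk_all > lo & brk_all < hi])))
    z[i] <- sum(vapply(seq_len(length(brk) - 1), function(k) {
      integrate(function(x) 4 * pi * x^2 * exp(-oracle_pair_u(x, params)),
                brk[k], brk[k + 1], rel.tol = 1e-10)$value
    }, numeric(1)))
  }
  stopifnot(edges[n] <= box / 2)  # radial shell volume valid below box/2
  z[n] <- box^3 - 4 / 3 * pi * edges[n]^3
  z
}

# discrete worm-like chain (freely rotating chain with harmonic bending and
# fluctuating harmonic bonds): exact mean squared end-to-end distance
oracle_wlc_ree2 <- function(n_beads, params) {
  cth <- mean_cos_angle(params$bend_k)
  kb <- params$bond_k; b0 <- params$bond_r0
  up <- b0 + 8 / sqrt(kb)
  f <- function(b) b^2 * exp(-0.5 * kb * (b - b0)^2)
  Z <- integrate(f, 0, up)$value
  Eb <- integrate(function(b) b * f(b), 0, up)$value / Z
  Eb2 <- integrate(function(b) b^2 * f(b), 0, up)$value / Z
  n <- n_beads - 1
  n * Eb2 + 2 * Eb^2 * (cth * (n - 1) / (1 - cth) -
                          cth^2 * (1 - cth^(n - 1)) / (1 - cth)^2)
}

# batch-means standard error for an autocorrelated scalar series
batch_se <- function(x, n_batches = 40) {
  blk <- rep(seq_len(n_batches), each = ceiling(length(x) / n_batches))[seq_along(x)]
  bm <- tapply(x, blk, mean)
  sd(bm) / sqrt(length(bm))
}
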