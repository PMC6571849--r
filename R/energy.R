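#' Debye screening length for monovalent salt
#'
#' `lambda_D = 0.304 / sqrt(M)` nm with `M` the Na+ molarity, the standard
#' room-temperature screening formula for monovalent salt.
#'
#' @param salt_Na_mM Sodium concentration in mM.
#' @return Screening length in nm.
#' @examples
#' debye_length_nm(300) # ~0.555 nm
#' @export
debye_length_nm <- function(salt_Na_mM) {
  check_number(salt_Na_mM, "salt_Na_mM")
  0.304 / sqrt(salt_Na_mM / 1000)
}

#' Energy parameters of the reduced coarse-grained DNA model
#'
#' One bead per nucleotide; energies in kT at `temperature`, distances in nm.
#' The terms are: harmonic bonds, harmonic bending (which sets the
#' persistence length), a purely repulsive truncated-shifted Lennard-Jones
#' (WCA) excluded volume capped at `ev_cap`, a truncated-shifted Yukawa
#' repulsion with screening length `debye_length`, and a finite square well
#' of depth `hyb_epsilon` acting only between the designed arm/site bead
#' pairs (a Go-like hybridization term).
#'
#' Defaults describe ssDNA at the capture conditions: 65 C, 300 mM Na+ (the
#' monovalent surrogate for a 10 mM Mg2+ / 100 mM Na+ buffer), a 0.65 nm
#' backbone rise, and `bend_k = 2.12` kT calibrated so the discrete
#' worm-like-chain persistence length is about 1.5 nm.
#'
#' @param bond_k Bond spring constant, kT/nm^2.
#' @param bond_r0 Rest bond length (ssDNA rise), nm.
#' @param bend_k Bending constant of the harmonic angle term, kT/rad^2.
#' @param ev_sigma,ev_epsilon WCA diameter (nm) and strength (kT).
#' @param ev_cap Finite cap on the repulsion for overlapping beads, kT.
#' @param el_amp Yukawa amplitude, kT*nm.
#' @param salt_Na_mM Sodium concentration, mM.
#' @param debye_length Screening length, nm; computed from `salt_Na_mM` when
#'   omitted, and must be consistent with it when given.
#' @param el_cutoff Truncation radius of the (shifted) Yukawa term, nm;
#'   defaults to `2 * debye_length`.
#' @param hyb_epsilon Hybridization well depth per designed pair, kT.
#' @param hyb_range Hybridization well radius, nm.
#' @param temperature Kelvin; bookkeeping only, since energies are in kT.
#' @param bend_on,ev_on,el_on Switches for the bending, excluded-volume and
#'   electrostatic terms (used by the ideal-chain reference tests).
#' @return A list of class `energy_params`.
#' @export
energy_params <- function(bond_k = 100, bond_r0 = 0.65, bend_k = 2.12,
                          ev_sigma = 0.65, ev_epsilon = 1.0, ev_cap = 100,
                          el_amp = 0.5, salt_Na_mM = 300,
                          debye_length = NULL, el_cutoff = NULL,
                          hyb_epsilon = 3.0, hyb_range = 0.85,
                          temperature = 338.15,
                          bend_on = TRUE, ev_on = TRUE, el_on = TRUE) {
  for (nm in c("bond_k", "bond_r0", "bend_k", "ev_sigma", "ev_epsilon",
               "ev_cap", "salt_Na_mM", "hyb_range", "temperature")) {
    check_number(get(nm), nm)
  }
  check_number(el_amp, "el_amp", allow_zero = TRUE)
  check_number(hyb_epsilon, "hyb_epsilon", allow_zero = TRUE)
  ld <- debye_length_nm(salt_Na_mM)
  if (is.null(debye_length)) {
    debye_length <- ld
  } else {
    check_number(debye_length, "debye_length")
    if (abs(debye_length - ld) > 1e-6) {
      stop_lasso(sprintf(
        "debye_length %.4f nm is inconsistent with salt_Na_mM = %g (expected %.4f nm)",
        debye_length, salt_Na_mM, ld), "invalid_params")
    }
  }
  el_cutoff <- el_cutoff %||% (2 * debye_length)
  check_number(el_cutoff, "el_cutoff")
  structure(
    list(bond_k = bond_k, bond_r0 = bond_r0, bend_k = bend_k,
         ev_sigma = ev_sigma, ev_epsilon = ev_epsilon, ev_cap = ev_cap,
         el_amp = el_amp, salt_Na_mM = salt_Na_mM,
         debye_length = debye_length, el_cutoff = el_cutoff,
         hyb_epsilon = hyb_epsilon, hyb_range = hyb_range,
         temperature = temperature,
         bend_on = isTRUE(bend_on), ev_on = isTRUE(ev_on), el_on = isTRUE(el_on)),
    class = "energy_params"
  )
}

#' @export
print.energy_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<energy_params> T = %.2f K, %g mM Na+ (lambda_D = %.3f nm)\n",
    "  bond %.3g kT/nm^2 @ %.2f nm | bend %.3g kT | WCA sigma %.2f eps %.2g\n",
    "  Yukawa amp %.2g kT nm (cut %.2f nm) | well %.2g kT @ %.2f nm\n"),
    x$temperature, x$salt_Na_mM, x$debye_length,
    x$bond_k, x$bond_r0, if (x$bend_on) x$bend_k else 0,
    x$ev_sigma, if (x$ev_on) x$ev_epsilon else 0,
    if (x$el_on) x$el_amp else 0, x$el_cutoff, x$hyb_epsilon, x$hyb_range))
  invisible(x)
}

#' Bending constant for a desired persistence length
#'
#' Inverts the discrete worm-like-chain relation
#' `<cos(theta)> = exp(-bond_r0 / lp)` for the harmonic angle potential
#' `0.5 * k * theta^2` (with the spherical `sin(theta)` measure) by
#' quadrature and root finding.
#'
#' @param lp_nm Desired persistence length in nm.
#' @param bond_r0 Bond length in nm.
#' @return Bending constant in kT.
#' @export
bend_k_for_persistence <- function(lp_nm, bond_r0 = 0.65) {
  check_number(lp_nm, "lp_nm")
  check_number(bond_r0, "bond_r0")
  target <- exp(-bond_r0 / lp_nm)
  f <- function(k) mean_cos_angle(k) - target
  uniroot(f, c(1e-3, 1e3), tol = 1e-10)$root
}

#' Mean bond-angle cosine under the harmonic bending potential
#'
#' @param bend_k Bending constant in kT.
#' @return `<cos(theta)>` with weight `exp(-bend_k * theta^2 / 2) sin(theta)`.
#' @export
mean_cos_angle <- function(bend_k) {
  check_number(bend_k, "bend_k")
  num <- integrate(function(th) cos(th) * exp(-0.5 * bend_k * th^2) * sin(th),
                   0, pi, rel.tol = 1e-12)$value
  den <- integrate(function(th) exp(-0.5 * bend_k * th^2) * sin(th),
                   0, pi, rel.tol = 1e-12)$value
  num / den
}

params_for_cpp <- function(params) {
  stopifnot(inherits(params, "energy_params"))
  params[c("bond_k", "bond_r0", "bend_k", "ev_sigma", "ev_epsilon", "ev_cap",
           "el_amp", "debye_length", "el_cutoff", "hyb_epsilon", "hyb_range",
           "bend_on", "ev_on", "el_on")]
}

#' Total energy of a configuration
#'
#' Sums bond, bending, excluded-volume, screened-electrostatic and
#' hybridization terms over the whole system; finite for any configuration
#' (overlaps are capped at `ev_cap`).
#'
#' @param system A [capture_system()].
#' @param params An [energy_params()].
#' @param by_term Return the per-term breakdown instead of the total?
#' @return Total energy in kT, or a one-row tibble of components when
#'   `by_term = TRUE`.
#' @export
total_energy <- function(system, params = energy_params(), by_term = FALSE) {
  stopifnot(inherits(system, "capture_system"))
  comp <- cg_total_energy(system$positions, system$chain_id, system$box_side,
                          params_for_cpp(params), system$ext_pairs,
                          system$lig_pairs)
  if (by_term) return(as_tibble(comp))
  comp$total
}
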