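#' Simulate Rancimat induction-period data
#'
#' Generates induction periods with exact Arrhenius structure,
#' `IP(T) = exp(Ea * 1000/(R T) - ln A)` hours, optionally perturbed by
#' multiplicative lognormal noise (IPs are positive and errors plausibly
#' proportional, hence lognormal rather than additive). With
#' `noise_sigma = 0` the output lies exactly on the generating line, so
#' [kinetic_fit()] recovers `ea_kj_mol` and `ln_a` to machine precision.
#'
#' @param ea_kj_mol Activation energy, kJ/mol, > 0.
#' @param ln_a Log frequency factor (k in h^-1).
#' @param temperatures_K Temperature grid, kelvin; defaults to the standard
#'   accelerated-oxidation grid 100-130 degC.
#' @param noise_sigma Lognormal sigma of the multiplicative error (0 = exact).
#' @param n_rep Replicates per temperature.
#' @param sample Sample label.
#' @param seed Optional integer; fixed seed gives identical tables.
#' @return An [ip_table()].
#' @examples
#' simulate_rancimat(50.59, 15.914)
#' @export
simulate_rancimat <- function(ea_kj_mol, ln_a,
                              temperatures_K = c(100, 110, 120, 130) + 273.15,
                              noise_sigma = 0, n_rep = 1L,
                              sample = "sim", seed = NULL) {
  stopifnot(is.finite(ea_kj_mol), ea_kj_mol > 0, is.finite(ln_a),
            noise_sigma >= 0, n_rep >= 1L)
  if (any(!is.finite(temperatures_K) | temperatures_K <= 0)) {
    stop("temperatures must be positive kelvin", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  temps <- rep(temperatures_K, each = n_rep)
  ip <- exp(ea_kj_mol * 1000 / (R_GAS * temps) - ln_a)
  if (noise_sigma > 0) {
    ip <- ip * exp(stats::rnorm(length(ip), 0, noise_sigma))
  }
  ip_table(sample = sample, temperature = temps, ip_hours = ip,
           temperature_unit = "K",
           replicate = if (n_rep > 1L) rep(seq_len(n_rep),
                                           times = length(temperatures_K)))
}

#' Simulate DSC peak temperatures from an isoconversional line
#'
#' For each heating rate beta, solves the chosen linearization
#' (FWO: `lg beta = slope * 1000/Tp + C`; KAS: `lg(beta/Tp^2) = ...`, with
#' `slope = -factor * Ea / R`) for the peak temperature Tp by bisection on
#' [200, 2000] K to an absolute residual below 1e-10. Because the fits only
#' ever see (beta, Tp) pairs, generating from the linearized relation itself
#' is exactly invertible: the matching fitter recovers `ea_kj_mol` and
#' `c_constant` to machine precision.
#'
#' @param ea_kj_mol Apparent activation energy, kJ/mol, > 0.
#' @param c_constant Intercept C1 (FWO) or C2 (KAS).
#' @param betas Heating rates, K/min.
#' @param method `"fwo"` or `"kas"`.
#' @param sample Sample label.
#' @return A [dsc_table()].
#' @examples
#' simulate_dsc_peaks(50.31, 6.2864, method = "fwo")
#' @export
simulate_dsc_peaks <- function(ea_kj_mol, c_constant,
                               betas = c(5, 10, 15, 20),
                               method = c("fwo", "kas"), sample = "sim") {
  method <- match.arg(method)
  stopifnot(is.finite(ea_kj_mol), ea_kj_mol > 0, is.finite(c_constant))
  if (any(!is.finite(betas) | betas <= 0)) {
    stop("heating rates must be positive", call. = FALSE)
  }
  fac <- if (method == "fwo") FWO_FACTOR else KAS_FACTOR
  slope <- -fac * ea_kj_mol / R_GAS # per 10^3/K
  resid_fun <- function(tp, beta) {
    lhs <- if (method == "fwo") log10(beta) else log10(beta / tp^2)
    lhs - (slope * 1000 / tp + c_constant)
  }
  tp <- vapply(betas, function(beta) {
    bisect_root(function(t) resid_fun(t, beta), 200, 2000, tol = 1e-10)
  }, numeric(1))
  dsc_table(sample = sample, beta = betas, tp = tp, tp_unit = "K")
}

# plain bisection to an absolute-residual tolerance
bisect_root <- function(f, lower, upper, tol = 1e-10, max_iter = 200L) {
  fl <- f(lower)
  fu <- f(upper)
  if (!is.finite(fl) || !is.finite(fu) || fl * fu > 0) {
    stop(sprintf(
      "no sign change in [%g, %g] K (f = %.3g, %.3g); parameters place the peak outside the bracket",
      lower, upper, fl, fu), call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fl * fm <= 0) {
      upper <- mid
    } else {
      lower <- mid
      fl <- fm
    }
  }
  stop("bisection failed to reach tolerance", call. = FALSE)
}

#' Simulate a sigmoidal radical-scavenging dose-response curve
#'
#' Hill-type (four-parameter logistic with zero lower asymptote) scavenging
#' curve `SR(c) = sr_max * c^hill / (ic50^hill + c^hill)` plus optional
#' Gaussian noise, converted to absorbance pairs with the control fixed at
#' `a0` (default 0.700, the standard ABTS working absorbance). Noisy SR
#' values are clamped to [a1 >= 0], i.e. SR <= 100.
#'
#' @param ic50_true True half-scavenging concentration, ug/mL, > 0.
#' @param hill Hill slope, > 0.
#' @param sr_max Upper asymptote, percent.
#' @param concentrations Concentration grid, ug/mL.
#' @param noise_sigma SD of additive Gaussian noise on SR (percent points).
#' @param a0 Control absorbance.
#' @param assay `"dpph"` or `"abts"`.
#' @param seed Optional integer seed.
#' @return A [dose_response()] table.
#' @examples
#' simulate_dose_response(10.5, hill = 1.5)
#' @export
simulate_dose_response <- function(ic50_true, hill = 1.5, sr_max = 100,
                                   concentrations = c(5, 10, 15, 20, 25, 30),
                                   noise_sigma = 0, a0 = 0.700,
                                   assay = c("dpph", "abts"), seed = NULL) {
  assay <- match.arg(assay)
  stopifnot(is.finite(ic50_true), ic50_true > 0, is.finite(hill), hill > 0,
            noise_sigma >= 0, a0 > 0)
  if (any(!is.finite(concentrations) | concentrations < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sr <- sr_max * concentrations^hill / (ic50_true^hill + concentrations^hill)
  sr[concentrations == 0] <- 0
  if (noise_sigma > 0) {
    sr <- sr + stats::rnorm(length(sr), 0, noise_sigma)
  }
  sr <- pmin(pmax(sr, -100), 100)
  a1 <- a0 * (1 - sr / 100)
  dose_response(concentrations, a0 = a0, a1 = a1, assay = assay)
}
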