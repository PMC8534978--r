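#' Build a DSC peak-temperature table
#'
#' Exotherm peak temperatures at several linear heating rates, the input to
#' isoconversional (fixed-conversion) kinetic analysis.
#'
#' @param sample Character sample identifiers.
#' @param beta Heating rates, K/min, positive.
#' @param tp Peak temperatures.
#' @param tp_unit `"K"` or `"C"` (scalar or per-row).
#' @return Data frame of class `dsc_table` with columns `sample`,
#'   `beta_K_per_min`, `tp_K`.
#' @examples
#' dsc_table("OA", c(5, 10, 15, 20), c(475, 490, 499, 506))
#' @export
dsc_table <- function(sample, beta, tp, tp_unit = "K") {
  n <- max(length(sample), length(beta), length(tp))
  sample <- rep_len(as.character(sample), n)
  beta <- rep_len(as.numeric(beta), n)
  tp <- rep_len(as.numeric(tp), n)
  bad <- which(!is.finite(beta) | beta <= 0)
  if (length(bad)) {
    stop(sprintf("heating rates must be positive; bad row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(sample = sample, beta_K_per_min = beta,
                    tp_K = to_kelvin(tp, tp_unit), stringsAsFactors = FALSE)
  for (s in unique(out$sample)) {
    nb <- length(unique(out$beta_K_per_min[out$sample == s]))
    if (nb < 3L) {
      warning(sprintf(
        "sample '%s' has only %d distinct heating rate(s); >= 3 recommended",
        s, nb), call. = FALSE)
    }
  }
  class(out) <- c("dsc_table", class(out))
  out
}

#' Isoconversional activation energy from a fitted slope
#'
#' Inverts the Doyle-approximation linearizations at peak temperature, with
#' the ordinate in log10 and x = 1000/Tp (K):
#' * FWO:  lg beta        = -0.4567 E/(R Tp) + C1, so E = -slope*8.314/0.4567
#' * KAS:  lg (beta/Tp^2) = -0.4343 E/(R Tp) + C2, so E = -slope*8.314/0.4343
#'
#' @param slope Slope in per-10^3/K units.
#' @param method `"fwo"` or `"kas"`.
#' @return Apparent activation energy, kJ/mol.
#' @examples
#' slope_to_ea_iso(-2.7636, "fwo") # 50.31
#' slope_to_ea_iso(-2.3126, "kas") # 44.27
#' @export
slope_to_ea_iso <- function(slope, method = c("fwo", "kas")) {
  method <- match.arg(method)
  stopifnot(is.numeric(slope), all(is.finite(slope)))
  fac <- if (method == "fwo") FWO_FACTOR else KAS_FACTOR
  -slope * R_GAS / fac
}

#' Fit Flynn-Wall-Ozawa or Kissinger-Akahira-Sunose kinetics to DSC peaks
#'
#' Model-free (isoconversional) estimate of the apparent activation energy
#' from peak temperatures at multiple heating rates. OLS of the linearized
#' ordinate on x = 1000/Tp (K):
#' * `"fwo"`: lg beta vs 1000/Tp (Doyle factor 0.4567)
#' * `"kas"`: lg(beta/Tp^2) vs 1000/Tp (factor 0.4343 = 1/ln 10)
#'
#' Only the fixed-conversion (peak temperature) variant is implemented; full
#' conversion-resolved integration is out of scope. Duplicated rows enter
#' the regression individually.
#'
#' @param peaks A [dsc_table()].
#' @param sample Which sample to fit; defaults to the only one present.
#' @param method `"fwo"` or `"kas"`.
#' @return Object of class `c("<method>_fit", "oxikin_fit")` with `slope`,
#'   `intercept` (C1 or C2), `r_squared`, `ea_kj_mol`, the abscissa
#'   convention, data and the underlying `lm`.
#' @examples
#' peaks <- simulate_dsc_peaks(ea_kj_mol = 50.31, c_constant = 6.2864)
#' isoconversional_fit(peaks, method = "fwo")
#' @export
isoconversional_fit <- function(peaks, sample = NULL,
                                method = c("fwo", "kas")) {
  method <- match.arg(method)
  if (is.null(sample)) {
    samples <- unique(peaks$sample)
    if (length(samples) != 1L) {
      stop("several samples present; name the one to fit", call. = FALSE)
    }
    sample <- samples
  }
  d <- peaks[peaks$sample == sample, , drop = FALSE]
  if (nrow(d) == 0L) {
    stop(sprintf("no rows for sample '%s'", sample), call. = FALSE)
  }
  if (length(unique(d$beta_K_per_min)) < 2L) {
    stop("need >= 2 distinct heating rates to fit", call. = FALSE)
  }
  x <- 1000 / d$tp_K
  y <- if (method == "fwo") {
    log10(d$beta_K_per_min)
  } else {
    log10(d$beta_K_per_min / d$tp_K^2)
  }
  fit <- linfit(x, y)
  out <- list(sample = sample, method = method,
              slope = fit$slope, intercept = fit$intercept,
              r_squared = fit$r_squared,
              ea_kj_mol = slope_to_ea_iso(fit$slope, method),
              abscissa = "1000/Tp (K)",
              data = d, lm = fit$lm)
  class(out) <- c(paste0(method, "_fit"), "oxikin_fit")
  out
}
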