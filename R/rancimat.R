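#' Build an induction-period table
#'
#' Rancimat induction periods per sample and temperature. Temperatures are
#' stored internally in kelvin; the unit is declared explicitly (no
#' autodetection — 100-130 is ambiguous between degC and K).
#'
#' @param sample Character vector of sample identifiers.
#' @param temperature Numeric temperatures.
#' @param ip_hours Positive induction periods, hours.
#' @param temperature_unit `"C"` or `"K"` (scalar or per-row).
#' @param replicate Optional integer replicate index.
#' @return Data frame of class `ip_table` with columns `sample`,
#'   `temperature_K`, `ip_hours` and optionally `replicate`.
#' @examples
#' ip_table("OA", c(100, 110, 120, 130), c(8.1, 4.3, 2.2, 1.1))
#' @export
ip_table <- function(sample, temperature, ip_hours,
                     temperature_unit = "C", replicate = NULL) {
  n <- max(length(sample), length(temperature), length(ip_hours))
  sample <- rep_len(as.character(sample), n)
  temperature <- rep_len(as.numeric(temperature), n)
  ip_hours <- rep_len(as.numeric(ip_hours), n)
  bad <- which(!is.finite(ip_hours) | ip_hours <= 0)
  if (length(bad)) {
    stop(sprintf("ip_hours must be positive and finite; bad row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(sample = sample,
                    temperature_K = to_kelvin(temperature, temperature_unit),
                    ip_hours = ip_hours, stringsAsFactors = FALSE)
  if (!is.null(replicate)) out$replicate <- rep_len(as.integer(replicate), n)
  for (s in unique(out$sample)) {
    nt <- length(unique(out$temperature_K[out$sample == s]))
    if (nt < 3L) {
      warning(sprintf(
        "sample '%s' has only %d distinct temperature(s); >= 3 recommended",
        s, nt), call. = FALSE)
    }
  }
  class(out) <- c("ip_table", class(out))
  out
}

to_kelvin <- function(temperature, unit) {
  unit <- rep_len(as.character(unit), length(temperature))
  ok <- unit %in% c("C", "K")
  if (!all(ok)) {
    stop(sprintf("temperature_unit must be 'C' or 'K'; bad row(s): %s",
                 paste(which(!ok), collapse = ", ")), call. = FALSE)
  }
  k <- ifelse(unit == "C", temperature + 273.15, temperature)
  if (any(!is.finite(k) | k <= 0)) {
    stop("temperatures must be positive on the kelvin scale", call. = FALSE)
  }
  k
}

#' Rate constants from induction periods
#'
#' The effective first-order oxidation rate constant is the reciprocal of
#' the induction period, k = 1/IP (h^-1).
#'
#' @param ip An [ip_table()] (any data frame with `sample`, `temperature_K`,
#'   `ip_hours`).
#' @return Data frame of class `rate_table` with columns `sample`,
#'   `temperature_K`, `k` (h^-1).
#' @examples
#' rate_constants(ip_table("OA", c(100, 110), c(4, 2)))
#' @export
rate_constants <- function(ip) {
  required <- c("sample", "temperature_K", "ip_hours")
  miss <- setdiff(required, names(ip))
  if (length(miss)) {
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(!is.finite(ip$ip_hours) | ip$ip_hours <= 0)
  if (length(bad)) {
    stop(sprintf("ip_hours must be > 0; bad row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(sample = as.character(ip$sample),
                    temperature_K = as.numeric(ip$temperature_K),
                    k = 1 / ip$ip_hours, stringsAsFactors = FALSE)
  class(out) <- c("rate_table", class(out))
  out
}

#' Arrhenius activation energy from a fitted slope
#'
#' With ln k regressed on x = 1000/T (K), the slope is -Ea/(10^3 R), so
#' `Ea = -slope * 8.314` kJ/mol.
#'
#' @param slope Slope in per-10^3/K units.
#' @return Activation energy, kJ/mol.
#' @examples
#' slope_to_ea(-6.085) # 50.59
#' @export
slope_to_ea <- function(slope) {
  stopifnot(is.numeric(slope), all(is.finite(slope)))
  -slope * R_GAS
}

#' Eyring activation parameters from a fitted line
#'
#' With ln(k/T) regressed on x = 1000/T (K):
#' `dH = -slope * 8.314` kJ/mol and `dS = (intercept - ln(kB/h)) * 8.314`
#' J/(mol K).
#'
#' @param slope,intercept Fitted line on the ln(k/T) vs 1000/T scale.
#' @param ln_kb_over_h Value of ln(kB/h) used for the entropy; defaults to
#'   the conventional 21.46 (see [oxikin_constants()] and the vignette).
#' @return List with `delta_h_kj_mol` and `delta_s_j_mol_k`.
#' @examples
#' eyring_params(-5.6975, 8.9535)
#' @export
eyring_params <- function(slope, intercept,
                          ln_kb_over_h = LN_KB_OVER_H_DEFAULT) {
  stopifnot(is.finite(slope), is.finite(intercept), is.finite(ln_kb_over_h))
  list(delta_h_kj_mol = -slope * R_GAS,
       delta_s_j_mol_k = (intercept - ln_kb_over_h) * R_GAS)
}

#' Fit Arrhenius or Eyring kinetics to induction-period rate constants
#'
#' The central fitting function for Rancimat data. Ordinary least squares of
#' the linearized model on x = 1000/T (K):
#' * `method = "arrhenius"`: ln k = ln A - Ea/(RT); slope gives Ea, intercept
#'   gives ln A.
#' * `method = "eyring"`: ln(k/T) = ln(kB/h) + dS/R - dH/(RT); slope gives
#'   dH, intercept (against `ln_kb_over_h`) gives dS.
#'
#' Replicates at the same temperature enter as individual points unless
#' `average_replicates = TRUE`. Fits are unweighted; R^2 is the ordinary
#' coefficient of determination.
#'
#' @param rates A [rate_constants()] table (or an [ip_table()], which is
#'   converted first).
#' @param sample Which sample to fit; defaults to the only sample present.
#' @param method `"arrhenius"` or `"eyring"`.
#' @param ln_kb_over_h ln(kB/h) for the Eyring entropy (default 21.46).
#' @param average_replicates Average k over replicates at each temperature
#'   before fitting.
#' @return An object of class `c("<method>_fit", "oxikin_fit")`: a list with
#'   `sample`, `method`, `slope`, `intercept`, `r_squared`, the derived
#'   parameter pair for the method (`ea_kj_mol`/`ln_a` or
#'   `delta_h_kj_mol`/`delta_s_j_mol_k` plus `ln_kb_over_h`), the abscissa
#'   convention, the fitting data and the underlying `lm`.
#' @examples
#' ip <- simulate_rancimat(ea_kj_mol = 66.29, ln_a = 20.55)
#' fit <- kinetic_fit(rate_constants(ip))
#' coef(fit)
#' @export
kinetic_fit <- function(rates, sample = NULL,
                        method = c("arrhenius", "eyring"),
                        ln_kb_over_h = LN_KB_OVER_H_DEFAULT,
                        average_replicates = FALSE) {
  method <- match.arg(method)
  if ("ip_hours" %in% names(rates) && !("k" %in% names(rates))) {
    rates <- rate_constants(rates)
  }
  if (is.null(sample)) {
    samples <- unique(rates$sample)
    if (length(samples) != 1L) {
      stop("several samples present; name the one to fit", call. = FALSE)
    }
    sample <- samples
  }
  d <- rates[rates$sample == sample, , drop = FALSE]
  if (nrow(d) == 0L) {
    stop(sprintf("no rows for sample '%s'", sample), call. = FALSE)
  }
  if (any(!is.finite(d$k) | d$k <= 0)) {
    stop("rate constants must be positive and finite", call. = FALSE)
  }
  if (average_replicates) {
    agg <- stats::aggregate(k ~ temperature_K, data = d, FUN = mean)
    d <- data.frame(sample = sample, temperature_K = agg$temperature_K,
                    k = agg$k, stringsAsFactors = FALSE)
  }
  if (length(unique(d$temperature_K)) < 2L) {
    stop("need >= 2 distinct temperatures to fit", call. = FALSE)
  }
  x <- 1000 / d$temperature_K
  y <- if (method == "arrhenius") log(d$k) else log(d$k / d$temperature_K)
  fit <- linfit(x, y)
  out <- list(sample = sample, method = method,
              slope = fit$slope, intercept = fit$intercept,
              r_squared = fit$r_squared,
              abscissa = "1000/T (K)",
              data = d, lm = fit$lm)
  if (method == "arrhenius") {
    out$ea_kj_mol <- slope_to_ea(fit$slope)
    out$ln_a <- fit$intercept
  } else {
    ep <- eyring_params(fit$slope, fit$intercept, ln_kb_over_h)
    out$delta_h_kj_mol <- ep$delta_h_kj_mol
    out$delta_s_j_mol_k <- ep$delta_s_j_mol_k
    out$ln_kb_over_h <- ln_kb_over_h
  }
  class(out) <- c(paste0(method, "_fit"), "oxikin_fit")
  out
}

# shared OLS core for all linearized fits
linfit <- function(x, y) {
  if (stats::var(x) <= .Machine$double.eps * max(1, mean(x)^2)) {
    stop("degenerate abscissa: no variance in 1000/T", call. = FALSE)
  }
  lm <- stats::lm(y ~ x)
  cf <- stats::coef(lm)
  ss_res <- sum(stats::residuals(lm)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
       r_squared = min(max(r2, 0), 1), lm = lm)
}
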