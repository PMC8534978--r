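#' Radical scavenging rate from absorbances
#'
#' DPPH and ABTS assays share the same arithmetic:
#' `SR% = (A0 - A1)/A0 * 100`, where A0 is the control absorbance and A1 the
#' absorbance with antioxidant present. A1 > A0 yields a negative rate and a
#' warning (plausible for coloured or turbid samples, so not an error).
#'
#' @param a0 Control absorbance, > 0.
#' @param a1 Sample absorbance, >= 0.
#' @return Scavenging rate, percent.
#' @examples
#' scavenging_rate(0.700, 0.350) # 50
#' @export
scavenging_rate <- function(a0, a1) {
  stopifnot(is.numeric(a0), is.numeric(a1))
  if (any(!is.finite(a0) | a0 <= 0)) {
    stop("control absorbance a0 must be positive", call. = FALSE)
  }
  if (any(!is.finite(a1) | a1 < 0)) {
    stop("sample absorbance a1 must be non-negative", call. = FALSE)
  }
  sr <- (a0 - a1) / a0 * 100
  if (any(sr < 0)) {
    warning("negative scavenging rate: sample absorbance exceeds control",
            call. = FALSE)
  }
  sr
}

#' Build a dose-response table
#'
#' Concentration series of a DPPH or ABTS assay with control (A0) and sample
#' (A1) absorbances; the derived scavenging rate `sr_percent` is attached.
#'
#' @param concentration Concentrations, ug/mL, >= 0.
#' @param a0,a1 Absorbances (recycled to length of `concentration`).
#' @param assay `"dpph"` or `"abts"` — metadata only, the arithmetic is
#'   identical.
#' @return Data frame of class `dose_response` with columns `assay`,
#'   `concentration`, `a0`, `a1`, `sr_percent`.
#' @examples
#' dose_response(c(5, 15), a0 = 0.700, a1 = c(0.525, 0.175))
#' @export
dose_response <- function(concentration, a0, a1, assay = c("dpph", "abts")) {
  assay <- match.arg(assay)
  n <- length(concentration)
  concentration <- as.numeric(concentration)
  if (any(!is.finite(concentration) | concentration < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  a0 <- rep_len(as.numeric(a0), n)
  a1 <- rep_len(as.numeric(a1), n)
  sr <- scavenging_rate(a0, a1)
  if (any(sr > 100 + 1e-9)) {
    stop("scavenging rate above 100% implies negative sample absorbance",
         call. = FALSE)
  }
  out <- data.frame(assay = assay, concentration = concentration,
                    a0 = a0, a1 = a1, sr_percent = sr,
                    stringsAsFactors = FALSE)
  out <- out[order(out$concentration), , drop = FALSE]
  class(out) <- c("dose_response", class(out))
  out
}

#' Half-maximal scavenging concentration (IC50)
#'
#' Estimates the concentration at which the scavenging rate crosses 50%.
#' Two estimators:
#' * `"interpolate"` (default): linear interpolation between the first pair
#'   of consecutive concentrations (ascending) whose SR values bracket 50%.
#'   Errors if no bracket exists.
#' * `"four_pl"`: least-squares four-parameter logistic
#'   `SR(c) = sr_min + (sr_max - sr_min) * c^h / (ec50^h + c^h)`, returning
#'   the concentration where the fitted curve crosses 50%.
#'
#' Non-monotonic SR sequences trigger a warning under either method.
#'
#' @param curve A [dose_response()] table (>= 2 concentrations).
#' @param method `"interpolate"` or `"four_pl"`.
#' @return Object of class `ic50_fit`: list with `ic50` (ug/mL), `method`,
#'   `assay`, the `data`, and for `four_pl` the fitted `coefficients`.
#' @examples
#' curve <- dose_response(c(5, 15), a0 = 0.700, a1 = c(0.525, 0.175))
#' ic50(curve)$ic50 # 10
#' @export
ic50 <- function(curve, method = c("interpolate", "four_pl")) {
  method <- match.arg(method)
  if (nrow(curve) < 2L) {
    stop("need >= 2 concentrations to estimate an IC50", call. = FALSE)
  }
  d <- curve[order(curve$concentration), , drop = FALSE]
  sr <- d$sr_percent
  if (is.unsorted(sr) && is.unsorted(rev(sr))) {
    warning("scavenging rates are not monotone in concentration",
            call. = FALSE)
  }
  est <- if (method == "interpolate") ic50_interpolate(d) else ic50_4pl(d)
  out <- c(list(method = method,
                assay = if ("assay" %in% names(d)) d$assay[1L] else NA_character_,
                data = d),
           est)
  class(out) <- "ic50_fit"
  out
}

ic50_interpolate <- function(d) {
  sr <- d$sr_percent
  conc <- d$concentration
  exact <- which(sr == 50)
  if (length(exact)) {
    return(list(ic50 = conc[exact[1L]]))
  }
  lo <- which((sr[-length(sr)] - 50) * (sr[-1L] - 50) < 0)
  if (!length(lo)) {
    stop(paste("no consecutive concentrations bracket SR = 50%;",
               "widen the concentration range or use method = 'four_pl'"),
         call. = FALSE)
  }
  i <- lo[1L]
  frac <- (50 - sr[i]) / (sr[i + 1L] - sr[i])
  list(ic50 = conc[i] + frac * (conc[i + 1L] - conc[i]))
}

ic50_4pl <- function(d) {
  sr <- d$sr_percent
  conc <- d$concentration
  start <- list(sr_min = max(min(sr), 0),
                sr_max = max(sr),
                ec50 = stats::median(conc[conc > 0]),
                hill = 1)
  # 0^hill = 0 for the hill > 0 enforced below, so c = 0 needs no special case
  fit <- minpack.lm::nlsLM(
    sr_percent ~ sr_min + (sr_max - sr_min) *
      concentration^hill / (ec50^hill + concentration^hill),
    data = as.data.frame(d), start = start,
    lower = c(-Inf, -Inf, .Machine$double.eps, .Machine$double.eps),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  q <- (50 - cf[["sr_min"]]) / (cf[["sr_max"]] - cf[["sr_min"]])
  if (!is.finite(q) || q <= 0 || q >= 1) {
    stop("fitted 4PL curve does not cross 50% within its asymptotes",
         call. = FALSE)
  }
  list(ic50 = cf[["ec50"]] * (q / (1 - q))^(1 / cf[["hill"]]),
       coefficients = cf, nls = fit)
}

#' @export
print.ic50_fit <- function(x, digits = 4, ...) {
  cat(sprintf("IC50 (%s, %s): %s ug/mL on %d concentrations\n",
              toupper(x$assay), x$method, format(x$ic50, digits = digits),
              nrow(x$data)))
  invisible(x)
}
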