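method_label <- function(x) {
  switch(x$method,
         arrhenius = "Arrhenius (ln k vs 1000/T)",
         eyring = "Eyring/ACT (ln k/T vs 1000/T)",
         fwo = "Flynn-Wall-Ozawa (lg beta vs 1000/Tp)",
         kas = "Kissinger-Akahira-Sunose (lg beta/Tp^2 vs 1000/Tp)",
         x$method)
}

#' @export
print.oxikin_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit, sample '%s'\n", method_label(x), x$sample))
  cat(sprintf("  slope = %s (per 10^3/K), intercept = %s, R^2 = %s\n",
              format(x$slope, digits = digits),
              format(x$intercept, digits = digits),
              format(x$r_squared, digits = digits)))
  if (!is.null(x$ea_kj_mol)) {
    cat(sprintf("  Ea = %s kJ/mol", format(x$ea_kj_mol, digits = digits)))
    if (!is.null(x$ln_a)) cat(sprintf(", ln A = %s", format(x$ln_a, digits = digits)))
    cat("\n")
  }
  if (!is.null(x$delta_h_kj_mol)) {
    cat(sprintf("  dH = %s kJ/mol, dS = %s J/(mol K)  [ln(kB/h) = %s]\n",
                format(x$delta_h_kj_mol, digits = digits),
                format(x$delta_s_j_mol_k, digits = digits),
                format(x$ln_kb_over_h, digits = digits)))
  }
  invisible(x)
}

#' @export
coef.oxikin_fit <- function(object, ...) {
  out <- c(slope = object$slope, intercept = object$intercept)
  for (nm in c("ea_kj_mol", "ln_a", "delta_h_kj_mol", "delta_s_j_mol_k")) {
    if (!is.null(object[[nm]])) out[nm] <- object[[nm]]
  }
  out
}

#' @export
summary.oxikin_fit <- function(object, ...) {
  structure(list(fit = object, lm_summary = summary(object$lm)),
            class = "summary.oxikin_fit")
}

#' @export
print.summary.oxikin_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  n = %d points; abscissa %s; residual SE = %s\n",
              nrow(x$fit$data), x$fit$abscissa,
              format(x$lm_summary$sigma, digits = 4)))
  invisible(x)
}

#' @export
residuals.oxikin_fit <- function(object, ...) {
  stats::residuals(object$lm)
}

#' Predicted response of a kinetic fit
#'
#' For Arrhenius/Eyring fits, returns the rate constant k (h^-1) predicted
#' at new temperatures; for FWO/KAS fits, the heating rate (K/min) at new
#' peak temperatures. With `scale = "linearized"` the fitted ordinate
#' (ln k, ln k/T, lg beta, lg beta/Tp^2) is returned instead.
#'
#' @param object An `oxikin_fit`.
#' @param temperature_K New temperatures (kelvin); defaults to those fitted.
#' @param scale `"response"` or `"linearized"`.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.oxikin_fit <- function(object, temperature_K = NULL,
                               scale = c("response", "linearized"), ...) {
  scale <- match.arg(scale)
  if (is.null(temperature_K)) {
    temperature_K <- if (object$method %in% c("arrhenius", "eyring")) {
      object$data$temperature_K
    } else {
      object$data$tp_K
    }
  }
  lin <- object$intercept + object$slope * 1000 / temperature_K
  if (scale == "linearized") {
    return(lin)
  }
  switch(object$method,
         arrhenius = exp(lin),
         eyring = temperature_K * exp(lin),
         fwo = 10^lin,
         kas = temperature_K^2 * 10^lin)
}

#' Plot a linearized kinetic fit
#'
#' Scatter of the transformed data against 1000/T with the fitted line, the
#' standard diagnostic for Arrhenius, Eyring and isoconversional fits.
#'
#' @param x An `oxikin_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.oxikin_fit <- function(x, ...) {
  mf <- stats::model.frame(x$lm)
  xs <- mf$x
  ys <- mf$y
  ylab <- switch(x$method, arrhenius = "ln k", eyring = "ln (k/T)",
                 fwo = "lg beta", kas = "lg (beta/Tp^2)")
  graphics::plot(xs, ys, xlab = x$abscissa, ylab = ylab,
                 main = sprintf("%s: %s", x$sample, method_label(x)), ...)
  graphics::abline(x$intercept, x$slope, col = "red3")
  invisible(x)
}

#' Simulate new data from a fitted kinetic model
#'
#' Draws `nsim` fresh datasets from the generating model implied by the fit:
#' Arrhenius fits yield induction-period tables via [simulate_rancimat()]
#' (lognormal noise of sd `sigma` on IP); FWO/KAS fits yield noise-free peak
#' tables via [simulate_dsc_peaks()]. Eyring fits are not simulated (the
#' rate model is the Arrhenius one; refit with `method = "arrhenius"`).
#'
#' @param object An `oxikin_fit`.
#' @param nsim Number of datasets.
#' @param seed Optional integer seed.
#' @param sigma Lognormal sigma for Arrhenius simulation.
#' @param ... Unused.
#' @return List of `nsim` tables.
#' @export
simulate.oxikin_fit <- function(object, nsim = 1, seed = NULL, sigma = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  gen <- switch(object$method,
    arrhenius = function() {
      simulate_rancimat(object$ea_kj_mol, object$ln_a,
                        temperatures_K = unique(object$data$temperature_K),
                        noise_sigma = sigma, sample = object$sample)
    },
    fwo = ,
    kas = function() {
      simulate_dsc_peaks(object$ea_kj_mol, object$intercept,
                         betas = unique(object$data$beta_K_per_min),
                         method = object$method, sample = object$sample)
    },
    stop(sprintf("simulation not defined for method '%s'", object$method),
         call. = FALSE))
  replicate(nsim, gen(), simplify = FALSE)
}
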