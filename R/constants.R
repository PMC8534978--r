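#' Physical constants and fitting conventions
#'
#' All physical constants and linearization conventions used by the package
#' live here and are echoed into every analysis report, so that a fitted
#' activation energy can always be traced to the gas constant, abscissa
#' scaling and log base that produced it.
#'
#' @details
#' * `hartree_kj_mol` — 1 hartree in kJ/mol (2625.4996).
#' * `r_gas` — gas constant, 8.314 J/(mol K), the rounded value conventional
#'   in thermal-analysis regressions.
#' * `ln_kb_over_h` — default ln(kB/h) used by the Eyring intercept, 21.46.
#'   This is the value conventionally tabulated alongside induction-period
#'   rate constants expressed per hour; it differs from the SI s^-1 value
#'   (`ln_kb_over_h_si`, 23.76). See the methods vignette.
#' * `fwo_factor` (0.4567) and `kas_factor` (0.4343 = 1/ln 10) — the Doyle
#'   approximation constants of the Flynn-Wall-Ozawa and
#'   Kissinger-Akahira-Sunose linearizations, which use log10 throughout.
#' * `abscissa` — every linear fit regresses on x = 1000/T (K), so slopes are
#'   in per-10^3/K units.
#'
#' @return Named list of constants and conventions.
#' @examples
#' oxikin_constants()$hartree_kj_mol
#' @export
oxikin_constants <- function() {
  list(
    hartree_kj_mol = HARTREE_KJ_MOL,
    r_gas = R_GAS,
    ln_kb_over_h = LN_KB_OVER_H_DEFAULT,
    ln_kb_over_h_si = LN_KB_OVER_H_SI,
    fwo_factor = FWO_FACTOR,
    kas_factor = KAS_FACTOR,
    abscissa = "1000/T (K)",
    log_base_isoconversional = 10
  )
}

HARTREE_KJ_MOL <- 2625.4996

# J/(mol K); the rounded value every regression in this domain uses
R_GAS <- 8.314

# Conventional Eyring intercept constant for rate constants in h^-1 context;
# kept distinct from the SI s^-1 value below.
LN_KB_OVER_H_DEFAULT <- 21.46
LN_KB_OVER_H_SI <- log(1.380658e-23 / 6.6260755e-34)

FWO_FACTOR <- 0.4567
KAS_FACTOR <- 0.4343
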