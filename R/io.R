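read_checked_csv <- function(path, required) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

coerce_numeric <- function(df, col, path) {
  raw <- df[[col]]
  # reject locale variants (decimal comma) rather than guessing
  num <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(num) & !is.na(raw))
  if (length(bad)) {
    stop(sprintf("%s: column '%s' not numeric at row(s) %s (value(s): %s)",
                 path, col, paste(bad, collapse = ", "),
                 paste(raw[bad], collapse = ", ")), call. = FALSE)
  }
  num
}

#' Read a species-energy CSV
#'
#' Expected columns: `label`, `energy`, `unit` (hartree | kJ_per_mol),
#' `role` (parent | radical | hydrogen_atom | orbital_homo | orbital_lumo).
#' Errors name the offending row and column.
#'
#' @param path CSV path.
#' @return Validated data frame usable with [bde_table()].
#' @export
read_species_table <- function(path) {
  df <- read_checked_csv(path, c("label", "energy", "unit", "role"))
  df$energy <- coerce_numeric(df, "energy", path)
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({
      match_energy_unit(df$unit[i])
      match.arg(df$role[i], species_roles)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) {
      stop(sprintf("%s: row %d: %s", path, i, ok), call. = FALSE)
    }
  }
  if (any(!is.finite(df$energy))) {
    stop(sprintf("%s: non-finite energy at row(s) %s", path,
                 paste(which(!is.finite(df$energy)), collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Read an induction-period CSV
#'
#' Expected columns: `sample`, `temperature`, `temperature_unit` (C | K),
#' `ip_hours`, optionally `replicate`.
#'
#' @param path CSV path.
#' @return An [ip_table()].
#' @export
read_ip_table <- function(path) {
  df <- read_checked_csv(path,
                         c("sample", "temperature", "temperature_unit",
                           "ip_hours"))
  temperature <- coerce_numeric(df, "temperature", path)
  ip_hours <- coerce_numeric(df, "ip_hours", path)
  bad <- which(!is.finite(ip_hours) | ip_hours <= 0)
  if (length(bad)) {
    stop(sprintf("%s: ip_hours must be > 0 at row(s) %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  ip_table(df$sample, temperature, ip_hours,
           temperature_unit = df$temperature_unit,
           replicate = df$replicate)
}

#' Read a DSC peak-temperature CSV
#'
#' Expected columns: `sample`, `beta_K_per_min`, `tp`, `tp_unit` (C | K).
#'
#' @param path CSV path.
#' @return A [dsc_table()].
#' @export
read_dsc_table <- function(path) {
  df <- read_checked_csv(path, c("sample", "beta_K_per_min", "tp", "tp_unit"))
  beta <- coerce_numeric(df, "beta_K_per_min", path)
  tp <- coerce_numeric(df, "tp", path)
  dsc_table(df$sample, beta, tp, tp_unit = df$tp_unit)
}

#' Read a dose-response CSV
#'
#' Expected columns: `assay` (dpph | abts), `concentration`, `a0`, `a1`.
#' All rows must belong to one assay.
#'
#' @param path CSV path.
#' @return A [dose_response()] table.
#' @export
read_dose_response <- function(path) {
  df <- read_checked_csv(path, c("assay", "concentration", "a0", "a1"))
  assay <- unique(tolower(df$assay))
  if (length(assay) != 1L) {
    stop(sprintf("%s: a dose-response file must contain a single assay", path),
         call. = FALSE)
  }
  dose_response(coerce_numeric(df, "concentration", path),
                a0 = coerce_numeric(df, "a0", path),
                a1 = coerce_numeric(df, "a1", path),
                assay = assay)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested stages in order — `bde`, `rancimat`, `dsc`,
#' `scavenge` — and assembles a machine-readable report: package version,
#' MD5 digests of every input file, the conventions block
#' ([oxikin_constants()]), and per-stage results. Optionally serialized to
#' JSON with TSV summaries per stage.
#'
#' @param config A named list or path to a YAML file. Recognised stages:
#'   * `bde`: `species` (CSV path), `parent`, `hydrogen` (labels)
#'   * `rancimat`: `ip` (CSV path), optional `eyring` (logical, default
#'     TRUE), `ln_kb_over_h`
#'   * `dsc`: `peaks` (CSV path), optional `method` ("fwo", "kas" or "both")
#'   * `scavenge`: `curve` (CSV path), optional `method`
#' @param out_dir Optional directory for `report.json` and per-stage TSVs.
#' @return The report, invisibly, as a nested list of class
#'   `oxikin_report`.
#' @examples
#' species <- system.file("extdata", "ca_species.csv", package = "oxikin")
#' rep <- run_pipeline(list(bde = list(species = species,
#'                                     parent = "CA", hydrogen = "H")))
#' rep$results$bde
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stages <- intersect(c("bde", "rancimat", "dsc", "scavenge"), names(config))
  if (length(stages) == 0L) {
    stop("configuration names no stage (bde, rancimat, dsc, scavenge)",
         call. = FALSE)
  }
  report <- list(
    tool = "oxikin",
    version = as.character(utils::packageVersion("oxikin")),
    conventions = oxikin_constants(),
    inputs = list(),
    results = list())

  digest <- function(path) {
    report$inputs[[path]] <<- unname(tools::md5sum(path))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  for (stage in stages) {
    cfg <- config[[stage]]
    report$results[[stage]] <- switch(stage,
      bde = run_stage("bde", {
        digest(cfg$species)
        sp <- read_species_table(cfg$species)
        recs <- bde_table(sp, parent = cfg$parent, hydrogen = cfg$hydrogen)
        as.data.frame(rank_sites(recs))
      }),
      rancimat = run_stage("rancimat", {
        digest(cfg$ip)
        ip <- read_ip_table(cfg$ip)
        rates <- rate_constants(ip)
        methods <- c("arrhenius",
                     if (isTRUE(cfg$eyring) || is.null(cfg$eyring)) "eyring")
        fits <- list()
        for (s in unique(rates$sample)) {
          for (m in methods) {
            f <- kinetic_fit(rates, sample = s, method = m,
                             ln_kb_over_h = cfg$ln_kb_over_h %||%
                               LN_KB_OVER_H_DEFAULT)
            fits[[paste(s, m, sep = ".")]] <- fit_as_row(f)
          }
        }
        do.call(rbind_fill, fits)
      }),
      dsc = run_stage("dsc", {
        digest(cfg$peaks)
        peaks <- read_dsc_table(cfg$peaks)
        method <- cfg$method %||% "both"
        methods <- if (method == "both") c("fwo", "kas") else method
        fits <- list()
        for (s in unique(peaks$sample)) {
          for (m in methods) {
            f <- isoconversional_fit(peaks, sample = s, method = m)
            fits[[paste(s, m, sep = ".")]] <- fit_as_row(f)
          }
        }
        do.call(rbind_fill, fits)
      }),
      scavenge = run_stage("scavenge", {
        digest(cfg$curve)
        curve <- read_dose_response(cfg$curve)
        est <- ic50(curve, method = cfg$method %||% "interpolate")
        list(assay = est$assay, method = est$method, ic50_ug_ml = est$ic50,
             sr_percent = curve$sr_percent,
             concentration = curve$concentration)
      }))
  }

  class(report) <- "oxikin_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_as_row <- function(f) {
  row <- data.frame(sample = f$sample, method = f$method, slope = f$slope,
                    intercept = f$intercept, r_squared = f$r_squared,
                    abscissa = f$abscissa, stringsAsFactors = FALSE)
  for (nm in c("ea_kj_mol", "ln_a", "delta_h_kj_mol", "delta_s_j_mol_k",
               "ln_kb_over_h")) {
    if (!is.null(f[[nm]])) row[[nm]] <- f[[nm]]
  }
  row
}

rbind_fill <- function(...) {
  rows <- list(...)
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(cols, names(r))) r[[nm]] <- NA
    r[cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize an analysis report
#'
#' Writes `report.json` (lossless via jsonlite) and one TSV summary per
#' tabular stage into `out_dir`.
#'
#' @param report An `oxikin_report` from [run_pipeline()].
#' @param out_dir Output directory, created if absent.
#' @return Paths written, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- json_path
  for (stage in names(report$results)) {
    res <- report$results[[stage]]
    if (is.data.frame(res)) {
      p <- file.path(out_dir, paste0(stage, ".tsv"))
      utils::write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' @export
print.oxikin_report <- function(x, ...) {
  cat(sprintf("oxikin analysis report (version %s)\n", x$version))
  cat(sprintf("  inputs: %d file(s); stages: %s\n", length(x$inputs),
              paste(names(x$results), collapse = ", ")))
  for (stage in names(x$results)) {
    cat(sprintf("-- %s --\n", stage))
    res <- x$results[[stage]]
    if (is.data.frame(res)) {
      print.data.frame(res, row.names = FALSE, digits = 4)
    } else {
      utils::str(res, give.attr = FALSE)
    }
  }
  invisible(x)
}
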