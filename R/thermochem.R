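#' Convert between hartree and kJ/mol
#'
#' Electronic-structure programs report total energies in hartree while
#' thermochemical tables use kJ/mol; this converter applies the fixed factor
#' 1 hartree = 2625.4996 kJ/mol (see [oxikin_constants()]).
#'
#' @param value Numeric vector of energies.
#' @param from,to Units, each one of `"hartree"` or `"kJ_per_mol"`.
#' @return Numeric vector in the target unit.
#' @examples
#' convert_energy(1, "hartree", "kJ_per_mol")
#' convert_energy(0.134801, "hartree", "kJ_per_mol")
#' @export
convert_energy <- function(value, from, to) {
  from <- match_energy_unit(from)
  to <- match_energy_unit(to)
  stopifnot(is.numeric(value), all(is.finite(value)))
  if (from == to) {
    return(value)
  }
  if (from == "hartree") value * HARTREE_KJ_MOL else value / HARTREE_KJ_MOL
}

energy_units <- c("hartree", "kJ_per_mol")
species_roles <- c("parent", "radical", "hydrogen_atom",
                   "orbital_homo", "orbital_lumo")

match_energy_unit <- function(unit) {
  if (length(unit) != 1L || is.na(unit)) {
    stop("energy unit must be a single non-missing string", call. = FALSE)
  }
  hit <- match(tolower(unit), tolower(energy_units))
  if (is.na(hit)) {
    stop(sprintf("unknown energy unit '%s'; expected one of: %s",
                 unit, paste(energy_units, collapse = ", ")), call. = FALSE)
  }
  energy_units[hit]
}

#' Construct a species-energy record
#'
#' One chemical species' tabulated energy (or enthalpy), carrying its unit
#' and its role in a homolysis reaction or orbital-gap calculation.
#'
#' @param label Free-text identifier, e.g. `"CA"` or `"CA-(18)O"`.
#' @param energy Finite numeric energy.
#' @param unit `"hartree"` or `"kJ_per_mol"`.
#' @param role One of `"parent"`, `"radical"`, `"hydrogen_atom"`,
#'   `"orbital_homo"`, `"orbital_lumo"`.
#' @return A one-row data frame of class `species_energy`.
#' @examples
#' species_energy("H", -1312.28, "kJ_per_mol", "hydrogen_atom")
#' @export
species_energy <- function(label, energy, unit, role) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(energy) || length(energy) != 1L || !is.finite(energy)) {
    stop("energy must be a single finite number", call. = FALSE)
  }
  unit <- match_energy_unit(unit)
  role <- match.arg(role, species_roles)
  out <- data.frame(label = label, energy = energy, unit = unit, role = role,
                    stringsAsFactors = FALSE)
  class(out) <- c("species_energy", class(out))
  out
}

species_kj <- function(x) convert_energy(x$energy, x$unit, "kJ_per_mol")

check_role <- function(x, expected) {
  if (!identical(x$role, expected)) {
    warning(sprintf("species '%s' has role '%s' where '%s' was expected",
                    x$label, x$role, expected), call. = FALSE)
  }
}

#' Homolytic bond-dissociation enthalpy
#'
#' BDE of an X-H bond from tabulated species enthalpies:
#' `BDE = E(radical) + E(hydrogen atom) - E(parent)`, everything converted to
#' kJ/mol first. A positive BDE is expected for homolysis of a stable parent;
#' a non-positive value triggers a warning, not an error.
#'
#' @param parent,radical,hydrogen [species_energy()] records (one-row data
#'   frames with `energy`, `unit`, `role` columns).
#' @param bond_label Optional label for the broken bond; defaults to the
#'   radical's label.
#' @return A one-row data frame of class `bde_record` with columns
#'   `bond_label`, `bde_kj_mol`, `parent_label`, `radical_label`.
#' @examples
#' ca  <- species_energy("CA", -2836114.23, "kJ_per_mol", "parent")
#' rad <- species_energy("CA-(18)O", -2834506.32, "kJ_per_mol", "radical")
#' h   <- species_energy("H", -1312.28, "kJ_per_mol", "hydrogen_atom")
#' bde_homolytic(ca, rad, h)
#' @export
bde_homolytic <- function(parent, radical, hydrogen,
                          bond_label = radical$label) {
  check_role(parent, "parent")
  check_role(radical, "radical")
  check_role(hydrogen, "hydrogen_atom")
  bde <- species_kj(radical) + species_kj(hydrogen) - species_kj(parent)
  if (!is.finite(bde)) stop("non-finite BDE", call. = FALSE)
  if (bde <= 0) {
    warning(sprintf("non-positive BDE (%.4g kJ/mol) for bond '%s'",
                    bde, bond_label), call. = FALSE)
  }
  out <- data.frame(bond_label = bond_label, bde_kj_mol = bde,
                    parent_label = parent$label,
                    radical_label = radical$label,
                    stringsAsFactors = FALSE)
  class(out) <- c("bde_record", class(out))
  out
}

#' BDE table from a species-energy table
#'
#' Computes one BDE per `radical` row of a species table against a named
#' parent and hydrogen-atom entry; the workhorse behind the CSV/CLI
#' interface.
#'
#' @param species Data frame with columns `label`, `energy`, `unit`, `role`
#'   (see [read_species_table()]).
#' @param parent Label of the parent species.
#' @param hydrogen Label of the hydrogen-atom species.
#' @return Data frame of class `bde_record`, one row per radical, sorted as
#'   in the input.
#' @examples
#' path <- system.file("extdata", "ca_species.csv", package = "oxikin")
#' bde_table(read_species_table(path), parent = "CA", hydrogen = "H")
#' @export
bde_table <- function(species, parent, hydrogen) {
  pick <- function(lbl) {
    i <- which(species$label == lbl)
    if (length(i) != 1L) {
      stop(sprintf("species table must contain exactly one row labelled '%s'",
                   lbl), call. = FALSE)
    }
    row <- species[i, , drop = FALSE]
    row
  }
  p <- pick(parent)
  h <- pick(hydrogen)
  radicals <- species[species$role == "radical", , drop = FALSE]
  if (nrow(radicals) == 0L) stop("no rows with role 'radical'", call. = FALSE)
  recs <- lapply(seq_len(nrow(radicals)), function(i) {
    bde_homolytic(p, radicals[i, , drop = FALSE], h)
  })
  out <- do.call(rbind, recs)
  class(out) <- c("bde_record", "data.frame")
  out
}

#' Frontier-orbital (HOMO-LUMO) gap
#'
#' Returns `E(LUMO) - E(HOMO)` in kJ/mol. A smaller gap indicates a more
#' reactive (less stable) electronic structure; the interpretation is
#' documented, not enforced, so negative gaps from mislabelled inputs pass
#' through arithmetically.
#'
#' @param homo,lumo [species_energy()] records for the highest occupied and
#'   lowest unoccupied molecular orbitals.
#' @return Gap in kJ/mol.
#' @examples
#' frontier_gap(species_energy("HOMO", -0.2, "hartree", "orbital_homo"),
#'              species_energy("LUMO",  0.0, "hartree", "orbital_lumo"))
#' @export
frontier_gap <- function(homo, lumo) {
  species_kj(lumo) - species_kj(homo)
}

#' Rank homolysis sites by bond strength
#'
#' Orders BDE records ascending by BDE, so the most reactive H-donor site
#' (lowest dissociation enthalpy) comes first. Ties break on `bond_label`
#' lexicographically.
#'
#' @param records A `bde_record` data frame (one or more rows).
#' @return The same rows, reordered.
#' @examples
#' path <- system.file("extdata", "ca_species.csv", package = "oxikin")
#' rank_sites(bde_table(read_species_table(path), "CA", "H"))
#' @export
rank_sites <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("cannot rank an empty BDE table", call. = FALSE)
  }
  ord <- order(records$bde_kj_mol, records$bond_label)
  records[ord, , drop = FALSE]
}

#' @export
print.bde_record <- function(x, ...) {
  cat("Homolytic bond-dissociation enthalpies (kJ/mol)\n")
  df <- as.data.frame(x)
  df$bde_kj_mol <- round(df$bde_kj_mol, 2)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
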