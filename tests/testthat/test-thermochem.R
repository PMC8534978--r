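test_that("unit conversion applies the hartree factor and round-trips", {
  expect_identical(convert_energy(1, "hartree", "hartree"), 1)
  expect_identical(convert_energy(-3.5, "kJ_per_mol", "kJ_per_mol"), -3.5)
  expect_equal(convert_energy(1, "hartree", "kJ_per_mol"), 2625.4996)
  expect_equal(convert_energy(0.134801, "hartree", "kJ_per_mol"),
               353.92, tolerance = 0.01 / 353.92)

  set.seed(11)
  for (x in stats::runif(20, -1e6, 1e6)) {
    back <- convert_energy(convert_energy(x, "hartree", "kJ_per_mol"),
                           "kJ_per_mol", "hartree")
    expect_equal(back, x, tolerance = 1e-9)
  }
  expect_error(convert_energy(1, "eV", "hartree"), "unknown energy unit")
})

test_that("phenolic O-H BDEs of carnosic acid come out of the kJ/mol table", {
  sp <- read_species_table(extdata("ca_species.csv"))
  recs <- bde_table(sp, parent = "CA", hydrogen = "H")
  expect_equal(recs$bde_kj_mol[recs$bond_label == "CA-(15)O"], 303.27,
               tolerance = 0.01 / 303.27)
  expect_equal(recs$bde_kj_mol[recs$bond_label == "CA-(18)O"], 295.63,
               tolerance = 0.01 / 295.63)
})

test_that("allylic C-H BDEs of oleic acid come out of the hartree table", {
  sp <- read_species_table(extdata("oa_species.csv"))
  recs <- bde_table(sp, parent = "OA", hydrogen = "H")
  expect_equal(recs$bde_kj_mol[recs$bond_label == "OA-C(8)"], 353.92,
               tolerance = 0.01 / 353.92)
  expect_equal(recs$bde_kj_mol[recs$bond_label == "OA-C(11)"], 353.72,
               tolerance = 0.01 / 353.72)
})

test_that("bde_homolytic is invariant to the unit of its inputs", {
  p_h <- species_energy("P", -856.390, "hartree", "parent")
  r_h <- species_energy("R", -855.757275, "hartree", "radical")
  h_h <- species_energy("H", -0.498, "hartree", "hydrogen_atom")
  in_kj <- function(s, role) {
    species_energy(s$label, convert_energy(s$energy, "hartree", "kJ_per_mol"),
                   "kJ_per_mol", role)
  }
  a <- bde_homolytic(p_h, r_h, h_h)$bde_kj_mol
  b <- bde_homolytic(in_kj(p_h, "parent"), in_kj(r_h, "radical"),
                     in_kj(h_h, "hydrogen_atom"))$bde_kj_mol
  expect_equal(a, b, tolerance = 0.01 / abs(a))
  expect_equal(a, 353.72, tolerance = 0.01 / 353.72)
})

test_that("energy-conserving homolysis gives zero BDE with a warning", {
  p <- species_energy("P", -10, "kJ_per_mol", "parent")
  r <- species_energy("R", -7, "kJ_per_mol", "radical")
  h <- species_energy("H", -3, "kJ_per_mol", "hydrogen_atom")
  expect_warning(rec <- bde_homolytic(p, r, h), "non-positive BDE")
  expect_equal(rec$bde_kj_mol, 0)
})

test_that("role mismatches warn rather than fail", {
  p <- species_energy("P", -10, "kJ_per_mol", "radical")
  r <- species_energy("R", -5, "kJ_per_mol", "radical")
  h <- species_energy("H", -3, "kJ_per_mol", "hydrogen_atom")
  expect_warning(rec <- bde_homolytic(p, r, h), "role")
  expect_equal(rec$bde_kj_mol, 2)
})

test_that("frontier gap is E(LUMO) - E(HOMO) in kJ/mol", {
  mk <- function(e, role, unit = "kJ_per_mol") {
    species_energy(role, e, unit, role)
  }
  expect_equal(frontier_gap(mk(-500, "orbital_homo"),
                            mk(25.21, "orbital_lumo")), 525.21)
  expect_equal(frontier_gap(mk(-1, "orbital_homo"), mk(-1, "orbital_lumo")), 0)
  expect_equal(frontier_gap(mk(-0.2, "orbital_homo", "hartree"),
                            mk(0, "orbital_lumo", "hartree")),
               525.10, tolerance = 0.01 / 525.10)
})

test_that("rank_sites orders ascending by BDE and identifies the active site", {
  sp <- read_species_table(extdata("ca_species.csv"))
  ranked <- rank_sites(bde_table(sp, "CA", "H"))
  expect_identical(ranked$bond_label, c("CA-(18)O", "CA-(15)O"))

  one <- ranked[1, , drop = FALSE]
  expect_identical(rank_sites(one)$bond_label, one$bond_label)

  tied <- data.frame(bond_label = c("b", "a"), bde_kj_mol = c(5, 5),
                     parent_label = "P", radical_label = c("b", "a"))
  expect_identical(rank_sites(tied)$bond_label, c("a", "b"))
  expect_error(rank_sites(tied[0, ]), "empty")
})

test_that("rank_sites returns a permutation with non-decreasing BDE", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(2:8, 1)
    recs <- data.frame(bond_label = sample(letters, n),
                       bde_kj_mol = round(stats::runif(n, 100, 400), 1),
                       parent_label = "P", radical_label = "R")
    ranked <- rank_sites(recs)
    expect_setequal(ranked$bond_label, recs$bond_label)
    expect_true(all(diff(ranked$bde_kj_mol) >= 0))
  }
})
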