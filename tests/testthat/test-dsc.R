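test_that("FWO and KAS slopes convert to the reference activation energies", {
  fits <- reference_fits()
  cases <- list(
    list(method = "fwo", sample = "OA", ea = 50.31),
    list(method = "fwo", sample = "CA + OA", ea = 52.58),
    list(method = "fwo", sample = "TBHQ + OA", ea = 51.51),
    list(method = "kas", sample = "OA", ea = 44.27),
    list(method = "kas", sample = "CA + OA", ea = 46.53),
    list(method = "kas", sample = "TBHQ + OA", ea = 45.47))
  for (cs in cases) {
    slope <- ref_line(fits, cs$sample, cs$method)$slope
    expect_equal(slope_to_ea_iso(slope, cs$method), cs$ea,
                 tolerance = 0.02 / cs$ea)
  }
  expect_equal(slope_to_ea_iso(0, "fwo"), 0)
  expect_error(slope_to_ea_iso(-2, "ozawa"), "arg")
})

test_that("noiseless peak tables invert to their generating parameters", {
  for (m in c("fwo", "kas")) {
    ea <- if (m == "fwo") 50 else 45
    peaks <- simulate_dsc_peaks(ea, 6.3, method = m)
    fit <- isoconversional_fit(peaks, method = m)
    expect_equal(fit$ea_kj_mol, ea, tolerance = 0.01 / ea)
    expect_equal(fit$intercept, 6.3, tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  }
})

test_that("fits are invariant to row order and behave predictably under duplication", {
  peaks <- simulate_dsc_peaks(50.31, 6.2864)
  shuffled <- peaks[c(3, 1, 4, 2), ]
  f1 <- isoconversional_fit(peaks, method = "fwo")
  f2 <- isoconversional_fit(shuffled, method = "fwo")
  expect_equal(f1$slope, f2$slope)
  expect_equal(f1$ea_kj_mol, f2$ea_kj_mol)

  doubled <- rbind(peaks, peaks)
  f3 <- isoconversional_fit(doubled, method = "fwo")
  expect_equal(f3$slope, f1$slope, tolerance = 1e-9)
  expect_equal(f3$ea_kj_mol, f1$ea_kj_mol, tolerance = 1e-9)
})

test_that("FWO and KAS agree within 15% on shared synthetic peaks", {
  peaks <- simulate_dsc_peaks(50, 6.3, method = "fwo",
                              betas = c(2, 5, 10, 15, 20))
  ea_fwo <- isoconversional_fit(peaks, method = "fwo")$ea_kj_mol
  ea_kas <- isoconversional_fit(peaks, method = "kas")$ea_kj_mol
  expect_lt(abs(ea_fwo - ea_kas) / ea_fwo, 0.15)
})

test_that("sample ranking by Ea matches under FWO and KAS reference slopes", {
  fits <- reference_fits()
  rank_of <- function(method) {
    sub <- fits[fits$method == method, ]
    sub$sample[order(slope_to_ea_iso(sub$slope, method), decreasing = TRUE)]
  }
  expect_identical(rank_of("fwo"), c("CA + OA", "TBHQ + OA", "OA"))
  expect_identical(rank_of("kas"), c("CA + OA", "TBHQ + OA", "OA"))
})

test_that("insufficient heating rates are refused", {
  expect_warning(one <- simulate_dsc_peaks(50, 6.3, betas = 10),
                 ">= 3 recommended")
  expect_error(isoconversional_fit(one, method = "fwo"),
               ">= 2 distinct heating rates")
  expect_error(suppressWarnings(dsc_table("s", c(-1, 5), c(450, 460))),
               "positive")
})
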