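test_that("rate constants are reciprocal induction periods in kelvin rows", {
  ip <- suppressWarnings(ip_table("s", c(100, 120), c(1, 4)))
  rt <- rate_constants(ip)
  expect_equal(rt$k, c(1, 0.25))
  expect_equal(rt$temperature_K, c(373.15, 393.15))
  expect_error(suppressWarnings(ip_table("s", 100, 0)), "positive")
  expect_error(suppressWarnings(ip_table("s", 100, -1)), "row")
})

test_that("slope_to_ea reproduces the reference Arrhenius activation energies", {
  fits <- reference_fits()
  arr <- fits[fits$method == "arrhenius", ]
  ea <- slope_to_ea(arr$slope)
  names(ea) <- arr$sample
  expect_equal(unname(ea["OA"]), 50.59, tolerance = 0.01 / 50.59)
  expect_equal(unname(ea["CA + OA"]), 66.29, tolerance = 0.01 / 66.29)
  expect_equal(unname(ea["TBHQ + OA"]), 57.32, tolerance = 0.01 / 57.32)
})

test_that("slope_to_ea is linear and odd", {
  set.seed(2)
  s <- stats::runif(10, -10, 10)
  expect_equal(slope_to_ea(-s), -slope_to_ea(s))
  expect_equal(slope_to_ea(2 * s), 2 * slope_to_ea(s))
  expect_equal(slope_to_ea(0), 0)
})

test_that("noiseless Arrhenius data inverts exactly", {
  ip <- simulate_rancimat(ea_kj_mol = 66.29, ln_a = 20.55,
                          temperatures_K = c(373.15, 383.15, 393.15, 403.15))
  fit <- kinetic_fit(rate_constants(ip), method = "arrhenius")
  expect_equal(fit$ea_kj_mol, 66.29, tolerance = 0.01 / 66.29)
  expect_equal(fit$ln_a, 20.55, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("two exact points give a perfect line; degenerate inputs error", {
  rt <- data.frame(sample = "s", temperature_K = c(373.15, 393.15),
                   k = exp(20 - 6 * 1000 / c(373.15, 393.15)))
  fit <- kinetic_fit(rt)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -6, tolerance = 1e-9)

  one <- rt[1, , drop = FALSE]
  expect_error(kinetic_fit(one), ">= 2 distinct temperatures")
  same_t <- data.frame(sample = "s", temperature_K = c(373.15, 373.15),
                       k = c(0.1, 0.2))
  expect_error(kinetic_fit(same_t), "distinct temperatures|degenerate")
})

test_that("Eyring parameters reproduce the reference dH and dS", {
  cases <- list(list(line = c(-5.6975, 8.9535), dh = 47.37, ds = -103.95),
                list(line = c(-6.5083, 10.912), dh = 54.11, ds = -87.66),
                list(line = c(-7.5879, 13.594), dh = 63.09, ds = -65.36))
  for (cs in cases) {
    ep <- eyring_params(cs$line[1], cs$line[2], ln_kb_over_h = 21.46)
    expect_equal(ep$delta_h_kj_mol, cs$dh, tolerance = 0.01 / cs$dh)
    expect_equal(ep$delta_s_j_mol_k, cs$ds, tolerance = 0.1 / abs(cs$ds))
  }
  # frozen independent arithmetic: (8.9535 - 21.46) * 8.314
  expect_equal(eyring_params(-5.6975, 8.9535)$delta_s_j_mol_k,
               -103.979, tolerance = 0.05 / 103.979)
  expect_equal(eyring_params(0, 21.46)$delta_s_j_mol_k, 0)
})

test_that("eyring_fit populates exactly the Eyring parameter pair", {
  ip <- simulate_rancimat(50, 16)
  fit <- kinetic_fit(rate_constants(ip), method = "eyring")
  expect_s3_class(fit, "eyring_fit")
  expect_null(fit$ea_kj_mol)
  expect_null(fit$ln_a)
  expect_true(is.finite(fit$delta_h_kj_mol))
  expect_true(is.finite(fit$delta_s_j_mol_k))
  expect_equal(fit$ln_kb_over_h, 21.46)
  arr <- kinetic_fit(rate_constants(ip), method = "arrhenius")
  expect_null(arr$delta_h_kj_mol)
  expect_true(is.finite(arr$ea_kj_mol))
})

test_that("a noiseless Eyring fit recovers its generating line", {
  temps <- c(373.15, 383.15, 393.15, 403.15)
  k <- temps * exp(8.9535 - 5.6975 * 1000 / temps)
  rt <- data.frame(sample = "OA", temperature_K = temps, k = k)
  fit <- kinetic_fit(rt, method = "eyring")
  expect_equal(fit$slope, -5.6975, tolerance = 1e-9)
  expect_equal(fit$intercept, 8.9535, tolerance = 1e-9)
  expect_equal(fit$delta_h_kj_mol, 47.37, tolerance = 0.01 / 47.37)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("noisy Arrhenius recovery is accurate over many seeds", {
  ea_true <- 66.29
  est <- vapply(1:200, function(s) {
    ip <- simulate_rancimat(ea_true, 20.55, noise_sigma = 0.05, seed = s)
    kinetic_fit(rate_constants(ip))$ea_kj_mol
  }, numeric(1))
  expect_lt(abs(mean(est) - ea_true) / ea_true, 0.02)
})

test_that("replicates fit as points unless averaging is requested", {
  ip <- simulate_rancimat(55, 17, n_rep = 3, noise_sigma = 0.1, seed = 42)
  rt <- rate_constants(ip)
  fit_pts <- kinetic_fit(rt)
  fit_avg <- kinetic_fit(rt, average_replicates = TRUE)
  expect_equal(nrow(fit_pts$data), 12)
  expect_equal(nrow(fit_avg$data), 4)
  expect_false(isTRUE(all.equal(fit_pts$slope, fit_avg$slope)))
})
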