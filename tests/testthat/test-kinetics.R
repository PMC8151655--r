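test_that("Michaelis-Menten fit recovers noise-free parameters exactly", {
  cases <- list(c(Km = 0.06, Vmax = 120.5), c(Km = 0.007, Vmax = 1111))
  for (cs in cases) {
    d <- simulate_kinetic_series(kinetic_truth(cs["Km"], cs["Vmax"]),
                                 doses = 0)
    f <- fit_michaelis_menten(d)
    expect_equal(f$Km, unname(cs["Km"]), tolerance = 1e-6)
    expect_equal(f$Vmax, unname(cs["Vmax"]), tolerance = 1e-6)
    expect_equal(unname(predict(f, cs["Km"])), unname(cs["Vmax"]) / 2,
                 tolerance = 1e-6)
  }
})

test_that("Michaelis-Menten Km is nearly unbiased at plate-reader noise", {
  # Monte-Carlo oracle: median relative Km bias below 5% at CV 5%
  tr <- kinetic_truth(0.06, 120.5, noise_cv = 0.05)
  kms <- purrr::map_dbl(1:200, function(i) {
    d <- simulate_kinetic_series(tr, doses = 0, seed = 1000 + i)
    fit_michaelis_menten(d)$Km
  })
  expect_lt(abs(median(kms) / 0.06 - 1), 0.05)
})

test_that("Lineweaver-Burk transform matches the nonlinear fit on exact data", {
  d <- simulate_kinetic_series(kinetic_truth(0.06, 120.5), doses = 0)
  lb <- lineweaver_burk(d)
  lines <- attr(lb, "lines")
  expect_equal(lines$intercept, 1 / 120.5, tolerance = 1e-9)
  expect_equal(lines$slope, 0.06 / 120.5, tolerance = 1e-9)
})

test_that("uncompetitive doses give parallel double-reciprocal lines", {
  d <- uncomp_series()
  lines <- attr(lineweaver_burk(d), "lines")
  expect_equal(diff(range(lines$slope)), 0, tolerance = 1e-9)
  # apparent Km and Vmax shrink together, keeping slope Km_app/Vmax_app fixed
  expect_gt(dplyr::n_distinct(round(lines$intercept, 6)), 1)
})

test_that("competitive doses share the 1/Vmax intercept", {
  d <- comp_series()
  lines <- attr(lineweaver_burk(d), "lines")
  expect_equal(lines$intercept, rep(1 / 120.5, nrow(lines)), tolerance = 1e-9)
})

test_that("zero rates are excluded from the reciprocal transform with warning", {
  d <- simulate_kinetic_series(kinetic_truth(0.06, 120.5), doses = 0,
                               replicates = 1)
  d$rate[1] <- 0
  expect_warning(lb <- lineweaver_burk(d), "zero")
  expect_equal(nrow(lb), nrow(d) - 1)
})

test_that("mechanism classifier recovers noise-free truths exactly", {
  mc <- classify_mechanism(uncomp_series())
  expect_equal(mc$label, "uncompetitive")
  expect_equal(mc$Ki, 0.009, tolerance = 1e-6)
  expect_equal(mc$Km, 0.007, tolerance = 1e-6)

  cc <- classify_mechanism(comp_series())
  expect_equal(cc$label, "competitive")
  expect_equal(cc$Ki, 0.05, tolerance = 1e-6)

  nc <- classify_mechanism(simulate_kinetic_series(
    kinetic_truth(0.06, 120.5, "noncompetitive", Ki = 0.05),
    doses = c(0.02, 0.05, 0.1)))
  expect_equal(nc$label, "noncompetitive")

  act <- classify_mechanism(simulate_kinetic_series(
    kinetic_truth(0.06, 120.5, "activation", Ki = 0.12, Emax = 1.1),
    doses = c(0.02, 0.05, 0.1, 0.3, 1)))
  expect_equal(act$label, "activation")
  expect_equal(act$Ka, 0.12, tolerance = 1e-4)
  expect_equal(act$Emax, 1.1, tolerance = 1e-4)

  none <- classify_mechanism(simulate_kinetic_series(
    kinetic_truth(0.06, 120.5, "none"), doses = c(0.02, 0.05, 0.1)))
  expect_equal(none$label, "none")
})

test_that("uncompetitive law conservation holds on fitted apparent parameters", {
  mc <- classify_mechanism(uncomp_series())
  pd <- mc$per_dose
  ctrl <- pd[pd$dose_mM == 0, ]
  nz <- pd[pd$dose_mM > 0, ]
  km_ratio <- nz$Km_app / ctrl$Km_app
  vmax_ratio <- nz$Vmax_app / ctrl$Vmax_app
  expect_equal(km_ratio, vmax_ratio, tolerance = 1e-6)
  expect_equal(km_ratio, 1 / (1 + nz$dose_mM / 0.009), tolerance = 1e-6)
})

test_that("classification is invariant to dose order and rate units", {
  d <- uncomp_series()
  shuffled <- d[rev(seq_len(nrow(d))), ]
  scaled <- mutate(d, rate = rate * 1000)
  expect_equal(classify_mechanism(shuffled)$label, "uncompetitive")
  sc <- classify_mechanism(scaled)
  expect_equal(sc$label, "uncompetitive")
  expect_equal(sc$Ki, 0.009, tolerance = 1e-6)
})

test_that("classifier input requirements are enforced", {
  d <- uncomp_series()
  expect_error(classify_mechanism(filter(d, dose_mM == 0)),
               class = "synerkin_input_error")
  expect_error(classify_mechanism(filter(d, dose_mM %in% c(0, 0.005))),
               class = "synerkin_input_error")
  expect_error(fit_michaelis_menten(
    tibble::tibble(substrate_mM = c(1, 2, 3), rate = c(1, 2, 3))),
    class = "synerkin_input_error")
})
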