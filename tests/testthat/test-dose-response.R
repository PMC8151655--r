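test_that("effect fractions follow the role-specific definitions", {
  d <- tibble::tibble(dose_mM = c(0, 1, 2), rate = c(100, 50, 25))
  fa <- effect_fraction(d, "inhibition")
  expect_equal(fa$fa, c(0.5, 0.75))

  # scavenging: blank absorbance plays the control role
  sc <- effect_fraction(tibble::tibble(dose_mM = c(1, 2), rate = c(0.8, 0.4)),
                        "scavenging", control_rate = 0.8)
  expect_equal(sc$fa, c(0, 0.5))

  # activation: v = 1.5 v0 is 50% activation, the operational AC50 level
  act <- effect_fraction(
    tibble::tibble(dose_mM = c(0, 0.1, 1), rate = c(100, 150, 190)),
    "activation", plateau = 100)
  expect_equal(act$activation_pct, c(50, 90))
  expect_equal(act$fa, c(0.5, 0.9))

  expect_error(effect_fraction(d, "inhibition", control_rate = 0),
               class = "synerkin_input_error")
  expect_error(
    effect_fraction(tibble::tibble(dose_mM = c(1, 2, 3),
                                   rate = c(99.9, 99.8, 0.01)),
                    "inhibition", control_rate = 100),
    class = "synerkin_data_quality_error")
})

test_that("median-effect fit recovers noise-free parameters", {
  for (pars in list(c(Dm = 0.69, m = 1), c(Dm = 0.009, m = 1.7))) {
    D <- pars["Dm"] * c(0.2, 0.5, 1, 2, 5)^(1 / pars["m"])
    fa <- 1 / (1 + (pars["Dm"] / D)^pars["m"])
    f <- fit_median_effect(tibble::tibble(dose_mM = D, fa = fa))
    expect_equal(f$Dm, unname(pars["Dm"]), tolerance = 1e-9)
    expect_equal(f$m, unname(pars["m"]), tolerance = 1e-9)
    expect_equal(abs(f$r), 1, tolerance = 1e-9)
  }
})

test_that("median-effect fit matches the closed-form OLS oracle", {
  # expected values frozen from the hand-computed OLS on the transformed
  # pairs (log10 fa/(1-fa) vs log10 D)
  f <- fit_median_effect(tibble::tibble(dose_mM = c(0.1, 0.2, 0.4, 0.8),
                                        fa = c(0.2, 0.35, 0.55, 0.75)))
  expect_equal(f$m, 1.1937478915, tolerance = 1e-9)
  expect_equal(f$Dm, 0.3279152579, tolerance = 1e-9)
  expect_equal(f$r, 0.9993721125, tolerance = 1e-9)
})

test_that("median-effect fit guards its inputs", {
  expect_error(fit_median_effect(tibble::tibble(dose_mM = c(-1, 1, 2),
                                                fa = c(0.1, 0.5, 0.9))),
               class = "synerkin_input_error")
  expect_warning(
    expect_error(
      fit_median_effect(tibble::tibble(dose_mM = c(1, 2, 3),
                                       fa = c(0, 0.5, 1))),
      class = "synerkin_fit_error"),
    "excluded")
  expect_warning(
    f <- fit_median_effect(tibble::tibble(dose_mM = c(1, 2, 4),
                                          fa = c(0.8, 0.5, 0.2))),
    "invalid")
  expect_false(f$valid)
})

test_that("Dx inversion and the forward law are exact inverses", {
  f <- fit_median_effect(tibble::tibble(dose_mM = c(0.05, 0.1, 0.2, 0.4),
                                        fa = c(1 / 3, 0.5, 2 / 3, 0.8)))
  expect_equal(dose_at_effect(f, 0.5), f$Dm, tolerance = 1e-12)
  xs <- seq(0.05, 0.95, by = 0.05)
  expect_equal(effect_at_dose(f, dose_at_effect(f, xs)), xs, tolerance = 1e-9)
  expect_true(all(diff(dose_at_effect(f, xs)) > 0))
  expect_error(dose_at_effect(f, 1), class = "synerkin_input_error")
})

test_that("Dx follows the closed form for m = 1", {
  D <- 0.10 * c(0.25, 0.5, 1, 2, 4)
  fa <- 1 / (1 + 0.10 / D)
  f <- fit_median_effect(tibble::tibble(dose_mM = D, fa = fa))
  expect_equal(dose_at_effect(f, 0.75), 0.30, tolerance = 1e-6)
})

test_that("IC50 equals the median-effect dose and is scale invariant", {
  for (Dm in c(0.009, 0.22)) {
    D <- Dm * c(0.25, 0.5, 1, 2, 4)
    rates <- tibble::tibble(dose_mM = c(0, D),
                            rate = 100 * c(1, 1 - 1 / (1 + (Dm / D)^1)))
    est <- estimate_ec50(effect_fraction(rates, "inhibition"),
                         "inhibition", B = 0)
    expect_equal(est$ec50_mM, Dm, tolerance = 1e-9)
    # rescaling every rate by a constant leaves the fractions unchanged
    est2 <- estimate_ec50(
      effect_fraction(mutate(rates, rate = rate * 37), "inhibition"),
      "inhibition", B = 0)
    expect_equal(est2$ec50_mM, est$ec50_mM, tolerance = 1e-12)
  }
})

test_that("clipping is a no-op when fractions are already interior", {
  d <- tibble::tibble(dose_mM = c(0.1, 0.2, 0.4, 0.8),
                      fa = c(0.2, 0.35, 0.55, 0.75))
  f1 <- fit_median_effect(d, fa_bounds = c(0.01, 0.99))
  f2 <- fit_median_effect(d, fa_bounds = c(0.001, 0.999))
  expect_equal(f1$Dm, f2$Dm, tolerance = 1e-12)
  expect_equal(f1$m, f2$m, tolerance = 1e-12)
})

test_that("activation curve fit recovers the hyperbola and its AC50", {
  plateau <- 110; Ka <- 0.12
  d <- tibble::tibble(dose_mM = c(0.02, 0.05, 0.1, 0.3, 1),
                      activation_pct = plateau * dose_mM / (Ka + dose_mM))
  f <- fit_activation_curve(d)
  expect_equal(f$plateau, plateau, tolerance = 1e-6)
  expect_equal(f$Ka, Ka, tolerance = 1e-6)
  expect_equal(f$ac50, Ka * 50 / (plateau - 50), tolerance = 1e-6)
  # the defining property: the fitted curve passes through 50% at the AC50
  expect_equal(predict(f, f$ac50), 50, tolerance = 1e-9)
  # plateau below 50% has no AC50
  low <- mutate(d, activation_pct = activation_pct * 0.3)
  expect_warning(f_low <- fit_activation_curve(low), "plateau")
  expect_true(is.na(f_low$ac50))
})

test_that("EC50 bootstrap is seeded and shrinks with replication", {
  Dm <- 0.2
  make_series <- function(reps, seed) {
    withr::with_seed(seed, {
      D <- rep(Dm * c(0.25, 0.5, 1, 2, 4), each = reps)
      fa <- 1 / (1 + (Dm / D)) * exp(rnorm(length(D), 0, 0.05))
      tibble::tibble(dose_mM = D, replicate = rep(1:reps, 5),
                     fa = pmin(fa, 0.99))
    })
  }
  s3 <- make_series(3, 21)
  e1 <- estimate_ec50(s3, "inhibition", B = 200, seed = 5)
  e2 <- estimate_ec50(s3, "inhibition", B = 200, seed = 5)
  expect_equal(e1$ec50_sd, e2$ec50_sd)
  expect_gt(e1$ec50_sd, 0)
  # tripling replication shrinks the bootstrap SD roughly like 1/sqrt(n)
  s27 <- make_series(27, 22)
  e27 <- estimate_ec50(s27, "inhibition", B = 200, seed = 5)
  expect_lt(e27$ec50_sd, e1$ec50_sd)
})
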