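test_that("sham combination (agent with itself) gives CI = 1 at every ratio", {
  # identical Dm/m for both components and psi = 1 makes the mixture
  # indistinguishable from the agent alone
  truth <- mixture_truth(Dm1 = 0.22, Dm2 = 0.22, m1 = 1.3, m2 = 1.3, psi = 1)
  res <- full_ci(truth, x = c(0.3, 0.5, 0.7))
  expect_equal(res$ci, rep(1, nrow(res)), tolerance = 1e-6)
  expect_true(all(res$label == "nearly additive"))
})

test_that("noise-free pipelines recover the constructed interaction index", {
  for (psi in c(0.25, 0.5, 1, 1.5, 2.5)) {
    truth <- mixture_truth(Dm1 = 0.10, Dm2 = 0.69, m1 = 1.2, m2 = 1.2,
                           psi = psi)
    res <- full_ci(truth, x = c(0.3, 0.5, 0.7))
    expect_equal(res$ci, rep(psi, nrow(res)), tolerance = 1e-6)
  }
})

test_that("CI equals the reciprocal-DRI sum identically", {
  truth <- mixture_truth(Dm1 = 0.10, Dm2 = 0.69, psi = 0.24)
  res <- full_ci(truth, x = c(0.3, 0.5, 0.7))
  expect_equal(res$ci, 1 / res$dri1 + 1 / res$dri2, tolerance = 1e-12)
  expect_equal(res$ci, res$d1_norm + res$d2_norm, tolerance = 1e-12)
  expect_true(all(res$d1_mM > 0 & res$d2_mM > 0))
})

test_that("CI is symmetric under swapping agents and mirroring ratios", {
  truth <- mixture_truth(Dm1 = 0.10, Dm2 = 0.69, psi = 0.5,
                         ratios = list(c(1, 4), c(4, 1)))
  sim <- simulate_mixture_series(truth)
  ag <- agent_split(sim)
  fwd <- combination_index(sim$mixtures, ag$a1, ag$a2)
  swapped <- sim$mixtures |>
    mutate(ratio = ifelse(ratio == "1:4", "4:1", "1:4"),
           tmp = d1_mM, d1_mM = d2_mM, d2_mM = tmp) |>
    select(-tmp)
  rev <- combination_index(swapped, ag$a2, ag$a1)
  expect_equal(sort(fwd$ci), sort(rev$ci), tolerance = 1e-9)
})

test_that("CI estimation is consistent under noise", {
  # median CI over seeded noisy runs stays within 10% of the construction
  psis <- c(0.5, 1.5)
  for (psi in psis) {
    truth <- mixture_truth(Dm1 = 0.10, Dm2 = 0.69, psi = psi,
                           ratios = list(c(1, 1)), noise_cv = 0.05)
    cis <- purrr::map_dbl(1:50, function(i) {
      full_ci(truth, seed = 3000 + i)$ci
    })
    expect_lt(abs(median(cis) / psi - 1), 0.10)
  }
})

test_that("interaction labels follow the refined band table", {
  expect_equal(classify_interaction(0.05), "very strong synergism")
  expect_equal(classify_interaction(0.24), "strong synergism")
  expect_equal(classify_interaction(c(0.46, 0.48, 0.53, 0.63, 0.69)),
               rep("synergism", 5))
  expect_equal(classify_interaction(0.75), "moderate synergism")
  expect_equal(classify_interaction(0.87), "slight synergism")
  expect_equal(classify_interaction(c(0.90, 0.98, 1, 1.10)),
               rep("nearly additive", 4))
  expect_equal(classify_interaction(1.15), "slight antagonism")
  expect_equal(classify_interaction(1.30), "moderate antagonism")
  expect_equal(classify_interaction(c(2.15, 2.21)), rep("antagonism", 2))
  expect_equal(classify_interaction(5), "strong antagonism")
  expect_equal(classify_interaction(12), "very strong antagonism")
  expect_error(classify_interaction(0), class = "synerkin_input_error")
  expect_error(classify_interaction(-1), class = "synerkin_input_error")
})

test_that("isobologram coordinates sit on the u + v = CI line", {
  truth <- mixture_truth(Dm1 = 0.2, Dm2 = 0.4, psi = 0.5)
  res <- full_ci(truth)
  pts <- isobologram_points(res)
  expect_equal(pts$d1_norm + pts$d2_norm, rep(0.5, nrow(pts)),
               tolerance = 1e-6)
  # sham at mirrored ratios lands at (0.2, 0.8) and (0.8, 0.2)
  sham <- mixture_truth(Dm1 = 0.22, Dm2 = 0.22, psi = 1,
                        ratios = list(c(1, 4), c(4, 1)))
  sp <- isobologram_points(full_ci(sham)) |> arrange(d1_norm)
  expect_equal(sp$d1_norm, c(0.2, 0.8), tolerance = 1e-6)
  expect_equal(sp$d2_norm, c(0.8, 0.2), tolerance = 1e-6)
})

test_that("CI bootstrap is seeded, near zero without noise, positive with", {
  quiet_ci_sd <- function(truth, seed) {
    sim <- simulate_mixture_series(truth, seed = seed)
    ag <- agent_split(sim)
    combination_index(sim$mixtures, ag$a1, ag$a2, B = 100, seed = 9)$ci_sd
  }
  noise_free <- mixture_truth(Dm1 = 0.1, Dm2 = 0.69, ratios = list(c(1, 1)))
  expect_equal(quiet_ci_sd(noise_free, 1), 0, tolerance = 1e-9)

  noisy <- mixture_truth(Dm1 = 0.1, Dm2 = 0.69, ratios = list(c(1, 1)),
                         noise_cv = 0.05)
  sd1 <- quiet_ci_sd(noisy, 2)
  sd2 <- quiet_ci_sd(noisy, 2)
  expect_equal(sd1, sd2)
  expect_gt(sd1, 0)
})

test_that("bootstrap requirements are enforced", {
  sim <- simulate_mixture_series(mixture_truth(Dm1 = 0.1, Dm2 = 0.69),
                                 replicates = 1)
  ag <- agent_split(sim)
  expect_error(ci_bootstrap(sim$mixtures, ag$a1, ag$a2, B = 100),
               class = "synerkin_input_error")
  sim3 <- simulate_mixture_series(mixture_truth(Dm1 = 0.1, Dm2 = 0.69))
  ag3 <- agent_split(sim3)
  expect_warning(ci_bootstrap(sim3$mixtures, ag3$a1, ag3$a2, B = 40),
                 "resamples")
  f1 <- fit_median_effect(ag3$a1)
  expect_error(ci_bootstrap(sim3$mixtures, f1, ag3$a2, B = 100),
               class = "synerkin_input_error")
})
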