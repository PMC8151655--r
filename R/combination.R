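#' Classify a combination index into Chou's interaction bands
#'
#' Maps a combination index to the refined interaction vocabulary: values
#' below 1 grade from slight to very strong synergism, values above 1 from
#' slight to very strong antagonism, with `[0.90, 1.10]` labelled nearly
#' additive. Bands (closed-open, monotone in CI): <0.1 very strong
#' synergism; 0.1-0.3 strong synergism; 0.3-0.7 synergism; 0.7-0.85
#' moderate synergism; 0.85-0.90 slight synergism; 0.90-1.10 nearly
#' additive; 1.10-1.20 slight antagonism; 1.20-1.45 moderate antagonism;
#' 1.45-3.3 antagonism; 3.3-10 strong antagonism; >10 very strong
#' antagonism.
#'
#' @param ci combination index value(s), > 0.
#' @return character vector of interaction labels.
#' @examples
#' classify_interaction(c(0.24, 0.98, 2.15))
#' @export
classify_interaction <- function(ci) {
  if (any(!is.finite(ci) | ci <= 0)) {
    abort("combination index must be a positive finite number.",
          class = "synerkin_input_error")
  }
  dplyr::case_when(
    ci < 0.10 ~ "very strong synergism",
    ci < 0.30 ~ "strong synergism",
    ci < 0.70 ~ "synergism",
    ci < 0.85 ~ "moderate synergism",
    ci < 0.90 ~ "slight synergism",
    ci <= 1.10 ~ "nearly additive",
    ci <= 1.20 ~ "slight antagonism",
    ci <= 1.45 ~ "moderate antagonism",
    ci <= 3.30 ~ "antagonism",
    ci <= 10 ~ "strong antagonism",
    TRUE ~ "very strong antagonism"
  )
}

as_medfx_fit <- function(x, what) {
  if (inherits(x, "medfx_fit")) return(x)
  if (is.data.frame(x)) return(fit_median_effect(x))
  abort(glue::glue("`{what}` must be a medfx_fit or a dose-effect tibble."),
        class = "synerkin_input_error")
}

# dose fraction of agent 1 within each mixture ratio group: prefer recorded
# component doses, otherwise parse the "a:b" label under the stock convention
mixture_p1 <- function(d, stock_conc) {
  if (all(c("d1_mM", "d2_mM") %in% names(d))) {
    p <- d$d1_mM / (d$d1_mM + d$d2_mM)
    return(mean(p))
  }
  parts <- as.numeric(strsplit(d$ratio[1], ":", fixed = TRUE)[[1]])
  if (length(parts) != 2 || any(!is.finite(parts)) || any(parts <= 0)) {
    abort(glue::glue("cannot parse mixture ratio '{d$ratio[1]}'."),
          class = "synerkin_input_error")
  }
  ratio_fraction(parts, stock_conc)
}

#' Combination index of fixed-ratio two-agent mixtures
#'
#' Implements the Chou-Talalay fixed-ratio isobolographic analysis. Each
#' mixture ratio is fitted with its own median-effect model on *total* dose;
#' the total dose achieving effect `x` is split into component doses by the
#' ratio, and the combination index at `x` is
#' `CI = d1/Dx1 + d2/Dx2`, where `Dx_i` is the dose of agent `i` alone
#' producing effect `x` from its single-agent fit. Dose-reduction indices
#' are `DRI_i = Dx_i / d_i`, so `CI = 1/DRI1 + 1/DRI2` identically. CI < 1
#' indicates synergy, CI = 1 Loewe additivity, CI > 1 antagonism.
#'
#' @param mixture tibble of mixture measurements: `ratio`, `total_dose_mM`,
#'   `fa`, optionally `d1_mM`/`d2_mM` and `replicate`.
#' @param single1,single2 single-agent dose-effect tibbles (`dose_mM`, `fa`)
#'   or fitted [fit_median_effect()] objects.
#' @param x effect level(s) at which to evaluate CI (default 0.5, the
#'   IC50/AC50 level).
#' @param stock_conc two stock concentrations used to convert a ratio label
#'   into dose fractions when component doses are not recorded.
#' @param B bootstrap resamples for the CI SD (0 = none); requires raw
#'   tibbles with >= 2 replicates per dose, see [ci_bootstrap()].
#' @param seed optional integer seed for the bootstrap.
#' @param fa_bounds clipping bounds for all median-effect fits.
#' @return a `combo_result` tibble: one row per (ratio, x) with component
#'   doses `d1_mM`, `d2_mM`, single-agent equipotent doses `Dx1_mM`,
#'   `Dx2_mM`, `ci`, `ci_sd`, `dri1`, `dri2`, normalized isobologram
#'   coordinates `d1_norm`, `d2_norm` and the interaction `label`. Supports
#'   [autoplot()] (normalized isobologram) and [glance()].
#' @examples
#' sim <- simulate_mixture_series(mixture_truth(Dm1 = 0.1, Dm2 = 0.69))
#' combination_index(sim$mixtures,
#'                   dplyr::filter(sim$agents, agent == 1),
#'                   dplyr::filter(sim$agents, agent == 2))
#' @export
combination_index <- function(mixture, single1, single2, x = 0.5,
                              stock_conc = c(1, 1), B = 0, seed = NULL,
                              fa_bounds = c(0.01, 0.99)) {
  check_columns(mixture, c("ratio", "total_dose_mM", "fa"), "mixture series")
  check_fraction(x, "x")
  fit1 <- as_medfx_fit(single1, "single1")
  fit2 <- as_medfx_fit(single2, "single2")
  if (!fit1$valid || !fit2$valid) {
    abort("single-agent median-effect fit is invalid (non-positive slope).",
          class = "synerkin_fit_error")
  }

  res <- mixture |>
    group_by(ratio = .data$ratio) |>
    dplyr::group_modify(function(d, key) {
      p1 <- mixture_p1(d, stock_conc)
      mixfit <- fit_median_effect(
        tibble(dose_mM = d$total_dose_mM, fa = d$fa), fa_bounds = fa_bounds)
      if (!mixfit$valid) {
        abort(glue::glue("mixture fit invalid at ratio {key$ratio}."),
              class = "synerkin_fit_error")
      }
      purrr::map(x, function(xx) {
        D <- medfx_dose(mixfit$Dm, mixfit$m, xx)
        d1 <- p1 * D
        d2 <- (1 - p1) * D
        Dx1 <- dose_at_effect(fit1, xx)
        Dx2 <- dose_at_effect(fit2, xx)
        ci <- d1 / Dx1 + d2 / Dx2
        tibble(x = xx, total_dose_mM = D, d1_mM = d1, d2_mM = d2,
               Dx1_mM = Dx1, Dx2_mM = Dx2, ci = ci,
               dri1 = Dx1 / d1, dri2 = Dx2 / d2,
               d1_norm = d1 / Dx1, d2_norm = d2 / Dx2)
      }) |> list_rbind()
    }) |>
    ungroup() |>
    mutate(label = classify_interaction(.data$ci), ci_sd = NA_real_)

  if (B > 0) {
    sds <- ci_bootstrap(mixture, single1, single2, x = x, B = B, seed = seed,
                        stock_conc = stock_conc, fa_bounds = fa_bounds)
    res <- res |>
      select(-"ci_sd") |>
      left_join(sds, by = c("ratio", "x"))
  }
  class(res) <- c("combo_result", class(res))
  res
}

#' Bootstrap standard deviation of the combination index
#'
#' Resamples replicate measurements within each dose of the two single-agent
#' series and of each mixture ratio, recomputes the combination index on
#' every resample, and returns the SD per (ratio, x).
#'
#' @inheritParams combination_index
#' @param B number of bootstrap resamples (a warning is issued below 50).
#' @return tibble `ratio`, `x`, `ci_sd`.
#' @export
ci_bootstrap <- function(mixture, single1, single2, x = 0.5, B = 1000,
                         seed = NULL, stock_conc = c(1, 1),
                         fa_bounds = c(0.01, 0.99)) {
  if (!is.data.frame(single1) || !is.data.frame(single2)) {
    abort("bootstrap needs replicate-level single-agent tibbles, not fits.",
          class = "synerkin_input_error")
  }
  if (B < 50) warn("fewer than 50 bootstrap resamples; SD will be unstable.")
  min_rep <- min(dplyr::count(single1, .data$dose_mM)$n,
                 dplyr::count(single2, .data$dose_mM)$n,
                 dplyr::count(mixture, .data$ratio, .data$total_dose_mM)$n)
  if (min_rep < 2) {
    abort("bootstrap unavailable with a single replicate per dose.",
          class = "synerkin_input_error")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  draws <- purrr::map(seq_len(B), function(b) {
    m_b <- mixture |>
      group_by(.data$ratio, .data$total_dose_mM) |>
      dplyr::slice_sample(prop = 1, replace = TRUE) |>
      ungroup()
    out <- tryCatch(
      suppressWarnings(combination_index(
        m_b, resample_within_dose(single1), resample_within_dose(single2),
        x = x, stock_conc = stock_conc, B = 0, fa_bounds = fa_bounds)),
      error = function(e) NULL)
    if (is.null(out)) NULL else select(out, "ratio", "x", "ci")
  }) |> list_rbind()
  draws |>
    group_by(.data$ratio, .data$x) |>
    summarise(ci_sd = sd(.data$ci), .groups = "drop")
}

#' Normalized isobologram coordinates
#'
#' Extracts the dose-normalized coordinates `(d1/Dx1, d2/Dx2)` from a
#' [combination_index()] result. Points on the unit anti-diagonal
#' `u + v = 1` are additive; points below it correspond to CI < 1
#' (synergy), above it to CI > 1 (antagonism).
#'
#' @param results a `combo_result` tibble.
#' @return tibble `ratio`, `x`, `d1_norm`, `d2_norm`, `ci`, `label`.
#' @export
isobologram_points <- function(results) {
  check_columns(results, c("ratio", "x", "d1_norm", "d2_norm", "ci", "label"),
                "combination results")
  if (!nrow(results)) abort("empty combination results.",
                            class = "synerkin_input_error")
  select(as_tibble(results), "ratio", "x", "d1_norm", "d2_norm", "ci", "label")
}
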