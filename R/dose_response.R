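#' Convert rates (or endpoint absorbances) to effect fractions
#'
#' Builds the dose-effect series consumed by [fit_median_effect()] and
#' [estimate_ec50()]. The conversion depends on the assay role:
#' \describe{
#'   \item{inhibition}{`fa = 1 - v / v0`, with `v0` the control rate.}
#'   \item{scavenging}{`fa = (A_blank - A) / A_blank`; pass the endpoint
#'     absorbance in the `rate` column and the blank as the control, the
#'     arithmetic is identical to inhibition.}
#'   \item{activation}{`activation_pct = 100 * (v / v0 - 1)`; the fraction
#'     used for median-effect arithmetic is `activation_pct / plateau_pct`,
#'     with the plateau taken from a hyperbolic fit of activation percent
#'     versus dose ([fit_activation_curve()]) unless supplied.}
#' }
#' Control rows (dose 0) supply `v0` when `control_rate` is not given and are
#' dropped from the output.
#'
#' @param rates tibble with `dose_mM`, `rate` and optionally `replicate`.
#' @param role `"inhibition"`, `"scavenging"` or `"activation"`.
#' @param control_rate control (or blank) signal; default: mean of dose-0
#'   rows.
#' @param plateau activation plateau in percent; default: fitted.
#' @param fa_bounds clipping bounds used by the downstream fit; if more than
#'   half the points fall outside them the series is rejected as
#'   low-quality.
#' @return tibble `dose_mM`, `replicate`, `fa` (plus `activation_pct` for
#'   activation), with the control rate and plateau as attributes.
#' @examples
#' d <- tibble::tibble(dose_mM = c(0, 1, 2), rate = c(100, 50, 25))
#' effect_fraction(d, "inhibition")
#' @export
effect_fraction <- function(rates, role = c("inhibition", "scavenging",
                                            "activation"),
                            control_rate = NULL, plateau = NULL,
                            fa_bounds = c(0.01, 0.99)) {
  role <- match.arg(role)
  check_columns(rates, c("dose_mM", "rate"), "rate table")
  if (!"replicate" %in% names(rates)) rates$replicate <- 1L
  if (is.null(control_rate)) {
    ctrl <- rates$rate[rates$dose_mM == 0]
    if (!length(ctrl)) {
      abort("no dose-0 control rows and no `control_rate` given.",
            class = "synerkin_input_error")
    }
    control_rate <- mean(ctrl)
  }
  if (control_rate <= 0) {
    abort("control rate must be > 0.", class = "synerkin_input_error")
  }
  out <- rates |>
    filter(.data$dose_mM > 0) |>
    select("dose_mM", "replicate", "rate")

  if (role %in% c("inhibition", "scavenging")) {
    out <- mutate(out, fa = 1 - .data$rate / control_rate)
  } else {
    out <- mutate(out, activation_pct = 100 * (.data$rate / control_rate - 1))
    if (is.null(plateau)) {
      plateau <- fit_activation_curve(out)$plateau
    }
    check_number(plateau, "plateau", positive = TRUE)
    out <- mutate(out, fa = .data$activation_pct / plateau)
  }
  frac_out <- mean(out$fa < fa_bounds[1] | out$fa > fa_bounds[2])
  if (frac_out > 0.5) {
    abort(glue::glue("{round(100 * frac_out)}% of effect fractions fall ",
                     "outside ({fa_bounds[1]}, {fa_bounds[2]}); ",
                     "the dose range does not bracket the median effect."),
          class = "synerkin_data_quality_error")
  }
  out <- select(out, -"rate")
  attr(out, "control_rate") <- control_rate
  if (role == "activation") attr(out, "plateau") <- plateau
  attr(out, "role") <- role
  out
}

#' Fit the median-effect dose-response model
#'
#' Chou's median-effect law `fa / (1 - fa) = (D / Dm)^m` is fitted by OLS of
#' `log10(fa / (1 - fa))` on `log10(D)`: the slope is the sigmoidicity `m`
#' and `Dm = 10^(-intercept / m)` is the median-effect dose. Effect fractions
#' at exactly 0 or 1 are excluded with a warning; remaining values are
#' clipped into `fa_bounds` before the logit transform (clipping is a no-op
#' when all values already lie inside).
#'
#' @param data tibble with `dose_mM` (> 0) and `fa`.
#' @param fa_bounds clipping bounds on the effect fraction
#'   (default 0.01-0.99).
#' @return an object of class `medfx_fit`: `Dm` (mM), `m`, the linear
#'   correlation `r` of the transformed fit, the coefficient covariance, and
#'   `valid` (`FALSE` when the fitted slope is not positive). Supports
#'   [tidy()], [glance()], [dose_at_effect()], [effect_at_dose()] and
#'   [autoplot()].
#' @examples
#' d <- tibble::tibble(dose_mM = c(0.1, 0.2, 0.4, 0.8),
#'                     fa = c(0.2, 0.35, 0.55, 0.75))
#' fit_median_effect(d)
#' @export
fit_median_effect <- function(data, fa_bounds = c(0.01, 0.99)) {
  check_columns(data, c("dose_mM", "fa"), "dose-effect series")
  if (any(data$dose_mM <= 0)) {
    abort("doses must be strictly positive.", class = "synerkin_input_error")
  }
  drop <- data$fa <= 0 | data$fa >= 1
  if (any(drop)) {
    warn(glue::glue("{sum(drop)} point(s) with fa at or beyond 0/1 excluded."))
    data <- data[!drop, ]
  }
  if (dplyr::n_distinct(data$dose_mM) < 3) {
    abort("need >= 3 usable doses for the median-effect fit.",
          class = "synerkin_fit_error")
  }
  fa <- pmin(pmax(data$fa, fa_bounds[1]), fa_bounds[2])
  x <- log10(data$dose_mM)
  y <- log10(fa / (1 - fa))
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2])
  Dm <- 10^(-unname(coef(fit)[1]) / m)
  r <- suppressWarnings(stats::cor(x, y))
  if (!is.finite(r)) r <- 1  # exactly collinear replicates
  valid <- is.finite(m) && m > 0
  if (!valid) warn("fitted sigmoidicity m is not positive; fit flagged invalid.")
  vc <- suppressWarnings(vcov(fit))  # zero-residual fits warn in summary.lm
  structure(list(Dm = Dm, m = m, r = r, vcov = vc,
                 n = nrow(data), n_doses = dplyr::n_distinct(data$dose_mM),
                 valid = valid, fit = fit, data = data),
            class = "medfx_fit")
}

#' @export
print.medfx_fit <- function(x, ...) {
  cat(sprintf("Median-effect fit: Dm = %.4g mM, m = %.4g (r = %.4f, n = %d)%s\n",
              x$Dm, x$m, x$r, x$n, if (x$valid) "" else " [INVALID]"))
  invisible(x)
}

#' Dose producing a given effect level
#'
#' Inverts the median-effect law: `Dx = Dm * (x / (1 - x))^(1/m)`. At
#' `x = 0.5` this is `Dm` identically, for any sigmoidicity.
#'
#' @param fit a [fit_median_effect()] object.
#' @param x effect fraction(s), strictly inside (0, 1).
#' @return dose(s) in mM.
#' @examples
#' f <- fit_median_effect(tibble::tibble(dose_mM = c(0.05, 0.1, 0.2, 0.4),
#'                                       fa = c(1/3, 0.5, 2/3, 0.8)))
#' dose_at_effect(f, 0.5)
#' @export
dose_at_effect <- function(fit, x) {
  stopifnot(inherits(fit, "medfx_fit"))
  check_fraction(x, "x")
  medfx_dose(fit$Dm, fit$m, x)
}

#' Effect fraction at a given dose
#'
#' Forward median-effect law: `fa = 1 / (1 + (Dm / D)^m)`. Inverse of
#' [dose_at_effect()].
#'
#' @param fit a [fit_median_effect()] object.
#' @param dose dose(s) in mM, > 0.
#' @return effect fraction(s) in (0, 1).
#' @export
effect_at_dose <- function(fit, dose) {
  stopifnot(inherits(fit, "medfx_fit"))
  if (any(dose <= 0)) abort("doses must be > 0.", class = "synerkin_input_error")
  1 / (1 + (fit$Dm / dose)^fit$m)
}

#' Fit the hyperbolic dose-activation curve
#'
#' Fits `activation_pct = plateau * D / (Ka + D)` (the dose-response of a
#' nonessential activator that multiplies Vmax hyperbolically) by nonlinear
#' least squares. The operational AC50 — the dose at which activation
#' reaches 50% of the *control* rate, i.e. `activation_pct = 50` — is
#' `Ka * 50 / (plateau - 50)`, defined only when the plateau exceeds 50%.
#'
#' @param data tibble with `dose_mM` and `activation_pct`.
#' @param restarts jittered restarts on fit failure.
#' @return object of class `act_fit` with `plateau` (%), `Ka` (mM), `ac50`
#'   (mM, `NA` with a warning if the plateau is below 50%), and the
#'   underlying fit. Supports [predict()], [tidy()] and [glance()].
#' @examples
#' d <- tibble::tibble(dose_mM = c(0.05, 0.1, 0.2, 0.5, 1),
#'                     activation_pct = 110 * d$dose_mM / (0.12 + d$dose_mM))
#' fit_activation_curve(d)
#' @export
fit_activation_curve <- function(data, restarts = 5) {
  check_columns(data, c("dose_mM", "activation_pct"), "activation series")
  d <- filter(data, .data$dose_mM > 0)
  if (dplyr::n_distinct(d$dose_mM) < 3) {
    abort("need >= 3 nonzero doses for the activation-curve fit.",
          class = "synerkin_fit_error")
  }
  start <- list(plateau = max(d$activation_pct) * 1.2,
                Ka = median(unique(d$dose_mM)))
  fit <- fit_nls(activation_pct ~ plateau * dose_mM / (Ka + dose_mM),
                 d, start, restarts = restarts)
  if (is.null(fit)) {
    abort("activation-curve fit failed to converge.",
          class = "synerkin_fit_error")
  }
  est <- coef(fit)
  plateau <- unname(est["plateau"])
  Ka <- unname(est["Ka"])
  ac50 <- if (plateau > 50) Ka * 50 / (plateau - 50) else {
    warn("activation plateau below 50%; AC50 undefined for this curve.")
    NA_real_
  }
  structure(list(plateau = plateau, Ka = Ka, ac50 = ac50,
                 sigma = summary(fit)$sigma, n = nrow(d), fit = fit, data = d),
            class = "act_fit")
}

#' @export
print.act_fit <- function(x, ...) {
  cat(sprintf(
    "Dose-activation fit: plateau = %.4g%%, Ka = %.4g mM, AC50 = %.4g mM\n",
    x$plateau, x$Ka, x$ac50))
  invisible(x)
}

#' @export
predict.act_fit <- function(object, dose_mM, ...) {
  object$plateau * dose_mM / (object$Ka + dose_mM)
}

# resample replicate rows within each dose (nonparametric bootstrap unit)
resample_within_dose <- function(data) {
  data |>
    group_by(.data$dose_mM) |>
    dplyr::slice_sample(prop = 1, replace = TRUE) |>
    ungroup()
}

#' Estimate the half-effect concentration (IC50 / AC50 / EC50)
#'
#' For inhibition and scavenging the estimate is the median-effect dose `Dm`
#' of [fit_median_effect()] (`fa = 0.5` is 50% inhibition by definition).
#' For activation it is the operational AC50 of [fit_activation_curve()]:
#' the dose whose fitted activation percent equals 50. Uncertainty is a
#' nonparametric bootstrap SD, resampling replicates within dose.
#'
#' @param data for inhibition/scavenging: a series from [effect_fraction()]
#'   (`dose_mM`, `fa`); for activation: `dose_mM`, `activation_pct`.
#' @param role assay role, as in [effect_fraction()].
#' @param B bootstrap resamples (default 1000; 0 skips the bootstrap).
#' @param seed optional integer seed for the bootstrap.
#' @param fa_bounds clipping bounds passed to the median-effect fit.
#' @return one-row tibble: `role`, `ec50_mM`, `ec50_sd`, `Dm`, `m` (NA for
#'   activation), `n`, `B`.
#' @examples
#' d <- tibble::tibble(dose_mM = rep(c(0.05, 0.1, 0.2, 0.4), each = 3),
#'                     replicate = rep(1:3, 4),
#'                     fa = rep(c(1/3, 0.5, 2/3, 0.8), each = 3))
#' estimate_ec50(d, "inhibition", B = 100, seed = 1)
#' @export
estimate_ec50 <- function(data, role = c("inhibition", "scavenging",
                                         "activation"),
                          B = 1000, seed = NULL, fa_bounds = c(0.01, 0.99)) {
  role <- match.arg(role)
  point <- function(d) {
    if (role == "activation") fit_activation_curve(d)$ac50
    else fit_median_effect(d, fa_bounds = fa_bounds)$Dm
  }
  est <- point(data)
  fitpars <- if (role == "activation") c(NA_real_, NA_real_) else {
    f <- fit_median_effect(data, fa_bounds = fa_bounds)
    c(f$Dm, f$m)
  }
  sd_boot <- NA_real_
  if (B > 0) {
    if (min(dplyr::count(data, .data$dose_mM)$n) < 2) {
      warn("single measurement per dose; bootstrap SD unavailable.")
    } else {
      if (!is.null(seed)) withr::local_seed(seed)
      boots <- purrr::map_dbl(seq_len(B), function(i) {
        tryCatch(suppressWarnings(point(resample_within_dose(data))),
                 error = function(e) NA_real_)
      })
      sd_boot <- sd(boots, na.rm = TRUE)
    }
  }
  tibble(role = role, ec50_mM = est, ec50_sd = sd_boot,
         Dm = fitpars[1], m = fitpars[2], n = nrow(data), B = B)
}
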