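# broom-style tidiers for the fitted-object classes

#' @describeIn fit_michaelis_menten one row per parameter (estimate, SE).
#' @param x,object fitted object.
#' @param ... unused.
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(term = c("Km", "Vmax"),
         estimate = c(x$Km, x$Vmax),
         std.error = unname(x$se[c("Km", "Vmax")]))
}

#' @describeIn fit_michaelis_menten one-row model summary.
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(Km = x$Km, Vmax = x$Vmax, sigma = x$sigma, nobs = x$n)
}

#' @describeIn fit_median_effect one row per parameter.
#' @param x,object fitted object.
#' @param ... unused.
#' @export
tidy.medfx_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble(term = c("m", "Dm"),
         estimate = c(x$m, x$Dm),
         # Dm SE by the delta method on (intercept, slope)
         std.error = c(se[2], medfx_dm_se(x)))
}

medfx_dm_se <- function(x) {
  b0 <- unname(coef(x$fit)[1]); b1 <- unname(coef(x$fit)[2])
  # Dm = 10^(-b0/b1); gradient wrt (b0, b1)
  g <- x$Dm * log(10) * c(-1 / b1, b0 / b1^2)
  sqrt(drop(t(g) %*% x$vcov %*% g))
}

#' @describeIn fit_median_effect one-row summary (Dm, m, r, validity).
#' @export
glance.medfx_fit <- function(x, ...) {
  tibble(Dm = x$Dm, m = x$m, r = x$r, nobs = x$n, n_doses = x$n_doses,
         valid = x$valid)
}

#' @describeIn classify_mechanism per-dose apparent Km and Vmax.
#' @param x,object fitted object.
#' @param ... unused.
#' @export
tidy.mechanism_fit <- function(x, ...) {
  x$per_dose
}

#' @describeIn classify_mechanism one-row summary: label, shared parameters,
#'   effector constant(s).
#' @export
glance.mechanism_fit <- function(x, ...) {
  tibble(label = x$label, Km = x$Km, Vmax = x$Vmax,
         Ki = x$Ki %||% NA_real_,
         Ki_uncomp = x$Ki_uncomp %||% NA_real_,
         Ka = x$Ka %||% NA_real_,
         Emax = x$Emax %||% NA_real_,
         nobs = x$n)
}

#' @describeIn fit_activation_curve one row per parameter.
#' @param x,object fitted object.
#' @param ... unused.
#' @export
tidy.act_fit <- function(x, ...) {
  est <- coef(x$fit)
  se <- tryCatch(sqrt(diag(vcov(x$fit))),
                 error = function(e) rep(NA_real_, 2))
  tibble(term = names(est), estimate = unname(est), std.error = unname(se))
}

#' @describeIn fit_activation_curve one-row summary including the AC50.
#' @export
glance.act_fit <- function(x, ...) {
  tibble(plateau = x$plateau, Ka = x$Ka, ac50 = x$ac50, sigma = x$sigma,
         nobs = x$n)
}

#' @describeIn combination_index across-ratio summary per effect level:
#'   mean CI, its SD over ratios, and the label of the mean.
#' @param x a `combo_result` tibble.
#' @param ... unused.
#' @export
glance.combo_result <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$x) |>
    summarise(mean_ci = mean(.data$ci), sd_ci = sd(.data$ci),
              n_ratios = dplyr::n(), .groups = "drop") |>
    mutate(label = classify_interaction(.data$mean_ci))
}
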