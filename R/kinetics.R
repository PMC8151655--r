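# Levenberg-Marquardt NLS with jittered restarts; returns the converged fit
# with the lowest (weighted) RSS, or NULL if every attempt fails.
fit_nls <- function(formula, data, start, restarts = 5, jitter_sd = 0.3,
                    weights = NULL) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14, maxiter = 500)
  data$.w <- weights %||% rep(1, nrow(data))
  best <- NULL
  for (i in seq_len(restarts + 1)) {
    st <- if (i == 1) start else {
      purrr::map(start, ~ .x * exp(rnorm(1, 0, jitter_sd)))
    }
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(formula, data = data, start = st,
                                         weights = .w, control = ctrl)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(data$.w * resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      if (i == 1) break  # first attempt converged; restarts are a rescue only
    }
  }
  best$fit
}

# relative (1/y^2) weights matching multiplicative plate-reader noise; falls
# back to unit weight on non-positive signals
relative_weights <- function(rate) {
  w <- ifelse(rate > 0, 1 / rate^2, 1)
  w / mean(w)
}

mm_start <- function(substrate, rate) {
  Vmax0 <- max(rate)
  half <- Vmax0 / 2
  Km0 <- substrate[which.min(abs(rate - half))]
  list(Vmax = Vmax0, Km = max(Km0, 1e-8))
}

#' Fit the Michaelis-Menten rate law
#'
#' Nonlinear least-squares fit of `v = Vmax * S / (Km + S)` on untransformed
#' rates (Levenberg-Marquardt, jittered restarts on failure). Initial values
#' are `Vmax = max(rate)` and `Km =` the substrate concentration nearest the
#' half-maximal rate.
#'
#' @param data tibble with columns `substrate_mM` and `rate` (replicate rows
#'   allowed).
#' @param restarts additional jittered starts tried if the first fails.
#' @return an object of class `mm_fit` with elements `Km`, `Vmax`, standard
#'   errors, residual SD and the underlying `nls` fit. Supports [tidy()],
#'   [glance()], [predict()] and [autoplot()].
#' @examples
#' d <- simulate_kinetic_series(kinetic_truth(0.06, 120.5), doses = 0)
#' fit_michaelis_menten(d)
#' @export
fit_michaelis_menten <- function(data, restarts = 5) {
  check_columns(data, c("substrate_mM", "rate"), "kinetic data")
  if (dplyr::n_distinct(data$substrate_mM) < 4) {
    abort("need >= 4 distinct substrate concentrations.",
          class = "synerkin_input_error")
  }
  if (any(data$rate < 0)) {
    warn("negative rates present; check trace extraction.")
  }
  fit <- fit_nls(rate ~ Vmax * substrate_mM / (Km + substrate_mM),
                 data, mm_start(data$substrate_mM, data$rate),
                 restarts = restarts, weights = relative_weights(data$rate))
  if (is.null(fit)) {
    abort("Michaelis-Menten fit failed to converge after restarts.",
          class = "synerkin_fit_error")
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(Vmax = NA, Km = NA))
  structure(list(Km = unname(est["Km"]), Vmax = unname(est["Vmax"]),
                 se = se, sigma = summary(fit)$sigma,
                 n = nrow(data), fit = fit, data = data),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit:",
      sprintf("Km = %.4g mM, Vmax = %.4g dAU/min (n = %d, sigma = %.3g)\n",
              x$Km, x$Vmax, x$n, x$sigma))
  invisible(x)
}

#' @export
predict.mm_fit <- function(object, substrate_mM, ...) {
  object$Vmax * substrate_mM / (object$Km + substrate_mM)
}

#' Lineweaver-Burk (double-reciprocal) coordinates
#'
#' Transforms a kinetic series to `(1/S, 1/v)` and fits an OLS line per
#' effector dose: slope `Km_app/Vmax_app`, intercept `1/Vmax_app`. The
#' transform is for display and mechanism diagnostics only; parameters are
#' reported from the untransformed nonlinear fit. Zero rates are excluded
#' with a warning.
#'
#' @param data tibble with `substrate_mM`, `rate` and optionally `dose_mM`.
#' @return tibble of coordinates (`dose_mM`, `inv_substrate`, `inv_rate`)
#'   whose `"lines"` attribute holds the per-dose OLS slope and intercept.
#' @examples
#' d <- simulate_kinetic_series(kinetic_truth(0.06, 120.5), doses = 0)
#' lb <- lineweaver_burk(d)
#' attr(lb, "lines")
#' @export
lineweaver_burk <- function(data) {
  check_columns(data, c("substrate_mM", "rate"), "kinetic data")
  if (!"dose_mM" %in% names(data)) data$dose_mM <- 0
  if (any(data$substrate_mM <= 0)) {
    abort("substrate concentrations must be > 0.", class = "synerkin_input_error")
  }
  if (any(data$rate == 0)) {
    warn("zero rates excluded from the double-reciprocal transform.")
    data <- filter(data, .data$rate != 0)
  }
  coords <- data |>
    mutate(inv_substrate = 1 / .data$substrate_mM,
           inv_rate = 1 / .data$rate) |>
    select("dose_mM", "inv_substrate", "inv_rate")
  lines <- coords |>
    group_by(.data$dose_mM) |>
    summarise(slope = unname(coef(lm(inv_rate ~ inv_substrate))[2]),
              intercept = unname(coef(lm(inv_rate ~ inv_substrate))[1]),
              .groups = "drop")
  attr(coords, "lines") <- lines
  coords
}

# candidate mechanism models -------------------------------------------------
# Each model predicts rate from substrate S and effector dose I; constants are
# fitted on the log scale to keep them positive.

mech_models <- function() {
  list(
    none = list(
      n_par = 2,
      formula = rate ~ Vmax * substrate_mM / (Km + substrate_mM),
      start = function(s) s[c("Vmax", "Km")]
    ),
    competitive = list(
      n_par = 3,
      formula = rate ~ Vmax * substrate_mM /
        (Km * (1 + dose_mM / exp(lKi)) + substrate_mM),
      start = function(s) c(s[c("Vmax", "Km")], lKi = s$lKi_comp)
    ),
    uncompetitive = list(
      n_par = 3,
      formula = rate ~ Vmax * substrate_mM /
        (Km + substrate_mM * (1 + dose_mM / exp(lKi))),
      start = function(s) c(s[c("Vmax", "Km")], lKi = s$lKi_v)
    ),
    noncompetitive = list(
      n_par = 3,
      formula = rate ~ (Vmax / (1 + dose_mM / exp(lKi))) * substrate_mM /
        (Km + substrate_mM),
      start = function(s) c(s[c("Vmax", "Km")], lKi = s$lKi_v)
    ),
    mixed = list(
      n_par = 4,
      formula = rate ~ Vmax * substrate_mM /
        (Km * (1 + dose_mM / exp(lKic)) + substrate_mM * (1 + dose_mM / exp(lKiu))),
      start = function(s) c(s[c("Vmax", "Km")],
                            lKic = s$lKi_comp, lKiu = s$lKi_v)
    ),
    activation = list(
      n_par = 4,
      formula = rate ~ Vmax * (1 + exp(lEmax) * dose_mM / (exp(lKa) + dose_mM)) *
        substrate_mM / (Km + substrate_mM),
      start = function(s) c(s[c("Vmax", "Km")], lEmax = s$lEmax, lKa = s$lKa)
    )
  )
}

# data-driven starts shared across candidates, from the control MM fit and
# per-dose apparent parameters
mech_starts <- function(per_dose, doses) {
  ctrl <- per_dose[per_dose$dose_mM == 0, ]
  nz <- per_dose[per_dose$dose_mM > 0, ]
  med_dose <- median(doses[doses > 0])
  clamp <- function(x, lo = med_dose * 1e-3, hi = med_dose * 1e3) {
    x <- x[is.finite(x) & x > 0]
    if (!length(x)) med_dose else min(max(median(x), lo), hi)
  }
  # factor estimates: Vmax ratio senses uncompetitive/noncompetitive Ki,
  # Km ratio senses competitive Ki
  ki_v <- clamp(nz$dose_mM / (ctrl$Vmax_app / nz$Vmax_app - 1))
  ki_comp <- clamp(nz$dose_mM / (nz$Km_app / ctrl$Km_app - 1))
  emax <- max(max(nz$Vmax_app / ctrl$Vmax_app) - 1, 0.2)
  list(Vmax = ctrl$Vmax_app, Km = ctrl$Km_app,
       lKi_v = log(ki_v), lKi_comp = log(ki_comp),
       lEmax = log(emax), lKa = log(med_dose))
}

aicc <- function(rss, n, n_par, scale = 1) {
  # floor the RSS at numerical precision so exact (noise-free) fits compare
  # as ties and the fewer-parameter rule decides
  rss <- pmax(rss, n * (1e-8 * scale)^2)
  k <- n_par + 1  # + residual variance
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Classify the mechanism of an effector from multi-dose kinetic series
#'
#' Fits six candidate global models sharing `Km` and `Vmax` across doses —
#' no effect, competitive, uncompetitive and noncompetitive inhibition
#' (the `(1 + I/Ki)` rescalings of apparent Km and/or Vmax), mixed
#' inhibition, and hyperbolic activation of Vmax — and selects among them by
#' small-sample corrected AIC. Models within 2 AICc of the best are treated
#' as tied and the tie is broken toward the model with fewer parameters.
#' `"activation"` is called only when the activation model is selected *and*
#' the fitted rates at every nonzero dose exceed the fitted control rates
#' (the rate-increase criterion read off a Lineweaver-Burk plot where the
#' control line lies above all effector lines).
#'
#' @param data tibble with `substrate_mM`, `dose_mM`, `rate`; must contain a
#'   dose-0 control block and at least two nonzero doses, each with >= 4
#'   distinct substrate concentrations.
#' @param restarts jittered restarts per candidate fit (used on failure).
#' @return an object of class `mechanism_fit`: the selected `label`, shared
#'   `Km` and `Vmax`, the effector constant(s) (`Ki`, or `Ka` and `Emax` for
#'   activation), a per-dose table of apparent Km/Vmax from independent
#'   Michaelis-Menten fits, and the AICc score table. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' tr <- kinetic_truth(0.007, 1111, "uncompetitive", Ki = 0.009)
#' d <- simulate_kinetic_series(tr, doses = c(0.005, 0.01, 0.02))
#' classify_mechanism(d)
#' @export
classify_mechanism <- function(data, restarts = 3) {
  check_columns(data, c("substrate_mM", "dose_mM", "rate"), "kinetic series")
  doses <- sort(unique(data$dose_mM))
  if (!0 %in% doses) {
    abort("a dose-0 control block is required.", class = "synerkin_input_error")
  }
  if (sum(doses > 0) < 2) {
    abort("need at least 2 nonzero effector doses.",
          class = "synerkin_input_error")
  }

  # per-dose apparent parameters from independent MM fits
  per_dose <- data |>
    group_by(dose_mM = .data$dose_mM) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_michaelis_menten(d, restarts = restarts)
      tibble(Km_app = f$Km, Vmax_app = f$Vmax)
    }) |>
    ungroup()

  starts <- mech_starts(per_dose, doses)
  models <- mech_models()
  w <- relative_weights(data$rate)
  fits <- purrr::imap(models, function(m, nm) {
    fit_nls(m$formula, data, m$start(starts), restarts = restarts,
            weights = w)
  })

  scores <- purrr::imap(models, function(m, nm) {
    f <- fits[[nm]]
    tibble(model = nm, n_par = m$n_par,
           rss = if (is.null(f)) NA_real_ else sum(w * resid(f)^2))
  }) |>
    list_rbind() |>
    mutate(aicc = aicc(.data$rss, nrow(data), .data$n_par)) |>
    mutate(delta = .data$aicc - min(.data$aicc, na.rm = TRUE))

  ok <- scores[!is.na(scores$aicc), ]
  if (!nrow(ok)) abort("all candidate fits failed.", class = "synerkin_fit_error")
  tied <- ok[ok$delta < 2, ]
  label <- tied$model[order(tied$n_par, match(tied$model, names(models)))][1]

  # the activation call additionally requires fitted rates above control at
  # every dose; otherwise fall back to the best non-activation candidate
  if (label == "activation") {
    f <- fits$activation
    pred <- data |>
      mutate(.fit = fitted(f)) |>
      group_by(.data$dose_mM, .data$substrate_mM) |>
      summarise(.fit = mean(.data$.fit), .groups = "drop")
    ctrl <- filter(pred, .data$dose_mM == 0)
    above <- pred |>
      filter(.data$dose_mM > 0) |>
      left_join(ctrl, by = "substrate_mM", suffix = c("", "_ctrl")) |>
      summarise(all(.data$.fit > .data$.fit_ctrl)) |>
      pull()
    if (!above) {
      rest <- ok[ok$model != "activation", ]
      tied <- rest[rest$aicc - min(rest$aicc) < 2, ]
      label <- tied$model[order(tied$n_par, match(tied$model, names(models)))][1]
    }
  }

  sel <- fits[[label]]
  est <- coef(sel)
  pars <- list(Km = unname(est["Km"]), Vmax = unname(est["Vmax"]),
               Ki = NULL, Ki_uncomp = NULL, Ka = NULL, Emax = NULL)
  if (label %in% c("competitive", "uncompetitive", "noncompetitive")) {
    pars$Ki <- unname(exp(est["lKi"]))
  } else if (label == "mixed") {
    pars$Ki <- unname(exp(est["lKic"]))
    pars$Ki_uncomp <- unname(exp(est["lKiu"]))
  } else if (label == "activation") {
    pars$Ka <- unname(exp(est["lKa"]))
    pars$Emax <- unname(exp(est["lEmax"]))
  }

  structure(c(list(label = label), pars,
              list(per_dose = per_dose, scores = scores, fit = sel,
                   data = data, n = nrow(data))),
            class = "mechanism_fit")
}

#' @export
print.mechanism_fit <- function(x, ...) {
  cat(sprintf("Effector mechanism: %s\n", x$label))
  cat(sprintf("  shared Km = %.4g mM, Vmax = %.4g dAU/min\n", x$Km, x$Vmax))
  if (!is.null(x$Ki)) cat(sprintf("  Ki = %.4g mM\n", x$Ki))
  if (!is.null(x$Ki_uncomp)) cat(sprintf("  Ki (uncompetitive) = %.4g mM\n",
                                         x$Ki_uncomp))
  if (!is.null(x$Ka)) cat(sprintf("  Ka = %.4g mM, Emax = %.3g-fold\n",
                                  x$Ka, x$Emax))
  invisible(x)
}
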