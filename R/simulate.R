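#' Ground-truth description of an enzyme/effector kinetic system
#'
#' Bundles the Michaelis-Menten parameters of the uninhibited enzyme with the
#' effector mechanism and its constant, plus the noise model, for use with
#' [simulate_kinetic_series()]. Mechanisms follow the rapid-equilibrium forms:
#' competitive scales the apparent Km by `(1 + I/Ki)`, uncompetitive divides
#' both apparent Km and Vmax by `(1 + I/Ki)`, noncompetitive divides Vmax
#' only, mixed combines a competitive and an uncompetitive constant, and
#' activation multiplies Vmax by the hyperbolic factor
#' `1 + Emax * A / (Ka + A)` (nonessential activator).
#'
#' @param Km Michaelis constant of the substrate (mM), > 0.
#' @param Vmax maximal velocity (delta-AU/min), > 0.
#' @param mechanism one of `"none"`, `"competitive"`, `"uncompetitive"`,
#'   `"noncompetitive"`, `"mixed"`, `"activation"`.
#' @param Ki effector constant (mM); required for every mechanism but
#'   `"none"`. For `"mixed"` this is the competitive constant.
#' @param Ki_uncomp uncompetitive constant of the mixed mechanism (mM).
#' @param Emax dimensionless plateau fold-increase of Vmax (activation only).
#' @param noise_cv coefficient of variation of multiplicative rate noise.
#' @return a `kinetic_truth` object (a validated list).
#' @examples
#' kinetic_truth(Km = 0.06, Vmax = 120.5, mechanism = "none")
#' @export
kinetic_truth <- function(Km, Vmax, mechanism = "none", Ki = NULL,
                          Ki_uncomp = NULL, Emax = NULL, noise_cv = 0) {
  mechanism <- match.arg(mechanism, c("none", "competitive", "uncompetitive",
                                      "noncompetitive", "mixed", "activation"))
  check_number(Km, "Km", positive = TRUE)
  check_number(Vmax, "Vmax", positive = TRUE)
  check_number(noise_cv, "noise_cv", nonneg = TRUE)
  if (mechanism != "none") {
    if (is.null(Ki)) abort("`Ki` is required when mechanism != 'none'.",
                           class = "synerkin_input_error")
    check_number(Ki, "Ki", positive = TRUE)
  }
  if (mechanism == "mixed") {
    if (is.null(Ki_uncomp)) abort("`Ki_uncomp` is required for mechanism 'mixed'.",
                                  class = "synerkin_input_error")
    check_number(Ki_uncomp, "Ki_uncomp", positive = TRUE)
  }
  if (mechanism == "activation") {
    if (is.null(Emax)) abort("`Emax` is required for mechanism 'activation'.",
                             class = "synerkin_input_error")
    check_number(Emax, "Emax", positive = TRUE)
  }
  structure(list(Km = Km, Vmax = Vmax, mechanism = mechanism, Ki = Ki,
                 Ki_uncomp = Ki_uncomp, Emax = Emax, noise_cv = noise_cv),
            class = "kinetic_truth")
}

# noise-free model rate for a kinetic_truth at substrate S and effector dose I
kinetic_rate <- function(truth, S, I) {
  Km <- truth$Km
  Vmax <- truth$Vmax
  switch(truth$mechanism,
    none = Vmax * S / (Km + S),
    competitive = Vmax * S / (Km * (1 + I / truth$Ki) + S),
    uncompetitive = Vmax * S / (Km + S * (1 + I / truth$Ki)),
    noncompetitive = Vmax / (1 + I / truth$Ki) * S / (Km + S),
    mixed = Vmax * S / (Km * (1 + I / truth$Ki) + S * (1 + I / truth$Ki_uncomp)),
    activation = Vmax * (1 + truth$Emax * I / (truth$Ki + I)) * S / (Km + S)
  )
}

#' Simulate substrate-velocity grids at several effector doses
#'
#' Evaluates the mechanism model of a [kinetic_truth()] on a substrate grid at
#' each effector dose (dose 0 is the control and is always included), adds
#' multiplicative Gaussian noise of the stated CV, and returns the long tibble
#' consumed by [classify_mechanism()].
#'
#' @param truth a [kinetic_truth()].
#' @param doses effector doses in mM (>= 0); 0 is added if absent.
#' @param substrate substrate grid in mM; default 8 log-spaced points from
#'   0.2 Km to 20 Km.
#' @param replicates technical replicates per (substrate, dose) cell.
#' @param seed optional integer; makes the noise reproducible.
#' @return tibble with columns `substrate_mM`, `dose_mM`, `replicate`, `rate`.
#' @examples
#' tr <- kinetic_truth(0.06, 120.5, "none")
#' simulate_kinetic_series(tr, doses = 0)
#' @export
simulate_kinetic_series <- function(truth, doses,
                                    substrate = NULL,
                                    replicates = 3, seed = NULL) {
  stopifnot(inherits(truth, "kinetic_truth"))
  if (is.null(substrate)) {
    substrate <- exp(seq(log(0.2 * truth$Km), log(20 * truth$Km), length.out = 8))
  }
  if (length(substrate) == 0 || length(doses) == 0) {
    abort("substrate and dose grids must be non-empty.",
          class = "synerkin_input_error")
  }
  if (any(substrate <= 0)) {
    abort("substrate concentrations must be > 0.", class = "synerkin_input_error")
  }
  if (any(doses < 0)) {
    abort("effector doses must be >= 0.", class = "synerkin_input_error")
  }
  doses <- sort(unique(c(0, doses)))
  check_number(replicates, "replicates", positive = TRUE)
  if (!is.null(seed)) withr::local_seed(seed)

  grid <- tidyr::expand_grid(dose_mM = doses, substrate_mM = substrate,
                             replicate = seq_len(replicates))
  model <- kinetic_rate(truth, grid$substrate_mM, grid$dose_mM)
  grid$rate <- model * cv_noise(nrow(grid), truth$noise_cv)
  arrange(grid[, c("substrate_mM", "dose_mM", "replicate", "rate")],
          .data$dose_mM, .data$substrate_mM, .data$replicate)
}

#' Ground-truth description of a two-agent fixed-ratio mixture system
#'
#' Each agent follows the median-effect law `fa/(1-fa) = (D/Dm)^m`; the
#' mixture is constructed so that at every generated effect level the
#' component doses satisfy `d1/Dx1 + d2/Dx2 = psi`. `psi = 1` is Loewe
#' additivity, `psi < 1` synergy, `psi > 1` antagonism, and `psi` is exactly
#' the combination index the downstream analysis should recover.
#'
#' @param Dm1,Dm2 median-effect doses of the two agents (mM).
#' @param m1,m2 sigmoidicity exponents (dimensionless).
#' @param psi Loewe interaction index (> 0).
#' @param ratios list of length-2 positive numeric vectors of volume ratios;
#'   defaults to 1:4, 4:1, 3:2, 2:3 and 1:1.
#' @param stock_conc length-2 stock concentrations (mM) used to convert
#'   volume ratios into dose fractions; equal stocks (the default) make a
#'   3:2 volume ratio a 0.6/0.4 dose split.
#' @param noise_cv coefficient of variation of multiplicative noise applied
#'   to the surviving-activity fraction `1 - fa`.
#' @return a `mixture_truth` object.
#' @examples
#' mixture_truth(Dm1 = 0.10, Dm2 = 0.69, psi = 1)
#' @export
mixture_truth <- function(Dm1, Dm2, m1 = 1, m2 = 1, psi = 1,
                          ratios = list(c(1, 4), c(4, 1), c(3, 2),
                                        c(2, 3), c(1, 1)),
                          stock_conc = c(1, 1), noise_cv = 0) {
  for (nm in c("Dm1", "Dm2", "m1", "m2", "psi")) {
    check_number(get(nm), nm, positive = TRUE)
  }
  check_number(noise_cv, "noise_cv", nonneg = TRUE)
  if (!length(ratios)) abort("`ratios` must be non-empty.",
                             class = "synerkin_input_error")
  ok <- vapply(ratios, function(r) length(r) == 2 && all(r > 0), logical(1))
  if (!all(ok)) abort("each ratio must be a pair of positive numbers.",
                      class = "synerkin_input_error")
  if (length(stock_conc) != 2 || any(stock_conc <= 0)) {
    abort("`stock_conc` must be two positive concentrations.",
          class = "synerkin_input_error")
  }
  structure(list(Dm1 = Dm1, Dm2 = Dm2, m1 = m1, m2 = m2, psi = psi,
                 ratios = ratios, stock_conc = stock_conc,
                 noise_cv = noise_cv),
            class = "mixture_truth")
}

# dose of a single median-effect agent producing effect x
medfx_dose <- function(Dm, m, x) Dm * (x / (1 - x))^(1 / m)

# dose fraction of agent 1 for a volume ratio under the stock convention
ratio_fraction <- function(ratio, stock_conc) {
  w <- ratio * stock_conc
  w[1] / sum(w)
}

ratio_label <- function(ratio) paste(ratio[1], ratio[2], sep = ":")

# perturb an effect fraction with multiplicative noise on surviving activity
noisy_fa <- function(fa, cv) {
  out <- 1 - (1 - fa) * cv_noise(length(fa), cv)
  pmin(pmax(out, 1e-6), 1 - 1e-6)
}

#' Simulate single-agent and fixed-ratio mixture dose-effect series
#'
#' For each target effect level the single-agent doses are the exact
#' median-effect doses `Dx`, and the total mixture dose at each volume ratio
#' is chosen so that the component doses satisfy `d1/Dx1 + d2/Dx2 = psi`.
#' Noise-free output therefore recovers `CI = psi` at every ratio and effect
#' level by construction.
#'
#' @param truth a [mixture_truth()].
#' @param effects target effect fractions, strictly inside (0, 1).
#' @param replicates replicate measurements per dose.
#' @param seed optional integer for reproducible noise.
#' @return list with `agents` (tibble: `agent`, `dose_mM`, `replicate`, `fa`)
#'   and `mixtures` (tibble: `ratio`, `total_dose_mM`, `d1_mM`, `d2_mM`,
#'   `replicate`, `fa`).
#' @examples
#' tr <- mixture_truth(Dm1 = 0.10, Dm2 = 0.69, psi = 1)
#' sim <- simulate_mixture_series(tr)
#' head(sim$mixtures)
#' @export
simulate_mixture_series <- function(truth,
                                    effects = seq(0.15, 0.85, by = 0.1),
                                    replicates = 3, seed = NULL) {
  stopifnot(inherits(truth, "mixture_truth"))
  check_fraction(effects, "effects")
  check_number(replicates, "replicates", positive = TRUE)
  if (!is.null(seed)) withr::local_seed(seed)

  singles <- purrr::map(1:2, function(i) {
    Dm <- if (i == 1) truth$Dm1 else truth$Dm2
    m <- if (i == 1) truth$m1 else truth$m2
    tidyr::expand_grid(effect = effects, replicate = seq_len(replicates)) |>
      mutate(agent = i,
             dose_mM = medfx_dose(Dm, m, .data$effect),
             fa = noisy_fa(.data$effect, truth$noise_cv)) |>
      select("agent", "dose_mM", "replicate", "fa")
  }) |> list_rbind()

  mixtures <- purrr::map(truth$ratios, function(r) {
    p1 <- ratio_fraction(r, truth$stock_conc)
    tidyr::expand_grid(effect = effects, replicate = seq_len(replicates)) |>
      mutate(
        Dx1 = medfx_dose(truth$Dm1, truth$m1, .data$effect),
        Dx2 = medfx_dose(truth$Dm2, truth$m2, .data$effect),
        total_dose_mM = truth$psi / (p1 / .data$Dx1 + (1 - p1) / .data$Dx2),
        d1_mM = p1 * .data$total_dose_mM,
        d2_mM = (1 - p1) * .data$total_dose_mM,
        ratio = ratio_label(r),
        fa = noisy_fa(.data$effect, truth$noise_cv)
      ) |>
      select("ratio", "total_dose_mM", "d1_mM", "d2_mM", "replicate", "fa")
  }) |> list_rbind()

  list(agents = singles, mixtures = mixtures)
}

#' Simulate linear plate-reader kinetic traces
#'
#' Builds absorbance-versus-time traces with a fixed slope (one well per
#' requested rate), optionally adding Gaussian read noise. A noise-free trace
#' is exactly linear: `A(t) = baseline + rate * t`.
#'
#' @param rates slope(s) in delta-AU/min, one trace per element.
#' @param duration_min total read time in minutes (>= 2 intervals).
#' @param interval_min time between reads in minutes (> 0).
#' @param baseline_AU absorbance at time 0.
#' @param noise_sd standard deviation of additive read noise (AU).
#' @param wavelength_nm recorded wavelength (470 for the peroxidase guaiacol
#'   assay, 234 for the lipoxygenase conjugated-diene assay).
#' @param seed optional integer for reproducible noise.
#' @return tibble in the trace schema of [read_traces()].
#' @examples
#' simulate_plate_traces(0.05, duration_min = 3)
#' @export
simulate_plate_traces <- function(rates, duration_min = 3, interval_min = 1,
                                  baseline_AU = 0.1, noise_sd = 0,
                                  wavelength_nm = 470, seed = NULL) {
  check_number(interval_min, "interval_min", positive = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  if (duration_min < 2 * interval_min) {
    abort("`duration_min` must cover at least 2 intervals.",
          class = "synerkin_input_error")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  times <- seq(0, duration_min, by = interval_min)
  purrr::imap(rates, function(r, i) {
    tibble(well_id = sprintf("W%02d", i),
           time_min = times,
           absorbance = baseline_AU + r * times +
             rnorm(length(times), 0, noise_sd),
           wavelength_nm = wavelength_nm)
  }) |> list_rbind()
}
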