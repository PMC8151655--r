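#' Read plate-reader kinetic traces from CSV
#'
#' Reads the long trace format: one row per absorbance read, with mandatory
#' columns `well_id`, `time_min`, `absorbance`, `wavelength_nm` and any
#' annotation columns (`compound`, `dose_mM`, `compound2`, `dose2_mM`,
#' `substrate_mM`, `ratio`, `replicate`, ...). Rows are sorted by time within
#' each well; duplicate (well, wavelength, time) reads are an error.
#'
#' @param path CSV file path (comma-separated, header row, dot decimal).
#' @return tibble of traces sorted by well and time.
#' @export
read_traces <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_traces(df, what = basename(path))
}

validate_traces <- function(df, what = "traces") {
  check_columns(df, c("well_id", "time_min", "absorbance", "wavelength_nm"),
                what = what)
  for (col in c("time_min", "absorbance", "wavelength_nm")) {
    vals <- df[[col]]
    if (!is.numeric(vals)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(vals)))))
      abort(glue::glue("{what}: non-numeric `{col}` at row(s) ",
                       "{paste(utils::head(bad, 5), collapse = ', ')}."),
            class = "synerkin_parse_error")
    }
  }
  key <- paste(df$well_id, df$wavelength_nm, df$time_min)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(glue::glue("{what}: duplicate (well, wavelength, time) read: {dup}."),
          class = "synerkin_parse_error")
  }
  arrange(as_tibble(df), .data$well_id, .data$wavelength_nm, .data$time_min)
}

#' Write traces (or any tidy table) to CSV
#'
#' @param x tibble to write.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Extract initial rates from kinetic traces
#'
#' Fits an ordinary-least-squares line of absorbance versus time to each
#' (well, wavelength) trace — the per-minute change of absorption — and
#' returns one row per trace with the slope, intercept, fit R-squared and
#' point count. Traces with fewer than 3 reads are an error; traces whose
#' R-squared falls below `r2_threshold` are flagged (`qc_flag = TRUE`), not
#' dropped.
#'
#' @param traces tibble in the schema of [read_traces()].
#' @param window optional length-2 numeric: only reads with
#'   `window[1] <= time_min <= window[2]` enter the fit (default: all reads).
#' @param r2_threshold QC flag threshold on R-squared (default 0.90).
#' @return tibble with one row per trace: annotation columns plus `rate`
#'   (delta-AU/min), `intercept`, `r2`, `n_points`, `qc_flag`.
#' @examples
#' tr <- simulate_plate_traces(0.05)
#' initial_rates(tr)
#' @export
initial_rates <- function(traces, window = NULL, r2_threshold = 0.90) {
  validate_traces(traces)
  if (!is.null(window)) {
    traces <- filter(traces, .data$time_min >= window[1],
                     .data$time_min <= window[2])
  }
  ann_cols <- setdiff(names(traces), c("time_min", "absorbance"))
  traces |>
    group_by(.data$well_id, .data$wavelength_nm) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) {
        abort(glue::glue("trace has fewer than 3 time points ",
                         "(well {key$well_id})."),
              class = "synerkin_insufficient_data")
      }
      fit <- lm(absorbance ~ time_min, data = d)
      ss_tot <- sum((d$absorbance - mean(d$absorbance))^2)
      r2 <- if (ss_tot == 0) 1 else 1 - sum(resid(fit)^2) / ss_tot
      ann <- d[1, setdiff(ann_cols, c("well_id", "wavelength_nm")), drop = FALSE]
      bind_cols(ann, tibble(rate = unname(coef(fit)[2]),
                            intercept = unname(coef(fit)[1]),
                            r2 = r2, n_points = nrow(d)))
    }) |>
    ungroup() |>
    mutate(qc_flag = .data$r2 < r2_threshold)
}

#' Convert a 234 nm absorbance rate to lipoxygenase activity units
#'
#' One unit of lipoxygenase activity is an absorbance increase of 0.001 per
#' minute at 234 nm, so `units = rate / 0.001`.
#'
#' @param rate rate(s) in delta-AU/min.
#' @param wavelength_nm wavelength at which the rate was recorded; must be
#'   234 (recycled against `rate`).
#' @return activity in units/min.
#' @examples
#' lox_units(0.001) # 1 unit
#' @export
lox_units <- function(rate, wavelength_nm = 234) {
  if (any(wavelength_nm != 234)) {
    abort("lipoxygenase unit conversion is defined at 234 nm only.",
          class = "synerkin_unit_error")
  }
  rate / 0.001
}
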