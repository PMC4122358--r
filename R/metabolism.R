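# Closed-chamber respirometry: oxygen partial pressure and concentration,
# OLS depletion-slope estimation with quality control, mass-specific rate
# and the Boltzmann temperature correction of metabolic rate.

BOLTZMANN_EV_K <- 8.62e-5  # eV per kelvin

#' Oxygen partial pressure from atmospheric and vapor pressure
#'
#' `pO2 = (AP - SVP) * 0.2096`, with 0.2096 the O2 fraction in air, `AP`
#' the atmospheric pressure and `SVP` the saturated vapor pressure of
#' water at the measurement temperature (all kPa).
#'
#' @param ap Atmospheric pressure, kPa.
#' @param svp Saturated vapor pressure, kPa.
#' @return Partial pressure of O2, kPa.
#' @export
partial_pressure_o2 <- function(ap, svp) {
  stopifnot(all(svp >= 0))
  if (any(ap < svp)) {
    abort("Atmospheric pressure must exceed the saturated vapor pressure.",
          class = "introdelta_physical_error")
  }
  (ap - svp) * 0.2096
}

#' Dissolved oxygen concentration
#'
#' `[O2] = pO2 * alpha`, where `alpha` (mg O2 per litre per kPa) is the
#' oxygen solubility at the measurement temperature and salinity.
#'
#' @param po2 O2 partial pressure, kPa.
#' @param alpha Solubility, mg L^-1 kPa^-1.
#' @return Concentration, mg L^-1.
#' @export
oxygen_concentration <- function(po2, alpha) {
  stopifnot(all(po2 >= 0), all(alpha >= 0))
  po2 * alpha
}

#' Construct a respirometry trace
#'
#' A time series of oxygen readings from a closed, stirred chamber, plus
#' the chamber and water metadata needed to convert readings into a total
#' oxygen budget. Readings may be percent air saturation
#' (`reading_type = "percent_sat"`, converted via the saturation
#' concentration `pO2 * alpha`) or a direct concentration in mg per litre.
#'
#' @param time_h Timestamps in hours, strictly increasing, >= 10 points.
#' @param reading Oxygen readings.
#' @param volume_l Chamber volume, litres.
#' @param temp_c Water temperature, degrees Celsius.
#' @param mass_kg Animal mass, kg.
#' @param ap_kpa,svp_kpa Atmospheric and saturated vapor pressure, kPa.
#' @param alpha O2 solubility, mg L^-1 kPa^-1.
#' @param salinity Salinity, permille (metadata only).
#' @param reading_type `"percent_sat"` or `"mg_per_l"`.
#' @param species_id Optional label.
#' @return A `respirometry_trace` tibble (`time_h`, `reading`, `o2_ug`)
#'   with the metadata stored as attributes. `o2_ug` is the total chamber
#'   oxygen in micrograms.
#' @export
respirometry_trace <- function(time_h, reading, volume_l, temp_c, mass_kg,
                               ap_kpa = 101.325, svp_kpa = 2.34,
                               alpha = 0.4, salinity = 0,
                               reading_type = c("percent_sat", "mg_per_l"),
                               species_id = NA_character_) {
  reading_type <- arg_match(reading_type)
  if (length(time_h) < 10L) {
    abort("A respirometry trace needs at least 10 points.")
  }
  if (any(diff(time_h) <= 0)) {
    abort("Timestamps must be strictly increasing.")
  }
  stopifnot(volume_l > 0, mass_kg > 0, length(reading) == length(time_h))
  conc <- if (reading_type == "percent_sat") {
    sat <- oxygen_concentration(partial_pressure_o2(ap_kpa, svp_kpa), alpha)
    reading / 100 * sat
  } else {
    reading
  }
  out <- tibble(time_h = time_h, reading = reading,
                o2_ug = conc * volume_l * 1000)
  attr(out, "meta") <- list(
    volume_l = volume_l, temp_c = temp_c, mass_kg = mass_kg,
    ap_kpa = ap_kpa, svp_kpa = svp_kpa, alpha = alpha,
    salinity = salinity, reading_type = reading_type,
    species_id = species_id)
  class(out) <- c("respirometry_trace", class(out))
  out
}

#' Read a respirometry trace from TSV
#'
#' Two-column TSV (`time_h`, `reading`); chamber metadata supplied as
#' arguments or as a one-row metadata TSV with matching column names.
#'
#' @param path Trace TSV.
#' @param meta Named list (or path to a one-row TSV) of metadata passed to
#'   [respirometry_trace()].
#' @param ... Additional arguments overriding `meta`.
#' @return A `respirometry_trace`.
#' @export
read_trace <- function(path, meta = list(), ...) {
  tr <- readr::read_tsv(path, show_col_types = FALSE)
  if (is.character(meta)) {
    meta <- as.list(readr::read_tsv(meta, show_col_types = FALSE)[1, ])
  }
  meta <- utils::modifyList(meta, list(...))
  do.call(respirometry_trace,
          c(list(time_h = tr[[1]], reading = tr[[2]]), meta))
}

#' Oxygen consumption rate from a trace
#'
#' Ordinary least-squares slope of total chamber oxygen versus time,
#' negated, in micrograms O2 per hour. An initial fraction of the trace
#' (default 10%) is trimmed to let the electrode and the animal settle.
#' Quality control: the relative fall of oxygen content over the analysed
#' window must not exceed `max_fall` (default 20%), and the fitted slope
#' must be negative (consumption); violations flag the trace invalid.
#'
#' @param trace A [respirometry_trace()].
#' @param trim_frac Fraction of the trace duration discarded from the
#'   start before fitting.
#' @param max_fall Maximum allowed relative fall of oxygen content.
#' @return An `o2_fit` object; see [tidy.o2_fit()] / [glance.o2_fit()].
#'   Fields: `rate_ug_h`, `r_squared`, `fall_fraction`, `valid`,
#'   `n_points`, `mass_kg`, `mr0` (mass-specific rate, mg O2 kg^-1 h^-1).
#' @export
consumption_rate <- function(trace, trim_frac = 0.10, max_fall = 0.20) {
  stopifnot(inherits(trace, "respirometry_trace"),
            trim_frac >= 0, trim_frac < 1)
  meta <- attr(trace, "meta")
  t0 <- min(trace$time_h)
  span <- diff(range(trace$time_h))
  keep <- trace$time_h >= t0 + trim_frac * span
  d <- trace[keep, ]
  fit <- lm(o2_ug ~ time_h, data = d)
  slope <- unname(coef(fit)[2])
  fall <- (d$o2_ug[1] - d$o2_ug[nrow(d)]) / d$o2_ug[1]
  flags <- character()
  if (slope >= 0) flags <- c(flags, "non_negative_slope")
  if (fall > max_fall) flags <- c(flags, "excessive_fall")
  rate <- -slope
  structure(
    list(rate_ug_h = rate,
         r_squared = suppressWarnings(summary(fit)$r.squared),
         fall_fraction = fall,
         valid = length(flags) == 0L,
         flags = flags,
         n_points = nrow(d),
         mass_kg = meta$mass_kg,
         temp_c = meta$temp_c,
         species_id = meta$species_id,
         mr0 = mass_specific_rate(rate, meta$mass_kg),
         fit = fit),
    class = "o2_fit")
}

#' @export
print.o2_fit <- function(x, ...) {
  cat(sprintf("<o2_fit> %.3g ugO2/h (MR0 %.3g mgO2/kg/h), R^2 %.4f, fall %.1f%%%s\n",
              x$rate_ug_h, x$mr0, x$r_squared, 100 * x$fall_fraction,
              if (x$valid) "" else paste0(" [INVALID: ",
                                          paste(x$flags, collapse = ", "), "]")))
  invisible(x)
}

#' Mass-specific metabolic rate
#'
#' Converts a whole-animal consumption rate (micrograms O2 per hour) into a
#' mass-specific rate in mg O2 per kg per hour: `rate / 1000 / mass`.
#'
#' @param rate_ug_h Consumption rate, ug O2 h^-1.
#' @param mass_kg Animal mass, kg.
#' @return Rate in mg O2 kg^-1 h^-1.
#' @export
mass_specific_rate <- function(rate_ug_h, mass_kg) {
  stopifnot(all(mass_kg > 0))
  rate_ug_h / 1000 / mass_kg
}

#' Boltzmann temperature correction of metabolic rate
#'
#' `MR = MR0 * exp(E / (k * T))` with `T` in kelvin, activation energy `E`
#' (default 0.65 eV, the canonical value for metabolic processes) and
#' Boltzmann constant `k = 8.62e-5 eV K^-1`. The correction factor is
#' strictly decreasing in temperature, so rates measured at different
#' temperatures become comparable.
#'
#' @param mr0 Mass-specific rate at the measurement temperature,
#'   mg O2 kg^-1 h^-1 (> 0).
#' @param temp_c Measurement temperature, degrees Celsius (-2 to 45).
#' @param e_ev Activation energy, eV.
#' @param k_ev_k Boltzmann constant, eV K^-1.
#' @return Temperature-corrected rate `MR`.
#' @export
boltzmann_correct <- function(mr0, temp_c, e_ev = 0.65,
                              k_ev_k = BOLTZMANN_EV_K) {
  if (any(mr0 <= 0)) {
    abort("mr0 must be positive.", class = "introdelta_parameter_error")
  }
  stopifnot(all(temp_c >= -2), all(temp_c <= 45))
  mr0 * exp(e_ev / (k_ev_k * (temp_c + 273.15)))
}

#' Summarise metabolic-rate records per species
#'
#' Fits each trace, applies the Boltzmann correction at the trace's
#' measurement temperature, and aggregates per species. Log-normalised MR
#' values (natural log by default, base 10 optional) accompany the raw
#' rates for box-plot-style reporting.
#'
#' @param traces List of [respirometry_trace()] objects.
#' @param e_ev Activation energy passed to [boltzmann_correct()].
#' @param log_base `"ln"` or `"log10"` for the normalised column.
#' @param ... Passed to [consumption_rate()].
#' @return List with `records` (one row per specimen: `species_id`, `mr0`,
#'   `temp_k`, `mr`, `log_mr`, `valid`) and `summary` (per species: `n`,
#'   `mean_mr`, `sd_mr`, `mean_log_mr`).
#' @export
summarize_mr <- function(traces, e_ev = 0.65, log_base = c("ln", "log10"),
                         ...) {
  log_base <- arg_match(log_base)
  logf <- if (log_base == "ln") log else log10
  records <- list_rbind(map(traces, function(tr) {
    f <- consumption_rate(tr, ...)
    mr <- boltzmann_correct(f$mr0, f$temp_c, e_ev = e_ev)
    tibble(species_id = f$species_id, mr0 = f$mr0,
           temp_k = f$temp_c + 273.15, mr = mr, log_mr = logf(mr),
           valid = f$valid)
  }))
  summary <- records |>
    filter(.data$valid) |>
    group_by(.data$species_id) |>
    summarise(n = n(), mean_mr = mean(.data$mr), sd_mr = sd(.data$mr),
              mean_log_mr = mean(.data$log_mr), .groups = "drop")
  list(records = records, summary = summary)
}
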