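## Synthetic daily-temperature scenario generation: annual sinusoid plus a
## warming offset and seeded AR(1) daily noise, with probability-weighted
## scenario sets standing in for observed / projected climate series.

#' Scenario generator parameters
#'
#' @param T_mean Annual mean temperature (°C).
#' @param amplitude Seasonal sinusoid amplitude A (°C).
#' @param phase Phase shift (days).
#' @param warming_offset Additive warming offset delta (°C); 0 for historic
#'   regimes, > 0 for future regimes.
#' @param ar1_rho AR(1) autocorrelation of daily anomalies, `|rho| < 1`.
#' @param daily_sd Stationary standard deviation sigma of daily anomalies
#'   (°C), >= 0.
#' @param seed RNG seed (integer) — identical seed and parameters give an
#'   identical series.
#' @param label Optional series label.
#' @return Object of class `scenario_params`.
#' @export
scenario_params <- function(T_mean = 26.5, amplitude = 3.5, phase = 105,
                            warming_offset = 0, ar1_rho = 0.65,
                            daily_sd = 1.2, seed = 1, label = NULL) {
  if (daily_sd < 0) stop("daily_sd must be >= 0")
  if (abs(ar1_rho) >= 1) stop("|ar1_rho| must be < 1 (stationarity)")
  structure(list(T_mean = T_mean, amplitude = amplitude, phase = phase,
                 warming_offset = warming_offset, ar1_rho = ar1_rho,
                 daily_sd = daily_sd, seed = as.integer(seed),
                 label = label),
            class = "scenario_params")
}

#' Generate one synthetic daily temperature series
#'
#' `temp_t = T_mean + delta + A sin(2 pi (t - phase) / 365) + e_t` with
#' `e_t = rho e_{t-1} + N(0, sigma^2 (1 - rho^2))`, `e_0 = 0`. The anomaly
#' process is stationary with standard deviation `sigma`. Generation is
#' seeded (R's default Mersenne-Twister) and leaves the global RNG state
#' untouched.
#'
#' @param params A [scenario_params()].
#' @param T_end Series length in days.
#' @return `data.frame(day, temp_C)` with a `label` attribute.
#' @export
generate_scenario <- function(params, T_end = 365) {
  stopifnot(inherits(params, "scenario_params"))
  t <- seq_len(T_end)
  base <- params$T_mean + params$warming_offset +
    params$amplitude * sin(2 * pi * (t - params$phase) / 365)
  e <- numeric(T_end)
  if (params$daily_sd > 0) {
    innov_sd <- params$daily_sd * sqrt(1 - params$ar1_rho^2)
    innov <- with_local_seed(params$seed, rnorm(T_end, 0, innov_sd))
    e <- as.numeric(stats::filter(innov, params$ar1_rho, method = "recursive"))
  }
  out <- data.frame(day = t, temp_C = base + e)
  attr(out, "label") <- if (is.null(params$label)) "scenario" else params$label
  out
}

#' Scenario set
#'
#' @param series List of daily temperature series (data frames with
#'   `day`, `temp_C`), equal lengths.
#' @param weights Probability weights, one per series. Defaults to equal
#'   weights; re-normalized to sum 1 with a warning when needed.
#' @return Object of class `scenario_set`.
#' @export
scenario_set <- function(series, weights = NULL) {
  n <- length(series)
  if (n < 1) stop("scenario set needs at least one series")
  len <- vapply(series, nrow, 0L)
  if (length(unique(len)) != 1)
    stop("all scenario series must have equal length")
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop("need one weight per series")
  if (any(weights < 0)) stop("scenario weights must be >= 0")
  s <- sum(weights)
  if (s <= 0) stop("scenario weights must have positive sum")
  if (abs(s - 1) > 1e-9) {
    warning("scenario weights re-normalized to sum 1")
    weights <- weights / s
  }
  structure(list(series = series, weights = weights), class = "scenario_set")
}

#' Generate a weighted scenario set
#'
#' @param param_list List of [scenario_params()].
#' @param weights Optional probability weights (default equal).
#' @param T_end Series length in days.
#' @return A [scenario_set()].
#' @export
generate_scenario_set <- function(param_list, weights = NULL, T_end = 365) {
  series <- lapply(param_list, generate_scenario, T_end = T_end)
  scenario_set(series, weights)
}

#' Scenario presets
#'
#' Editable defaults emulating four temperature regimes: historic vs future
#' (future adds a warming offset) crossed with median vs high daily thermal
#' variability (larger anomaly sd). Tuned to a tropical coastal climate.
#'
#' @param name One of `"historic_median"`, `"historic_high"`,
#'   `"future_median"`, `"future_high"`.
#' @param seed RNG seed stored in the returned params.
#' @return A [scenario_params()].
#' @export
scenario_preset <- function(name, seed = 1) {
  presets <- list(
    historic_median = list(warming_offset = 0,   daily_sd = 1.0),
    historic_high   = list(warming_offset = 0,   daily_sd = 2.2),
    future_median   = list(warming_offset = 1.5, daily_sd = 1.2),
    future_high     = list(warming_offset = 1.5, daily_sd = 2.6))
  if (!name %in% names(presets)) stop("unknown scenario preset: ", name)
  p <- presets[[name]]
  scenario_params(T_mean = 26.5, amplitude = 3.5, phase = 105,
                  warming_offset = p$warming_offset, ar1_rho = 0.65,
                  daily_sd = p$daily_sd, seed = seed, label = name)
}

#' Pointwise weighted mean of a scenario set
#'
#' Reproduces the deterministic-on-average workflow: a single series that
#' averages the set (which smooths the appearance of extremes).
#'
#' @param set A [scenario_set()].
#' @return `data.frame(day, temp_C)`.
#' @export
mean_series <- function(set) {
  stopifnot(inherits(set, "scenario_set"))
  m <- Reduce(`+`, Map(function(s, w) w * s$temp_C, set$series, set$weights))
  out <- data.frame(day = set$series[[1]]$day, temp_C = m)
  attr(out, "label") <- "weighted_mean"
  out
}

#' Write a scenario set as CSV files plus a manifest
#'
#' One `series_<label>.csv` (columns day, temp_C) per scenario and a
#' `manifest.csv` (columns series_file, weight).
#'
#' @param set A [scenario_set()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_scenario_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(set$series))
  for (i in seq_along(set$series)) {
    lab <- attr(set$series[[i]], "label")
    if (is.null(lab)) lab <- paste0("s", i)
    files[i] <- paste0("series_", i, "_", lab, ".csv")
    write.csv(set$series[[i]], file.path(dir, files[i]), row.names = FALSE)
  }
  manifest <- data.frame(series_file = files, weight = set$weights)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a scenario set from a manifest
#'
#' @param manifest_path Path to a manifest CSV (columns series_file, weight);
#'   series files are resolved relative to the manifest.
#' @return A [scenario_set()].
#' @export
read_scenario_set <- function(manifest_path) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("series_file", "weight") %in% names(man)))
    stop("manifest must have columns series_file, weight")
  dir <- dirname(manifest_path)
  series <- lapply(seq_len(nrow(man)), function(i) {
    s <- read.csv(file.path(dir, man$series_file[i]))
    if (!all(c("day", "temp_C") %in% names(s)))
      stop("series file must have columns day, temp_C: ", man$series_file[i])
    attr(s, "label") <- sub("\\.csv$", "", man$series_file[i])
    s
  })
  scenario_set(series, man$weight)
}
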