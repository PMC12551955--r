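## Thermal biology: temperature-dependent life-history rate functions.
## Supported functional forms are the standard vector thermal-biology
## repertoire: constant, linear, quadratic (concave, zero outside its
## thermal limits) and Briere.

#' Briere thermal performance curve
#'
#' Evaluates the Briere function `a * T * (T - T_min) * sqrt(T_max - T)` on
#' `[T_min, T_max]` and 0 outside, the canonical unimodal form for insect
#' development and fecundity rates.
#'
#' @param T Temperature in degrees Celsius (vectorized).
#' @param a Positive scale coefficient.
#' @param T_min,T_max Lower and upper thermal limits (°C), `T_min < T_max`.
#' @return Rate per day, continuous and zero at both limits.
#' @examples
#' briere_rate(25, 2.13e-4, 13.35, 40.08)
#' @export
briere_rate <- function(T, a, T_min, T_max) {
  if (T_min >= T_max) stop("invalid thermal bounds: T_min must be < T_max")
  if (a <= 0) stop("Briere coefficient 'a' must be > 0")
  r <- ifelse(T > T_min & T < T_max,
              a * T * (T - T_min) * sqrt(pmax(T_max - T, 0)), 0)
  pmax(r, 0)
}

#' Quadratic thermal performance curve
#'
#' Evaluates `c * (T - T_min) * (T_max - T)`, clamped at 0 outside
#' `[T_min, T_max]`.
#'
#' @inheritParams briere_rate
#' @param c Scale coefficient.
#' @return Rate per day.
#' @examples
#' quadratic_rate(25, 1e-3, 10, 40)
#' @export
quadratic_rate <- function(T, c, T_min, T_max) {
  if (T_min >= T_max) stop("invalid thermal bounds: T_min must be < T_max")
  r <- ifelse(T > T_min & T < T_max, c * (T - T_min) * (T_max - T), 0)
  pmax(r, 0)
}

#' Thermal response specification
#'
#' A single life-history rate as a function of temperature. Forms:
#' * `constant`: `params = c(rate = r)`
#' * `linear`: `params = c(intercept = b0, slope = b1)`, i.e. `b0 + b1 * T`
#' * `quadratic`: `params = c(c = , T_min = , T_max = )`
#' * `briere`: `params = c(a = , T_min = , T_max = )`
#'
#' All evaluations are clamped below at `floor` (>= 0), so a response never
#' returns a negative or sub-floor rate at any real temperature.
#'
#' @param form One of `"constant"`, `"linear"`, `"quadratic"`, `"briere"`.
#' @param params Named numeric vector of form-specific coefficients.
#' @param floor Minimum rate per day (clamp), >= 0.
#' @return An object of class `thermal_response`.
#' @export
thermal_response <- function(form = c("constant", "linear", "quadratic", "briere"),
                             params, floor = 0) {
  form <- match.arg(form)
  params <- unlist(params)
  need <- switch(form,
    constant  = "rate",
    linear    = c("intercept", "slope"),
    quadratic = c("c", "T_min", "T_max"),
    briere    = c("a", "T_min", "T_max"))
  if (!all(need %in% names(params)))
    stop("thermal_response '", form, "' needs params: ",
         paste(need, collapse = ", "))
  if (form %in% c("quadratic", "briere") &&
      params[["T_min"]] >= params[["T_max"]])
    stop("invalid thermal bounds: T_min must be < T_max")
  if (form == "briere" && params[["a"]] <= 0)
    stop("Briere coefficient 'a' must be > 0")
  if (floor < 0) stop("floor must be >= 0")
  structure(list(form = form, params = params, floor = floor),
            class = "thermal_response")
}

#' Evaluate a thermal response at a temperature
#'
#' @param resp A [thermal_response()].
#' @param T Temperature (°C), vectorized.
#' @return Rate per day, `>= resp$floor`.
#' @export
eval_rate <- function(resp, T) {
  stopifnot(inherits(resp, "thermal_response"))
  p <- resp$params
  r <- switch(resp$form,
    constant  = rep(p[["rate"]], length(T)),
    linear    = p[["intercept"]] + p[["slope"]] * T,
    quadratic = quadratic_rate(T, p[["c"]], p[["T_min"]], p[["T_max"]]),
    briere    = briere_rate(T, p[["a"]], p[["T_min"]], p[["T_max"]]))
  pmax(r, resp$floor)
}

#' Species life-history parameterization
#'
#' Bundles per-stage thermal responses for a stage-structured (egg, larva,
#' pupa, adult) mosquito life cycle: development and mortality per juvenile
#' stage, adult mortality, and adult female fecundity.
#'
#' @param name Species label.
#' @param development Named list of [thermal_response()] for `egg`, `larva`,
#'   `pupa` (stage progression rates, per day).
#' @param mortality Named list of [thermal_response()] for `egg`, `larva`,
#'   `pupa`, `adult` (per-day mortality).
#' @param fecundity A [thermal_response()]: eggs per female per day.
#' @param mort_floor Minimum mortality rate per day (guards the equilibrium
#'   computation against division by zero). Default 1e-6.
#' @return Object of class `species_params`.
#' @export
species_params <- function(name, development, mortality, fecundity,
                           mort_floor = 1e-6) {
  for (s in c("egg", "larva", "pupa"))
    if (is.null(development[[s]]))
      stop("species '", name, "': missing development response for stage ", s)
  for (s in c("egg", "larva", "pupa", "adult"))
    if (is.null(mortality[[s]]))
      stop("species '", name, "': missing mortality response for stage ", s)
  if (is.null(fecundity))
    stop("species '", name, "': missing fecundity response")
  structure(list(name = name, development = development,
                 mortality = mortality, fecundity = fecundity,
                 mort_floor = mort_floor),
            class = "species_params")
}

#' Evaluate all stage rates at one temperature
#'
#' @param T Temperature (°C), scalar.
#' @param species A [species_params()].
#' @return Object of class `stage_rates`: list with `fecundity` (nu),
#'   `development` (named: egg, larva, pupa) and `mortality`
#'   (named: egg, larva, pupa, adult), all per day and >= 0. Mortality
#'   entries are additionally clamped at `species$mort_floor`.
#' @export
stage_rates_at <- function(T, species) {
  stopifnot(inherits(species, "species_params"))
  dev <- vapply(c("egg", "larva", "pupa"),
                function(s) eval_rate(species$development[[s]], T), 0)
  mort <- vapply(c("egg", "larva", "pupa", "adult"),
                 function(s) pmax(eval_rate(species$mortality[[s]], T),
                                  species$mort_floor), 0)
  structure(list(fecundity = eval_rate(species$fecundity, T),
                 development = dev, mortality = mort),
            class = "stage_rates")
}

# internal: n_days x 8 matrix (nu, thE, muE, thL, muL, thP, muP, muA)
# evaluated on a daily temperature vector; the layout rollout_core expects.
rate_table <- function(species, temps_C) {
  n <- length(temps_C)
  out <- matrix(0, n, 8,
                dimnames = list(NULL, c("nu", "thE", "muE", "thL", "muL",
                                        "thP", "muP", "muA")))
  for (i in seq_len(n)) {
    r <- stage_rates_at(temps_C[i], species)
    out[i, ] <- c(r$fecundity, r$development[["egg"]], r$mortality[["egg"]],
                  r$development[["larva"]], r$mortality[["larva"]],
                  r$development[["pupa"]], r$mortality[["pupa"]],
                  r$mortality[["adult"]])
  }
  out
}

resp_from_config <- function(x) {
  thermal_response(x$form, unlist(x$params),
                   floor = if (is.null(x$floor)) 0 else x$floor)
}

#' Load a shipped species preset
#'
#' Editable YAML presets under `inst/extdata/species/` with one thermal
#' response block per stage. Presently available: `"aedes_aegypti"` and
#' `"anopheles_gambiae"`. Preset coefficients are simplified transcriptions
#' in the style of published thermal-trait fits and are meant to be edited
#' for local application; no package test depends on their numeric values.
#'
#' @param name Preset name.
#' @return A [species_params()].
#' @export
species_preset <- function(name) {
  path <- system.file("extdata", "species", paste0(name, ".yaml"),
                      package = "vectoropt")
  if (path == "") stop("unknown species preset: ", name)
  species_from_config(yaml::read_yaml(path))
}

# internal: build species_params from a parsed config list
species_from_config <- function(cfg) {
  species_params(
    name = cfg$name,
    development = lapply(cfg$development, resp_from_config),
    mortality = lapply(cfg$mortality, resp_from_config),
    fecundity = resp_from_config(cfg$fecundity),
    mort_floor = if (is.null(cfg$mort_floor)) 1e-6 else cfg$mort_floor)
}
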