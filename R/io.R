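## File formats and configuration. CSV dialect everywhere: comma separator,
## '.' decimal, header row, 1-based day indexing. Numeric columns are
## written with 17 significant digits so write -> read round-trips to
## floating-point precision.

fmt_num <- function(x) sprintf("%.17g", x)

write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

# small polynomial content hash for provenance manifests (kept below 2^31
# so it stays in R integer range; no external digest dependency)
content_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write / read a daily temperature series CSV
#'
#' Columns `day`, `temp_C`; exactly one row per day, 1-based.
#'
#' @param series `data.frame(day, temp_C)`.
#' @param path File path.
#' @return `read_temperature_csv` returns the validated data frame.
#' @export
write_temperature_csv <- function(series, path) {
  write_csv_precise(series[, c("day", "temp_C")], path)
  invisible(path)
}

#' @rdname write_temperature_csv
#' @param n_days Optional expected horizon; validated when given.
#' @export
read_temperature_csv <- function(path, n_days = NULL) {
  x <- read.csv(path)
  if (!all(c("day", "temp_C") %in% names(x)))
    stop("temperature CSV needs columns day, temp_C: ", path)
  if (!identical(as.integer(x$day), seq_len(nrow(x))))
    stop("temperature CSV must have exactly one row per day, 1-based: ", path)
  if (!all(is.finite(x$temp_C))) stop("non-finite temperatures in ", path)
  if (!is.null(n_days) && nrow(x) != n_days)
    stop("temperature CSV has ", nrow(x), " days, expected ", n_days)
  x
}

#' Write / read a release schedule CSV
#'
#' Columns `day`, `node`, `genotype`, `count`. Counts are rounded to whole
#' organisms in the writer (raw values live in the solution report).
#'
#' @param schedule A [release_schedule()].
#' @param path File path.
#' @param drop_zero Drop rows with zero (rounded) count. Default TRUE.
#' @export
write_schedule_csv <- function(schedule, path, drop_zero = TRUE) {
  e <- schedule$entries
  e$count <- round(e$count)
  if (drop_zero) e <- e[e$count > 0, , drop = FALSE]
  write.csv(e, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @param horizon Horizon for the reconstructed schedule.
#' @param genotypes A [genotype_set()].
#' @export
read_schedule_csv <- function(path, horizon, genotypes) {
  e <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("day", "node", "genotype", "count") %in% names(e)))
    stop("schedule CSV needs columns day, node, genotype, count: ", path)
  release_schedule(e, horizon, genotypes)
}

#' Write a trajectory as tidy CSV
#'
#' Columns `day, node, stage, genotype_female, genotype_male, count`
#' (`genotype_male` empty except for mated females).
#'
#' @param traj A `vo_trajectory`.
#' @param path File path.
#' @export
write_trajectory_csv <- function(traj, path) {
  write_csv_precise(trajectory_to_df(traj), path)
  invisible(path)
}

config_defaults <- list(
  genetics = list(alleles = c("W", "R"), penetrance = 1.0,
                  female_only = FALSE, release_genotype = NULL),
  decision = list(psi = 0.20, t0 = 200, T_end = 365, c_max = 1e5,
                  alpha_c = 1, alpha_F = 1, tracking_window = "from_t0",
                  n_sub = 4, theta_trip = 1, budget = NULL),
  solver = list(maxit = 2000, factr = 1e8),
  log_level = "INFO")

vo_log <- function(level, ...) {
  lv <- c(DEBUG = 1, INFO = 2, WARN = 3, ERROR = 4)
  cur <- getOption("vectoropt.log_level", "INFO")
  if (lv[[level]] >= lv[[cur]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

#' Load and validate a run configuration
#'
#' Parses a YAML configuration describing species, genetics, node topology,
#' temperature scenarios, the decision problem and solver options. Unknown
#' keys raise an error naming them; defaults (psi = 0.20, t0 = 200,
#' T_end = 365, ...) are resolved and echoed to the log.
#'
#' @param path Path to a YAML config file.
#' @return Object of class `run_config` with constructed package objects:
#'   `species`, `cube`, `genotypes`, `network`, `scenarios` (a
#'   [scenario_set()]), `spec` (a [decision_spec()]), `solver`, `output`,
#'   and a provenance `config_hash`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("species", "genetics", "network", "scenarios", "decision",
               "solver", "output", "log_level")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  errs <- character(0)
  if (is.null(raw$species)) errs <- c(errs, "missing 'species' block")
  if (is.null(raw$network)) errs <- c(errs, "missing 'network' block")
  if (is.null(raw$scenarios)) errs <- c(errs, "missing 'scenarios' block")
  if (length(errs) > 0)
    stop("config validation failed:\n  - ", paste(errs, collapse = "\n  - "))

  species <- if (!is.null(raw$species$preset)) species_preset(raw$species$preset)
             else if (!is.null(raw$species$custom))
               species_from_config(raw$species$custom)
             else stop("species block needs 'preset' or 'custom'")

  gen <- modifyList(config_defaults$genetics,
                    if (is.null(raw$genetics)) list() else raw$genetics)
  cube <- apply_ridl(mendelian_cube(unlist(gen$alleles)),
                     penetrance = gen$penetrance,
                     female_only = isTRUE(gen$female_only))

  nodes <- lapply(raw$network$nodes, function(nd) {
    sp <- if (!is.null(nd$preset)) species_preset(nd$preset) else species
    list(id = nd$id, species = sp, K = nd$K)
  })
  mig <- if (!is.null(raw$network$migration))
    do.call(rbind, lapply(raw$network$migration, unlist)) else NULL
  net <- network(nodes, mig)

  sc <- raw$scenarios
  scenarios <- if (!is.null(sc$manifest)) {
    read_scenario_set(file.path(dirname(path), sc$manifest))
  } else if (!is.null(sc$generator)) {
    g <- sc$generator
    T_end <- if (is.null(g$T_end)) 365 else g$T_end
    params <- if (!is.null(g$presets)) {
      seeds <- if (is.null(g$seeds)) seq_along(unlist(g$presets)) else unlist(g$seeds)
      Map(scenario_preset, unlist(g$presets), seeds)
    } else {
      lapply(g$params, function(p) do.call(scenario_params, p))
    }
    generate_scenario_set(params, weights = unlist(g$weights), T_end = T_end)
  } else stop("scenarios block needs 'manifest' or 'generator'")

  dec <- modifyList(config_defaults$decision,
                    if (is.null(raw$decision)) list() else raw$decision)
  mask <- if (is.null(dec$mask)) weekly_mask(dec$t0, dec$T_end)
  else {
    m <- dec$mask
    start <- if (is.null(m$start)) dec$t0 else m$start
    switch(if (is.null(m$type)) "weekly" else m$type,
           weekly = weekly_mask(start, dec$T_end),
           biweekly = biweekly_mask(start, dec$T_end),
           custom = as.integer(unlist(m$days)),
           stop("unknown mask type: ", m$type))
  }
  spec <- decision_spec(T_end = dec$T_end, t0 = dec$t0, psi = dec$psi,
                        mask = mask, c_max = dec$c_max, budget = dec$budget,
                        alpha_c = dec$alpha_c, alpha_F = dec$alpha_F,
                        tracking_window = dec$tracking_window,
                        n_sub = dec$n_sub,
                        release_genotype = gen$release_genotype,
                        theta_trip = dec$theta_trip)
  solver <- modifyList(config_defaults$solver,
                       if (is.null(raw$solver)) list() else raw$solver)
  lvl <- if (is.null(raw$log_level)) config_defaults$log_level else raw$log_level
  options(vectoropt.log_level = lvl)
  cfg <- structure(list(raw = raw, path = path, species = species,
                        cube = cube, genotypes = cube$genotypes,
                        network = net, scenarios = scenarios, spec = spec,
                        solver = solver, output = raw$output,
                        config_hash = content_hash(raw)),
                   class = "run_config")
  vo_log("INFO", "config loaded: psi=", spec$psi, " t0=", spec$t0,
         " T_end=", spec$T_end, " scenarios=", length(scenarios$series),
         " hash=", cfg$config_hash)
  cfg
}

write_run_manifest <- function(cfg, out_dir, extra = list()) {
  man <- c(list(config_hash = cfg$config_hash,
                package_version = as.character(packageVersion("vectoropt")),
                timestamp = format(Sys.time(), tz = "UTC")),
           extra)
  jsonlite::write_json(man, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}
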