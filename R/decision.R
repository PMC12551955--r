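## Decision models: deterministic and scenario-weighted stochastic nonlinear
## programs that schedule modified-male releases. The transcription is
## reduced-space single shooting: release amounts on mask days are the only
## decision variables (box-bounded), and the states inside the objective are
## produced by the same compiled Euler update used by rollout_discrete(),
## so re-simulating a returned schedule reproduces the optimizer's states
## exactly ("build once, solve twice").

#' Release masks
#'
#' Calendar days on which deployments are permitted.
#'
#' @param start First allowed day.
#' @param T_end Horizon end.
#' @param period Days between allowed deployments.
#' @return Integer vector of allowed days.
#' @export
release_mask <- function(start, T_end, period) {
  if (period < 1) stop("period must be >= 1")
  seq.int(start, T_end, by = period)
}

#' @rdname release_mask
#' @export
weekly_mask <- function(start, T_end) release_mask(start, T_end, 7L)

#' @rdname release_mask
#' @export
biweekly_mask <- function(start, T_end) release_mask(start, T_end, 14L)

#' Decision problem specification
#'
#' @param T_end Horizon length T (days). Default 365.
#' @param t0 Intervention start day (suppression goal applies from here
#'   under the default tracking window). Default 200.
#' @param psi Suppression fraction in (0, 1]: target wildtype female level
#'   is `psi * F_1` per wild genotype. Default 0.20.
#' @param mask Allowed release days (subset of 1..T_end); e.g.
#'   [weekly_mask()]. Default: weekly from t0.
#' @param c_max Upper bound on a single deployment (organisms).
#' @param budget Optional bound on total organisms released (enforced via a
#'   smooth quadratic penalty).
#' @param alpha_c,alpha_F Objective weights on the release-cost and tracking
#'   terms (defaults 1, 1 — the printed form).
#' @param tracking_window `"from_t0"` (tracking term over t >= t0) or
#'   `"all"` (over every day of the horizon).
#' @param n_sub Euler substeps per day in the transcription. Default 4.
#' @param release_genotype Released genotype label (must be modified);
#'   default: the last modified genotype (homozygous construct).
#' @param release_nodes Node ids eligible for release; default all.
#' @param theta_trip Organism threshold for counting a (day, node) release
#'   as one field deployment. Default 1.
#' @return Object of class `decision_spec`.
#' @export
decision_spec <- function(T_end = 365, t0 = 200, psi = 0.20,
                          mask = weekly_mask(t0, T_end),
                          c_max = 1e5, budget = NULL,
                          alpha_c = 1, alpha_F = 1,
                          tracking_window = c("from_t0", "all"),
                          n_sub = 4, release_genotype = NULL,
                          release_nodes = NULL, theta_trip = 1) {
  tracking_window <- match.arg(tracking_window)
  if (psi <= 0 || psi > 1) stop("psi must lie in (0, 1]")
  if (t0 < 1 || t0 > T_end) stop("t0 must lie within 1..T_end")
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) > 0 && (min(mask) < 1 || max(mask) > T_end))
    stop("release mask must be a subset of 1..T_end")
  if (c_max < 0) stop("c_max must be >= 0")
  structure(list(T_end = as.integer(T_end), t0 = as.integer(t0), psi = psi,
                 mask = mask, c_max = c_max, budget = budget,
                 alpha_c = alpha_c, alpha_F = alpha_F,
                 tracking_window = tracking_window, n_sub = as.integer(n_sub),
                 release_genotype = release_genotype,
                 release_nodes = release_nodes, theta_trip = theta_trip),
            class = "decision_spec")
}

tracking_days <- function(spec) {
  if (spec$tracking_window == "from_t0") spec$t0:spec$T_end
  else seq_len(spec$T_end)
}

#' Evaluate the release-scheduling objective
#'
#' Computes
#' `sum_t alpha_c c_t + sum_k p_k sum_{t in window} alpha_F
#'  sum_{g in wild} (F^k_{g,t} - psi F^k_{g,1})^2`,
#' where `c_t` is the total release on day t across nodes and genotypes and
#' `F_{g,t}` the mated females of wild genotype g (all mate genotypes, all
#' nodes). The deterministic case is one trajectory with weight 1.
#'
#' @param trajectories A `vo_trajectory` or list of them (one per scenario).
#' @param weights Scenario probabilities, summing to 1.
#' @param schedule A [release_schedule()].
#' @param spec A [decision_spec()].
#' @return Scalar objective value.
#' @export
evaluate_objective <- function(trajectories, weights, schedule, spec) {
  if (inherits(trajectories, "vo_trajectory"))
    trajectories <- list(trajectories)
  if (length(weights) != length(trajectories))
    stop("need one weight per trajectory")
  if (abs(sum(weights) - 1) > 1e-9) stop("scenario weights must sum to 1")
  cost <- 0
  if (nrow(schedule$entries) > 0)
    cost <- spec$alpha_c * sum(schedule$entries$count)
  win <- tracking_days(spec)
  track <- 0
  for (k in seq_along(trajectories)) {
    wf <- wild_female_matrix(trajectories[[k]])
    dev <- sweep(wf[win, , drop = FALSE], 2, spec$psi * wf[1, ], "-")
    track <- track + weights[k] * spec$alpha_F * sum(dev^2)
  }
  cost + track
}

# internal: shared builder for deterministic/stochastic models
new_decision_model <- function(spec, species, cube, network, series_list,
                               weights, init) {
  if (abs(sum(weights) - 1) > 1e-9)
    stop("scenario weights must sum to 1 (got ", sum(weights), ")")
  gs <- cube$genotypes
  G <- length(gs$labels)
  rg <- spec$release_genotype
  if (is.null(rg)) rg <- gs$modified[length(gs$modified)]
  if (!(rg %in% gs$modified))
    stop("release genotype must be in the modified subset")
  nodes_el <- spec$release_nodes
  if (is.null(nodes_el)) nodes_el <- network$ids
  if (!all(nodes_el %in% network$ids)) stop("unknown release node id(s)")
  tl <- lapply(series_list, temps_per_node, network = network,
               n_days = spec$T_end)
  rates <- lapply(tl, function(per_node)
    lapply(seq_along(per_node), function(k)
      rate_table(network$nodes[[k]]$species, per_node[[k]])))
  if (is.null(init)) {
    init <- unlist(lapply(seq_along(network$ids), function(k)
      as.numeric(equilibrium_state(network$nodes[[k]]$species, cube,
                                   network$nodes[[k]]$K,
                                   T_ref = mean(tl[[1]][[k]]),
                                   node_id = network$ids[k]))))
  }
  vars <- expand.grid(day = spec$mask, node = nodes_el,
                      stringsAsFactors = FALSE)
  ca <- cube_arrays(cube)
  K <- vapply(network$nodes, `[[`, 0, "K")
  gi <- match(rg, gs$labels)
  ni <- match(vars$node, network$ids)
  rel_template <- lapply(seq_along(network$ids),
                         function(k) matrix(0, spec$T_end, G))
  win <- tracking_days(spec)
  wf_target_cache <- new.env(parent = emptyenv())

  rel_from_cvec <- function(cvec) {
    rel <- rel_template
    if (length(cvec) > 0)
      for (i in seq_along(cvec))
        rel[[ni[i]]][vars$day[i], gi] <- rel[[ni[i]]][vars$day[i], gi] + cvec[i]
    rel
  }
  rollout_fn <- function(cvec, k) {
    rollout_core(init, spec$T_end, spec$n_sub, G, rates[[k]],
                 ca$probs, ca$s_f, ca$s_m, ca$eta, ca$beta,
                 K, network$migration, rel_from_cvec(cvec))
  }
  # value + exact discrete-adjoint gradient, cached so optim's paired
  # fn/gr calls at the same point cost one evaluation
  cache <- new.env(parent = emptyenv())
  eval_full <- function(cvec) {
    if (!is.null(cache$par) && identical(cache$par, cvec)) return(cache$res)
    rel <- rel_from_cvec(cvec)
    val <- spec$alpha_c * sum(cvec)
    grad <- rep(spec$alpha_c, length(cvec))
    if (!is.null(spec$budget)) {
      over <- sum(cvec) - spec$budget
      if (over > 0) {
        val <- val + 1e6 * over^2
        grad <- grad + 2e6 * over
      }
    }
    for (k in seq_along(rates)) {
      a <- rollout_adjoint_core(init, spec$T_end, spec$n_sub, G, rates[[k]],
                                ca$probs, ca$s_f, ca$s_m, ca$eta, ca$beta,
                                K, network$migration, rel,
                                as.integer(win), spec$psi, spec$alpha_F,
                                as.integer(gs$wild_idx))
      val <- val + weights[k] * a$value_track
      if (length(cvec) > 0)
        grad <- grad + weights[k] *
          vapply(seq_along(cvec),
                 function(i) a$grad[[ni[i]]][vars$day[i], gi], 0)
    }
    cache$par <- cvec
    cache$res <- list(value = val, gradient = grad)
    cache$res
  }
  obj_fn <- function(cvec) eval_full(cvec)$value
  grad_fn <- function(cvec) eval_full(cvec)$gradient
  structure(list(spec = spec, cube = cube, genotypes = gs, network = network,
                 weights = weights, init = init, vars = vars,
                 release_genotype = rg, n_scenarios = length(rates),
                 objective = obj_fn, gradient = grad_fn, rollout = rollout_fn),
            class = "decision_model")
}

#' Build the deterministic decision model
#'
#' One temperature series, one state trajectory; releases bounded by
#' `[0, c_max]` on mask days and fixed at 0 elsewhere; dynamics enter via
#' the shared Euler rollout.
#'
#' @param spec A [decision_spec()].
#' @param species A [species_params()] (used for default initialization;
#'   per-node species come from `network`).
#' @param cube Inheritance cube.
#' @param network A [network()].
#' @param temps Single daily temperature series (data frame, vector, or
#'   per-node list).
#' @param init Optional initial state; default: per-node wildtype
#'   equilibrium at the series mean temperature.
#' @return Object of class `decision_model`.
#' @export
build_deterministic <- function(spec, species, cube, network, temps,
                                init = NULL) {
  new_decision_model(spec, species, cube, network, list(temps),
                     weights = 1, init = init)
}

#' Build the stochastic decision model
#'
#' One state copy per scenario, a single shared (non-anticipative) release
#' schedule, and a probability-weighted tracking term.
#'
#' @inheritParams build_deterministic
#' @param scenarios A [scenario_set()] (or list with `series`, `weights`).
#' @return Object of class `decision_model`.
#' @export
build_stochastic <- function(spec, species, cube, network, scenarios,
                             init = NULL) {
  new_decision_model(spec, species, cube, network, scenarios$series,
                     weights = scenarios$weights, init = init)
}

# internal: schedule object from a decision-variable vector
schedule_from_cvec <- function(model, cvec) {
  df <- data.frame(day = model$vars$day, node = model$vars$node,
                   genotype = rep_len(model$release_genotype,
                                      nrow(model$vars)),
                   count = as.numeric(cvec))
  release_schedule(df, model$spec$T_end, model$genotypes)
}

#' Solve a decision model
#'
#' Minimizes the objective over box-bounded release variables with
#' `stats::optim(method = "L-BFGS-B")` (finite-difference gradients on the
#' parscale level). The default initial guess is the no-release rollout
#' (feasible for the dynamics by construction, deterministic).
#'
#' @param model A `decision_model` from [build_deterministic()] /
#'   [build_stochastic()].
#' @param init_schedule Optional warm-start: a [release_schedule()] or a
#'   numeric vector over the model's release variables.
#' @param maxit,factr L-BFGS-B controls.
#' @return Object of class `solution_report`: `schedule`,
#'   `objective_value`, `termination_status`, `max_constraint_violation`
#'   (re-simulation residual), `trajectories` (per scenario, discrete mode),
#'   `totals` (organisms released, deployment count), plus solver details.
#' @export
solve_decision_model <- function(model, init_schedule = NULL,
                                 maxit = 2000, factr = 1e8) {
  spec <- model$spec
  nv <- nrow(model$vars)
  par0 <- rep(0, nv)
  if (!is.null(init_schedule)) {
    if (is.numeric(init_schedule)) {
      par0 <- rep_len(init_schedule, nv)
    } else {
      e <- init_schedule$entries
      for (r in seq_len(nrow(e))) {
        i <- which(model$vars$day == e$day[r] &
                     model$vars$node == as.character(e$node[r]))
        if (length(i) == 1) par0[i] <- par0[i] + e$count[r]
      }
    }
  }
  if (nv > 0) {
    ctrl <- list(maxit = maxit, factr = factr,
                 parscale = rep(max(1, spec$c_max / 100), nv))
    res <- optim(par0, model$objective, gr = model$gradient,
                 method = "L-BFGS-B",
                 lower = rep(0, nv), upper = rep(spec$c_max, nv),
                 control = ctrl)
  } else {
    res <- list(par = numeric(0), value = model$objective(numeric(0)),
                convergence = 0L, message = "no release variables (empty mask)",
                counts = c(0, 0))
  }
  cvec <- res$par
  schedule <- schedule_from_cvec(model, cvec)
  trajs <- lapply(seq_len(model$n_scenarios), function(k)
    new_trajectory(model$rollout(cvec, k)$states, model$genotypes,
                   model$network, "discrete", spec$n_sub))
  objective <- evaluate_objective(trajs, model$weights, schedule, spec)
  report <- structure(list(
    schedule = schedule,
    objective_value = objective,
    termination_status = list(convergence = res$convergence,
                              message = res$message,
                              counts = res$counts,
                              solver = "L-BFGS-B (single shooting)"),
    max_constraint_violation = NA_real_,
    trajectories = trajs,
    totals = list(released = total_released(schedule),
                  deployments = count_deployments(schedule, spec$theta_trip)),
    cvec = cvec, par0 = par0, solver_value = res$value),
    class = "solution_report")
  report$max_constraint_violation <- verify_consistency(report, model)
  report
}

#' @export
print.solution_report <- function(x, ...) {
  cat("Release-schedule solution report\n")
  cat("  status      :", x$termination_status$convergence,
      if (!is.null(x$termination_status$message)) x$termination_status$message
      else "", "\n")
  cat("  objective   :", format(x$objective_value), "\n")
  cat("  released    :", format(x$totals$released), "organisms\n")
  cat("  deployments :", x$totals$deployments, "\n")
  cat("  consistency :", format(x$max_constraint_violation),
      "(max relative re-simulation residual)\n")
  invisible(x)
}

#' Count field deployments in a schedule
#'
#' Number of (day, node) pairs whose summed release reaches `theta_trip`.
#'
#' @param schedule A [release_schedule()].
#' @param theta_trip Organism threshold per trip (> 0).
#' @return Integer count.
#' @export
count_deployments <- function(schedule, theta_trip = 1) {
  if (theta_trip <= 0) stop("theta_trip must be > 0")
  e <- schedule$entries
  if (nrow(e) == 0) return(0L)
  agg <- aggregate(count ~ day + node, data = e, FUN = sum)
  sum(agg$count >= theta_trip)
}

#' Total organisms in a schedule
#' @param schedule A [release_schedule()].
#' @return Sum of release counts.
#' @export
total_released <- function(schedule) {
  if (nrow(schedule$entries) == 0) return(0)
  sum(schedule$entries$count)
}

#' Verify transcription consistency of a solution
#'
#' Re-runs the discrete rollout with the report's schedule (same `n_sub`)
#' and returns the maximum absolute state discrepancy against the states
#' stored in the report, scaled by `1 + max|state|`. Accepted solutions must
#' satisfy residual `<= 1e-6`.
#'
#' @param report A `solution_report`.
#' @param model The `decision_model` that produced it.
#' @return Maximum relative residual across scenarios.
#' @export
verify_consistency <- function(report, model) {
  cvec <- report$cvec
  if (is.null(cvec)) {
    # reconstruct variables from the schedule
    cvec <- rep(0, nrow(model$vars))
    e <- report$schedule$entries
    for (r in seq_len(nrow(e))) {
      i <- which(model$vars$day == e$day[r] &
                   model$vars$node == as.character(e$node[r]))
      if (length(i) == 1) cvec[i] <- cvec[i] + e$count[r]
    }
  }
  worst <- 0
  for (k in seq_len(model$n_scenarios)) {
    ref <- model$rollout(cvec, k)$states
    got <- report$trajectories[[k]]$states
    sc <- 1 + max(abs(ref))
    worst <- max(worst, max(abs(ref - got)) / sc)
  }
  worst
}
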