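## Population dynamics: stage- and genotype-structured ODE model driven by a
## daily temperature series, an exactly matching explicit-Euler rollout
## (shared with the decision model), equilibria, and trajectory utilities.
##
## State layout per node (length S = 4G + G^2, G = number of genotypes):
##   E[1..G], L, P, M (adult males), F (mated females, column-major
##   F[gf, gm]: own genotype gf, mate genotype gm).

state_dim <- function(G) 4L * G + G * G

state_slots <- function(G) {
  list(E = 1:G, L = G + 1:G, P = 2 * G + 1:G, M = 3 * G + 1:G,
       F = 4 * G + 1:(G * G))
}

#' Node state constructor
#'
#' @param G Number of genotypes.
#' @param E,L,P,M Per-genotype egg, larva, pupa, adult-male counts
#'   (length G; scalars are recycled).
#' @param F Mated adult female counts: G x G matrix `F[gf, gm]` (own
#'   genotype by mate genotype), or a scalar.
#' @return Numeric state vector of length `4G + G^2`.
#' @export
node_state <- function(G, E = 0, L = 0, P = 0, M = 0, F = 0) {
  Fm <- if (is.matrix(F)) F else matrix(F, G, G)
  c(rep_len(E, G), rep_len(L, G), rep_len(P, G), rep_len(M, G), as.vector(Fm))
}

#' Node network
#'
#' A set of well-mixed geographic nodes, each with its own species
#' parameterization and larval carrying capacity, linked by adult-only
#' migration.
#'
#' @param nodes List of nodes; each a list with `id`, `species`
#'   (a [species_params()]), and `K` (larval carrying capacity, > 0).
#' @param migration Optional n x n matrix of per-day movement rates,
#'   `migration[i, j]` = rate from node i to node j; diagonal must be zero.
#' @return Object of class `vo_network`.
#' @export
network <- function(nodes, migration = NULL) {
  n <- length(nodes)
  for (nd in nodes) {
    if (is.null(nd$id) || is.null(nd$species) || is.null(nd$K))
      stop("each node needs id, species and K")
    if (nd$K <= 0) stop("carrying capacity K must be > 0 (node ", nd$id, ")")
  }
  if (is.null(migration)) migration <- matrix(0, n, n)
  migration <- as.matrix(migration)
  if (any(dim(migration) != n)) stop("migration matrix must be n x n")
  if (any(diag(migration) != 0)) stop("migration diagonal must be zero")
  if (any(migration < 0)) stop("migration rates must be >= 0")
  structure(list(nodes = nodes, migration = migration,
                 ids = vapply(nodes, `[[`, "", "id")),
            class = "vo_network")
}

#' Release schedule
#'
#' Scheduled impulses of modified adult males: one row per (day, node,
#' genotype) with a non-negative count, applied at the start of the day.
#'
#' @param entries Data frame with columns `day`, `node`, `genotype`, `count`.
#' @param horizon Number of days T in the horizon.
#' @param genotypes A [genotype_set()]; release genotypes must belong to its
#'   modified subset.
#' @return Object of class `release_schedule`.
#' @export
release_schedule <- function(entries, horizon, genotypes) {
  if (nrow(entries) > 0) {
    if (any(entries$count < 0)) stop("release counts must be >= 0")
    if (any(entries$day < 1 | entries$day > horizon))
      stop("release days must lie within the horizon 1..", horizon)
    bad <- setdiff(unique(entries$genotype), genotypes$modified)
    if (length(bad) > 0)
      stop("release genotypes must be in the modified subset; got: ",
           paste(bad, collapse = ", "))
  }
  structure(list(entries = entries, horizon = horizon),
            class = "release_schedule")
}

#' Empty release schedule
#' @inheritParams release_schedule
#' @export
empty_schedule <- function(horizon, genotypes) {
  release_schedule(data.frame(day = integer(0), node = character(0),
                              genotype = character(0), count = numeric(0)),
                   horizon, genotypes)
}

# internal: per-node n_days x G matrices of male release impulses
schedule_matrices <- function(schedule, n_days, network, genotypes) {
  G <- length(genotypes$labels)
  out <- lapply(seq_along(network$ids),
                function(i) matrix(0, n_days, G))
  e <- schedule$entries
  if (nrow(e) > 0) {
    ni <- match(as.character(e$node), network$ids)
    if (anyNA(ni)) stop("schedule references unknown node(s): ",
                        paste(unique(e$node[is.na(ni)]), collapse = ", "))
    gi <- match(e$genotype, genotypes$labels)
    for (r in seq_len(nrow(e)))
      out[[ni[r]]][e$day[r], gi[r]] <- out[[ni[r]]][e$day[r], gi[r]] + e$count[r]
  }
  out
}

# internal: normalize temperature input to a list of per-node daily vectors
temps_per_node <- function(temps, network, n_days) {
  n <- length(network$ids)
  tl <- if (is.data.frame(temps)) rep(list(temps), n)
        else if (is.numeric(temps)) rep(list(data.frame(day = seq_along(temps),
                                                        temp_C = temps)), n)
        else temps
  if (length(tl) != n) stop("need one temperature series per node")
  lapply(tl, function(x) {
    v <- if (is.data.frame(x)) x$temp_C else as.numeric(x)
    if (length(v) < n_days)
      stop("temperature series (", length(v),
           " days) does not cover the horizon (", n_days, " days)")
    v[seq_len(n_days)]
  })
}

#' Time derivative of the population state
#'
#' Right-hand side of the stage- and genotype-structured dynamics at one
#' instant: births through the inheritance cube, density-dependent larval
#' mortality `mu_L * (1 + L_tot / K)`, 1:1 sex ratio at emergence with
#' genotype survival modifiers, instantaneous mating with male weights
#' `eta` (mating fraction defined as 0 when no males are present), and
#' adult-only migration.
#'
#' @param state Full state vector (all nodes concatenated).
#' @param T_t Temperature(s) at this instant: scalar or one per node.
#' @param network A [network()].
#' @param cube An inheritance cube.
#' @return Derivative vector, same length as `state`.
#' @export
rhs_eval <- function(state, T_t, network, cube) {
  G <- length(cube$genotypes$labels)
  S <- state_dim(G)
  n <- length(network$ids)
  T_t <- rep_len(T_t, n)
  dy <- numeric(length(state))
  sl <- state_slots(G)
  fit <- cube$fitness
  probs <- cube$probs
  for (k in seq_len(n)) {
    off <- (k - 1) * S
    r <- stage_rates_at(T_t[k], network$nodes[[k]]$species)
    nu <- r$fecundity
    thE <- r$development[["egg"]]; muE <- r$mortality[["egg"]]
    thL <- r$development[["larva"]]; muL <- r$mortality[["larva"]]
    thP <- r$development[["pupa"]]; muP <- r$mortality[["pupa"]]
    muA <- r$mortality[["adult"]]
    E <- state[off + sl$E]; L <- state[off + sl$L]; P <- state[off + sl$P]
    M <- state[off + sl$M]
    Fm <- matrix(state[off + sl$F], G, G)
    denom <- sum(fit$eta * M)
    mf <- if (denom > 0) fit$eta * M / denom else numeric(G)
    em <- 0.5 * thP * P
    # births: B_go = nu * sum_{gf,gm} beta_gf F[gf,gm] probs[gf,gm,go]
    W <- Fm * fit$beta  # recycles beta down rows (gf index)
    B <- nu * vapply(seq_len(G), function(go) sum(W * probs[, , go]), 0)
    dd <- muL * (1 + sum(L) / network$nodes[[k]]$K)
    dy[off + sl$E] <- B - (thE + muE) * E
    dy[off + sl$L] <- thE * E - (thL + dd) * L
    dy[off + sl$P] <- thL * L - (thP + muP) * P
    dy[off + sl$M] <- fit$s_m * em - muA * M
    dF <- outer(fit$s_f * em, mf) - muA * Fm
    dy[off + sl$F] <- as.vector(dF)
  }
  mig <- network$migration
  if (n > 1 && any(mig > 0)) {
    adult <- c(sl$M, sl$F)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == b || mig[a, b] <= 0) next
      fl <- mig[a, b] * state[(a - 1) * S + adult]
      dy[(a - 1) * S + adult] <- dy[(a - 1) * S + adult] - fl
      dy[(b - 1) * S + adult] <- dy[(b - 1) * S + adult] + fl
    }
  }
  dy
}

## Dormand-Prince 5(4) adaptive step integrator (f autonomous within a day).
rk45_integrate <- function(f, y, t_span, rtol = 1e-8, atol = 1e-8, h0 = 0.25) {
  a <- list(c2 = 1 / 5, c3 = 3 / 10, c4 = 4 / 5, c5 = 8 / 9)
  t <- t_span[1]; t_end <- t_span[2]
  h <- min(h0, t_end - t)
  nstep <- 0L
  while (t < t_end - 1e-12) {
    h <- min(h, t_end - t)
    k1 <- f(y)
    k2 <- f(y + h * (1 / 5) * k1)
    k3 <- f(y + h * (3 / 40 * k1 + 9 / 40 * k2))
    k4 <- f(y + h * (44 / 45 * k1 - 56 / 15 * k2 + 32 / 9 * k3))
    k5 <- f(y + h * (19372 / 6561 * k1 - 25360 / 2187 * k2 +
                       64448 / 6561 * k3 - 212 / 729 * k4))
    k6 <- f(y + h * (9017 / 3168 * k1 - 355 / 33 * k2 + 46732 / 5247 * k3 +
                       49 / 176 * k4 - 5103 / 18656 * k5))
    y5 <- y + h * (35 / 384 * k1 + 500 / 1113 * k3 + 125 / 192 * k4 -
                     2187 / 6784 * k5 + 11 / 84 * k6)
    k7 <- f(y5)
    y4 <- y + h * (5179 / 57600 * k1 + 7571 / 16695 * k3 + 393 / 640 * k4 -
                     92097 / 339200 * k5 + 187 / 2100 * k6 + 1 / 40 * k7)
    err <- max(abs(y5 - y4) / (atol + rtol * pmax(abs(y), abs(y5))))
    if (is.na(err)) stop("integrator produced NaN")
    if (err <= 1) {
      t <- t + h
      y <- y5
    }
    fac <- if (err > 0) 0.9 * err^(-0.2) else 5
    h <- h * min(5, max(0.2, fac))
    nstep <- nstep + 1L
    if (nstep > 100000L) stop("integrator failed to converge (step limit)")
  }
  y
}

new_trajectory <- function(states, genotypes, network, mode, n_sub = NA) {
  structure(list(days = seq_len(nrow(states)), states = states,
                 genotypes = genotypes, network = network,
                 G = length(genotypes$labels), n_nodes = length(network$ids),
                 mode = mode, n_sub = n_sub),
            class = "vo_trajectory")
}

#' Simulate the dynamic (ODE) model
#'
#' Adaptive Runge-Kutta integration of [rhs_eval()] with daily
#' piecewise-constant temperatures. Release impulses are added to the adult
#' male compartment at the start of their day; the reported state at day t
#' includes that day's impulse. Day 1 equals the initial state (plus any
#' day-1 release).
#'
#' @param init Full state vector (all nodes), e.g. from
#'   [equilibrium_state()] or [node_state()].
#' @param temps Daily temperature input: a `data.frame(day, temp_C)`, a
#'   numeric vector, or a list with one of these per node.
#' @param network A [network()].
#' @param cube Inheritance cube.
#' @param schedule A [release_schedule()] (default: empty).
#' @param n_days Horizon in days (default: schedule horizon or series length).
#' @param rtol,atol Integrator tolerances.
#' @return A `vo_trajectory`: daily states (rows) clamped at 0 on output
#'   (tolerance -1e-9).
#' @export
simulate_ode <- function(init, temps, network, cube, schedule = NULL,
                         n_days = NULL, rtol = 1e-8, atol = 1e-8) {
  G <- length(cube$genotypes$labels)
  if (is.null(n_days))
    n_days <- if (!is.null(schedule)) schedule$horizon
              else if (is.data.frame(temps)) nrow(temps)
              else if (is.numeric(temps)) length(temps)
              else length(temps[[1]])
  if (is.null(schedule)) schedule <- empty_schedule(n_days, cube$genotypes)
  tl <- temps_per_node(temps, network, n_days)
  rel <- schedule_matrices(schedule, n_days, network, cube$genotypes)
  S <- state_dim(G)
  n <- length(network$ids)
  midx <- as.vector(vapply(seq_len(n),
                           function(k) (k - 1) * S + 3 * G + 1:G, numeric(G)))
  states <- matrix(0, n_days, n * S)
  y <- as.numeric(init)
  if (length(y) != n * S) stop("init has wrong length for this network")
  for (t in seq_len(n_days)) {
    y[midx] <- y[midx] + as.vector(vapply(seq_len(n),
                                          function(k) rel[[k]][t, ],
                                          numeric(G)))
    states[t, ] <- y
    if (t == n_days) break
    Tt <- vapply(tl, `[[`, 0, t)
    f <- function(z) rhs_eval(z, Tt, network, cube)
    y <- tryCatch(rk45_integrate(f, y, c(0, 1), rtol = rtol, atol = atol),
                  error = function(e)
                    stop("integrator failure on day ", t, ": ",
                         conditionMessage(e)))
  }
  if (min(states) < -1e-9)
    warning("states below -1e-9 encountered; clamped to 0 on output")
  states[states < 0] <- 0
  new_trajectory(states, cube$genotypes, network, mode = "ode")
}

# internal: cube pieces in the layout rollout_core expects
cube_arrays <- function(cube) {
  list(probs = as.numeric(cube$probs),
       s_f = as.numeric(cube$fitness$s_f), s_m = as.numeric(cube$fitness$s_m),
       eta = as.numeric(cube$fitness$eta), beta = as.numeric(cube$fitness$beta))
}

#' Discrete (explicit-Euler) rollout of the dynamics
#'
#' The discrete twin of [simulate_ode()]: explicit-Euler updates with step
#' `1/n_sub` day, temperatures held constant within a day, releases added to
#' the adult male compartment before the first substep of their day. The
#' update expressions are the same compiled code used by the decision-model
#' objective, which makes the transcription-consistency check exact.
#'
#' @inheritParams simulate_ode
#' @param n_sub Euler substeps per day (>= 1).
#' @param check Raise a stability error when any state dips below
#'   `-1e-6 * max(1, max|state|)` mid-rollout (advises a larger `n_sub`).
#' @return A `vo_trajectory` with `mode = "discrete"`.
#' @export
rollout_discrete <- function(init, temps, network, cube, schedule = NULL,
                             n_sub = 4, n_days = NULL, check = TRUE) {
  if (n_sub < 1) stop("n_sub must be >= 1")
  G <- length(cube$genotypes$labels)
  if (is.null(n_days))
    n_days <- if (!is.null(schedule)) schedule$horizon
              else if (is.data.frame(temps)) nrow(temps)
              else if (is.numeric(temps)) length(temps)
              else length(temps[[1]])
  if (is.null(schedule)) schedule <- empty_schedule(n_days, cube$genotypes)
  tl <- temps_per_node(temps, network, n_days)
  rates <- lapply(seq_along(tl), function(k)
    rate_table(network$nodes[[k]]$species, tl[[k]]))
  rel <- schedule_matrices(schedule, n_days, network, cube$genotypes)
  ca <- cube_arrays(cube)
  K <- vapply(network$nodes, `[[`, 0, "K")
  res <- rollout_core(as.numeric(init), as.integer(n_days),
                      as.integer(n_sub), as.integer(G),
                      rates, ca$probs, ca$s_f, ca$s_m, ca$eta, ca$beta,
                      K, network$migration, rel)
  if (check && res$min_state < -1e-6 * max(1, res$max_abs))
    stop("discrete rollout went negative (min state ",
         format(res$min_state), "); increase n_sub")
  traj <- new_trajectory(res$states, cube$genotypes, network,
                         mode = "discrete", n_sub = n_sub)
  traj
}

#' Steady state of the dynamics at constant temperature
#'
#' Computes the wildtype equilibrium of [rhs_eval()] at a constant reference
#' temperature for a single node: an analytic solve of the stage-balance
#' equations (density-dependent larval mortality pins total larvae) followed
#' by damped Newton polishing with a finite-difference Jacobian. When the
#' parameterization is non-viable (net reproduction below replacement) a
#' zero state is returned with a warning.
#'
#' @param species A [species_params()].
#' @param cube Inheritance cube (its first wild genotype is the resident).
#' @param K Larval carrying capacity.
#' @param T_ref Reference temperature (°C).
#' @param node_id Node id used for the throwaway single-node network.
#' @return Single-node state vector; attribute `residual` holds the final
#'   `||rhs||` (must satisfy `<= 1e-8 * ||state||`).
#' @export
equilibrium_state <- function(species, cube, K, T_ref, node_id = "node1") {
  G <- length(cube$genotypes$labels)
  g0 <- cube$genotypes$wild_idx[1]
  r <- stage_rates_at(T_ref, species)
  nu <- r$fecundity
  thE <- r$development[["egg"]]; muE <- r$mortality[["egg"]]
  thL <- r$development[["larva"]]; muL <- r$mortality[["larva"]]
  thP <- r$development[["pupa"]]; muP <- r$mortality[["pupa"]]
  muA <- r$mortality[["adult"]]
  fit <- cube$fitness
  A <- fit$beta[g0] * nu * thE * 0.5 * thP * thL * fit$s_f[g0] /
    ((thE + muE) * (thP + muP) * muA)
  y <- node_state(G)
  if (!is.finite(A) || A <= thL + muL) {
    warning("non-viable parameterization at T_ref = ", T_ref,
            " (no positive growth); returning zero state")
    attr(y, "residual") <- 0
    return(y)
  }
  L <- K * (A - thL - muL) / muL
  P <- thL * L / (thP + muP)
  Fq <- fit$s_f[g0] * 0.5 * thP * P / muA
  M <- fit$s_m[g0] * 0.5 * thP * P / muA
  E <- nu * fit$beta[g0] * Fq / (thE + muE)
  sl <- state_slots(G)
  y[sl$E[g0]] <- E; y[sl$L[g0]] <- L; y[sl$P[g0]] <- P; y[sl$M[g0]] <- M
  y[sl$F[1] - 1 + (g0 - 1) * G + g0] <- Fq
  net <- network(list(list(id = node_id, species = species, K = K)))
  f <- function(z) rhs_eval(z, T_ref, net, cube)
  # damped Newton polish
  res <- f(y)
  for (it in 1:40) {
    nr <- sqrt(sum(res^2))
    if (nr <= 1e-10 * (1 + sqrt(sum(y^2)))) break
    J <- matrix(0, length(y), length(y))
    h <- pmax(1e-6 * abs(y), 1e-8)
    for (j in seq_along(y)) {
      yp <- y; yp[j] <- yp[j] + h[j]
      ym <- y; ym[j] <- ym[j] - h[j]
      J[, j] <- (f(yp) - f(ym)) / (2 * h[j])
    }
    step <- tryCatch(solve(J, -res),
                     error = function(e)
                       solve(J + diag(1e-8, length(y)), -res))
    lam <- 1
    repeat {
      y2 <- y + lam * step
      res2 <- f(y2)
      if (sqrt(sum(res2^2)) < nr || lam < 1e-4) break
      lam <- lam / 2
    }
    y <- y2; res <- res2
  }
  nr <- sqrt(sum(res^2))
  if (nr > 1e-8 * sqrt(sum(y^2)))
    stop("equilibrium solve did not converge: ||rhs|| = ", format(nr),
         " vs state norm ", format(sqrt(sum(y^2))))
  attr(y, "residual") <- nr
  y
}

# internal: T x n_wild matrix of wild-genotype female counts
# (summed over mate genotype and over nodes)
wild_female_matrix <- function(traj, genotypes = traj$genotypes) {
  G <- traj$G
  S <- state_dim(G)
  wf <- matrix(0, nrow(traj$states), length(genotypes$wild_idx))
  for (k in seq_len(traj$n_nodes)) {
    off <- (k - 1) * S + 4 * G
    for (j in seq_along(genotypes$wild_idx)) {
      gf <- genotypes$wild_idx[j]
      cols <- off + (seq_len(G) - 1) * G + gf
      wf[, j] <- wf[, j] + rowSums(traj$states[, cols, drop = FALSE])
    }
  }
  wf
}

#' Wildtype adult female count at a day
#'
#' Sums mated adult females whose own genotype is in the wild subset, over
#' all mate genotypes and all nodes (the vector-competent population).
#'
#' @param traj A `vo_trajectory`.
#' @param t Day index within the horizon.
#' @param genotypes A [genotype_set()] (defaults to the trajectory's).
#' @return Scalar count.
#' @export
wild_female_count <- function(traj, t, genotypes = traj$genotypes) {
  if (t < 1 || t > nrow(traj$states)) stop("day ", t, " outside the horizon")
  sum(wild_female_matrix(traj, genotypes)[t, ])
}

#' Tidy data frame view of a trajectory
#'
#' One row per (day, node, stage, genotype) — mated females additionally
#' carry the mate genotype.
#'
#' @param traj A `vo_trajectory`.
#' @return Data frame with columns day, node, stage, genotype_female,
#'   genotype_male, count (genotype_male is NA except for stage "F").
#' @export
trajectory_to_df <- function(traj) {
  G <- traj$G; S <- state_dim(G)
  labels <- traj$genotypes$labels
  out <- vector("list", traj$n_nodes)
  stages <- c("E", "L", "P", "M")
  for (k in seq_len(traj$n_nodes)) {
    off <- (k - 1) * S
    parts <- list()
    for (si in seq_along(stages)) {
      cols <- off + (si - 1) * G + 1:G
      parts[[si]] <- data.frame(
        day = rep(traj$days, each = G), node = traj$network$ids[k],
        stage = stages[si], genotype_female = rep(labels, nrow(traj$states)),
        genotype_male = NA_character_,
        count = as.vector(t(traj$states[, cols, drop = FALSE])))
    }
    fc <- off + 4 * G + 1:(G * G)
    parts[[5]] <- data.frame(
      day = rep(traj$days, each = G * G), node = traj$network$ids[k],
      stage = "F",
      genotype_female = rep(rep(labels, G), nrow(traj$states)),
      genotype_male = rep(rep(labels, each = G), nrow(traj$states)),
      count = as.vector(t(traj$states[, fc, drop = FALSE])))
    out[[k]] <- do.call(rbind, parts)
  }
  do.call(rbind, out)
}
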