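test_that("rhs follows the stated conventions on degenerate states", {
  cube <- toy_cube()
  net <- toy_network()
  G <- 3; sl <- toy_slots()
  # extinction is absorbing
  expect_equal(rhs_eval(node_state(G), 25, net, cube), rep(0, 21))
  # all-wild state puts zero derivative mass on modified genotypes
  y <- node_state(G, E = c(10, 0, 0), L = c(5, 0, 0), P = c(2, 0, 0),
                  M = c(4, 0, 0), F = diag(c(3, 0, 0)))
  d <- rhs_eval(y, 25, net, cube)
  mod <- c(sl$E[2:3], sl$L[2:3], sl$P[2:3], sl$M[2:3],
           setdiff(sl$F, sl$F[1]))
  expect_true(all(d[mod] == 0))
  # no males: existing mated females still lay, but no new mated females
  y2 <- node_state(G, F = diag(c(3, 0, 0)), P = c(10, 0, 0))
  d2 <- rhs_eval(y2, 25, net, cube)
  expect_gt(d2[sl$E[1]], 0)                       # eggs from mated females
  expect_equal(d2[sl$F[1]], -0.1 * 3)             # mortality only, no mating
  expect_gt(d2[sl$M[1]], 0)                       # males still emerge
  expect_error(toy_network(K = 0), "carrying capacity")
})

test_that("Euler substep arithmetic is exact on a pure-mortality stage", {
  # adults only, muA = 0.1/day: x2 = 90 with one substep, 90.25 with two
  sp <- species_params(
    "decay",
    development = list(egg = const_resp(0), larva = const_resp(0),
                       pupa = const_resp(0)),
    mortality = list(egg = const_resp(0), larva = const_resp(0),
                     pupa = const_resp(0), adult = const_resp(0.1)),
    fecundity = const_resp(0), mort_floor = 0)
  cube <- toy_cube()
  net <- toy_network(species = sp)
  sl <- toy_slots()
  init <- node_state(3, M = c(100, 0, 0))
  t1 <- rollout_discrete(init, rep(25, 2), net, cube, n_sub = 1)
  expect_equal(t1$states[2, sl$M[1]], 90)
  t2 <- rollout_discrete(init, rep(25, 2), net, cube, n_sub = 2)
  expect_equal(t2$states[2, sl$M[1]], 100 * 0.95^2)
})

test_that("discrete rollout converges to the adaptive ODE integration", {
  inst <- toy_instance()
  eq <- equilibrium_state(inst$species, inst$cube, K = 200, T_ref = 25)
  y0 <- as.numeric(eq) * 0.5   # smooth relaxation transient
  tode <- simulate_ode(y0, rep(25, 30), inst$network, inst$cube)
  tdis <- rollout_discrete(y0, rep(25, 30), inst$network, inst$cube,
                           n_sub = 24)
  rel <- abs(tdis$states[30, ] - tode$states[30, ]) /
    (1 + abs(tode$states[30, ]))
  expect_lt(max(rel), 0.02)
})

test_that("release impulses raise adult males by exactly the released count", {
  inst <- toy_instance()
  sl <- toy_slots()
  eq <- equilibrium_state(inst$species, inst$cube, K = 200, T_ref = 25)
  sched <- release_schedule(
    data.frame(day = 10, node = "n1", genotype = "RR", count = 1234),
    horizon = 20, genotypes = inst$cube$genotypes)
  for (traj in list(
    rollout_discrete(eq, rep(25, 20), inst$network, inst$cube, sched),
    simulate_ode(eq, rep(25, 20), inst$network, inst$cube, sched))) {
    base <- rollout_discrete(eq, rep(25, 20), inst$network, inst$cube)
    expect_equal(traj$states[10, sl$M[3]] - base$states[10, sl$M[3]], 1234)
    expect_equal(traj$states[9, sl$M[3]], base$states[9, sl$M[3]])
  }
  # schedule validation
  expect_error(release_schedule(
    data.frame(day = 10, node = "n1", genotype = "WW", count = 1),
    20, inst$cube$genotypes), "modified subset")
  expect_error(release_schedule(
    data.frame(day = 30, node = "n1", genotype = "RR", count = 1),
    20, inst$cube$genotypes), "horizon")
  expect_error(release_schedule(
    data.frame(day = 10, node = "n1", genotype = "RR", count = -2),
    20, inst$cube$genotypes), ">= 0")
})

test_that("equilibrium_state satisfies the density-dependence balance", {
  sp <- toy_species()
  cube <- toy_cube()
  sl <- toy_slots()
  for (K in c(100, 200, 500)) {
    eq <- equilibrium_state(sp, cube, K = K, T_ref = 25)
    expect_lte(attr(eq, "residual"), 1e-8 * sqrt(sum(eq^2)))
    # oracle: analytic larval balance L = K (A - thL - muL) / muL
    expect_equal(sum(eq[sl$L]), toy_L_eq(K), tolerance = 1e-8)
  }
  # doubling K increases equilibrium larvae (density-dependence monotonicity)
  L1 <- sum(equilibrium_state(sp, cube, 200, 25)[sl$L])
  L2 <- sum(equilibrium_state(sp, cube, 400, 25)[sl$L])
  expect_gt(L2, L1)
  # oracle: long-run ODE integration from a perturbed start converges to it
  eq <- equilibrium_state(sp, cube, K = 200, T_ref = 25)
  traj <- simulate_ode(as.numeric(eq) * 1.7, rep(25, 400),
                       toy_network(K = 200, species = sp), cube)
  expect_equal(traj$states[400, ], as.numeric(eq), tolerance = 1e-4)
  # non-viable parameterization returns the zero state with a warning
  expect_warning(z <- equilibrium_state(toy_species(nu = 0), cube, 200, 25),
                 "non-viable")
  expect_equal(as.numeric(z), rep(0, 21))
})

test_that("transgene mass stays exactly zero without releases (discrete)", {
  inst <- toy_instance()
  eq <- equilibrium_state(inst$species, inst$cube, K = 200, T_ref = 25)
  traj <- rollout_discrete(eq, rep(25, 365), inst$network, inst$cube)
  sl <- toy_slots()
  mod_cols <- c(sl$E[2:3], sl$L[2:3], sl$P[2:3], sl$M[2:3],
                setdiff(sl$F, sl$F[1]))
  expect_identical(max(abs(traj$states[, mod_cols])), 0)
})

test_that("states stay non-negative across random viable parameterizations", {
  cube <- toy_cube()
  set.seed(42)
  for (rep_i in 1:5) {
    nu <- runif(1, 1.5, 6)
    muA <- runif(1, 0.08, 0.2)
    sp <- toy_species(nu = nu, muA = muA)
    net <- toy_network(K = runif(1, 50, 500), species = sp)
    eq <- suppressWarnings(equilibrium_state(sp, cube, net$nodes[[1]]$K, 25))
    y0 <- as.numeric(eq) * runif(21, 0.2, 2)
    traj <- rollout_discrete(y0, rep(25, 100), net, cube, n_sub = 8)
    expect_gte(min(traj$states), -1e-9)
    tode <- simulate_ode(y0, rep(25, 50), net, cube)
    expect_gte(min(tode$states), 0)  # clamped on output
  }
})

test_that("pure migration conserves total adults (discrete, 3 nodes)", {
  # births, deaths and stage transitions disabled
  sp <- species_params(
    "inert",
    development = list(egg = const_resp(0), larva = const_resp(0),
                       pupa = const_resp(0)),
    mortality = list(egg = const_resp(0), larva = const_resp(0),
                     pupa = const_resp(0), adult = const_resp(0)),
    fecundity = const_resp(0), mort_floor = 0)
  cube <- toy_cube()
  mig <- matrix(c(0, 0.02, 0.01,
                  0.03, 0, 0.02,
                  0.01, 0.04, 0), 3, 3, byrow = TRUE)
  diag(mig) <- 0
  net <- toy_network(species = sp, n_nodes = 3, migration = mig)
  init <- c(node_state(3, M = c(100, 10, 5), F = matrix(20, 3, 3)),
            node_state(3, M = c(50, 0, 0)),
            node_state(3))
  traj <- rollout_discrete(init, rep(25, 365), net, cube, n_sub = 4)
  totals <- rowSums(traj$states)
  expect_lt(max(abs(totals - totals[1])) / totals[1], 1e-9)
})

test_that("sustained large RIDL release suppresses wildtype females", {
  inst <- toy_instance(T_end = 200)
  eq <- equilibrium_state(inst$species, inst$cube, K = 200, T_ref = 25)
  sched <- release_schedule(
    data.frame(day = seq(1, 200, by = 7), node = "n1", genotype = "RR",
               count = 5e4),
    horizon = 200, genotypes = inst$cube$genotypes)
  base <- rollout_discrete(eq, rep(25, 200), inst$network, inst$cube)
  sup <- rollout_discrete(eq, rep(25, 200), inst$network, inst$cube, sched)
  expect_lt(wild_female_count(sup, 200), 0.1 * wild_female_count(base, 200))
})

test_that("wild_female_count sums wild-genotype females over mates", {
  inst <- toy_instance()
  G <- 3; S <- 21
  states <- matrix(0, 2, S)
  Fmat <- matrix(0, G, G)
  Fmat[1, 1] <- 3; Fmat[1, 2] <- 2   # WW females mated to WW and RW males
  Fmat[3, 3] <- 7                    # RR females: not wild
  states[2, 12 + 1:9] <- as.vector(Fmat)
  traj <- vectoropt:::new_trajectory(states, inst$cube$genotypes,
                                     inst$network, "discrete")
  expect_equal(wild_female_count(traj, 1), 0)
  expect_equal(wild_female_count(traj, 2), 5)
  expect_error(wild_female_count(traj, 3), "horizon")
})

test_that("trajectory tidy export matches the state matrix", {
  inst <- toy_instance()
  eq <- equilibrium_state(inst$species, inst$cube, K = 200, T_ref = 25)
  traj <- rollout_discrete(eq, rep(25, 5), inst$network, inst$cube)
  df <- trajectory_to_df(traj)
  expect_equal(nrow(df), 5 * 21)
  f11 <- df[df$stage == "F" & df$genotype_female == "WW" &
              df$genotype_male == "WW" & df$day == 3, "count"]
  sl <- toy_slots()
  expect_equal(f11, traj$states[3, sl$F[1]])
  m1 <- df[df$stage == "M" & df$genotype_female == "WW" & df$day == 2, "count"]
  expect_equal(m1, traj$states[2, sl$M[1]])
})
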