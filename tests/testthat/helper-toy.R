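# Toy fixtures built in code. The toy species has temperature-independent
# (constant-form) rates so dynamics are autonomous and analytic balance
# equations are available as oracles:
#   A = nu * thE * 0.5 * thP * thL / ((thE+muE)(thP+muP) muA)
#   L_eq = K (A - thL - muL) / muL   (positive iff A > thL + muL)

const_resp <- function(r) thermal_response("constant", c(rate = r))

toy_rates <- function(nu = 2) {
  list(nu = nu, thE = 0.4, muE = 0.05, thL = 0.2, muL = 0.1,
       thP = 0.3, muP = 0.05, muA = 0.1)
}

toy_species <- function(nu = 2, muA = 0.1, name = "toy") {
  r <- toy_rates(nu)
  species_params(
    name,
    development = list(egg = const_resp(r$thE), larva = const_resp(r$thL),
                       pupa = const_resp(r$thP)),
    mortality = list(egg = const_resp(r$muE), larva = const_resp(r$muL),
                     pupa = const_resp(r$muP), adult = const_resp(muA)),
    fecundity = const_resp(nu))
}

toy_cube <- function(eps = 1) apply_ridl(mendelian_cube(), penetrance = eps)

toy_network <- function(K = 200, species = toy_species(), n_nodes = 1,
                        migration = NULL) {
  nodes <- lapply(seq_len(n_nodes), function(i)
    list(id = paste0("n", i), species = species, K = K))
  network(nodes, migration)
}

# analytic equilibrium larvae for the toy species (density-balance oracle)
toy_L_eq <- function(K, nu = 2) {
  r <- toy_rates(nu)
  A <- nu * r$thE * 0.5 * r$thP * r$thL /
    ((r$thE + r$muE) * (r$thP + r$muP) * r$muA)
  K * (A - r$thL - r$muL) / r$muL
}

toy_slots <- function(G = 3) vectoropt:::state_slots(G)

# temperature-sensitive toy: unimodal development/fecundity, linear adult
# mortality; viable and Euler-stable (n_sub = 4) for temperatures ~23-28 C
toy_species_thermal <- function() {
  species_params(
    "toy_thermal",
    development = list(
      egg = thermal_response("briere", c(a = 2.13e-4, T_min = 13.35,
                                         T_max = 40.08)),
      larva = thermal_response("quadratic", c(c = 1e-3, T_min = 10,
                                              T_max = 40)),
      pupa = thermal_response("briere", c(a = 3e-4, T_min = 11.36,
                                          T_max = 39.67))),
    mortality = list(
      egg = const_resp(0.05), larva = const_resp(0.1), pupa = const_resp(0.05),
      adult = thermal_response("linear", c(intercept = 0.02, slope = 0.003),
                               floor = 0.02)),
    fecundity = thermal_response("quadratic", c(c = 2.2e-2, T_min = 15,
                                                T_max = 35)))
}

# small deterministic toy decision instance (constant 25 C temperatures)
toy_instance <- function(T_end = 120, t0 = 60, psi = 0.2,
                         mask = weekly_mask(30, T_end), K = 200,
                         c_max = 1e5, n_sub = 4) {
  sp <- toy_species()
  cube <- toy_cube()
  net <- toy_network(K = K, species = sp)
  spec <- decision_spec(T_end = T_end, t0 = t0, psi = psi, mask = mask,
                        c_max = c_max, n_sub = n_sub)
  list(species = sp, cube = cube, network = net, spec = spec,
       temps = rep(25, T_end))
}

# minimal YAML run configuration on the toy species (inline custom species)
write_toy_config <- function(path, T_end = 90, t0 = 45, n_scenarios = 1,
                             mask_start = 20, c_max = 1e5, maxit = 200,
                             seeds = seq_len(n_scenarios)) {
  cfg <- list(
    species = list(custom = list(
      name = "toy",
      development = list(
        egg = list(form = "constant", params = list(rate = 0.4)),
        larva = list(form = "constant", params = list(rate = 0.2)),
        pupa = list(form = "constant", params = list(rate = 0.3))),
      mortality = list(
        egg = list(form = "constant", params = list(rate = 0.05)),
        larva = list(form = "constant", params = list(rate = 0.1)),
        pupa = list(form = "constant", params = list(rate = 0.05)),
        adult = list(form = "constant", params = list(rate = 0.1))),
      fecundity = list(form = "constant", params = list(rate = 2)))),
    genetics = list(penetrance = 1.0),
    network = list(nodes = list(list(id = "site1", K = 200))),
    scenarios = list(generator = list(
      params = lapply(seeds, function(s)
        list(T_mean = 25, amplitude = 0.5, daily_sd = 0.3, seed = s)),
      T_end = T_end)),
    decision = list(psi = 0.2, t0 = t0, T_end = T_end,
                    mask = list(type = "weekly", start = mask_start),
                    c_max = c_max),
    solver = list(maxit = maxit))
  yaml::write_yaml(cfg, path)
  path
}
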