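## Genotype bookkeeping: genotype sets, the inheritance cube (offspring
## genotype distribution per parental cross), and RIDL dominant-lethal
## fitness modifiers.

#' Genotype set
#'
#' The ordered set G of genotypes, partitioned into the wild subset (no
#' transgene) and the modified subset (construct carriers). The label order
#' is the canonical state ordering used everywhere in the package.
#'
#' @param labels Character vector of genotype names, e.g. `c("WW","RW","RR")`.
#' @param wild Labels (or indices) of wildtype genotypes.
#' @param modified Labels (or indices) of modified genotypes.
#' @param allele_counts Optional matrix (genotype x allele) of allele copy
#'   numbers.
#' @return Object of class `genotype_set`.
#' @export
genotype_set <- function(labels, wild, modified, allele_counts = NULL) {
  if (is.numeric(wild)) wild <- labels[wild]
  if (is.numeric(modified)) modified <- labels[modified]
  if (length(intersect(wild, modified)) > 0)
    stop("wild and modified subsets must be disjoint")
  if (!setequal(union(wild, modified), labels))
    stop("wild and modified subsets must partition the genotype labels")
  structure(list(labels = labels,
                 wild = wild, modified = modified,
                 wild_idx = match(wild, labels),
                 modified_idx = match(modified, labels),
                 allele_counts = allele_counts),
            class = "genotype_set")
}

new_cube <- function(probs, genotypes, fitness) {
  structure(list(probs = probs, genotypes = genotypes, fitness = fitness),
            class = "inheritance_cube")
}

#' Single-locus Mendelian inheritance cube
#'
#' Builds the inheritance cube for one biallelic locus (wild allele first,
#' construct allele second), with genotypes ordered homozygous-wild,
#' heterozygous, homozygous-construct (e.g. WW, RW, RR). Offspring
#' distributions follow Mendelian segregation; all fitness modifiers
#' (egg-to-adult survival `s` applied at emergence, separately for females
#' `s_f` and males `s_m`; male mating weight `eta`; female fecundity factor
#' `beta`) are initialized to 1.
#'
#' @param alleles Length-2 character vector, wild allele first.
#' @return Object of class `inheritance_cube`; element `genotypes` is the
#'   corresponding [genotype_set()].
#' @export
mendelian_cube <- function(alleles = c("W", "R")) {
  if (length(alleles) != 2) stop("exactly two alleles are required")
  w <- alleles[1]; r <- alleles[2]
  labels <- c(paste0(w, w), paste0(r, w), paste0(r, r))
  counts <- matrix(c(2, 1, 0, 0, 1, 2), nrow = 3,
                   dimnames = list(labels, c(w, r)))
  gs <- genotype_set(labels, wild = labels[1], modified = labels[2:3],
                     allele_counts = counts)
  # gamete distribution over alleles per genotype
  gam <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1))
  G <- 3
  probs <- array(0, dim = c(G, G, G),
                 dimnames = list(labels, labels, labels))
  for (gf in 1:G) for (gm in 1:G)
    for (af in 1:2) for (am in 1:2) {
      off <- sort(c(af, am))  # 1,1 -> WW; 1,2 -> RW; 2,2 -> RR
      go <- if (off[1] == 1 && off[2] == 1) 1 else if (off[2] == 2 && off[1] == 1) 2 else 3
      probs[gf, gm, go] <- probs[gf, gm, go] + gam[gf, af] * gam[gm, am]
    }
  fitness <- list(s_f = setNames(rep(1, G), labels),
                  s_m = setNames(rep(1, G), labels),
                  eta = setNames(rep(1, G), labels),
                  beta = setNames(rep(1, G), labels))
  new_cube(probs, gs, fitness)
}

#' Apply RIDL dominant lethality to a cube
#'
#' Sets the emergence survival of every genotype carrying at least one copy
#' of the construct allele to `1 - penetrance` (late-acting bi-sex lethality
#' applied at pupa-to-adult emergence). With `female_only = TRUE` (fsRIDL)
#' only emerging females are affected. Mating weights and fecundity factors
#' are left unchanged. Idempotent at the same penetrance.
#'
#' @param cube An [mendelian_cube()]-style cube.
#' @param penetrance Lethality penetrance in `[0, 1]` (default 1).
#' @param female_only Apply lethality only to emerging females (fsRIDL).
#' @return The modified cube.
#' @export
apply_ridl <- function(cube, penetrance = 1, female_only = FALSE) {
  stopifnot(inherits(cube, "inheritance_cube"))
  if (penetrance < 0 || penetrance > 1)
    stop("penetrance must lie in [0, 1]")
  carriers <- cube$genotypes$modified
  cube$fitness$s_f[carriers] <- 1 - penetrance
  if (!female_only) cube$fitness$s_m[carriers] <- 1 - penetrance
  else cube$fitness$s_m[carriers] <- 1
  cube
}

#' Offspring genotype distribution for one cross
#'
#' @param cube An inheritance cube.
#' @param g_f,g_m Maternal and paternal genotype labels.
#' @return Named numeric vector over genotypes, summing to 1.
#' @export
offspring_distribution <- function(cube, g_f, g_m) {
  labels <- cube$genotypes$labels
  if (!(g_f %in% labels)) stop("unknown genotype: ", g_f)
  if (!(g_m %in% labels)) stop("unknown genotype: ", g_m)
  cube$probs[g_f, g_m, ]
}

#' Validate an inheritance cube
#'
#' Checks row normalization (tolerance 1e-12), probability non-negativity,
#' and fitness-modifier bounds (`s` in `[0,1]`, `eta >= 0`, `beta >= 0`).
#' Reports rather than raises.
#'
#' @param cube An inheritance cube.
#' @return Character vector of violations; empty when valid.
#' @export
validate_cube <- function(cube) {
  out <- character(0)
  labels <- cube$genotypes$labels
  G <- length(labels)
  for (gf in 1:G) for (gm in 1:G) {
    row <- cube$probs[gf, gm, ]
    if (any(row < 0))
      out <- c(out, sprintf("negative probability in cross (%s, %s)",
                            labels[gf], labels[gm]))
    if (abs(sum(row) - 1) > 1e-12)
      out <- c(out, sprintf("cross (%s, %s) row sums to %.15g, not 1",
                            labels[gf], labels[gm], sum(row)))
  }
  for (f in c("s_f", "s_m")) {
    v <- cube$fitness[[f]]
    if (any(v < 0 | v > 1))
      out <- c(out, paste0(f, " outside [0, 1] for: ",
                           paste(labels[v < 0 | v > 1], collapse = ", ")))
  }
  for (f in c("eta", "beta")) {
    v <- cube$fitness[[f]]
    if (any(v < 0))
      out <- c(out, paste0(f, " negative for: ",
                           paste(labels[v < 0], collapse = ", ")))
  }
  out
}
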