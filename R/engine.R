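#' Two-sex population state
#'
#' The state of the deterministic model is the joint frequency distribution
#' over (sex, genotype).  Frequencies are non-negative and sum to one across
#' both sexes; releases and offspring are produced at a 1:1 sex ratio, so in
#' the absence of sex-specific effects the female and male marginals stay
#' identical.
#'
#' @param gset a [enumerate_genotypes()] genotype set.
#' @param female,male numeric vectors of genotype frequencies (one entry per
#'   genotype, in the canonical genotype order).  Together they must sum to 1.
#' @return an object of class `population_state`: a 2 x n matrix with rows
#'   `female`, `male` and genotype labels as column names.
#' @export
population_state <- function(gset, female, male) {
  stopifnot(inherits(gset, "genotype_set"))
  if (length(female) != gset$n || length(male) != gset$n)
    stop("frequency vectors must have one entry per genotype", call. = FALSE)
  if (any(female < 0) || any(male < 0))
    stop("genotype frequencies must be non-negative", call. = FALSE)
  tot <- sum(female) + sum(male)
  if (abs(tot - 1) > 1e-9)
    stop("population state must sum to 1 (got ", format(tot), ")", call. = FALSE)
  m <- rbind(female = as.numeric(female), male = as.numeric(male))
  colnames(m) <- gset$labels
  structure(m, class = c("population_state", "matrix", "array"))
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state> ", ncol(x), " genotypes x 2 sexes\n", sep = "")
  nz <- which(colSums(x) > 1e-12)
  print(round(unclass(x)[, nz, drop = FALSE], 6))
  invisible(x)
}

#' Allele frequencies of a population state
#'
#' Population-level frequency of each tracked allele (transgenic constructs
#' A, B, C and the resistance allele R, whichever exist in the model), i.e.
#' copies carried divided by two gene copies per individual at that locus,
#' pooled over both sexes.
#'
#' @param pop a [population_state()].
#' @param model a drive model (see [sdkr_model()]).
#' @return named numeric vector of allele frequencies.
#' @export
allele_frequencies <- function(pop, model) {
  w <- colSums(unclass(pop))
  drop(w %*% model$copies) / 2
}

# nG x nH^2 collapse matrix: column (h2 - 1) * nH + h1 (egg haplotype h1,
# sperm haplotype h2, column-major order of outer(eggs, sperm)) carries a 1 in
# the row of the genotype formed by the per-locus unordered allele pairs.
build_collapse <- function(gset) {
  nH <- nrow(gset$haplotypes)
  nl <- length(gset$loci)
  # label-free lookup: map per-locus sorted pair to the genotype row
  key <- function(pairs) apply(pairs, 1L, paste, collapse = ".")
  geno_key <- key(gset$pairs)
  C <- matrix(0, gset$n, nH * nH)
  for (h2 in seq_len(nH)) {
    for (h1 in seq_len(nH)) {
      pr <- integer(2L * nl)
      for (l in seq_len(nl)) {
        a <- sort(c(gset$haplotypes[h1, l], gset$haplotypes[h2, l]))
        pr[2L * l - 1L] <- a[1L]
        pr[2L * l]      <- a[2L]
      }
      g <- match(paste(pr, collapse = "."), geno_key)
      C[g, (h2 - 1L) * nH + h1] <- 1
    }
  }
  C
}

# build the nG x nH gamete matrix from a model's per-locus segregation rule.
# segregation(gset, g, l) returns a probability vector over the alleles of
# locus l for genotype g; unlinked loci recombine freely, so the haplotype
# distribution is the product over loci.
build_gamete_matrix <- function(gset, segregation) {
  nH <- nrow(gset$haplotypes)
  G <- matrix(0, gset$n, nH)
  for (g in seq_len(gset$n)) {
    per_locus <- lapply(seq_along(gset$loci), function(l) {
      p <- segregation(gset, g, l)
      if (length(p) != gset$n_alleles[l] || any(p < -1e-12))
        stop("segregation rule produced an invalid allele distribution for ",
             gset$labels[g], " at locus ", gset$locus_names[l], call. = FALSE)
      if (abs(sum(p) - 1) > 1e-9)
        stop("segregation rule not normalized for ", gset$labels[g],
             " at locus ", gset$locus_names[l], call. = FALSE)
      p
    })
    for (h in seq_len(nH)) {
      pr <- 1
      for (l in seq_along(gset$loci))
        pr <- pr * per_locus[[l]][gset$haplotypes[h, l]]
      G[g, h] <- pr
    }
  }
  G
}

# Mendelian segregation: each allele of the pair with probability 1/2.
mendelian_segregation <- function(gset, g, l) {
  k <- gset$n_alleles[l]
  p <- numeric(k)
  a1 <- gset$pairs[g, 2L * l - 1L]
  a2 <- gset$pairs[g, 2L * l]
  p[a1] <- p[a1] + 0.5
  p[a2] <- p[a2] + 0.5
  p
}

#' Gamete distribution of a genotype
#'
#' Probability distribution over gamete haplotypes produced by one genotype
#' under the model's germline distortion rules.  Undistorted loci segregate
#' Mendelianly; distorted loci (homing) follow the model's cut/repair rule.
#' Because the loci are unlinked, the haplotype distribution factorizes as
#' the product of the per-locus allele distributions.
#'
#' @param model a drive model.
#' @param genotype genotype index or label.
#' @return named numeric vector over haplotypes, summing to 1.
#' @examples
#' m <- sdkr_model(drive_params(phi = 0.9, eps = 0.95, L = 1))
#' gamete_distribution(m, "A/wt;B/B")
#' @export
gamete_distribution <- function(model, genotype) {
  g <- resolve_genotype(model$gset, genotype)
  stats::setNames(model$G[g, ], model$gset$hap_labels)
}

resolve_genotype <- function(gset, genotype) {
  if (is.character(genotype)) {
    g <- match(genotype, gset$labels)
    if (is.na(g)) stop("unknown genotype label: ", genotype, call. = FALSE)
    g
  } else {
    g <- as.integer(genotype)
    if (g < 1L || g > gset$n) stop("genotype index out of range", call. = FALSE)
    g
  }
}

#' Offspring genotype distribution of a cross
#'
#' Random union of one maternal and one paternal gamete: the probability of
#' an (unordered) offspring genotype is the sum over all ordered haplotype
#' pairs that collapse to it.
#'
#' @param maternal,paternal named haplotype probability vectors, as returned
#'   by [gamete_distribution()]; both must be over the same haplotype set.
#' @param gset the [enumerate_genotypes()] genotype set the haplotypes
#'   belong to.
#' @return named numeric vector over genotypes, summing to 1.
#' @export
offspring_distribution <- function(maternal, paternal, gset) {
  stopifnot(inherits(gset, "genotype_set"))
  if (length(maternal) != nrow(gset$haplotypes) ||
      length(paternal) != nrow(gset$haplotypes))
    stop("gamete distributions must cover the model's haplotype set",
         call. = FALSE)
  if (!is.null(names(maternal)) && !is.null(names(paternal)) &&
      !identical(names(maternal), names(paternal)))
    stop("maternal and paternal gamete distributions are over different ",
         "haplotype sets", call. = FALSE)
  C <- build_collapse(gset)
  z <- drop(C %*% as.vector(outer(as.numeric(maternal), as.numeric(paternal))))
  stats::setNames(z, gset$labels)
}

#' Zygote-to-adult survival weight of a genotype
#'
#' The product of toxin viability and multiplicative fitness: a genotype
#' carrying the lethal effector (one or more A) without any rescue copy (B)
#' survives its lethal effect with probability 1 - L, and fitness costs are
#' applied multiplicatively over the transgenic material carried (per allele
#' copy by default; see [drive_params()] for the dominant per-construct
#' alternative).  The all-wild-type genotype has weight 1.
#'
#' @param model a drive model.
#' @param genotype genotype index or label.
#' @return survival probability in \[0, 1\].
#' @export
survival_weight <- function(model, genotype) {
  g <- resolve_genotype(model$gset, genotype)
  unname(model$w[g])
}

#' Apply sex-specific suppression effects to zygote classes
#'
#' Suppression effectors act on females carrying construct A at the
#' zygote-to-adult stage, after toxin viability and fitness survival.  With
#' `mode = "sex_conversion"` a fraction delta of each affected female class
#' is moved into the same genotype's male class (converted individuals are
#' fertile males), conserving total mass.  With `mode = "female_lethality"`
#' a fraction gamma of each affected female class is removed, reducing mass.
#' Affected classes carry at least one A copy (dominant) or are A/A
#' homozygous (recessive).
#'
#' @param zygotes list with numeric elements `female` and `male` (surviving
#'   zygote masses per genotype, not necessarily normalized).
#' @param model a drive model carrying a [suppression_params()] object.
#' @return list with adjusted `female` and `male` vectors.
#' @export
apply_sex_effects <- function(zygotes, model) {
  sp <- model$suppression
  f <- as.numeric(zygotes$female)
  m <- as.numeric(zygotes$male)
  if (is.null(sp) || sp$mode == "none")
    return(list(female = f, male = m))
  affected <- model$affected_female
  moved <- sp$rate * f * affected
  if (sp$mode == "sex_conversion") {
    list(female = f - moved, male = m + moved)
  } else if (sp$mode == "female_lethality") {
    list(female = f - moved, male = m)
  } else {
    stop("unknown suppression mode: ", sp$mode, call. = FALSE)
  }
}

# fast inner step on raw frequency vectors; returns pre-normalization masses.
# life-cycle order: mating -> zygotes -> 1:1 sex assignment -> viability and
# fitness survival -> sex-specific suppression effects -> renormalization.
step_core <- function(model, f, m) {
  fs <- sum(f)
  ms <- sum(m)
  if (fs <= 0 || ms <= 0)
    stop_annihilated("population annihilated: no fertile ",
                     if (fs <= 0) "females" else "males", " remain")
  eggs <- drop(crossprod(model$G, f / fs))
  sperm <- drop(crossprod(model$G, m / ms))
  z <- drop(model$collapse %*% as.vector(outer(eggs, sperm)))
  zs <- 0.5 * z * model$w
  zf <- zs
  zm <- zs
  sp <- model$suppression
  if (!is.null(sp) && sp$mode != "none" && sp$rate > 0) {
    moved <- sp$rate * zf * model$affected_female
    zf <- zf - moved
    if (sp$mode == "sex_conversion") zm <- zm + moved
  }
  female_mass <- sum(zf)
  male_mass <- sum(zm)
  mass <- female_mass + male_mass
  if (mass <= 0)
    stop_annihilated("population annihilated: no surviving zygotes")
  list(f = zf / mass, m = zm / mass,
       mass = mass, female_mass = female_mass, male_mass = male_mass)
}

stop_annihilated <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("sdkr_annihilation", "error")))
}

#' Advance the population by one generation
#'
#' One discrete, non-overlapping generation: adults mate at random with
#' contributions proportional to their frequencies, zygotes are formed from
#' the pooled maternal and paternal gamete distributions (germline distortion
#' applies in both sexes), assigned 1:1 to the sexes, subjected to viability
#' and fitness survival and then to any sex-specific suppression effect, and
#' finally renormalized.  The pre-normalization masses are retained because
#' the genetic load is defined from them (see [genetic_load()]).
#'
#' @param pop a [population_state()].
#' @param model a drive model.
#' @return an object of class `generation_step` with elements `state` (the
#'   new [population_state()]), `mass` (pre-normalization total surviving
#'   mass per wild-type zygote equivalent), `female_mass` and `male_mass`.
#'   Signals an error of class `sdkr_annihilation` if no mass survives.
#' @export
generation_step <- function(pop, model) {
  stopifnot(inherits(pop, "population_state"))
  res <- step_core(model, unclass(pop)["female", ], unclass(pop)["male", ])
  structure(list(
    state = population_state(model$gset, res$f, res$m),
    mass = res$mass,
    female_mass = res$female_mass,
    male_mass = res$male_mass
  ), class = "generation_step")
}
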