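#' Drive parameters
#'
#' Parameters shared by all model variants.  `phi` is the homing (HDR) rate:
#' the probability that a cut wild-type allele is repaired using the drive
#' construct as template.  `cleavage` is the probability that an eligible
#' wild-type target is cut at all; it is fixed at 1 in the base model and is
#' only meaningful in the end-joining (NHEJ) variant, where uncut targets
#' stay wild-type and cut-but-not-homed targets become resistance alleles.
#' `eps` is the per-construct relative fitness (applied multiplicatively),
#' `eps_R` the analogous factor for the resistance allele, and `L` the
#' lethal penetrance: the probability that a toxin-bearing, rescue-lacking
#' genotype dies.
#'
#' Under the default `cost_basis = "per_copy"` each transgenic allele copy
#' carried contributes one factor of `eps` (a double homozygote of a
#' two-construct system has fitness `eps^4`) and each R copy one factor of
#' `eps_R`.  The alternative `"per_construct"` basis applies `eps` once per
#' distinct construct type carried (dominant costs) and `eps_R` once if any
#' R is carried.  The per-copy basis reproduces the published tolerable-cost
#' and threshold behaviour of these systems; see the methods vignette.
#'
#' @param phi homing rate in \[0, 1\].
#' @param eps per-construct relative fitness in (0, 1].
#' @param L lethal penetrance in \[0, 1\].
#' @param cleavage cut probability in \[0, 1\] (NHEJ model only; 1 otherwise).
#' @param eps_R resistance-allele relative fitness in (0, 1].
#' @param cost_basis `"per_copy"` (default) or `"per_construct"`; see above.
#' @return object of class `drive_params`.
#' @export
drive_params <- function(phi, eps, L, cleavage = 1, eps_R = 1,
                         cost_basis = c("per_copy", "per_construct")) {
  cost_basis <- match.arg(cost_basis)
  check_prob(phi, "phi")
  check_prob(eps, "eps")
  check_prob(L, "L")
  check_prob(cleavage, "cleavage")
  check_prob(eps_R, "eps_R")
  if (eps <= 0) stop("`eps` must be > 0", call. = FALSE)
  if (eps_R <= 0) stop("`eps_R` must be > 0", call. = FALSE)
  structure(list(phi = phi, eps = eps, L = L, cleavage = cleavage,
                 eps_R = eps_R, cost_basis = cost_basis),
            class = "drive_params")
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("`", name, "` must be a single number in [0, 1]", call. = FALSE)
  invisible(x)
}

#' Suppression parameters
#'
#' Configuration of the population-suppression effector carried on construct
#' A.  `sex_conversion` turns a fraction `rate` (delta) of affected females
#' into fertile males; `female_lethality` kills a fraction `rate` (gamma) of
#' affected females.  `dominance` decides which females are affected: any A
#' carrier (`"dominant"`) or A/A homozygotes only (`"recessive"`).
#' `migration` is the per-generation unidirectional migration rate used by
#' the two-deme model (see [two_deme_step()]).
#'
#' @param mode one of `"none"`, `"sex_conversion"`, `"female_lethality"`.
#' @param dominance `"dominant"` or `"recessive"`.
#' @param rate effect probability delta or gamma in \[0, 1\].
#' @param migration per-generation migration rate m in \[0, 1\].
#' @return object of class `suppression_params`.
#' @export
suppression_params <- function(mode = c("none", "sex_conversion",
                                        "female_lethality"),
                               dominance = c("dominant", "recessive"),
                               rate = 0, migration = 0.02) {
  mode <- match.arg(mode)
  dominance <- match.arg(dominance)
  check_prob(rate, "rate")
  check_prob(migration, "migration")
  structure(list(mode = mode, dominance = dominance, rate = rate,
                 migration = migration), class = "suppression_params")
}

# assemble the shared model skeleton
new_drive_model <- function(name, gset, params, suppression, segregation) {
  copies_A <- allele_copies(gset, "A", "A")
  copies_B <- allele_copies(gset, "B", "B")
  copies_C <- allele_copies(gset, "C", "C")
  copies_R <- allele_copies(gset, "A", "R")

  tracked <- list(A = copies_A, B = copies_B)
  if ("C" %in% gset$locus_names) tracked$C <- copies_C
  if (any(copies_R > 0) || "R" %in% gset$loci[[1L]]$alleles)
    tracked$R <- copies_R
  copies <- do.call(cbind, tracked)

  # viability x fitness: multiplicative costs (per allele copy by default,
  # per construct type under the dominant-cost basis), genotype-level lethal
  # penetrance (>=1 toxin, 0 rescue)
  if (identical(params$cost_basis, "per_construct")) {
    n_cost <- (copies_A > 0) + (copies_B > 0) + (copies_C > 0)
    r_cost <- copies_R > 0
  } else {
    n_cost <- copies_A + copies_B + copies_C
    r_cost <- copies_R
  }
  w <- params$eps^n_cost * params$eps_R^r_cost
  lethal <- copies_A > 0 & copies_B == 0
  w[lethal] <- w[lethal] * (1 - params$L)

  affected <- if (suppression$dominance == "dominant") copies_A >= 1
              else copies_A == 2

  structure(list(
    name = name,
    params = params,
    suppression = suppression,
    gset = gset,
    G = build_gamete_matrix(gset, segregation),
    collapse = build_collapse(gset),
    w = as.numeric(w),
    copies = copies,
    affected_female = as.numeric(affected)
  ), class = "drive_model")
}

#' @export
print.drive_model <- function(x, ...) {
  p <- x$params
  cat("<drive_model> ", x$name, ": ", x$gset$n, " genotypes\n",
      "  phi = ", p$phi, ", eps = ", p$eps, ", L = ", p$L,
      if (x$name == "nhej") paste0(", cleavage = ", p$cleavage,
                                   ", eps_R = ", p$eps_R),
      "\n", sep = "")
  if (x$suppression$mode != "none")
    cat("  suppression: ", x$suppression$dominance, " ",
        x$suppression$mode, ", rate = ", x$suppression$rate, "\n", sep = "")
  invisible(x)
}

# pair at locus l is {a1, a2} (unordered)?
pair_is <- function(gset, g, l, a1, a2) {
  i <- match(a1, gset$loci[[l]]$alleles)
  j <- match(a2, gset$loci[[l]]$alleles)
  p <- sort(c(i, j))
  gset$pairs[g, 2L * l - 1L] == p[1L] && gset$pairs[g, 2L * l] == p[2L]
}

#' Split-drive killer-rescue model
#'
#' The two-locus base system: construct A carries a dominant toxin and the
#' sgRNA targeting wild-type locus A; construct B carries Cas9 and the
#' antidote.  In A/wt heterozygotes that carry at least one B, the wild-type
#' allele at A is converted to A in the germline with probability `phi`, so
#' such individuals transmit A with probability (1 + phi) / 2.  All cutting
#' is assumed productive (cleavage fixed at 1); see [nhej_model()] for the
#' variant with end-joining repair.  Genotypes with the toxin but no rescue
#' die with probability `L`; each construct carried multiplies fitness by
#' `eps`.  Killer-rescue (`phi = 0`, `L = 1`) and split drive (`phi > 0`,
#' `L = 0`) are special cases.
#'
#' @param params a [drive_params()] object (`cleavage` and `eps_R` ignored).
#' @param suppression a [suppression_params()] object; the suppression
#'   effector rides on construct A.
#' @return object of class `drive_model` over 9 genotypes.
#' @examples
#' m <- sdkr_model(drive_params(phi = 0.9, eps = 0.95, L = 1))
#' survival_weight(m, "A/A;wt/wt")  # killed by unrescued toxin
#' @export
sdkr_model <- function(params, suppression = suppression_params()) {
  stopifnot(inherits(params, "drive_params"),
            inherits(suppression, "suppression_params"))
  gset <- enumerate_genotypes(list(locus("A", c("wt", "A")),
                                   locus("B", c("wt", "B"))))
  copies_B <- allele_copies(gset, "B", "B")
  phi <- params$phi
  seg <- function(gs, g, l) {
    if (l == 1L && phi > 0 && copies_B[g] >= 1 && pair_is(gs, g, 1L, "wt", "A")) {
      c(wt = (1 - phi) / 2, A = (1 + phi) / 2)
    } else {
      mendelian_segregation(gs, g, l)
    }
  }
  new_drive_model("sdkr", gset, params, suppression, seg)
}

#' SDKR with end-joining resistance alleles
#'
#' Extends [sdkr_model()] with the alternative double-strand-break repair
#' outcome: in A/wt genotypes carrying at least one B, the wild-type allele
#' at A is cut with probability `cleavage`; a cut allele is repaired by HDR
#' (becoming A) with probability `phi` or by end-joining (becoming the
#' resistance allele R) with probability 1 - phi.  R destroys the sgRNA
#' target site and is never cut again, and genotypes without a wild-type A
#' allele (A/A, A/R, R/R) offer nothing to cut.  Carrying any R multiplies
#' fitness by `eps_R` once (dominant cost); R carries no toxin.
#'
#' @inheritParams sdkr_model
#' @return object of class `drive_model` over 18 genotypes.
#' @examples
#' m <- nhej_model(drive_params(phi = 0.8, eps = 0.95, L = 1, cleavage = 0.95))
#' gamete_distribution(m, "wt/A;wt/B")
#' @export
nhej_model <- function(params, suppression = suppression_params()) {
  stopifnot(inherits(params, "drive_params"),
            inherits(suppression, "suppression_params"))
  gset <- enumerate_genotypes(list(locus("A", c("wt", "A", "R")),
                                   locus("B", c("wt", "B"))))
  copies_B <- allele_copies(gset, "B", "B")
  phi <- params$phi
  cv <- params$cleavage
  seg <- function(gs, g, l) {
    if (l == 1L && cv > 0 && copies_B[g] >= 1 && pair_is(gs, g, 1L, "wt", "A")) {
      c(wt = (1 - cv) / 2,
        A  = (1 + cv * phi) / 2,
        R  = cv * (1 - phi) / 2)
    } else {
      mendelian_segregation(gs, g, l)
    }
  }
  new_drive_model("nhej", gset, params, suppression, seg)
}

#' Daisy-drive killer-rescue model
#'
#' Adds a third unlinked construct C carrying a sgRNA that directs Cas9 to
#' cut the wild-type sequence at locus B, so construct B itself homes in
#' B/wt genotypes that carry at least one C (Cas9 is supplied by the B
#' allele, present by construction in such genotypes).  Distortion at locus
#' A is exactly as in [sdkr_model()]; locus C is never distorted.  Fitness
#' is `eps` per distinct construct carried, up to `eps^3`.
#'
#' @inheritParams sdkr_model
#' @return object of class `drive_model` over 27 genotypes.
#' @export
ddkr_model <- function(params, suppression = suppression_params()) {
  stopifnot(inherits(params, "drive_params"),
            inherits(suppression, "suppression_params"))
  gset <- enumerate_genotypes(list(locus("A", c("wt", "A")),
                                   locus("B", c("wt", "B")),
                                   locus("C", c("wt", "C"))))
  copies_B <- allele_copies(gset, "B", "B")
  copies_C <- allele_copies(gset, "C", "C")
  phi <- params$phi
  seg <- function(gs, g, l) {
    if (phi > 0 && l == 1L && copies_B[g] >= 1 && pair_is(gs, g, 1L, "wt", "A")) {
      c(wt = (1 - phi) / 2, A = (1 + phi) / 2)
    } else if (phi > 0 && l == 2L && copies_C[g] >= 1 &&
               pair_is(gs, g, 2L, "wt", "B")) {
      c(wt = (1 - phi) / 2, B = (1 + phi) / 2)
    } else {
      mendelian_segregation(gs, g, l)
    }
  }
  new_drive_model("ddkr", gset, params, suppression, seg)
}

#' Construct a drive model by variant name
#'
#' @param variant `"sdkr"`, `"nhej"` or `"ddkr"`.
#' @inheritParams sdkr_model
#' @return a `drive_model`.
#' @export
drive_model <- function(variant = c("sdkr", "nhej", "ddkr"), params,
                        suppression = suppression_params()) {
  variant <- match.arg(variant)
  switch(variant,
         sdkr = sdkr_model(params, suppression),
         nhej = nhej_model(params, suppression),
         ddkr = ddkr_model(params, suppression))
}

#' Release specification
#'
#' A release mixes transgenic homozygotes into a wild-type population at a
#' 1:1 sex ratio.  Size may be given either as a released-to-wild ratio
#' (`ratio = 2` is a 2:1 release) or directly as the post-release transgene
#' introduction frequency `frequency = ratio / (1 + ratio)` (so `ratio = 2`
#' is frequency 2/3).
#'
#' @param ratio released-to-wild ratio >= 0.
#' @param frequency introduction frequency in \[0, 1); overrides `ratio`.
#' @param genotype label of the released genotype, or `NULL` for the model
#'   default (homozygous for every transgenic construct).
#' @return object of class `release_spec`.
#' @export
release_spec <- function(ratio = NULL, frequency = NULL, genotype = NULL) {
  if (is.null(ratio) && is.null(frequency))
    stop("supply `ratio` or `frequency`", call. = FALSE)
  if (!is.null(frequency)) {
    if (!is.numeric(frequency) || frequency < 0 || frequency >= 1)
      stop("introduction `frequency` must be in [0, 1)", call. = FALSE)
    ratio <- frequency / (1 - frequency)
  } else {
    if (!is.numeric(ratio) || ratio < 0)
      stop("release `ratio` must be >= 0", call. = FALSE)
    frequency <- ratio / (1 + ratio)
  }
  structure(list(ratio = ratio, frequency = frequency, genotype = genotype),
            class = "release_spec")
}

# homozygous-for-every-construct label, e.g. "A/A;B/B" or "A/A;B/B;C/C"
default_release_genotype <- function(model) {
  paste(vapply(model$gset$locus_names,
               function(nm) paste0(nm, "/", nm), character(1)),
        collapse = ";")
}

all_wt_genotype <- function(model) {
  paste(rep("wt/wt", length(model$gset$loci)), collapse = ";")
}

#' Build the post-release population state
#'
#' Mixture of an all-wild-type population (weight 1 / (1 + r)) and released
#' construct homozygotes (weight r / (1 + r)), each at a 1:1 sex ratio.
#'
#' @param model a drive model.
#' @param release a [release_spec()].
#' @return a [population_state()].
#' @examples
#' m <- sdkr_model(drive_params(phi = 0.9, eps = 0.95, L = 1))
#' make_release(m, release_spec(ratio = 2))  # introduction frequency 2/3
#' @export
make_release <- function(model, release) {
  stopifnot(inherits(model, "drive_model"), inherits(release, "release_spec"))
  q <- release$frequency
  wt <- resolve_genotype(model$gset, all_wt_genotype(model))
  rel_label <- if (is.null(release$genotype)) default_release_genotype(model)
               else release$genotype
  rel <- resolve_genotype(model$gset, rel_label)
  f <- numeric(model$gset$n)
  f[wt] <- f[wt] + (1 - q) / 2
  f[rel] <- f[rel] + q / 2
  population_state(model$gset, f, f)
}
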