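# Brute-force mating-table oracle, implemented independently of the engine:
# everything works on genotype label strings ("wt/A;B/B"), enumerates all
# female x male genotype pairs explicitly, and recomputes gamete, survival
# and sex-effect rules from first principles.

oracle_allele_order <- list(A = c("wt", "A", "R"), B = c("wt", "B"),
                            C = c("wt", "C"))

oracle_split <- function(label) {
  lapply(strsplit(strsplit(label, ";", fixed = TRUE)[[1]], "/", fixed = TRUE),
         identity)
}

oracle_locus_names <- function(label) {
  n <- length(oracle_split(label))
  c("A", "B", "C")[seq_len(n)]
}

# per-locus gamete allele distributions for one parent genotype
oracle_gametes <- function(label, variant, p) {
  pairs <- oracle_split(label)
  nms <- oracle_locus_names(label)
  nB <- sum(pairs[[2]] == "B")
  nC <- if (length(pairs) >= 3) sum(pairs[[3]] == "C") else 0
  per <- list()
  for (l in seq_along(pairs)) {
    pr <- pairs[[l]]
    mendel <- c(0.5, 0.5)
    names(mendel) <- pr
    mendel <- tapply(mendel, names(mendel), sum)
    dist <- as.numeric(mendel)
    names(dist) <- names(mendel)
    if (nms[l] == "A" && setequal(pr, c("wt", "A")) && nB >= 1) {
      if (variant == "nhej") {
        dist <- c(wt = (1 - p$cleavage) / 2,
                  A = (1 + p$cleavage * p$phi) / 2,
                  R = p$cleavage * (1 - p$phi) / 2)
      } else {
        dist <- c(wt = (1 - p$phi) / 2, A = (1 + p$phi) / 2)
      }
    }
    if (nms[l] == "B" && variant == "ddkr" && setequal(pr, c("wt", "B")) &&
        nC >= 1) {
      dist <- c(wt = (1 - p$phi) / 2, B = (1 + p$phi) / 2)
    }
    per[[l]] <- dist
  }
  per
}

# canonical unordered-genotype label from two haplotype vectors
oracle_geno_label <- function(hap1, hap2, nms) {
  paste(vapply(seq_along(hap1), function(l) {
    ord <- oracle_allele_order[[nms[l]]]
    a <- c(hap1[l], hap2[l])
    a <- a[order(match(a, ord))]
    paste(a, collapse = "/")
  }, character(1)), collapse = ";")
}

# offspring genotype distribution of one mating pair (named label -> prob)
oracle_cross <- function(mother, father, variant, p) {
  gm <- oracle_gametes(mother, variant, p)
  gf <- oracle_gametes(father, variant, p)
  nms <- oracle_locus_names(mother)
  hap_tab <- function(per) {
    grid <- expand.grid(lapply(per, names), stringsAsFactors = FALSE)
    prob <- rep(1, nrow(grid))
    for (l in seq_along(per)) prob <- prob * per[[l]][grid[, l]]
    list(grid = as.matrix(grid), prob = as.numeric(prob))
  }
  hm <- hap_tab(gm)
  hf <- hap_tab(gf)
  out <- list()
  for (i in seq_along(hm$prob)) {
    for (j in seq_along(hf$prob)) {
      lab <- oracle_geno_label(hm$grid[i, ], hf$grid[j, ], nms)
      pr <- hm$prob[i] * hf$prob[j]
      out[[lab]] <- (if (is.null(out[[lab]])) 0 else out[[lab]]) + pr
    }
  }
  unlist(out)
}

oracle_survival <- function(label, p) {
  pairs <- oracle_split(label)
  nA <- sum(pairs[[1]] == "A")
  nR <- sum(pairs[[1]] == "R")
  nB <- sum(pairs[[2]] == "B")
  nC <- if (length(pairs) >= 3) sum(pairs[[3]] == "C") else 0
  if (identical(p$cost_basis, "per_construct")) {
    w <- p$eps^((nA > 0) + (nB > 0) + (nC > 0)) * p$eps_R^(nR > 0)
  } else {
    w <- p$eps^(nA + nB + nC) * p$eps_R^nR
  }
  if (nA > 0 && nB == 0) w <- w * (1 - p$L)
  w
}

oracle_affected <- function(label, dominance) {
  nA <- sum(oracle_split(label)[[1]] == "A")
  if (dominance == "dominant") nA >= 1 else nA == 2
}

# one full generation: explicit enumeration over all mating pairs, then
# survival, sex effects and renormalization; returns per-sex frequency
# vectors in the order of `labels` plus pre-normalization masses.
oracle_step <- function(fem, mal, labels, variant, p, sup = NULL) {
  fem <- fem / sum(fem)
  mal <- mal / sum(mal)
  zyg <- setNames(numeric(length(labels)), labels)
  for (i in seq_along(labels)) {
    if (fem[i] == 0) next
    for (j in seq_along(labels)) {
      if (mal[j] == 0) next
      off <- oracle_cross(labels[i], labels[j], variant, p)
      zyg[names(off)] <- zyg[names(off)] + fem[i] * mal[j] * off
    }
  }
  w <- vapply(labels, oracle_survival, numeric(1), p = p)
  zf <- 0.5 * zyg * w
  zm <- zf
  if (!is.null(sup) && sup$mode != "none" && sup$rate > 0) {
    aff <- vapply(labels, oracle_affected, logical(1),
                  dominance = sup$dominance)
    moved <- sup$rate * zf * aff
    zf <- zf - moved
    if (sup$mode == "sex_conversion") zm <- zm + moved
  }
  mass <- sum(zf) + sum(zm)
  list(female = as.numeric(zf) / mass, male = as.numeric(zm) / mass,
       mass = mass, female_mass = sum(zf),
       load = min(max(1 - sum(zf) / 0.5, 0), 1))
}

# random valid population state (joint frequencies summing to 1)
random_state <- function(n) {
  f <- stats::runif(n)
  m <- stats::runif(n)
  tot <- sum(f) + sum(m)
  list(female = f / tot, male = m / tot)
}

random_params <- function(variant) {
  drive_params(phi = stats::runif(1),
               eps = stats::runif(1, 0.6, 1),
               L = stats::runif(1),
               cleavage = if (variant == "nhej") stats::runif(1) else 1,
               eps_R = if (variant == "nhej") stats::runif(1, 0.6, 1) else 1)
}
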