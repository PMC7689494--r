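#' Declare a locus
#'
#' A locus is a named site with an ordered set of allele labels.  The drive
#' systems modelled here use two or three unlinked autosomal loci: locus A
#' carries the toxin + sgRNA construct (alleles `wt`, `A`, and optionally the
#' end-joining resistance allele `R`), locus B carries the Cas9 + antidote
#' construct (`wt`, `B`), and locus C (daisy variant only) carries the sgRNA
#' that lets Cas9 home construct B (`wt`, `C`).
#'
#' @param name single character label, unique among the declared loci.
#' @param alleles character vector of 2 or 3 unique allele labels.  The
#'   declared order is the canonical order used for genotype and haplotype
#'   enumeration.
#' @return an object of class `locus_spec`.
#' @examples
#' locus("A", c("wt", "A"))
#' locus("A", c("wt", "A", "R"))
#' @export
locus <- function(name, alleles) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("locus `name` must be a single non-empty string", call. = FALSE)
  alleles <- as.character(alleles)
  if (length(alleles) < 2L || length(alleles) > 3L)
    stop("locus `", name, "` must declare 2 or 3 alleles", call. = FALSE)
  if (anyDuplicated(alleles))
    stop("allele labels at locus `", name, "` must be unique", call. = FALSE)
  structure(list(name = name, alleles = alleles), class = "locus_spec")
}

#' @export
print.locus_spec <- function(x, ...) {
  cat("<locus> ", x$name, ": {", paste(x$alleles, collapse = ", "), "}\n",
      sep = "")
  invisible(x)
}

# Unordered allele pairs (i <= j as indices into the declared allele order)
# for one locus, in lexicographic order: (1,1), (1,2), ..., (2,2), (2,3), ...
locus_pairs <- function(k) {
  idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  unname(idx)
}

#' Enumerate the diploid genotypes of a set of unlinked loci
#'
#' Builds the full, deterministically ordered genotype table for 1-3 loci with
#' 2-3 alleles each.  A genotype is one unordered allele pair per locus, so a
#' locus with k alleles contributes k(k+1)/2 pairs and the genotype count is
#' the product over loci.  Two diallelic loci give 9 genotypes, a triallelic
#' locus times a diallelic one gives 18, and three diallelic loci give 27.
#'
#' Ordering is lexicographic: the first declared locus varies slowest; within
#' a locus, unordered pairs are sorted by declared allele order, i.e.
#' (a1,a1), (a1,a2), (a1,a3), (a2,a2), (a2,a3), (a3,a3).  This ordering is
#' stable across runs and is the column order of all serialized outputs.
#'
#' @param loci list of [locus()] objects (1 to 3).
#' @return an object of class `genotype_set` with elements `loci`, `pairs`
#'   (integer matrix, one row per genotype, two columns per locus holding
#'   allele indices), `labels` (e.g. `"A/wt;B/B"`), `n` (genotype count) and
#'   `haplotypes` (matrix of single-allele-per-locus gamete types, same
#'   lexicographic order).
#' @examples
#' gs <- enumerate_genotypes(list(locus("A", c("wt", "A")),
#'                                locus("B", c("wt", "B"))))
#' gs$n       # 9
#' gs$labels
#' @export
enumerate_genotypes <- function(loci) {
  if (!is.list(loci) || length(loci) < 1L || length(loci) > 3L)
    stop("`loci` must be a list of 1 to 3 locus_spec objects", call. = FALSE)
  if (!all(vapply(loci, inherits, logical(1), "locus_spec")))
    stop("every element of `loci` must be a locus_spec", call. = FALSE)
  nms <- vapply(loci, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate locus names: ", paste(nms[duplicated(nms)], collapse = ", "),
         call. = FALSE)

  nl <- length(loci)
  ks <- vapply(loci, function(l) length(l$alleles), integer(1))
  pair_tabs <- lapply(ks, locus_pairs)

  # cartesian product with the first locus varying slowest
  combo <- expand.grid(rev(lapply(pair_tabs, function(p) seq_len(nrow(p)))),
                       KEEP.OUT.ATTRS = FALSE)
  combo <- as.matrix(combo[, rev(seq_len(nl)), drop = FALSE])
  pairs <- matrix(0L, nrow(combo), 2L * nl)
  for (l in seq_len(nl)) {
    pairs[, 2L * l - 1L] <- pair_tabs[[l]][combo[, l], 1L]
    pairs[, 2L * l]      <- pair_tabs[[l]][combo[, l], 2L]
  }

  labels <- apply(pairs, 1L, function(row) {
    paste(vapply(seq_len(nl), function(l) {
      al <- loci[[l]]$alleles
      paste0(al[row[2L * l - 1L]], "/", al[row[2L * l]])
    }, character(1)), collapse = ";")
  })

  hap_combo <- expand.grid(rev(lapply(ks, seq_len)), KEEP.OUT.ATTRS = FALSE)
  haplotypes <- as.matrix(hap_combo[, rev(seq_len(nl)), drop = FALSE])
  colnames(haplotypes) <- nms
  hap_labels <- apply(haplotypes, 1L, function(row) {
    paste(vapply(seq_len(nl), function(l) loci[[l]]$alleles[row[l]],
                 character(1)), collapse = ";")
  })

  structure(list(
    loci = loci,
    locus_names = nms,
    n_alleles = ks,
    pairs = pairs,
    labels = unname(labels),
    n = nrow(pairs),
    haplotypes = unname(haplotypes),
    hap_labels = unname(hap_labels)
  ), class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("<genotype_set> ", x$n, " genotypes over ", length(x$loci),
      " unlinked loci (", paste(x$locus_names, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# copies (0, 1 or 2) of allele `allele` at locus `locus_name` carried by each
# genotype; zero vector if the locus or allele is absent from the set.
allele_copies <- function(gset, locus_name, allele) {
  l <- match(locus_name, gset$locus_names)
  if (is.na(l)) return(numeric(gset$n))
  ai <- match(allele, gset$loci[[l]]$alleles)
  if (is.na(ai)) return(numeric(gset$n))
  (gset$pairs[, 2L * l - 1L] == ai) + (gset$pairs[, 2L * l] == ai)
}
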