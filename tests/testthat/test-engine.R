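test_that("gamete distributions follow the cut/repair arithmetic", {
  m <- sdkr_model(drive_params(phi = 0.9, eps = 0.95, L = 1))
  # wild-type at every locus: the all-wt haplotype with certainty
  g <- gamete_distribution(m, "wt/wt;wt/wt")
  expect_equal(unname(g["wt;wt"]), 1)
  # A/wt;B/B heterozygote homes: A at (1 + phi)/2, B certain
  g <- gamete_distribution(m, "wt/A;B/B")
  expect_equal(unname(g["A;B"]), (1 + 0.9) / 2)
  expect_equal(unname(g["wt;B"]), (1 - 0.9) / 2)
  expect_equal(sum(g), 1)
  # no B present: Mendelian at locus A despite phi > 0
  g <- gamete_distribution(m, "wt/A;wt/wt")
  expect_equal(unname(g["A;wt"]), 0.5)
  # NHEJ partition: cut with c, then HDR phi / end-joining 1 - phi
  mn <- nhej_model(drive_params(phi = 0.8, eps = 0.95, L = 1,
                                cleavage = 0.95))
  g <- gamete_distribution(mn, "wt/A;wt/B")
  pA <- sum(g[c("A;wt", "A;B")])
  pR <- sum(g[c("R;wt", "R;B")])
  pwt <- sum(g[c("wt;wt", "wt;B")])
  expect_equal(pA, 0.88)
  expect_equal(pR, 0.095)
  expect_equal(pwt, 0.025)
  # R alleles are never cut: A/R and R/wt segregate Mendelianly
  g <- gamete_distribution(mn, "A/R;B/B")
  expect_equal(sum(g[c("A;B")]), 0.5)
  expect_equal(sum(g[c("R;B")]), 0.5)
  g <- gamete_distribution(mn, "wt/R;B/B")
  expect_equal(sum(g[startsWith(names(g), "R;")]), 0.5)
})

test_that("offspring distribution collapses ordered haplotype pairs", {
  m <- sdkr_model(drive_params(phi = 0, eps = 1, L = 0))
  gs <- m$gset
  wt <- gamete_distribution(m, "wt/wt;wt/wt")
  expect_equal(unname(offspring_distribution(wt, wt, gs)["wt/wt;wt/wt"]), 1)
  hom <- gamete_distribution(m, "A/A;B/B")
  off <- offspring_distribution(hom, wt, gs)
  expect_equal(unname(off["wt/A;wt/B"]), 1)  # obligate double heterozygote
  expect_equal(sum(off), 1)
  # mismatched haplotype sets are rejected
  mn <- nhej_model(drive_params(phi = 0.8, eps = 1, L = 0))
  expect_error(offspring_distribution(gamete_distribution(mn, 1), wt, gs),
               "haplotype")
})

test_that("survival weights combine toxin viability and fitness", {
  m <- sdkr_model(drive_params(phi = 0.9, eps = 1, L = 1))
  expect_equal(survival_weight(m, "A/A;wt/wt"), 0)  # unrescued toxin
  expect_equal(survival_weight(m, "A/A;wt/B"), 1)   # one rescue suffices
  expect_equal(survival_weight(m, "wt/wt;wt/wt"), 1)
  m2 <- sdkr_model(drive_params(phi = 0.9, eps = 1, L = 0.6))
  expect_equal(survival_weight(m2, "wt/A;wt/wt"), 0.4)
  # per-copy multiplicative costs
  m3 <- sdkr_model(drive_params(phi = 0.9, eps = 0.9, L = 0))
  expect_equal(survival_weight(m3, "A/A;B/B"), 0.9^4)
  expect_equal(survival_weight(m3, "wt/A;wt/B"), 0.9^2)
  # dominant per-construct alternative
  m4 <- sdkr_model(drive_params(phi = 0.9, eps = 0.9, L = 0,
                                cost_basis = "per_construct"))
  expect_equal(survival_weight(m4, "A/A;B/B"), 0.9^2)
  expect_equal(survival_weight(m4, "wt/A;wt/B"), 0.9^2)
})

test_that("an all-wild-type population is a fixed point", {
  m <- sdkr_model(drive_params(phi = 0.9, eps = 0.8, L = 1))
  st <- make_release(m, release_spec(ratio = 0))
  stepped <- generation_step(st, m)
  expect_equal(unclass(stepped$state), unclass(st), tolerance = 1e-14)
  expect_equal(stepped$mass, 1)
})

test_that("neutral limit conserves allele frequencies and reaches HWE", {
  m <- sdkr_model(drive_params(phi = 0, eps = 1, L = 0))
  set.seed(11)
  for (rep in 1:5) {
    # symmetric initialization: identical female and male marginals
    f <- runif(m$gset$n)
    f <- f / (2 * sum(f))
    st <- population_state(m$gset, f, f)
    before <- allele_frequencies(st, m)
    s1 <- generation_step(st, m)
    after <- allele_frequencies(s1$state, m)
    expect_equal(after, before, tolerance = 1e-10)
    # each locus reaches Hardy-Weinberg proportions in one generation
    # (cross-locus associations decay geometrically, not instantly)
    pA <- unname(after["A"]); pB <- unname(after["B"])
    hw <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)
    nA <- sdkr:::allele_copies(m$gset, "A", "A")
    nB <- sdkr:::allele_copies(m$gset, "B", "B")
    got <- colSums(unclass(s1$state))
    marginal <- function(n) vapply(0:2, function(k) sum(got[n == k]),
                                   numeric(1))
    expect_equal(marginal(nA), hw(pA), tolerance = 1e-10)
    expect_equal(marginal(nB), hw(pB), tolerance = 1e-10)
  }
})

test_that("Mendelian limit conserves allele frequencies across generations", {
  m <- sdkr_model(drive_params(phi = 0, eps = 1, L = 0, cleavage = 0.7))
  st <- make_release(m, release_spec(frequency = 0.37))
  tr <- simulate_drive(m, st, 40, keep_genotypes = FALSE)
  expect_equal(tr$freq_A, rep(0.37, 41), tolerance = 1e-10)
  expect_equal(tr$freq_B, rep(0.37, 41), tolerance = 1e-10)
})

test_that("every returned state is normalized with no negative entries", {
  set.seed(23)
  for (variant in c("sdkr", "nhej", "ddkr")) {
    for (rep in 1:5) {
      m <- drive_model(variant, random_params(variant))
      rs <- random_state(m$gset$n)
      st <- population_state(m$gset, rs$female, rs$male)
      for (k in 1:3) {
        res <- generation_step(st, m)
        st <- res$state
        expect_true(all(unclass(st) >= 0))
        expect_equal(sum(unclass(st)), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("sexes stay symmetric without sex-specific effects", {
  m <- ddkr_model(drive_params(phi = 0.85, eps = 0.92, L = 0.8))
  st <- make_release(m, release_spec(ratio = 1.5))
  for (k in 1:30) {
    res <- generation_step(st, m)
    st <- res$state
    expect_equal(unclass(st)["female", ], unclass(st)["male", ],
                 tolerance = 1e-14)
  }
})

test_that("one generation equals the brute-force mating-table oracle", {
  set.seed(42)
  variants <- c("sdkr", "nhej", "ddkr")
  draws_per_variant <- 7  # 21 randomized draws + 4 suppression draws
  for (variant in variants) {
    for (rep in seq_len(draws_per_variant)) {
      p <- random_params(variant)
      m <- drive_model(variant, p)
      rs <- random_state(m$gset$n)
      got <- sdkr:::step_core(m, rs$female, rs$male)
      want <- oracle_step(rs$female, rs$male, m$gset$labels, variant,
                          unclass(p))
      expect_equal(got$f, want$female, tolerance = 1e-12)
      expect_equal(got$m, want$male, tolerance = 1e-12)
      expect_equal(got$mass, want$mass, tolerance = 1e-12)
    }
  }
  # suppression variants (conversion and lethality, both dominance modes)
  for (mode in c("sex_conversion", "female_lethality")) {
    for (dom in c("dominant", "recessive")) {
      p <- random_params("sdkr")
      sup <- suppression_params(mode, dom, rate = stats::runif(1))
      m <- sdkr_model(p, sup)
      rs <- random_state(m$gset$n)
      got <- sdkr:::step_core(m, rs$female, rs$male)
      want <- oracle_step(rs$female, rs$male, m$gset$labels, "sdkr",
                          unclass(p), sup)
      expect_equal(got$f, want$female, tolerance = 1e-12)
      expect_equal(got$m, want$male, tolerance = 1e-12)
      expect_equal(got$female_mass, want$female_mass, tolerance = 1e-12)
    }
  }
})

test_that("a release under drive parameters matches the oracle trajectory", {
  p <- drive_params(phi = 0.9, eps = 0.95, L = 1)
  m <- sdkr_model(p)
  st <- make_release(m, release_spec(ratio = 1))
  f <- unclass(st)["female", ]; mm <- unclass(st)["male", ]
  of <- f; om <- mm
  for (k in 1:5) {
    got <- sdkr:::step_core(m, f, mm)
    want <- oracle_step(of, om, m$gset$labels, "sdkr", unclass(p))
    expect_equal(got$f, want$female, tolerance = 1e-12)
    f <- got$f; mm <- got$m; of <- want$female; om <- want$male
  }
})

test_that("annihilation is signalled when nothing survives", {
  m <- sdkr_model(drive_params(phi = 0, eps = 1, L = 1))
  gs <- m$gset
  f <- numeric(gs$n)
  f[match("A/A;wt/wt", gs$labels)] <- 0.5  # all toxin, no rescue
  st <- population_state(gs, f, f)
  expect_error(generation_step(st, m), class = "sdkr_annihilation")
})
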