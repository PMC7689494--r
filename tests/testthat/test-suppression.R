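conv_model <- function(phi = 0.9, rate = 0.9, dom = "dominant",
                       eps = 0.95) {
  sdkr_model(drive_params(phi, eps, 1),
             suppression_params("sex_conversion", dom, rate))
}
leth_model <- function(phi = 0.9, rate = 0.9, dom = "dominant",
                       eps = 0.95) {
  sdkr_model(drive_params(phi, eps, 1),
             suppression_params("female_lethality", dom, rate))
}

test_that("sex effects move or remove exactly the affected female mass", {
  set.seed(7)
  z <- list(female = runif(9), male = runif(9))
  none <- sdkr_model(drive_params(0.9, 0.95, 1))
  expect_identical(apply_sex_effects(z, none),
                   list(female = z$female, male = z$male))
  # dominant conversion conserves mass
  m <- conv_model(rate = 0.6)
  out <- apply_sex_effects(z, m)
  expect_equal(sum(out$female) + sum(out$male), sum(z$female) + sum(z$male))
  expect_equal(out$female, z$female * (1 - 0.6 * m$affected_female))
  expect_equal(out$male, z$male + 0.6 * z$female * m$affected_female)
  # lethality removes mass without adding males
  ml <- leth_model(rate = 0.5)
  out <- apply_sex_effects(z, ml)
  expect_equal(out$male, z$male)
  expect_equal(out$female, z$female * (1 - 0.5 * ml$affected_female))
  expect_lt(sum(out$female), sum(z$female))
  # recessive effects touch only A/A classes
  mr <- conv_model(rate = 1, dom = "recessive")
  aa <- sdkr:::allele_copies(mr$gset, "A", "A") == 2
  expect_equal(mr$affected_female, as.numeric(aa))
})

test_that("complete dominant conversion of a fixed drive collapses females", {
  m <- conv_model(rate = 1)
  gs <- m$gset
  f <- numeric(gs$n)
  f[match("A/A;B/B", gs$labels)] <- 0.5
  st <- population_state(gs, f, f)
  res <- generation_step(st, m)
  expect_equal(res$female_mass, 0)
  expect_equal(sum(unclass(res$state)["female", ]), 0)
  expect_equal(genetic_load(res), 1)   # no fertile females remain
  # the next generation has no mothers: annihilation
  expect_error(generation_step(res$state, m), class = "sdkr_annihilation")
})

test_that("genetic load is zero for wild-type and bounded in [0, 1]", {
  m <- leth_model(rate = 0.7)
  wt <- make_release(m, release_spec(ratio = 0))
  expect_equal(genetic_load(generation_step(wt, m)), 0)
  # any transgene with eps < 1 gives a strictly positive load
  m2 <- sdkr_model(drive_params(0.9, 0.95, 1))
  st <- make_release(m2, release_spec(frequency = 0.5))
  expect_gt(genetic_load(generation_step(st, m2)), 0)
  set.seed(31)
  for (k in 1:5) {
    rs <- random_state(m$gset$n)
    st <- population_state(m$gset, rs$female, rs$male)
    res <- tryCatch(generation_step(st, m), sdkr_annihilation = function(e) NULL)
    if (is.null(res)) next
    expect_gte(genetic_load(res), 0)
    expect_lte(genetic_load(res), 1)
  }
})

test_that("genetic load matches the independently coded oracle formula", {
  p <- drive_params(0.9, 0.95, 1)
  sup <- suppression_params("female_lethality", "recessive", 0.9)
  m <- sdkr_model(p, sup)
  st <- make_release(m, release_spec(frequency = 0.75))
  f <- unclass(st)["female", ]; mm <- unclass(st)["male", ]
  of <- f; om <- mm
  for (k in 1:20) {
    got <- sdkr:::step_core(m, f, mm)
    want <- oracle_step(of, om, m$gset$labels, "sdkr", unclass(p), sup)
    expect_equal(genetic_load(got), want$load, tolerance = 1e-12)
    f <- got$f; mm <- got$m; of <- want$female; om <- want$male
  }
})

test_that("two demes with m = 0 equal two independent simulations", {
  m <- conv_model(rate = 0.5)
  tr2 <- simulate_two_deme(m, release_spec(frequency = 0.6), 50, m = 0)
  tr1 <- simulate_drive(m, release_spec(frequency = 0.6), 50,
                        keep_genotypes = FALSE)
  expect_equal(tr2$target_freq_A, tr1$freq_A, tolerance = 1e-12)
  expect_equal(tr2$target_load[-1], tr1$load[-1], tolerance = 1e-12)
  expect_equal(tr2$nontarget_freq_A, rep(0, 51))  # founded all-wt, stays wt
})

test_that("migration between wild-type demes changes nothing", {
  m <- sdkr_model(drive_params(0.9, 0.95, 1))
  st <- two_deme_state(make_release(m, release_spec(ratio = 0)),
                       make_release(m, release_spec(ratio = 0)))
  s1 <- two_deme_step(st, m, m = 0.02)
  expect_equal(sum(unclass(s1$nontarget)[, "wt/wt;wt/wt"]), 1)
  expect_equal(s1$target_size, 1)
  expect_equal(s1$nontarget_size, 1)
})

test_that("migrant weighting gives share m/(1+m) under equal suppression", {
  m <- sdkr_model(drive_params(0, 1, 0))  # fully neutral model
  target <- make_release(m, release_spec(frequency = 0.5))
  nontarget <- make_release(m, release_spec(ratio = 0))
  st <- two_deme_state(target, nontarget)
  s1 <- two_deme_step(st, m, m = 0.02)
  # neutral loads are 0 in both demes, so migrants weigh m vs residents 1
  fA <- allele_frequencies(s1$nontarget, m)["A"]
  expect_equal(unname(fA), 0.5 * 0.02 / 1.02, tolerance = 1e-12)
})

test_that("one-way migration leaves the target deme untouched", {
  m <- leth_model(phi = 0.9, rate = 0.5)
  tr_mig <- simulate_two_deme(m, release_spec(frequency = 0.75), 100,
                              m = 0.02)
  tr_iso <- simulate_two_deme(m, release_spec(frequency = 0.75), 100, m = 0)
  expect_equal(tr_mig$target_freq_A, tr_iso$target_freq_A, tolerance = 1e-12)
  expect_equal(tr_mig$target_load, tr_iso$target_load, tolerance = 1e-12)
})

test_that("non-target transgene frequencies stay below the target's", {
  m <- conv_model(phi = 0.9, rate = 0.9)
  tr <- simulate_two_deme(m, release_spec(frequency = 0.75), 200, m = 0.02)
  expect_true(all(tr$nontarget_freq_A <= tr$target_freq_A + 1e-12))
  expect_true(all(tr$nontarget_freq_B <= tr$target_freq_B + 1e-12))
})

test_that("sub-threshold migrant influx keeps the non-target load low", {
  # dominant lethality at high homing/lethality: strong target suppression
  # but migration pressure alone cannot push the neighbour past threshold
  m <- leth_model(phi = 0.9, rate = 0.8)
  tr <- simulate_two_deme(m, release_spec(frequency = 0.75), 1000, m = 0.02)
  expect_gt(tail(tr$target_load, 1), 0.5)
  expect_lt(tail(tr$nontarget_load, 1), 0.1)
  expect_lt(tail(tr$nontarget_freq_A, 1), 0.1)
})
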