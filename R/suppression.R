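#' Genetic load of one generation
#'
#' The genetic load is the proportional reduction in the population's
#' reproductive output relative to an all-wild-type population.  Females
#' limit reproduction here, so the load is measured on the surviving fertile
#' female mass: a wild-type generation retains female mass 0.5 per zygote
#' equivalent, and
#' \deqn{G = 1 - \frac{\text{surviving fertile-female mass}}{0.5}}
#' clipped to \[0, 1\].  An all-wild-type population gives exactly 0; total
#' loss of fertile females (e.g. complete dominant sex conversion at
#' fixation) gives 1.
#'
#' @param step a `generation_step` result from [generation_step()].
#' @return load in \[0, 1\].
#' @export
genetic_load <- function(step) {
  stopifnot(inherits(step, "generation_step") || is.list(step))
  load <- 1 - step$female_mass / 0.5
  min(max(load, 0), 1)
}

#' Two-deme state
#'
#' A target deme (where the release happens) and a non-target neighbour deme
#' coupled by unidirectional migration.  Relative deme sizes are proxied by
#' 1 - genetic load and are used to weight migrants against residents.
#'
#' @param target,nontarget [population_state()] objects over the same model.
#' @param target_size,nontarget_size relative sizes in \[0, 1\]
#'   (1 - genetic load of the deme's last generation).
#' @return object of class `two_deme_state`.
#' @export
two_deme_state <- function(target, nontarget, target_size = 1,
                           nontarget_size = 1) {
  stopifnot(inherits(target, "population_state"),
            inherits(nontarget, "population_state"))
  check_prob(target_size, "target_size")
  check_prob(nontarget_size, "nontarget_size")
  structure(list(target = target, nontarget = nontarget,
                 target_size = target_size, nontarget_size = nontarget_size),
            class = "two_deme_state")
}

#' Advance a two-deme system by one generation
#'
#' Each deme advances one generation independently under the same model;
#' the non-target adult pool is then replaced by a mixture of resident
#' non-target adults (weight 1 - G_nt) and migrants from the target deme
#' (weight m * (1 - G_t)), where G_t and G_nt are the demes' genetic loads
#' this generation, and renormalized.  Migration is strictly one-way: the
#' target deme's composition is unaffected.  With no suppression the
#' migrant share is m / (1 + m), i.e. about m for small m.
#'
#' @param state a [two_deme_state()].
#' @param model a drive model.
#' @param m per-generation migration rate; defaults to the model's
#'   `suppression$migration`.
#' @return a new `two_deme_state`; its sizes are 1 minus each deme's load
#'   this generation.  Errors (class `sdkr_annihilation`) if both demes are
#'   annihilated.
#' @export
two_deme_step <- function(state, model, m = NULL) {
  stopifnot(inherits(state, "two_deme_state"))
  if (is.null(m)) m <- model$suppression$migration
  check_prob(m, "m")
  res <- two_deme_step_core(
    model,
    unclass(state$target)["female", ], unclass(state$target)["male", ],
    unclass(state$nontarget)["female", ], unclass(state$nontarget)["male", ],
    m)
  if (res$both_dead)
    stop_annihilated("both demes annihilated")
  mk <- function(f, mm) population_state(model$gset, f, mm)
  two_deme_state(mk(res$tf, res$tm), mk(res$nf, res$nm),
                 target_size = 1 - res$target_load,
                 nontarget_size = 1 - res$nontarget_load)
}

# raw-vector core shared by two_deme_step and the scan drivers
two_deme_step_core <- function(model, tf, tm, nf, nm, m) {
  t_dead <- FALSE
  n_dead <- FALSE
  tres <- tryCatch(step_core(model, tf, tm),
                   sdkr_annihilation = function(e) NULL)
  if (is.null(tres)) t_dead <- TRUE
  nres <- tryCatch(step_core(model, nf, nm),
                   sdkr_annihilation = function(e) NULL)
  if (is.null(nres)) n_dead <- TRUE
  if (t_dead && n_dead)
    return(list(both_dead = TRUE))

  G_t <- if (t_dead) 1 else genetic_load(tres)
  G_nt <- if (n_dead) 1 else genetic_load(nres)

  n <- model$gset$n
  tf2 <- if (t_dead) numeric(n) else tres$f
  tm2 <- if (t_dead) numeric(n) else tres$m
  nf2 <- if (n_dead) numeric(n) else nres$f
  nm2 <- if (n_dead) numeric(n) else nres$m

  w_res <- 1 - G_nt
  w_mig <- m * (1 - G_t)
  tot <- w_res + w_mig
  if (tot > 0) {
    nf2 <- (w_res * nf2 + w_mig * tf2) / tot
    nm2 <- (w_res * nm2 + w_mig * tm2) / tot
  }
  list(both_dead = FALSE,
       tf = tf2, tm = tm2, nf = nf2, nm = nm2,
       target_load = G_t, nontarget_load = G_nt,
       target_dead = t_dead)
}

#' Simulate a two-deme release
#'
#' Releases transgenic homozygotes into the target deme only (the non-target
#' deme starts all wild-type) and iterates [two_deme_step()] for the given
#' number of generations.
#'
#' @param model a drive model.
#' @param release a [release_spec()] applied to the target deme.
#' @param generations number of generations >= 1.
#' @param m per-generation unidirectional migration rate; defaults to the
#'   model's `suppression$migration`.
#' @return a data frame of class `two_deme_trajectory`: one row per
#'   generation (0 .. generations) with per-deme allele frequencies and
#'   loads (loads are `NA` at generation 0, before any selection acted).
#' @export
simulate_two_deme <- function(model, release, generations, m = NULL) {
  stopifnot(inherits(model, "drive_model"), generations >= 1)
  if (is.null(m)) m <- model$suppression$migration
  check_prob(m, "m")
  target <- make_release(model, release)
  nontarget <- make_release(model, release_spec(ratio = 0))

  alleles <- colnames(model$copies)
  nrec <- generations + 1L
  rec <- data.frame(generation = 0:generations)
  for (a in alleles) {
    rec[[paste0("target_freq_", a)]] <- NA_real_
    rec[[paste0("nontarget_freq_", a)]] <- NA_real_
  }
  rec$target_load <- NA_real_
  rec$nontarget_load <- NA_real_

  freqs <- function(f, m2) drop((f + m2) %*% model$copies) / 2
  tf <- unclass(target)["female", ]; tm <- unclass(target)["male", ]
  nf <- unclass(nontarget)["female", ]; nm <- unclass(nontarget)["male", ]
  rec[1, paste0("target_freq_", alleles)] <- as.list(freqs(tf, tm))
  rec[1, paste0("nontarget_freq_", alleles)] <- as.list(freqs(nf, nm))

  for (t in seq_len(generations)) {
    res <- two_deme_step_core(model, tf, tm, nf, nm, m)
    if (res$both_dead)
      stop_annihilated("both demes annihilated at generation ", t)
    tf <- res$tf; tm <- res$tm; nf <- res$nf; nm <- res$nm
    i <- t + 1L
    rec[i, paste0("target_freq_", alleles)] <- as.list(freqs(tf, tm))
    rec[i, paste0("nontarget_freq_", alleles)] <- as.list(freqs(nf, nm))
    rec$target_load[i] <- res$target_load
    rec$nontarget_load[i] <- res$nontarget_load
  }
  attr(rec, "model") <- model$name
  attr(rec, "migration") <- m
  class(rec) <- c("two_deme_trajectory", "data.frame")
  rec
}
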