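#' Simulate a drive release
#'
#' Deterministic trajectory of the genotype-frequency recursion: generation
#' 0 is the release state, and each later row is one [generation_step()].
#' Repeated runs of the same configuration are bit-identical.
#'
#' @param model a drive model.
#' @param release a [release_spec()] or a [population_state()] to start from.
#' @param generations number of generations >= 1.
#' @param keep_genotypes if `TRUE` (default) include per-sex genotype
#'   frequency columns (`f_<genotype>`, `m_<genotype>`) alongside allele
#'   frequencies and load.
#' @return a data frame of class `drive_trajectory`: columns `generation`,
#'   `freq_<allele>` for each tracked allele (A, B and, per model, C or R),
#'   `load` (`NA` at generation 0), and optionally genotype frequencies.
#' @examples
#' m <- sdkr_model(drive_params(phi = 0.9, eps = 0.95, L = 1))
#' tr <- simulate_drive(m, release_spec(ratio = 2), 50)
#' tail(tr[, c("generation", "freq_A", "freq_B")])
#' @export
simulate_drive <- function(model, release, generations,
                           keep_genotypes = TRUE) {
  stopifnot(inherits(model, "drive_model"), generations >= 1)
  state <- if (inherits(release, "population_state")) release
           else make_release(model, release)
  f <- unclass(state)["female", ]
  m <- unclass(state)["male", ]

  alleles <- colnames(model$copies)
  n <- generations + 1L
  freq_mat <- matrix(NA_real_, n, length(alleles))
  load <- rep(NA_real_, n)
  if (keep_genotypes) {
    fmat <- matrix(NA_real_, n, model$gset$n)
    mmat <- matrix(NA_real_, n, model$gset$n)
  }

  record <- function(i, f, m) {
    freq_mat[i, ] <<- drop((f + m) %*% model$copies) / 2
    if (keep_genotypes) {
      fmat[i, ] <<- f
      mmat[i, ] <<- m
    }
  }
  record(1L, f, m)
  for (t in seq_len(generations)) {
    res <- step_core(model, f, m)
    f <- res$f
    m <- res$m
    record(t + 1L, f, m)
    load[t + 1L] <- genetic_load(res)
  }

  out <- data.frame(generation = 0:generations)
  colnames(freq_mat) <- paste0("freq_", alleles)
  out <- cbind(out, as.data.frame(freq_mat))
  out$load <- load
  if (keep_genotypes) {
    colnames(fmat) <- paste0("f_", model$gset$labels)
    colnames(mmat) <- paste0("m_", model$gset$labels)
    out <- cbind(out, as.data.frame(fmat), as.data.frame(mmat))
  }
  attr(out, "model") <- model$name
  attr(out, "params") <- unclass(model$params)
  class(out) <- c("drive_trajectory", "data.frame")
  out
}

#' Did the drive spread?
#'
#' Operational spread criterion: the drive is considered to have spread if
#' the A-allele frequency is above `level` (default 0.95) at the end of the
#' trajectory, i.e. the drive has increased in frequency and retained its
#' gains over the horizon.  Requiring retention (rather than a transient
#' excursion above the level) is what makes very large releases that
#' subsequently collapse count as failures, matching the notion of a system
#' "unable to increase in frequency".  With `when = "any"` a transient
#' excursion above `level` counts instead.  The threshold analyses use the
#' retention criterion over a 1000-generation horizon; level, horizon and
#' mode are configurable policy, and reported thresholds are only
#' meaningful together with them.
#'
#' @param traj a [simulate_drive()] trajectory.
#' @param level frequency the A allele must exceed.
#' @param when `"final"` (retention, default) or `"any"` (transient).
#' @return `TRUE` or `FALSE`.
#' @export
spread_criterion <- function(traj, level = 0.95, when = c("final", "any")) {
  when <- match.arg(when)
  stopifnot("freq_A" %in% names(traj))
  if (when == "any") any(traj$freq_A > level, na.rm = TRUE)
  else tail(traj$freq_A, 1) > level
}

# fast spread check on raw vectors; exits early once the A allele is fixed
# (wild-type and resistant alleles at locus A are then extinct, so fixation
# is absorbing in every model variant)
spreads_from <- function(model, q, genotype = NULL, horizon = 1000,
                         level = 0.95) {
  state <- make_release(model, release_spec(frequency = q,
                                            genotype = genotype))
  f <- unclass(state)["female", ]
  m <- unclass(state)["male", ]
  iA <- model$copies[, "A"]
  fa <- sum((f + m) * iA) / 2
  for (t in seq_len(horizon)) {
    res <- tryCatch(step_core(model, f, m),
                    sdkr_annihilation = function(e) NULL)
    if (is.null(res)) return(FALSE)
    f <- res$f
    m <- res$m
    fa <- sum((f + m) * iA) / 2
    if (fa > 1 - 1e-9) return(TRUE)
  }
  fa > level
}

#' Find the introduction threshold by bisection
#'
#' The smallest introduction frequency at which the drive spreads (per
#' [spread_criterion()]).  A coarse 11-point pre-scan over \[0, `max_freq`\]
#' first verifies that the spread outcome is monotone in release frequency
#' (a failed check raises a diagnostic error); bisection then narrows the
#' failing/spreading bracket to width `tol`.  If no frequency up to
#' `max_freq` (default 0.99) spreads, the system is unable to increase in
#' frequency and a sentinel result with `no_spread = TRUE` is returned.
#'
#' @param model a drive model.
#' @param genotype released genotype label, or `NULL` for the model default.
#' @param tol bisection tolerance on introduction frequency.
#' @param horizon generations simulated per candidate release.
#' @param level spread criterion level (see [spread_criterion()]).
#' @param max_freq largest introduction frequency considered.
#' @return object of class `threshold_result` with elements `threshold`
#'   (midpoint of the final bracket, or `NA` when `no_spread`), `bracket`
#'   (largest failing and smallest spreading frequency found), `tol`,
#'   `level`, `horizon`, `no_spread`.
#' @examples
#' m <- sdkr_model(drive_params(phi = 0.9, eps = 0.85, L = 1))
#' find_threshold(m, tol = 0.01, horizon = 300)
#' @export
find_threshold <- function(model, genotype = NULL, tol = 0.002,
                           horizon = 1000, level = 0.95, max_freq = 0.99) {
  stopifnot(inherits(model, "drive_model"), tol > 0)
  qs <- seq(0, max_freq, length.out = 11L)
  outcome <- vapply(qs, function(q)
    spreads_from(model, q, genotype, horizon, level), logical(1))
  if (any(outcome) && is.unsorted(outcome))
    stop(errorCondition(
      paste0("spread outcome is not monotone in release frequency; ",
             "profile: ", paste(as.integer(outcome), collapse = "")),
      class = c("sdkr_nonmonotone", "error")))
  if (!any(outcome)) {
    return(structure(list(threshold = NA_real_, bracket = c(max_freq, NA),
                          tol = tol, level = level, horizon = horizon,
                          no_spread = TRUE),
                     class = "threshold_result"))
  }
  hi <- qs[which(outcome)[1L]]
  lo <- if (which(outcome)[1L] == 1L) 0 else qs[which(outcome)[1L] - 1L]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (spreads_from(model, mid, genotype, horizon, level)) hi <- mid
    else lo <- mid
  }
  structure(list(threshold = (lo + hi) / 2, bracket = c(lo, hi), tol = tol,
                 level = level, horizon = horizon, no_spread = FALSE),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$no_spread) {
    cat("<threshold_result> no spread at any introduction frequency <= ",
        x$bracket[1], "\n", sep = "")
  } else {
    cat("<threshold_result> introduction threshold = ",
        format(x$threshold, digits = 4), " (bracket [",
        format(x$bracket[1], digits = 4), ", ",
        format(x$bracket[2], digits = 4), "], tol ", x$tol, ")\n", sep = "")
  }
  cat("  criterion: A-allele frequency retained above ", x$level, " at ",
      x$horizon, " generations\n", sep = "")
  invisible(x)
}

#' Bisect a monotone spread boundary over an arbitrary parameter
#'
#' Generic monotone bisection used for questions like "what is the smallest
#' homing rate at which a given release spreads?".  `f` must be a predicate
#' that is `FALSE` below the boundary and `TRUE` above it on
#' \[`lower`, `upper`\].
#'
#' @param f predicate function of one numeric argument.
#' @param lower,upper bracket endpoints with `f(lower) = FALSE`,
#'   `f(upper) = TRUE` (checked).
#' @param tol bracket width at which to stop.
#' @return the boundary estimate (bracket midpoint).
#' @export
bisect_boundary <- function(f, lower, upper, tol = 0.005) {
  stopifnot(lower < upper, tol > 0)
  if (f(lower)) stop("f(lower) is already TRUE; no boundary in bracket",
                     call. = FALSE)
  if (!f(upper)) stop("f(upper) is FALSE; no boundary in bracket",
                      call. = FALSE)
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (f(mid)) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}

#' Persistence time of the drive
#'
#' Number of generations in which the A-allele frequency exceeds `level`
#' (default 0.8, at which over 95% of individuals carry at least one A copy
#' under Hardy-Weinberg proportions).  All recorded generations are counted,
#' including the release generation and non-contiguous excursions; see the
#' methods vignette for the rationale.
#'
#' @param traj a [simulate_drive()] trajectory.
#' @param level frequency that must be exceeded.
#' @return integer count of generations.
#' @export
persistence_time <- function(traj, level = 0.8) {
  stopifnot("freq_A" %in% names(traj))
  sum(traj$freq_A > level, na.rm = TRUE)
}

#' Equilibrium summary of a trajectory
#'
#' Allele frequencies and genetic load at a stated generation, with a
#' convergence flag: `TRUE` if every tracked quantity changed by less than
#' `1e-8` over the preceding 100 generations (or all available ones).
#'
#' @param traj a [simulate_drive()] or [simulate_two_deme()] trajectory.
#' @param at generation at which to assess the equilibrium (default: last).
#' @return list with `generation`, the frequency/load columns at that
#'   generation, and `converged`.
#' @export
equilibrium_summary <- function(traj, at = max(traj$generation)) {
  stopifnot(at %in% traj$generation)
  cols <- setdiff(names(traj),
                  c("generation", grep("^[fm]_", names(traj), value = TRUE)))
  i <- match(at, traj$generation)
  win <- traj$generation >= max(0, at - 100) & traj$generation <= at
  delta <- vapply(cols, function(cn) {
    v <- traj[[cn]][win]
    v <- v[!is.na(v)]
    if (length(v) < 2L) 0 else diff(range(v))
  }, numeric(1))
  out <- as.list(traj[i, cols, drop = FALSE])
  c(list(generation = at), out, list(converged = all(delta < 1e-8)))
}

# single-run metric collector on raw vectors (no per-generation allocation)
run_metrics_single <- function(model, release, horizon, persistence_level) {
  state <- make_release(model, release)
  f <- unclass(state)["female", ]
  m <- unclass(state)["male", ]
  iA <- model$copies[, "A"]
  iR <- if ("R" %in% colnames(model$copies)) model$copies[, "R"] else NULL
  persist <- if (sum((f + m) * iA) / 2 > persistence_level) 1L else 0L
  load <- NA_real_
  for (t in seq_len(horizon)) {
    res <- tryCatch(step_core(model, f, m),
                    sdkr_annihilation = function(e) NULL)
    if (is.null(res))
      return(list(load = 1, persistence = persist, freq_R = NA_real_,
                  annihilated = TRUE))
    f <- res$f
    m <- res$m
    load <- genetic_load(res)
    if (sum((f + m) * iA) / 2 > persistence_level) persist <- persist + 1L
  }
  list(load = load, persistence = persist,
       freq_R = if (is.null(iR)) NA_real_ else sum((f + m) * iR) / 2,
       annihilated = FALSE)
}

run_metrics_two_deme <- function(model, release, horizon, m_rate) {
  target <- make_release(model, release)
  tf <- unclass(target)["female", ]
  tm <- unclass(target)["male", ]
  nf <- numeric(model$gset$n)
  nm <- numeric(model$gset$n)
  wt <- resolve_genotype(model$gset, all_wt_genotype(model))
  nf[wt] <- 0.5
  nm[wt] <- 0.5
  t_load <- NA_real_
  n_load <- NA_real_
  for (t in seq_len(horizon)) {
    res <- two_deme_step_core(model, tf, tm, nf, nm, m_rate)
    if (res$both_dead)
      return(list(target_load = 1, nontarget_load = 1, annihilated = TRUE))
    tf <- res$tf; tm <- res$tm; nf <- res$nf; nm <- res$nm
    t_load <- res$target_load
    n_load <- res$nontarget_load
  }
  list(target_load = t_load, nontarget_load = n_load, annihilated = FALSE)
}

#' Scan a parameter grid
#'
#' Runs one experiment per grid cell and collects the requested metrics.
#' `model_family` is a constructor taking one named scalar argument per axis
#' and returning a drive model, e.g.
#' `function(phi, delta) sdkr_model(drive_params(phi, 0.95, 1),
#' suppression_params("sex_conversion", "dominant", delta))`.
#'
#' Metrics: `threshold` (introduction threshold, `NA` when the system cannot
#' spread), `equilibrium_load_target` / `equilibrium_load_nontarget`
#' (genetic loads after `horizon` generations; the non-target metric runs
#' the two-deme model with migration `migration`), `persistence` (see
#' [persistence_time()]) and `equilibrium_R` (resistance-allele frequency
#' after `horizon` generations).
#'
#' @param model_family function mapping axis values to a drive model.
#' @param axes named list of numeric grid vectors; names must match the
#'   `model_family` arguments.
#' @param metric character vector of metric names (see above).
#' @param release [release_spec()] used for every cell (ignored by
#'   `threshold`).
#' @param horizon generations per cell for equilibrium/persistence metrics.
#' @param migration two-deme migration rate (non-target load metric only).
#' @param persistence_level level for the `persistence` metric.
#' @param threshold_tol,threshold_horizon,threshold_level bisection controls
#'   for the `threshold` metric, as in [find_threshold()].
#' @return object of class `grid_scan`: list with `axes`, `metric` and
#'   `grid`, a data frame of one row per cell (axis columns then metric
#'   columns); the cell count is the product of the axis lengths.
#' @export
scan_grid <- function(model_family, axes,
                      metric = "equilibrium_load_target",
                      release = release_spec(frequency = 0.75),
                      horizon = 1000, migration = 0.02,
                      persistence_level = 0.8,
                      threshold_tol = 0.002, threshold_horizon = 1000,
                      threshold_level = 0.95) {
  known <- c("threshold", "equilibrium_load_target",
             "equilibrium_load_nontarget", "persistence", "equilibrium_R")
  if (!all(metric %in% known))
    stop("unknown metric: ", paste(setdiff(metric, known), collapse = ", "),
         call. = FALSE)
  if (!is.list(axes) || is.null(names(axes)) || any(names(axes) == ""))
    stop("`axes` must be a fully named list of numeric vectors",
         call. = FALSE)
  for (a in names(axes))
    if (any(axes[[a]] < 0 | axes[[a]] > 1))
      stop("axis `", a, "` must lie within [0, 1]", call. = FALSE)

  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  for (mt in metric) grid[[mt]] <- NA_real_

  need_single <- any(c("equilibrium_load_target", "persistence",
                       "equilibrium_R") %in% metric) &&
                 !("equilibrium_load_nontarget" %in% metric)
  need_two <- "equilibrium_load_nontarget" %in% metric

  for (i in seq_len(nrow(grid))) {
    cell <- as.list(grid[i, names(axes), drop = FALSE])
    model <- do.call(model_family, cell)
    if ("threshold" %in% metric) {
      th <- find_threshold(model, tol = threshold_tol,
                           horizon = threshold_horizon,
                           level = threshold_level)
      grid$threshold[i] <- th$threshold
    }
    if (need_two) {
      res <- run_metrics_two_deme(model, release, horizon, migration)
      grid$equilibrium_load_nontarget[i] <- res$nontarget_load
      if ("equilibrium_load_target" %in% metric)
        grid$equilibrium_load_target[i] <- res$target_load
      if (any(c("persistence", "equilibrium_R") %in% metric)) {
        res1 <- run_metrics_single(model, release, horizon,
                                   persistence_level)
        if ("persistence" %in% metric)
          grid$persistence[i] <- res1$persistence
        if ("equilibrium_R" %in% metric)
          grid$equilibrium_R[i] <- res1$freq_R
      }
    } else if (need_single) {
      res <- run_metrics_single(model, release, horizon, persistence_level)
      if ("equilibrium_load_target" %in% metric)
        grid$equilibrium_load_target[i] <- res$load
      if ("persistence" %in% metric)
        grid$persistence[i] <- res$persistence
      if ("equilibrium_R" %in% metric)
        grid$equilibrium_R[i] <- res$freq_R
    }
  }
  structure(list(axes = axes, metric = metric, grid = grid),
            class = "grid_scan")
}

#' @export
print.grid_scan <- function(x, ...) {
  cat("<grid_scan> ", nrow(x$grid), " cells over (",
      paste(names(x$axes), collapse = ", "), "); metrics: ",
      paste(x$metric, collapse = ", "), "\n", sep = "")
  for (mt in x$metric) {
    v <- x$grid[[mt]]
    cat("  ", mt, ": range [", format(min(v, na.rm = TRUE), digits = 4),
        ", ", format(max(v, na.rm = TRUE), digits = 4), "]",
        if (anyNA(v)) paste0(" (", sum(is.na(v)), " NA)"), "\n", sep = "")
  }
  invisible(x)
}
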