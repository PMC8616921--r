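#' Mean per-capita biomass contribution per species
#'
#' Divides biomass by abundance elementwise at occupied sites and averages
#' per species across all sites where the species is present. Species absent
#' from every site are excluded from the result.
#'
#' @param biomass Site-by-species biomass matrix (or `community_matrix`).
#' @param abundance Site-by-species abundance matrix with the same
#'   dimensions; abundance must be positive wherever biomass is positive.
#' @return Named numeric vector, one mean per occurring species.
#' @export
mean_per_capita <- function(biomass, abundance) {
  if (inherits(biomass, "community_matrix")) biomass <- biomass$biomass
  abundance <- as.matrix(abundance)
  stopifnot(identical(dim(biomass), dim(abundance)))
  occ <- biomass > 0
  if (any(occ & abundance <= 0))
    stop("positive biomass with zero abundance; per-capita contribution undefined",
         call. = FALSE)
  keep <- colSums(occ) > 0
  vapply(which(keep), function(j) {
    i <- occ[, j]
    mean(biomass[i, j] / abundance[i, j])
  }, numeric(1), USE.NAMES = TRUE)
}

#' Describe the null-composition randomization of an observed matrix
#'
#' Captures everything the randomization preserves from the observed data:
#' per-site species richness, per-species mean per-capita contribution, and
#' the per-species range of observed integer abundances. Randomized matrices
#' then differ from the observed one only in which species occupy which
#' sites and in resampled abundances.
#'
#' @param m Observed [community_matrix()].
#' @param abundance Observed site-by-species abundance matrix (same
#'   dimensions).
#' @return Object of class `null_spec`: list with `richness_targets` (per
#'   site), `mean_per_capita`, `abundance_min`, `abundance_max` (per
#'   occurring species), `species`, `sites`, `coordinates`.
#' @export
null_spec <- function(m, abundance) {
  stopifnot(inherits(m, "community_matrix"))
  abundance <- as.matrix(abundance)
  stopifnot(identical(dim(m$biomass), dim(abundance)))
  percap <- mean_per_capita(m$biomass, abundance)
  sp <- names(percap)
  occ <- m$biomass[, sp, drop = FALSE] > 0
  ab <- abundance[, sp, drop = FALSE]
  amin <- vapply(seq_along(sp), function(j) min(ab[occ[, j], j]), numeric(1))
  amax <- vapply(seq_along(sp), function(j) max(ab[occ[, j], j]), numeric(1))
  structure(list(
    richness_targets = rowSums(m$biomass > 0),
    mean_per_capita = percap,
    abundance_min = stats::setNames(floor(amin), sp),
    abundance_max = stats::setNames(ceiling(amax), sp),
    species = sp,
    sites = rownames(m$biomass),
    coordinates = m$coordinates
  ), class = "null_spec")
}

#' Simulate one randomized-composition community matrix
#'
#' Builds a "maximum richness" matrix in which every occurring species is
#' present at every site with biomass equal to a uniformly sampled integer
#' abundance (inclusive of both observed bounds) times the species' mean
#' per-capita contribution; then, for each site, retains a uniform random
#' subset of exactly the observed number of species, zeroing the rest.
#' Richness is thereby held at observed levels and per-species biomass stays
#' within the observed per-capita range, while composition is random.
#'
#' @param spec A [null_spec()].
#' @return A [community_matrix()] with the same sites, species, and
#'   coordinates as the observed matrix.
#' @export
simulate_null_matrix <- function(spec) {
  stopifnot(inherits(spec, "null_spec"))
  n_site <- length(spec$sites)
  n_sp <- length(spec$species)
  if (any(spec$richness_targets > n_sp))
    stop("site richness target exceeds the species pool", call. = FALSE)
  # uniform integer abundance on [min, max], inclusive; degenerate when equal
  draw_counts <- function() {
    vapply(seq_len(n_sp), function(j) {
      lo <- spec$abundance_min[[j]]; hi <- spec$abundance_max[[j]]
      if (hi > lo) lo + sample.int(hi - lo + 1L, 1L) - 1L else lo
    }, numeric(1))
  }
  b <- matrix(0, n_site, n_sp, dimnames = list(spec$sites, spec$species))
  for (i in seq_len(n_site)) {
    full <- draw_counts() * spec$mean_per_capita
    keep <- sample.int(n_sp, spec$richness_targets[[i]])
    b[i, keep] <- full[keep]
  }
  community_matrix(b, spec$coordinates)
}

#' Test observed component means against randomized-composition nulls
#'
#' Re-runs the full pairing-and-decomposition pipeline on `n_reps`
#' randomized matrices ([simulate_null_matrix()]) and compares the observed
#' scaled-component means against the null distribution of means. By
#' default the greedy pairing is recomputed per replicate (randomization
#' changes the biomass ordering); set `repairing = "freeze"` to reuse the
#' observed comparison sets instead.
#'
#' Two one-tailed p-values are reported per component, with the tail taken
#' in the direction of the observed deviation from the null mean: a
#' one-sample t-test of the null replicate means against the observed value,
#' and the distribution-free empirical tail proportion
#' `(1 + #{null at least as extreme}) / (n_reps + 1)`.
#'
#' @param m Observed [community_matrix()].
#' @param abundance Observed abundance matrix (same dimensions).
#' @param n_reps Number of randomized replicates (default 1000).
#' @param seed Integer seed for the master RNG stream.
#' @param radius_km,min_comparisons,aggregation Passed to [run_pipeline()].
#' @param repairing `"rerun"` (default) to recompute comparison sets per
#'   replicate, `"freeze"` to reuse the observed sets.
#' @return Object of class `null_distribution`: list with `observed` (scaled
#'   component means), `null_means` (`n_reps` x 5 matrix), `p_empirical`,
#'   `p_ttest`, `tail` (direction per component), `n_reps`.
#' @export
null_test <- function(m, abundance, n_reps = 1000, seed = NULL,
                      radius_km = 100, min_comparisons = 5,
                      aggregation = c("raw", "per-reference"),
                      repairing = c("rerun", "freeze")) {
  aggregation <- match.arg(aggregation)
  repairing <- match.arg(repairing)
  if (n_reps < 2L) stop("n_reps must be at least 2", call. = FALSE)
  obs <- run_pipeline(m, radius_km, min_comparisons, aggregation)
  observed <- stats::setNames(obs$summary$mean, obs$summary$component)
  spec <- null_spec(m, abundance)
  frozen <- if (repairing == "freeze") obs$sets else NULL

  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  null_means <- matrix(NA_real_, n_reps, 5,
                       dimnames = list(NULL, obs$summary$component))
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[[r]])
    sim <- simulate_null_matrix(spec)
    res <- suppressWarnings(
      run_pipeline(sim, radius_km, min_comparisons, aggregation,
                   sets = frozen)
    )
    null_means[r, ] <- res$summary$mean
  }

  mu_null <- colMeans(null_means)
  tail <- ifelse(observed < mu_null, "lower", "upper")
  p_emp <- p_t <- stats::setNames(numeric(5), names(observed))
  for (k in seq_along(observed)) {
    x <- null_means[, k]
    if (tail[[k]] == "lower") {
      p_emp[[k]] <- (1 + sum(x <= observed[[k]])) / (n_reps + 1)
      alt <- "greater"
    } else {
      p_emp[[k]] <- (1 + sum(x >= observed[[k]])) / (n_reps + 1)
      alt <- "less"
    }
    p_t[[k]] <- if (stats::sd(x) == 0) {
      if (all(x == observed[[k]])) 1 else 0
    } else {
      stats::t.test(x, mu = observed[[k]], alternative = alt)$p.value
    }
  }

  structure(list(
    observed = observed,
    null_means = null_means,
    p_empirical = p_emp,
    p_ttest = p_t,
    tail = tail,
    n_reps = n_reps,
    repairing = repairing
  ), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution: %d randomized-composition replicates (%s pairing)\n",
              x$n_reps,
              if (x$repairing == "rerun") "recomputed" else "frozen"))
  out <- data.frame(
    component = names(x$observed),
    observed = round(x$observed, 4),
    null_mean = round(colMeans(x$null_means), 4),
    tail = x$tail,
    p_empirical = signif(x$p_empirical, 3),
    p_ttest = signif(x$p_ttest, 3),
    row.names = NULL
  )
  print(out)
  invisible(x)
}
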