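#' Configuration for the synthetic metacommunity generator
#'
#' Defaults describe a mid-sized reef-fish-like survey: 120 sites in spatial
#' clusters across a 2000-km extent, a regional pool of 100 species with
#' log-normally distributed body sizes (heavy-tailed biomass once cubed
#' through the allometry), per-site richness spanning 30-70 species coupled
#' to a latent site-productivity gradient, overdispersed abundances, and
#' roughly half of the species shared between any two sites.
#'
#' `composition_bias` controls how strongly large-bodied species concentrate
#' at high-productivity (and hence high-biomass, high-richness) sites: 0
#' means species identity is independent of site productivity; larger values
#' weight large species towards productive sites and small species towards
#' unproductive ones.
#'
#' @param n_sites Number of sites.
#' @param pool_size Regional species pool.
#' @param richness_range `c(min, max)` species per site; realized richness
#'   increases with site productivity across this range. The default
#'   (`NULL`) derives the range from `target_overlap`: when species are
#'   drawn exchangeably from the pool, two sites of richness `r` share an
#'   expected `r / pool_size` of their species, so centring the range on
#'   `target_overlap * pool_size` (spanning 0.6-1.4 of it) delivers the
#'   requested overlap without imposing any occupancy structure that the
#'   randomized-composition null model would not also have.
#' @param body_size_meanlog,body_size_sdlog Log-normal parameters of body
#'   length (cm).
#' @param abundance_mu,abundance_size Negative-binomial mean and dispersion
#'   of per-(site, species) abundance (shifted by +1 so present species have
#'   at least one individual).
#' @param composition_bias Dimensionless >= 0; strength of the body-size /
#'   site-productivity association.
#' @param spatial_extent_km Side of the square bounding box.
#' @param n_clusters,cluster_sd_km Sites are scattered around this many
#'   cluster centres with this spread, mimicking the patchy geography of
#'   reef sites; this is what makes radius-based pairing produce several
#'   independent comparison sets.
#' @param target_overlap Expected shared-species fraction between two sites
#'   (shared count over mean richness), default 0.5.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return Object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_sites = 120, pool_size = 100,
                             richness_range = NULL,
                             body_size_meanlog = log(20),
                             body_size_sdlog = 0.8,
                             abundance_mu = 20, abundance_size = 1,
                             composition_bias = 0,
                             spatial_extent_km = 2000,
                             n_clusters = 10, cluster_sd_km = 30,
                             target_overlap = 0.5, seed = 1) {
  stopifnot(n_sites >= 2, pool_size >= 2,
            target_overlap > 0, target_overlap <= 1)
  if (is.null(richness_range)) {
    r_bar <- target_overlap * pool_size
    richness_range <- pmax(1, pmin(pool_size,
                                   round(c(0.6, 1.4) * r_bar)))
  }
  stopifnot(length(richness_range) == 2)
  if (richness_range[1] < 1 || richness_range[2] > pool_size ||
      richness_range[1] > richness_range[2])
    stop("richness_range must lie within [1, pool_size]", call. = FALSE)
  stopifnot(body_size_sdlog >= 0, abundance_mu > 0, abundance_size > 0,
            composition_bias >= 0, spatial_extent_km > 0,
            n_clusters >= 1, cluster_sd_km >= 0)
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a synthetic survey with known statistical structure
#'
#' Builds a seeded metacommunity according to a [generator_config()]:
#'
#' 1. sites scatter around uniformly placed cluster centres in the bounding
#'    box (coordinates in degrees, box anchored at the equator);
#' 2. each species draws one body length from the log-normal; biomass per
#'    individual follows the fixed allometry `0.01 * L^3`;
#' 3. each site draws a latent productivity `u` in (0, 1); its richness
#'    interpolates `richness_range` along `u`;
#' 4. each site draws its species from the pool without replacement with
#'    weights `exp(bias * (u - 1/2) * size_z)` (`size_z` = standardized log
#'    body length): uniform and exchangeable when `composition_bias = 0`
#'    (which is exactly the assumption of the randomized-composition null
#'    model), increasingly concentrating large-bodied species at
#'    high-productivity sites as the bias grows;
#' 5. abundances are shifted negative-binomial draws per (site, species).
#'
#' @param cfg A [generator_config()].
#' @return List with `records` (collapsed long survey rows: one per
#'   site-species, with `size_class_cm` = body length), `matrix`
#'   (biomass [community_matrix()]), `abundance` (matching abundance
#'   matrix), `body_size_cm` (per species), `productivity` (per site), and
#'   `config`.
#' @export
generate_metacommunity <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)

  site_id <- sprintf("S%04d", seq_len(cfg$n_sites))
  species <- sprintf("sp%04d", seq_len(cfg$pool_size))

  # clustered geography inside the box; degrees via the equatorial scale
  km_per_deg <- pi / 180 * 6371
  centres <- cbind(stats::runif(cfg$n_clusters, 0, cfg$spatial_extent_km),
                   stats::runif(cfg$n_clusters, 0, cfg$spatial_extent_km))
  assign_cl <- sample.int(cfg$n_clusters, cfg$n_sites, replace = TRUE)
  xy <- centres[assign_cl, , drop = FALSE] +
    matrix(stats::rnorm(2 * cfg$n_sites, 0, cfg$cluster_sd_km), ncol = 2)
  xy <- pmin(pmax(xy, 0), cfg$spatial_extent_km)
  coords <- data.frame(site_id = site_id,
                       latitude = xy[, 2] / km_per_deg,
                       longitude = xy[, 1] / km_per_deg)

  length_cm <- stats::rlnorm(cfg$pool_size, cfg$body_size_meanlog,
                             cfg$body_size_sdlog)
  ind_mass <- allometric_weight(length_cm, a = 0.01, b = 3)

  u <- stats::runif(cfg$n_sites)
  rmin <- cfg$richness_range[1]; rmax <- cfg$richness_range[2]
  richness <- round(rmin + (rmax - rmin) * u)

  size_z <- as.vector(scale(log(length_cm)))
  if (anyNA(size_z)) size_z <- rep(0, cfg$pool_size)  # all sizes equal

  b <- matrix(0, cfg$n_sites, cfg$pool_size,
              dimnames = list(site_id, species))
  a_mat <- b
  for (i in seq_len(cfg$n_sites)) {
    w <- exp(cfg$composition_bias * (u[i] - 0.5) * size_z)
    chosen <- sample.int(cfg$pool_size, richness[i], prob = w)
    counts <- 1 + stats::rnbinom(length(chosen), size = cfg$abundance_size,
                                 mu = cfg$abundance_mu)
    a_mat[i, chosen] <- counts
    b[i, chosen] <- counts * ind_mass[chosen]
  }

  m <- community_matrix(b, coords)
  ab <- a_mat[rownames(m$biomass), colnames(m$biomass), drop = FALSE]

  rec <- matrix_to_records(m)
  idx <- cbind(match(rec$site_id, rownames(ab)),
               match(rec$species, colnames(ab)))
  rec$abundance <- ab[idx]
  rec$length_cm <- length_cm[match(rec$species, species)]
  rec$size_class_cm <- rec$length_cm
  rec <- rec[, c("site_id", "latitude", "longitude", "species", "abundance",
                 "length_cm", "biomass", "size_class_cm")]

  list(records = rec, matrix = m, abundance = ab,
       body_size_cm = stats::setNames(length_cm, species),
       productivity = stats::setNames(u, site_id),
       config = cfg)
}

#' Mean pairwise shared-species fraction of a community matrix
#'
#' Shared species count divided by the mean richness of the two sites,
#' averaged over all site pairs. Diagnostic used to check generated data
#' against `target_overlap`.
#'
#' @param m A [community_matrix()].
#' @return Single numeric fraction.
#' @export
mean_shared_fraction <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  occ <- m$biomass > 0
  shared <- tcrossprod(occ * 1)      # pairwise shared counts
  rich <- rowSums(occ)
  denom <- outer(rich, rich, function(a, b) (a + b) / 2)
  f <- shared / denom
  mean(f[upper.tri(f)])
}

#' Archetypal two-site contrasts with known decompositions
#'
#' Five minimal reference/comparison pairs, each isolating one way two
#' communities can differ: pure richness loss (unique reference species of
#' average size), richness plus composition loss (unique reference species
#' larger than average), pure richness gain, richness plus composition gain,
#' and a pure context-dependent effect (identical membership, shared species
#' heavier at the reference). Each element carries the expected raw
#' component vector for direct checking.
#'
#' @return Named list of contrasts; each has `reference`, `comparison`
#'   (named biomass vectors), `expected` (named 5-vector), `description`.
#' @examples
#' w <- worked_contrasts()
#' partition_pair(w$pure_richness_loss$reference,
#'                w$pure_richness_loss$comparison)$components
#' @export
worked_contrasts <- function() {
  comp5 <- function(rich_l, comp_l, rich_g, comp_g, cde)
    c(rich_l = rich_l, comp_l = comp_l, rich_g = rich_g, comp_g = comp_g,
      cde = cde)
  list(
    pure_richness_loss = list(
      reference = c(A = 4, B = 4, C = 4), comparison = c(B = 4, C = 4),
      expected = comp5(-4, 0, 0, 0, 0),
      description = "unique reference species matches the shared mean; only richness loss"
    ),
    richness_and_composition_loss = list(
      reference = c(A = 10, B = 4, C = 4), comparison = c(B = 4, C = 4),
      expected = comp5(-4, -6, 0, 0, 0),
      description = "unique reference species larger than shared mean; composition loss adds to richness loss"
    ),
    pure_richness_gain = list(
      reference = c(B = 4, C = 4), comparison = c(B = 4, C = 4, D = 4),
      expected = comp5(0, 0, 4, 0, 0),
      description = "comparison gains an average-sized species; only richness gain"
    ),
    richness_and_composition_gain = list(
      reference = c(B = 4, C = 4), comparison = c(B = 4, C = 4, D = 10),
      expected = comp5(0, 0, 4, 6, 0),
      description = "comparison gains a larger-than-average species; composition gain adds to richness gain"
    ),
    pure_context_effect = list(
      reference = c(B = 6, C = 6), comparison = c(B = 3, C = 3),
      expected = comp5(0, 0, 0, 0, -6),
      description = "identical membership, shared species lighter at the comparison; only the context-dependent effect"
    )
  )
}
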