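# Shared fixtures, all built in code.

# Random community pair with at least one shared species. Biomass is
# log-normal (heavy-tailed, like body-size-driven fish biomass).
random_pair <- function(n_shared = NULL, n_only_b = NULL, n_only_f = NULL) {
  if (is.null(n_shared)) n_shared <- sample(1:8, 1)
  if (is.null(n_only_b)) n_only_b <- sample(0:6, 1)
  if (is.null(n_only_f)) n_only_f <- sample(0:6, 1)
  total <- n_shared + n_only_b + n_only_f
  sp <- sprintf("sp%02d", seq_len(total))
  shared <- sp[seq_len(n_shared)]
  only_b <- sp[n_shared + seq_len(n_only_b)]
  only_f <- sp[n_shared + n_only_b + seq_len(n_only_f)]
  draw <- function(n) stats::rlnorm(n, meanlog = 2, sdlog = 1.2)
  ref <- c(stats::setNames(draw(n_shared), shared),
           stats::setNames(draw(n_only_b), only_b))
  comp <- c(stats::setNames(draw(n_shared), shared),
            stats::setNames(draw(n_only_f), only_f))
  list(reference = ref, comparison = comp)
}

# The worked pair used throughout: reference {A:10, B:6, C:2},
# comparison {B:4, C:4, D:1}; components (-4, -6, +4, -3, 0).
worked_pair <- function() {
  list(reference = c(A = 10, B = 6, C = 2),
       comparison = c(B = 4, C = 4, D = 1))
}

# Tiny survey with transects: 2 sites, 3 species, uneven transect effort.
transect_records <- function() {
  data.frame(
    site_id = c("s1", "s1", "s1", "s1", "s2", "s2"),
    latitude = c(0, 0, 0, 0, 1, 1),
    longitude = c(0, 0, 0, 0, 1, 1),
    transect_id = c("t1", "t2", "t1", "t2", "t1", "t2"),
    species = c("carp", "carp", "pike", "sole", "carp", "carp"),
    abundance = c(2, 4, 1, 1, 3, 3),
    biomass = c(3, 6, 9, 12, 4, 4),
    stringsAsFactors = FALSE
  )
}

# Collinear sites along the equator at given km offsets, with biomass set so
# the greedy pass is easy to trace by hand.
collinear_matrix <- function(km = c(0, 10, 20, 200, 210),
                             biomass = c(100, 50, 40, 90, 10)) {
  n <- length(km)
  sites <- sprintf("site%02d", seq_len(n))
  km_per_deg <- pi / 180 * 6371
  # two species per site, one shared everywhere, keeps pairs decomposable
  b <- cbind(common = biomass * 0.6, rare = biomass * 0.4)
  rownames(b) <- sites
  community_matrix(b, data.frame(site_id = sites, latitude = 0,
                                 longitude = km / km_per_deg))
}

small_config <- function(...) {
  generator_config(n_sites = 30, pool_size = 40, n_clusters = 4,
                   spatial_extent_km = 800, ...)
}
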