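#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6371 km, via
#' [geosphere::distHaversine()].
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorised).
#' @return Distance(s) in km.
#' @examples
#' haversine_km(0, 0, 0, 1)  # ~111.195
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_coordinates(c(lat1, lat2), c(lon1, lon2))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Greedy pairing of high-biomass reference sites with nearby comparisons
#'
#' Orders sites by decreasing total biomass (ties broken by site id) and
#' repeatedly takes the highest-biomass unused site as a reference, claiming
#' every unused site within `radius_km` (great-circle) as its comparisons.
#' Reference and comparisons are then removed from the pool, so no site ever
#' appears in more than one set. A set is flagged `included` iff it has at
#' least `min_comparisons` comparison sites; sets failing the cutoff still
#' consume their sites but are excluded from downstream aggregation.
#'
#' @param m A [community_matrix()].
#' @param radius_km Pairing radius in km (the study radii are 15, 25, 50,
#'   100).
#' @param min_comparisons Minimum comparisons for a set to enter the means
#'   (default 5).
#' @return Object of class `comparison_sets`: list of sets, each with
#'   `reference_id`, `comparison_ids`, `distance_km` (to each comparison),
#'   `radius_km`, `included`.
#' @export
build_comparison_sets <- function(m, radius_km, min_comparisons = 5) {
  stopifnot(inherits(m, "community_matrix"), radius_km > 0)
  tot <- site_totals(m)
  if (nrow(tot) < 2L) stop("need at least two sites", call. = FALSE)
  # decreasing biomass, site id as deterministic tie-break
  ord <- order(-tot$total_biomass, tot$site_id)
  pool <- tot$site_id[ord]
  co <- m$coordinates
  lat <- co$latitude[match(pool, co$site_id)]
  lon <- co$longitude[match(pool, co$site_id)]
  names(lat) <- names(lon) <- pool

  sets <- list()
  while (length(pool) > 0L) {
    ref <- pool[1L]
    rest <- pool[-1L]
    if (length(rest) > 0L) {
      d <- haversine_km(lat[[ref]], lon[[ref]], lat[rest], lon[rest])
      near <- d <= radius_km
      comps <- rest[near]
      dist_km <- d[near]
    } else {
      comps <- character(0)
      dist_km <- numeric(0)
    }
    sets[[length(sets) + 1L]] <- list(
      reference_id = ref,
      comparison_ids = comps,
      distance_km = unname(dist_km),
      radius_km = radius_km,
      included = length(comps) >= min_comparisons
    )
    pool <- setdiff(rest, comps)
  }
  structure(sets, class = "comparison_sets",
            min_comparisons = min_comparisons)
}

#' @export
print.comparison_sets <- function(x, ...) {
  inc <- vapply(x, `[[`, TRUE, "included")
  nc <- vapply(x, function(s) length(s$comparison_ids), 0L)
  cat(sprintf("comparison_sets: %d reference sites (%d included, >= %d comparisons)\n",
              length(x), sum(inc), attr(x, "min_comparisons")))
  cat(sprintf("  comparisons per reference: mean %.1f, range %d-%d\n",
              mean(nc), min(nc), max(nc)))
  invisible(x)
}

#' Decompose and aggregate all reference/comparison pairs
#'
#' Runs the full spatial analysis on a community matrix: greedy pairing
#' ([build_comparison_sets()]), per-pair decomposition
#' ([partition_pair()]) and scaling ([scale_components()]), then component
#' means with normal-approximation 95% confidence intervals. Pairs without
#' shared species are skipped with a warning and counted in the diagnostics.
#'
#' Two aggregation modes: `"raw"` averages the scaled components over all
#' pairs from included sets; `"per-reference"` first averages within each
#' reference site and then takes the grand mean of those averages, so that
#' references with many comparisons do not dominate.
#'
#' @param m A [community_matrix()].
#' @param radius_km Pairing radius in km.
#' @param min_comparisons Minimum comparisons per included reference
#'   (default 5).
#' @param aggregation `"raw"` (default) or `"per-reference"`.
#' @param sets Optional precomputed `comparison_sets` (e.g. to freeze the
#'   observed pairing when decomposing a randomized matrix).
#' @return Object of class `pipeline_result`: list with `pairs` (one row per
#'   decomposed pair: ids, distance, species counts, shared fraction, raw and
#'   scaled components, `div`, `delta_T`, `q`, `included`), `summary`
#'   (per-component mean, se, 95% CI over included pairs under the chosen
#'   mode), `sets`, `aggregation`, and `diagnostics` (skipped pairs, count of
#'   pairs whose richness-loss magnitude exceeds the reference total).
#' @export
run_pipeline <- function(m, radius_km = 100, min_comparisons = 5,
                         aggregation = c("raw", "per-reference"),
                         sets = NULL) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(m, "community_matrix"))
  if (is.null(sets))
    sets <- build_comparison_sets(m, radius_km, min_comparisons)

  rows <- list()
  n_skipped <- 0L
  for (s in sets) {
    ref_vec <- m$biomass[s$reference_id, ]
    for (k in seq_along(s$comparison_ids)) {
      cid <- s$comparison_ids[[k]]
      comp_vec <- m$biomass[cid, ]
      d <- tryCatch(partition_pair(ref_vec, comp_vec), error = function(e) e)
      if (inherits(d, "error")) {
        warning("skipping pair ", s$reference_id, " vs ", cid, ": ",
                conditionMessage(d), call. = FALSE)
        n_skipped <- n_skipped + 1L
        next
      }
      sc <- scale_components(d)
      r_b <- d$s_uB + d$s_c
      r_f <- d$s_uF + d$s_c
      rows[[length(rows) + 1L]] <- data.frame(
        reference_id = s$reference_id, comparison_id = cid,
        distance_km = s$distance_km[[k]],
        s_uB = d$s_uB, s_c = d$s_c, s_uF = d$s_uF,
        shared_fraction = d$s_c / ((r_b + r_f) / 2),
        richness_change = (r_f - r_b) / r_b,
        rich_l = d$components[["rich_l"]], comp_l = d$components[["comp_l"]],
        rich_g = d$components[["rich_g"]], comp_g = d$components[["comp_g"]],
        cde = d$components[["cde"]],
        div = d$div, delta_T = d$delta_T,
        scaled_rich_l = sc[["rich_l"]], scaled_comp_l = sc[["comp_l"]],
        scaled_rich_g = sc[["rich_g"]], scaled_comp_g = sc[["comp_g"]],
        scaled_cde = sc[["cde"]],
        q = q_statistic(d),
        rich_l_exceeds_tb = d$rich_l_exceeds_tb,
        included = s$included,
        stringsAsFactors = FALSE
      )
    }
  }
  pairs <- if (length(rows) > 0L) do.call(rbind, rows) else
    empty_pairs_frame()
  rownames(pairs) <- NULL

  used <- pairs[pairs$included, , drop = FALSE]
  if (nrow(used) == 0L)
    warning("no included comparison sets (all below min_comparisons)",
            call. = FALSE)
  summary <- aggregate_components(used, aggregation)

  structure(list(
    pairs = pairs,
    summary = summary,
    sets = sets,
    aggregation = aggregation,
    radius_km = radius_km,
    diagnostics = list(
      n_pairs = nrow(pairs),
      n_included_pairs = nrow(used),
      n_skipped_no_shared = n_skipped,
      n_rich_l_exceeds_tb = sum(pairs$rich_l_exceeds_tb)
    )
  ), class = "pipeline_result")
}

scaled_cols <- c("scaled_rich_l", "scaled_comp_l", "scaled_rich_g",
                 "scaled_comp_g", "scaled_cde")

aggregate_components <- function(used, aggregation) {
  comp_names <- c("rich_l", "comp_l", "rich_g", "comp_g", "cde")
  if (nrow(used) == 0L) {
    return(data.frame(component = comp_names, mean = NA_real_, se = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_, n = 0L))
  }
  vals <- if (aggregation == "per-reference") {
    do.call(rbind, lapply(split(used[scaled_cols], used$reference_id),
                          colMeans))
  } else {
    as.matrix(used[scaled_cols])
  }
  mu <- colMeans(vals)
  se <- apply(vals, 2, stats::sd) / sqrt(nrow(vals))
  data.frame(
    component = comp_names,
    mean = unname(mu),
    se = unname(se),
    ci_low = unname(mu - 1.96 * se),
    ci_high = unname(mu + 1.96 * se),
    n = nrow(vals),
    row.names = NULL
  )
}

empty_pairs_frame <- function() {
  data.frame(
    reference_id = character(0), comparison_id = character(0),
    distance_km = numeric(0), s_uB = integer(0), s_c = integer(0),
    s_uF = integer(0), shared_fraction = numeric(0),
    richness_change = numeric(0),
    rich_l = numeric(0), comp_l = numeric(0), rich_g = numeric(0),
    comp_g = numeric(0), cde = numeric(0), div = numeric(0),
    delta_T = numeric(0),
    scaled_rich_l = numeric(0), scaled_comp_l = numeric(0),
    scaled_rich_g = numeric(0), scaled_comp_g = numeric(0),
    scaled_cde = numeric(0), q = numeric(0),
    rich_l_exceeds_tb = logical(0), included = logical(0),
    stringsAsFactors = FALSE
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: radius %.0f km, %d pairs (%d in included sets), aggregation '%s'\n",
              x$radius_km, x$diagnostics$n_pairs,
              x$diagnostics$n_included_pairs, x$aggregation))
  print(transform(x$summary, mean = round(mean, 4), se = round(se, 4),
                  ci_low = round(ci_low, 4), ci_high = round(ci_high, 4)))
  if (x$diagnostics$n_skipped_no_shared > 0L)
    cat(sprintf("  %d pair(s) skipped: no shared species\n",
                x$diagnostics$n_skipped_no_shared))
  invisible(x)
}
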