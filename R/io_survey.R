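#' Read a long-format survey table
#'
#' Expects a delimited text file with header and columns `site_id`,
#' `latitude`, `longitude`, `species`, `abundance`, and at least one of
#' `length_cm` or `biomass`; optional `transect_id` and `size_class_cm`.
#' Identifiers are whitespace-trimmed; species matching downstream is exact
#' string match (no taxonomic resolution).
#'
#' @param file Path to the survey file.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return Data frame of survey records.
#' @export
read_survey <- function(file, sep = ",") {
  rec <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("site_id", "latitude", "longitude", "species", "abundance")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0L)
    stop("survey file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!any(c("length_cm", "biomass") %in% names(rec)))
    stop("survey file needs a length_cm or biomass column", call. = FALSE)
  rec$site_id <- trimws(as.character(rec$site_id))
  rec$species <- trimws(as.character(rec$species))
  if (any(rec$abundance < 0, na.rm = TRUE))
    stop("negative abundance in survey file", call. = FALSE)
  check_coordinates(rec$latitude, rec$longitude)
  coord_per_site <- unique(rec[, c("site_id", "latitude", "longitude")])
  if (anyDuplicated(coord_per_site$site_id)) {
    bad <- coord_per_site$site_id[duplicated(coord_per_site$site_id)]
    stop("conflicting coordinates for site(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  rec
}

#' Read length-weight coefficients
#'
#' One row per species with the allometric scale coefficient `a` and exponent
#' `b` of the standard length-weight relationship `W = a * L^b`.
#'
#' @param file Path to a delimited file with columns `species`, `a`, `b`.
#' @param sep Field separator.
#' @return Data frame with columns `species`, `a`, `b`.
#' @export
read_lw_coefficients <- function(file, sep = ",") {
  cf <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("species", "a", "b") %in% names(cf)))
    stop("coefficient file needs columns species, a, b", call. = FALSE)
  cf$species <- trimws(as.character(cf$species))
  if (anyDuplicated(cf$species))
    stop("duplicate species in coefficient file", call. = FALSE)
  if (any(cf$a <= 0) || any(cf$b <= 0))
    stop("length-weight coefficients must be positive", call. = FALSE)
  cf
}

#' Convert observed lengths to weights by the allometric relationship
#'
#' Applies `W = a * L^b` per species. Records that already carry biomass are
#' left untouched; coefficients are required only for species whose records
#' have lengths but no biomass.
#'
#' @param records Survey records (see [read_survey()]).
#' @param coefficients Data frame with `species`, `a`, `b`
#'   (see [read_lw_coefficients()]).
#' @return `records` with a fully populated `biomass` column; biomass of a
#'   record is `abundance * a * length_cm^b` when converted from length.
#' @export
length_to_weight <- function(records, coefficients) {
  if (is.null(records$biomass)) records$biomass <- NA_real_
  needs <- is.na(records$biomass)
  if (!any(needs)) return(records)
  if (is.null(records$length_cm) || anyNA(records$length_cm[needs]))
    stop("records without biomass must carry length_cm", call. = FALSE)
  sp <- unique(records$species[needs])
  missing_sp <- setdiff(sp, coefficients$species)
  if (length(missing_sp) > 0L)
    stop("no length-weight coefficients for species: ",
         paste(sort(missing_sp), collapse = ", "), call. = FALSE)
  i <- match(records$species[needs], coefficients$species)
  w <- coefficients$a[i] * records$length_cm[needs]^coefficients$b[i]
  w[records$length_cm[needs] == 0] <- 0
  records$biomass[needs] <- records$abundance[needs] * w
  records
}

#' Per-individual weight from length
#'
#' The bare allometric conversion `W = a * L^b` for a single species.
#'
#' @param length_cm Observed total length in cm (non-negative).
#' @param a Scale coefficient, > 0.
#' @param b Allometric exponent, > 0.
#' @return Mass per individual, 0 when `length_cm` is 0.
#' @examples
#' allometric_weight(10, a = 0.01, b = 3)  # 10
#' @export
allometric_weight <- function(length_cm, a, b) {
  stopifnot(all(length_cm >= 0), all(a > 0), all(b > 0))
  ifelse(length_cm == 0, 0, a * length_cm^b)
}

#' Collapse replicate transects to one site-level mean per species
#'
#' Averages biomass (and abundance) over all transects surveyed at a site,
#' counting a species as 0 on transects where it was not recorded: the
#' divisor is the number of transects surveyed at the site, not the number of
#' transects where the species occurred. This yields a per-survey mean that
#' is comparable across sites with different survey effort. Set
#' `occupied_only = TRUE` to instead divide by the number of transects where
#' the species was recorded.
#'
#' @param records Survey records with resolved `biomass` and a `transect_id`
#'   column.
#' @param occupied_only Divide by occupied rather than surveyed transects.
#' @return Data frame with one row per (site, species): `site_id`,
#'   `latitude`, `longitude`, `species`, `abundance`, `biomass`, plus
#'   `size_class_cm` (abundance-weighted mean over transects) when present.
#' @export
collapse_transects <- function(records, occupied_only = FALSE) {
  if (is.null(records$transect_id))
    stop("records have no transect_id column", call. = FALSE)
  if (anyNA(records$biomass))
    stop("resolve biomass (length_to_weight) before collapsing transects",
         call. = FALSE)
  n_transects <- tapply(records$transect_id, records$site_id,
                        function(x) length(unique(x)))
  if (any(n_transects < 1L)) stop("site with zero transects", call. = FALSE)

  key <- interaction(records$site_id, records$species, drop = TRUE, sep = "\r")
  agg <- function(v, f) as.vector(tapply(v, key, f))
  parts <- strsplit(levels(key), "\r", fixed = TRUE)
  out <- data.frame(
    site_id = vapply(parts, `[`, "", 1L),
    species = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
  # tapply returns groups in factor-level order, matching `parts`
  out$biomass_sum <- agg(records$biomass, sum)
  out$abundance_sum <- agg(records$abundance, sum)
  out$n_occupied <- agg(records$transect_id, function(x) length(unique(x)))
  co <- unique(records[, c("site_id", "latitude", "longitude")])
  out$latitude <- co$latitude[match(out$site_id, co$site_id)]
  out$longitude <- co$longitude[match(out$site_id, co$site_id)]

  divisor <- if (occupied_only) out$n_occupied else
    as.vector(n_transects[out$site_id])
  out$biomass <- out$biomass_sum / divisor
  out$abundance <- out$abundance_sum / divisor
  if (!is.null(records$size_class_cm)) {
    wsum <- agg(records$size_class_cm * records$abundance, sum)
    out$size_class_cm <- ifelse(out$abundance_sum > 0,
                                wsum / out$abundance_sum, NA_real_)
  }
  keep <- c("site_id", "latitude", "longitude", "species", "abundance",
            "biomass", intersect("size_class_cm", names(out)))
  out <- out[order(out$site_id, out$species), keep]
  rownames(out) <- NULL
  out
}

#' Pivot collapsed records to a site-by-species community matrix
#'
#' @param records Collapsed records: exactly one row per (site, species),
#'   with columns `site_id`, `latitude`, `longitude`, `species`, `biomass`.
#' @param value Column to pivot, `"biomass"` (default) or `"abundance"`.
#' @return A [community_matrix()]; absent (site, species) pairs are 0, sites
#'   and species ordered lexicographically.
#' @export
to_matrix <- function(records, value = "biomass") {
  if (nrow(records) == 0L) stop("no records to pivot", call. = FALSE)
  if (!value %in% names(records))
    stop("records have no '", value, "' column", call. = FALSE)
  dup <- duplicated(records[, c("site_id", "species")])
  if (any(dup)) {
    d <- records[dup, c("site_id", "species")][1, ]
    stop("duplicate record for site '", d$site_id, "', species '", d$species,
         "'; collapse transects first", call. = FALSE)
  }
  sites <- sort(unique(records$site_id))
  species <- sort(unique(records$species))
  b <- matrix(0, nrow = length(sites), ncol = length(species),
              dimnames = list(sites, species))
  b[cbind(match(records$site_id, sites), match(records$species, species))] <-
    records[[value]]
  co <- unique(records[, c("site_id", "latitude", "longitude")])
  community_matrix(b, co)
}
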