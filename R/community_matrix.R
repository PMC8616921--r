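#' Construct a site-by-species community biomass matrix
#'
#' The substrate of the pairing pipeline: a wide non-negative matrix with
#' sites as rows and species as columns, plus one (latitude, longitude) pair
#' per site. A species is present at a site iff its value is strictly
#' positive; zeros are absences.
#'
#' @param biomass Numeric matrix (or data frame) of non-negative biomass,
#'   sites in rows (rownames = site ids), species in columns (colnames).
#' @param coordinates Data frame with columns `site_id`, `latitude`,
#'   `longitude`, one row per site in `biomass`.
#' @return Object of class `community_matrix`: list with elements `biomass`
#'   (matrix, rows/columns sorted lexicographically) and `coordinates`
#'   (data frame aligned to the matrix rows).
#' @export
community_matrix <- function(biomass, coordinates) {
  biomass <- as.matrix(biomass)
  if (!is.numeric(biomass)) stop("biomass matrix must be numeric", call. = FALSE)
  if (is.null(rownames(biomass)) || is.null(colnames(biomass)))
    stop("biomass matrix needs site rownames and species colnames", call. = FALSE)
  if (anyDuplicated(rownames(biomass)))
    stop("duplicate site identifiers in biomass matrix", call. = FALSE)
  if (anyDuplicated(colnames(biomass)))
    stop("duplicate species identifiers in biomass matrix", call. = FALSE)
  if (anyNA(biomass) || any(biomass < 0))
    stop("biomass values must be non-negative and non-missing", call. = FALSE)

  coordinates <- as.data.frame(coordinates)
  need <- c("site_id", "latitude", "longitude")
  if (!all(need %in% names(coordinates)))
    stop("coordinates need columns site_id, latitude, longitude", call. = FALSE)
  coordinates$site_id <- trimws(as.character(coordinates$site_id))
  coordinates <- unique(coordinates[, need])
  if (anyDuplicated(coordinates$site_id))
    stop("conflicting coordinates for at least one site", call. = FALSE)
  missing_sites <- setdiff(rownames(biomass), coordinates$site_id)
  if (length(missing_sites) > 0L)
    stop("no coordinates for site(s): ", paste(missing_sites, collapse = ", "),
         call. = FALSE)
  check_coordinates(coordinates$latitude, coordinates$longitude)

  ord_sites <- order(rownames(biomass))
  ord_sp <- order(colnames(biomass))
  biomass <- biomass[ord_sites, ord_sp, drop = FALSE]
  coordinates <- coordinates[match(rownames(biomass), coordinates$site_id), ]
  rownames(coordinates) <- NULL

  structure(list(biomass = biomass, coordinates = coordinates),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  b <- x$biomass
  cat(sprintf("community_matrix: %d sites x %d species\n", nrow(b), ncol(b)))
  cat(sprintf("  total biomass %.4g; occupancy %.1f%%\n",
              sum(b), 100 * mean(b > 0)))
  cat(sprintf("  latitude range [%.3f, %.3f], longitude range [%.3f, %.3f]\n",
              min(x$coordinates$latitude), max(x$coordinates$latitude),
              min(x$coordinates$longitude), max(x$coordinates$longitude)))
  invisible(x)
}

#' Per-site total biomass and richness
#'
#' @param m A `community_matrix`.
#' @return Data frame with `site_id`, `total_biomass`, `richness`.
#' @export
site_totals <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  data.frame(
    site_id = rownames(m$biomass),
    total_biomass = rowSums(m$biomass),
    richness = rowSums(m$biomass > 0),
    row.names = NULL
  )
}

#' Melt a community matrix back to long records
#'
#' Inverse of [to_matrix()]: emits one row per (site, species) pair with
#' positive biomass, with coordinates attached.
#'
#' @param m A `community_matrix`.
#' @return Data frame with `site_id`, `latitude`, `longitude`, `species`,
#'   `biomass`, sorted by site then species.
#' @export
matrix_to_records <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  idx <- which(m$biomass > 0, arr.ind = TRUE)
  out <- data.frame(
    site_id = rownames(m$biomass)[idx[, 1]],
    species = colnames(m$biomass)[idx[, 2]],
    biomass = m$biomass[idx],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$site_id, out$species), ]
  co <- m$coordinates
  out$latitude <- co$latitude[match(out$site_id, co$site_id)]
  out$longitude <- co$longitude[match(out$site_id, co$site_id)]
  rownames(out) <- NULL
  out[, c("site_id", "latitude", "longitude", "species", "biomass")]
}

#' Read a wide site-by-species matrix and its coordinates from delimited text
#'
#' @param matrix_file Path to a delimited file whose first column is
#'   `site_id` and remaining columns are species biomasses.
#' @param coords_file Path to a delimited file with columns `site_id`,
#'   `latitude`, `longitude`.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return A `community_matrix`.
#' @export
read_matrix <- function(matrix_file, coords_file, sep = ",") {
  wide <- utils::read.table(matrix_file, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(wide) < 2L) stop("matrix file needs site_id plus species columns",
                            call. = FALSE)
  sites <- trimws(as.character(wide[[1]]))
  b <- as.matrix(wide[, -1, drop = FALSE])
  rownames(b) <- sites
  colnames(b) <- trimws(colnames(b))
  co <- utils::read.table(coords_file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  community_matrix(b, co)
}

check_coordinates <- function(lat, lon) {
  if (anyNA(lat) || anyNA(lon) || any(lat < -90 | lat > 90) ||
      any(lon < -180 | lon > 180))
    stop("coordinates out of range: latitude in [-90, 90], longitude in [-180, 180]",
         call. = FALSE)
  invisible(TRUE)
}
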