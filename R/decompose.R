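#' Five-component partition of a between-site biomass difference
#'
#' Decomposes the difference in total additive biomass between a reference
#' community `B` and a comparison community `F` into five components. Species
#' present in both communities ("shared" species) serve as the frame of
#' reference: the mean biomass per shared species is the "expected"
#' contribution of any species at that site.
#'
#' Writing `s_uB`, `s_c`, `s_uF` for the counts of species unique to the
#' reference, shared, and unique to the comparison, and `z_uB`, `z_cB`,
#' `z_cF`, `z_uF` for the corresponding mean biomasses per species, the
#' difference `T_F - T_B` in total biomass splits exactly into
#'
#' * `RICH_L = -s_uB * z_cB` — loss expected from the number of species
#'   absent from the comparison site, were each an average shared species;
#' * `COMP_L = -s_uB * (z_uB - z_cB)` — additional loss (or gain) because the
#'   absent species deviate from the shared-species mean;
#' * `RICH_G = +s_uF * z_cF` — gain expected from the number of species
#'   present only at the comparison site;
#' * `COMP_G = +s_uF * (z_uF - z_cF)` — deviation of those gained species
#'   from the shared-species mean at the comparison site;
#' * `CDE = s_c * (z_cF - z_cB)` — the context-dependent effect: biomass
#'   change among shared species only, i.e. extrinsic drivers rather than
#'   membership change.
#'
#' The first four terms sum to the total diversity effect `DIV`. A species is
#' present iff its biomass is strictly positive; zero entries are absences.
#' Means over empty sets (no unique species on one side) are defined as 0 so
#' the corresponding terms vanish.
#'
#' @param reference Named numeric vector of non-negative biomass per species
#'   for the reference community (conventionally the higher-biomass site).
#' @param comparison Named numeric vector of non-negative biomass per species
#'   for the comparison community.
#' @return An object of class `pair_decomposition`: a list with the species
#'   counts (`s_uB`, `s_c`, `s_uF`), group means (`z_uB`, `z_cB`, `z_cF`,
#'   `z_uF`), deviations (`delta_B`, `delta_F`), totals (`T_B`, `T_F`,
#'   `delta_T`), the component vector `components` (named `rich_l`, `comp_l`,
#'   `rich_g`, `comp_g`, `cde`), `div`, and `rich_l_exceeds_tb` (flag set when
#'   `|RICH_L| > T_B`, a documented edge case left uncorrected because scaled
#'   components are the primary surface).
#' @examples
#' b <- c(A = 10, B = 6, C = 2)
#' f <- c(B = 4, C = 4, D = 1)
#' d <- partition_pair(b, f)
#' d$components            # (-4, -6, +4, -3, 0)
#' sum(d$components)       # equals d$delta_T = -9
#' @seealso [scale_components()], [fox_kerr_partition()], [q_statistic()]
#' @export
partition_pair <- function(reference, comparison) {
  reference <- check_community(reference, "reference")
  comparison <- check_community(comparison, "comparison")

  sp_b <- names(reference)[reference > 0]
  sp_f <- names(comparison)[comparison > 0]
  shared <- intersect(sp_b, sp_f)
  only_b <- setdiff(sp_b, sp_f)
  only_f <- setdiff(sp_f, sp_b)

  if (length(shared) == 0L) {
    stop("no shared species between reference and comparison communities; ",
         "the decomposition is undefined", call. = FALSE)
  }

  s_ub <- length(only_b)
  s_c <- length(shared)
  s_uf <- length(only_f)

  mean0 <- function(x) if (length(x) == 0L) 0 else mean(x)
  z_ub <- mean0(reference[only_b])
  z_cb <- mean(reference[shared])
  z_cf <- mean(comparison[shared])
  z_uf <- mean0(comparison[only_f])

  delta_b <- z_ub - z_cb
  delta_f <- z_uf - z_cf

  comp <- c(
    rich_l = -s_ub * z_cb,
    comp_l = -s_ub * delta_b,
    rich_g = +s_uf * z_cf,
    comp_g = +s_uf * delta_f,
    cde    = s_c * (z_cf - z_cb)
  )

  t_b <- sum(reference[sp_b])
  t_f <- sum(comparison[sp_f])

  structure(list(
    s_uB = s_ub, s_c = s_c, s_uF = s_uf,
    z_uB = z_ub, z_cB = z_cb, z_cF = z_cf, z_uF = z_uf,
    delta_B = delta_b, delta_F = delta_f,
    T_B = t_b, T_F = t_f, delta_T = t_f - t_b,
    components = comp,
    div = sum(comp[c("rich_l", "comp_l", "rich_g", "comp_g")]),
    rich_l_exceeds_tb = abs(comp[["rich_l"]]) > t_b
  ), class = "pair_decomposition")
}

#' @export
print.pair_decomposition <- function(x, ...) {
  cat("Pair decomposition of biomass difference\n")
  cat(sprintf("  species: %d unique to reference, %d shared, %d unique to comparison\n",
              x$s_uB, x$s_c, x$s_uF))
  cat(sprintf("  totals:  T_B = %.4g, T_F = %.4g, difference = %.4g\n",
              x$T_B, x$T_F, x$delta_T))
  print(round(x$components, 4))
  cat(sprintf("  DIV = %.4g, CDE = %.4g\n", x$div, x$components[["cde"]]))
  if (isTRUE(x$rich_l_exceeds_tb))
    cat("  note: |RICH_L| exceeds total reference biomass\n")
  invisible(x)
}

#' Scale decomposition components to the interval (-1, 1)
#'
#' Divides each component by the sum of the absolute values of all five, so
#' that the scaled absolute values sum to 1. This relativization makes pairs
#' comparable when raw biomass differs by orders of magnitude between sites
#' and regions. When every raw component is 0 (identical communities) the
#' scaled vector is all zeros.
#'
#' @param d A `pair_decomposition` object, or a numeric vector of the five
#'   raw components (order `rich_l`, `comp_l`, `rich_g`, `comp_g`, `cde`).
#' @return Named numeric vector of length 5 in `[-1, 1]`.
#' @examples
#' scale_components(c(-4, -6, 4, -3, 0))  # divides by 17
#' @export
scale_components <- function(d) {
  comp <- if (inherits(d, "pair_decomposition")) d$components else d
  if (!is.numeric(comp) || length(comp) != 5L)
    stop("expected a pair_decomposition or a numeric vector of 5 components",
         call. = FALSE)
  names(comp) <- c("rich_l", "comp_l", "rich_g", "comp_g", "cde")
  denom <- sum(abs(comp))
  if (denom == 0) return(comp * 0)
  comp / denom
}

#' Alternative partition relative to the whole-community species mean
#'
#' Partitions the same biomass difference as [partition_pair()] but measures
#' unique species against the mean over *all* species in their community
#' (`T_B / s_B`, `T_F / s_F`) rather than the shared-species mean. The two
#' partitions agree exactly on the context-dependent effect and on the summed
#' four-term diversity effect, but distribute the diversity effect
#' differently between richness and composition terms; the shared-species
#' version used elsewhere in this package works with the unique-versus-shared
#' deviation directly. Useful as an independent cross-check.
#'
#' Components: `sre_l = -s_uB * zbar_B`, `sce_l = s_c * (z_cB - zbar_B)`,
#' `sre_g = +s_uF * zbar_F`, `sce_g = s_c * (zbar_F - z_cF)`, and `cde` as in
#' [partition_pair()], with `zbar_B = T_B / s_B` the all-species mean.
#'
#' @inheritParams partition_pair
#' @return Object of class `fox_kerr_decomposition` with the component vector
#'   (`sre_l`, `sce_l`, `sre_g`, `sce_g`, `cde`), `div`, and `delta_T`.
#' @examples
#' b <- c(A = 10, B = 6, C = 2)
#' f <- c(B = 4, C = 4, D = 1)
#' fox_kerr_partition(b, f)$components  # (-6, -4, +3, -2, 0)
#' @export
fox_kerr_partition <- function(reference, comparison) {
  d <- partition_pair(reference, comparison)
  s_b <- d$s_uB + d$s_c
  s_f <- d$s_uF + d$s_c
  zbar_b <- d$T_B / s_b
  zbar_f <- d$T_F / s_f
  comp <- c(
    sre_l = -d$s_uB * zbar_b,
    sce_l = d$s_c * (d$z_cB - zbar_b),
    sre_g = +d$s_uF * zbar_f,
    sce_g = d$s_c * (zbar_f - d$z_cF),
    cde   = d$components[["cde"]]
  )
  structure(list(
    components = comp,
    div = sum(comp[c("sre_l", "sce_l", "sre_g", "sce_g")]),
    delta_T = d$delta_T
  ), class = "fox_kerr_decomposition")
}

#' @export
print.fox_kerr_decomposition <- function(x, ...) {
  cat("Whole-community-mean partition of biomass difference\n")
  print(round(x$components, 4))
  cat(sprintf("  DIV = %.4g, difference = %.4g\n", x$div, x$delta_T))
  invisible(x)
}

# validate a community vector: named, numeric, non-negative, non-empty
check_community <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0L)
    stop(what, " community must be a non-empty numeric vector", call. = FALSE)
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    stop(what, " community must have species names", call. = FALSE)
  if (anyDuplicated(names(x)))
    stop(what, " community has duplicated species names", call. = FALSE)
  if (anyNA(x) || any(x < 0))
    stop(what, " community has missing or negative biomass", call. = FALSE)
  if (all(x == 0))
    stop(what, " community is empty (all biomass zero)", call. = FALSE)
  x
}
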