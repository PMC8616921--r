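#' Ratio of unique- to shared-species mean biomass at the reference (Q)
#'
#' For a pair decomposition, `Q = (COMP_L + RICH_L) / RICH_L`, which reduces
#' algebraically to `z_uB / z_cB`: the mean biomass of species unique to the
#' reference relative to the "expected" (shared-species) contribution per
#' species. Q > 1 means the species missing from the comparison site are
#' larger-than-average contributors.
#'
#' @param d A `pair_decomposition` from [partition_pair()].
#' @return The ratio, or `NA` when undefined (`s_uB = 0` or `z_cB = 0`).
#' @export
q_statistic <- function(d) {
  stopifnot(inherits(d, "pair_decomposition"))
  if (d$s_uB == 0L || d$z_cB == 0) return(NA_real_)
  d$z_uB / d$z_cB
}

#' Ratio of the total diversity effect to the context-dependent effect
#'
#' @param d A `pair_decomposition`.
#' @param absolute Return `|DIV| / |CDE|` instead of the signed ratio.
#' @return The ratio, or `NA` when `CDE = 0`.
#' @export
ratio_div_cde <- function(d, absolute = FALSE) {
  stopifnot(inherits(d, "pair_decomposition"))
  cde <- d$components[["cde"]]
  if (cde == 0) return(NA_real_)
  if (absolute) abs(d$div) / abs(cde) else d$div / cde
}

#' Geometric mean of a ratio with a percentile bootstrap interval
#'
#' Ratios are averaged on the log scale (geometric mean) to avoid the bias of
#' arithmetically averaging ratios. The 95% interval comes from the 2.5 and
#' 97.5 percentiles of `n_boot` resampled geometric means. Non-positive
#' values, for which the log is undefined, are excluded before both the point
#' estimate and the resampling when `exclude_nonpositive` is set; `NA`s are
#' always dropped.
#'
#' @param values Numeric vector of ratios (e.g. per-pair `DIV/CDE` or Q).
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param exclude_nonpositive Drop values `<= 0` (default `TRUE`).
#' @param seed Optional integer seed for reproducible resampling.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `ratio_summary`: list with `point`, `ci_low`,
#'   `ci_high`, `n_used`, `n_excluded`, `n_boot`.
#' @examples
#' geometric_mean_bootstrap(c(1, 10, 100), n_boot = 100, seed = 1)$point # 10
#' @export
geometric_mean_bootstrap <- function(values, n_boot = 5000,
                                     exclude_nonpositive = TRUE,
                                     seed = NULL, conf = 0.95) {
  values <- values[!is.na(values)]
  n_in <- length(values)
  if (exclude_nonpositive) values <- values[values > 0]
  if (length(values) == 0L)
    stop("no positive values left for the geometric mean", call. = FALSE)
  if (any(values <= 0))
    stop("non-positive values present; set exclude_nonpositive = TRUE",
         call. = FALSE)
  gm <- function(x) exp(mean(log(x)))
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  boots <- vapply(seq_len(n_boot), function(i) {
    gm(values[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  structure(list(
    point = gm(values),
    ci_low = ci[1], ci_high = ci[2],
    n_used = length(values), n_excluded = n_in - length(values),
    n_boot = n_boot, conf = conf
  ), class = "ratio_summary")
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat(sprintf("geometric mean %.3g, %d%% bootstrap CI [%.3g, %.3g] (n = %d used, %d excluded, %d resamples)\n",
              x$point, round(100 * x$conf), x$ci_low, x$ci_high,
              x$n_used, x$n_excluded, x$n_boot))
  invisible(x)
}

#' Biomass share per size class within membership groups
#'
#' Summarizes how total biomass is distributed over body-size classes within
#' each membership group (unique-to-reference, unique-to-comparison,
#' shared-at-reference, shared-at-comparison): within a group, biomass is
#' summed per size bin and normalized to proportions. The default bins follow
#' the reported cuts for observed total length: small (< 50 cm), medium
#' (50-200 cm), large (> 200 cm); bins are half-open `[low, high)`.
#'
#' @param records Data frame with columns `group`, `size_class_cm` (observed
#'   length in cm), `biomass`.
#' @param breaks Bin edges in cm (default `c(0, 50, 200, Inf)`).
#' @return Data frame with `group`, `bin`, `biomass`, `biomass_share`;
#'   shares within each group sum to 1. Groups whose records all lack size
#'   classes are dropped with a warning.
#' @export
size_class_contributions <- function(records, breaks = c(0, 50, 200, Inf)) {
  stopifnot(all(c("group", "size_class_cm", "biomass") %in% names(records)))
  miss <- is.na(records$size_class_cm)
  if (any(miss)) {
    lost <- setdiff(unique(records$group), unique(records$group[!miss]))
    if (length(lost) > 0L)
      warning("dropping group(s) without size classes: ",
              paste(lost, collapse = ", "), call. = FALSE)
    records <- records[!miss, , drop = FALSE]
  }
  if (nrow(records) == 0L)
    return(data.frame(group = character(0), bin = character(0),
                      biomass = numeric(0), biomass_share = numeric(0)))
  labels <- size_bin_labels(breaks)
  records$bin <- cut(records$size_class_cm, breaks = breaks, labels = labels,
                     right = FALSE, include.lowest = TRUE)
  agg <- stats::aggregate(biomass ~ group + bin, data = records, FUN = sum,
                          drop = TRUE)
  tot <- tapply(agg$biomass, agg$group, sum)
  agg$biomass_share <- agg$biomass / as.vector(tot[as.character(agg$group)])
  agg <- agg[order(agg$group, agg$bin), c("group", "bin", "biomass",
                                          "biomass_share")]
  agg$bin <- as.character(agg$bin)
  rownames(agg) <- NULL
  agg
}

size_bin_labels <- function(breaks) {
  n <- length(breaks) - 1L
  vapply(seq_len(n), function(i) {
    lo <- breaks[i]; hi <- breaks[i + 1L]
    if (is.infinite(hi)) paste0(">", format(lo))
    else if (lo == 0) paste0("<", format(hi))
    else paste0(format(lo), "-", format(hi))
  }, character(1))
}
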