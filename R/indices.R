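# Scalar indices: G regularity statistic, Ivlev's electivity, breeding
# density, and percentile rank against literature NNDs.

#' G index of spatial regularity
#'
#' Ratio of the geometric to the arithmetic mean of the squared
#' nearest-neighbour distances (Brown & Rothery's regularity statistic):
#' g = exp(mean(log d^2)) / mean(d^2). Equal spacing gives g = 1; values
#' from 0 to 0.65 indicate a random arrangement, values above 0.65
#' increasing regularity.
#'
#' @param nnds positive nearest-neighbour distances (or an
#'   \code{nnd_result}).
#' @return object of class \code{g_index_result}: list with \code{g} and
#'   \code{classification} ("regular" iff g > 0.65, else "random").
#' @export
g_index <- function(nnds) {
  if (inherits(nnds, "nnd_result")) nnds <- nnds$per_point_nnd_m
  nnds <- as.numeric(nnds)
  if (length(nnds) < 2)
    stop("G index needs at least 2 distances", call. = FALSE)
  if (any(nnds <= 0))
    stop("all distances must be positive for the G index", call. = FALSE)
  g <- exp(mean(log(nnds^2))) / mean(nnds^2)
  structure(list(g = g,
                 classification = if (g > 0.65) "regular" else "random",
                 threshold = 0.65, n = length(nnds)),
            class = "g_index_result")
}

#' @export
print.g_index_result <- function(x, ...) {
  cat(sprintf("<g_index> g = %.3f (%s; threshold %.2f, n = %d)\n",
              x$g, x$classification, x$threshold, x$n))
  invisible(x)
}

#' Ivlev's electivity index
#'
#' S = (r - p) / (r + p), contrasting use with availability: r is the
#' percentage of nests found in a forest type, p the percentage of total
#' forest area that type occupies. S ranges from -1 (never used) to +1;
#' positive values indicate preference. Vectorised over r and p.
#'
#' @param r percentage of nests in the forest type (>= 0).
#' @param p percentage of available forest area (>= 0).
#' @return S at full precision (report to 2 decimals, as customary).
#' @export
ivlev_electivity <- function(r, p) {
  if (any(r < 0) || any(p < 0))
    stop("r and p must be non-negative percentages", call. = FALSE)
  if (any(r + p == 0))
    stop("electivity undefined where r and p are both zero", call. = FALSE)
  (r - p) / (r + p)
}

#' Electivity table for a set of nests
#'
#' Mirrors the customary habitat-preference report: per forest type, the
#' percentage of nests (r), the percentage of available forest area (p),
#' Ivlev's S (reported to 2 decimals) and the preference flag (S > 0).
#' Types with neither use nor availability are omitted.
#'
#' @param use_pct named percentages of nests per forest type (e.g. from
#'   \code{\link{observed_type_proportions}}); types absent from the name
#'   set count as 0% use.
#' @param availability_pct named percentages of forest area per type (from
#'   \code{\link{availability_proportions}}).
#' @return data.frame with \code{forest_type, r, p, S, preferred}; \code{S}
#'   is rounded to 2 decimals, \code{S_exact} keeps full precision.
#' @export
electivity_table <- function(use_pct, availability_pct) {
  types <- sort(unique(as.integer(c(names(use_pct), names(availability_pct)))))
  r <- ifelse(as.character(types) %in% names(use_pct),
              use_pct[as.character(types)], 0)
  p <- ifelse(as.character(types) %in% names(availability_pct),
              availability_pct[as.character(types)], 0)
  keep <- (r + p) > 0
  types <- types[keep]; r <- unname(r[keep]); p <- unname(p[keep])
  s <- ivlev_electivity(r, p)
  data.frame(forest_type = types, r = r, p = p,
             S = round(s, 2), S_exact = s, preferred = s > 0)
}

#' Breeding density
#'
#' Breeding pairs per 100 km^2 of study area (the whole study area, not just
#' forest).
#'
#' @param n_pairs number of breeding pairs (active nests or territories).
#' @param study_area_km2 study area in km^2.
#' @return density at full precision (report to 1 decimal, as customary).
#' @export
breeding_density <- function(n_pairs, study_area_km2) {
  if (any(n_pairs < 0)) stop("n_pairs must be non-negative", call. = FALSE)
  if (any(study_area_km2 <= 0)) stop("study area must be positive", call. = FALSE)
  100 * n_pairs / study_area_km2
}

#' Percentile rank of a mean NND among literature populations
#'
#' Position, as a percentage, of an observed mean nearest-neighbour distance
#' within the ascending-ordered literature values; ties take half weight
#' (mid-rank convention).
#'
#' @param value observed mean NND (m).
#' @param reference a literature table (data.frame with \code{mean_nnd_m})
#'   or a numeric vector of reference means.
#' @return object of class \code{percentile_result}: list with
#'   \code{observed_mean_nnd_m}, \code{percentile}, \code{n_reference}.
#' @export
percentile_rank <- function(value, reference) {
  ref <- if (is.data.frame(reference)) reference$mean_nnd_m else as.numeric(reference)
  if (!length(ref)) stop("reference table is empty", call. = FALSE)
  pct <- 100 * (sum(ref < value) + 0.5 * sum(ref == value)) / length(ref)
  structure(list(observed_mean_nnd_m = value, percentile = pct,
                 n_reference = length(ref)),
            class = "percentile_result")
}

#' @export
print.percentile_result <- function(x, ...) {
  cat(sprintf("<percentile> mean NND %.1f m falls at the %.1f percentile of %d populations\n",
              x$observed_mean_nnd_m, x$percentile, x$n_reference))
  invisible(x)
}
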