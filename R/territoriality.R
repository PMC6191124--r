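# Core territoriality computations: nearest-neighbour distances at annual and
# multi-annual scales, use-weighted territory centroids, the habitat-
# constrained Monte-Carlo null model, and the observed-vs-null frequency
# histogram.

#' Nearest-neighbour distances of a point pattern
#'
#' For each point, the Euclidean distance to the nearest other point of the
#' same set (con-specific active nests, or territory centroids at the
#' multi-annual scale).
#'
#' @param points matrix or data.frame with columns \code{x}, \code{y} (or an
#'   unnamed two-column matrix); optional \code{nest_id} column or rownames
#'   name the distances.
#' @return object of class \code{nnd_result}: list with
#'   \code{per_point_nnd_m}, \code{mean_m}, \code{se_m} (sd/sqrt(n)),
#'   \code{min_m}, \code{max_m}, \code{n}.
#' @export
nearest_neighbour_distances <- function(points) {
  pts <- as_point_matrix(points)
  n <- nrow(pts)
  if (n < 2)
    stop("need at least 2 points to compute nearest-neighbour distances",
         call. = FALSE)
  if (anyDuplicated(pts))
    stop("duplicate coordinates: two active con-specific nests cannot share ",
         "a location", call. = FALSE)
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  nnd <- apply(d, 1, min)
  names(nnd) <- rownames(pts)
  structure(list(per_point_nnd_m = nnd,
                 mean_m = mean(nnd),
                 se_m = stats::sd(nnd) / sqrt(n),
                 min_m = min(nnd), max_m = max(nnd), n = n),
            class = "nnd_result")
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    ids <- if ("nest_id" %in% names(points)) points$nest_id else rownames(points)
    pts <- as.matrix(points[, c("x", "y")])
    rownames(pts) <- ids
  } else {
    pts <- as.matrix(points)
    if (ncol(pts) != 2) stop("points must have two columns", call. = FALSE)
    colnames(pts) <- c("x", "y")
  }
  storage.mode(pts) <- "double"
  pts
}

#' @export
print.nnd_result <- function(x, ...) {
  cat(sprintf("<nnd_result> n = %d, mean = %.1f m (SE %.1f), range %.1f-%.1f m\n",
              x$n, x$mean_m, x$se_m, x$min_m, x$max_m))
  invisible(x)
}

#' Split nest records into annual nest sets
#'
#' One point set per year: the active nests of that breeding season (years
#' with fewer than \code{min_n} active nests are dropped, since an NND needs
#' at least two points).
#'
#' @param nests nest-record data.frame (list column \code{years}).
#' @param min_n minimum active nests for a year to be kept.
#' @return named list (by year) of data.frames with \code{nest_id},
#'   \code{territory_id}, \code{x}, \code{y}.
#' @export
annual_nest_sets <- function(nests, min_n = 2L) {
  yrs <- sort(unique(unlist(nests$years)))
  sets <- lapply(yrs, function(yr) {
    keep <- vapply(nests$years, function(v) yr %in% v, logical(1))
    nests[keep, c("nest_id", "territory_id", "x", "y"), drop = FALSE]
  })
  names(sets) <- yrs
  sets[vapply(sets, nrow, integer(1)) >= min_n]
}

#' Use-weighted territory centroids
#'
#' The multi-annual representation of a nesting territory: the mean of its
#' nest coordinates weighted by each nest's number of active years, with the
#' count of distinct years in which the territory had any active nest.
#'
#' @param nests nest-record data.frame (list column \code{years}).
#' @return data.frame with \code{species}, \code{territory_id}, \code{x},
#'   \code{y}, \code{n_years_active}; empty territories are skipped with a
#'   message.
#' @export
territory_centroids <- function(nests) {
  split_idx <- split(seq_len(nrow(nests)), nests$territory_id)
  rows <- lapply(names(split_idx), function(tid) {
    idx <- split_idx[[tid]]
    w <- lengths(nests$years[idx])
    if (sum(w) == 0) {
      message("territory ", tid, " has no active years; skipped")
      return(NULL)
    }
    data.frame(species = nests$species[idx[1]], territory_id = tid,
               x = sum(nests$x[idx] * w) / sum(w),
               y = sum(nests$y[idx] * w) / sum(w),
               n_years_active = length(unique(unlist(nests$years[idx]))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configuration of the habitat-constrained null spatial model
#'
#' Random "nests" are placed so that (i) their forest-type proportions match
#' the observed nest proportions, (ii) patches smaller than the smallest
#' patch used by the species are excluded, and (iii) patches above the
#' highest elevation where nests were found are excluded.
#'
#' @param type_proportions named percentages per forest type (the observed
#'   nest proportions); must sum to 100 within 1e-6.
#' @param min_patch_ha minimum eligible patch area (ha).
#' @param max_elevation_m maximum eligible patch elevation (m a.s.l.).
#' @param n_iterations Monte-Carlo iterations (default 100).
#' @param seed integer seed.
#' @param quota if TRUE, each iteration hits the type proportions exactly by
#'   largest-remainder quota; if FALSE (default) each null nest draws its
#'   type independently (multinomial), matching proportions in expectation.
#' @param store_points keep the null-nest coordinates of every iteration
#'   (for constraint audits).
#' @return object of class \code{null_model_config}.
#' @export
null_model_config <- function(type_proportions, min_patch_ha, max_elevation_m,
                              n_iterations = 100L, seed = 1L,
                              quota = FALSE, store_points = FALSE) {
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  if (min_patch_ha <= 0) stop("min_patch_ha must be positive", call. = FALSE)
  if (max_elevation_m <= 0) stop("max_elevation_m must be positive", call. = FALSE)
  if (abs(sum(type_proportions) - 100) > 1e-6)
    stop("type_proportions must sum to 100 (got ", sum(type_proportions), ")",
         call. = FALSE)
  structure(list(type_proportions = type_proportions,
                 min_patch_ha = min_patch_ha,
                 max_elevation_m = max_elevation_m,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), quota = isTRUE(quota),
                 store_points = isTRUE(store_points)),
            class = "null_model_config")
}

# patches passing the size and elevation filters, grouped by forest type;
# errors if a type with positive target proportion has no eligible area
eligible_patch_sets <- function(landscape, cfg) {
  pat <- landscape$patches
  ok <- pat$area_ha >= cfg$min_patch_ha & pat$elevation_m <= cfg$max_elevation_m
  elig <- pat[ok, , drop = FALSE]
  types <- names(cfg$type_proportions)[cfg$type_proportions > 0]
  sets <- lapply(types, function(tp) {
    sub <- elig[elig$forest_type == as.integer(tp), , drop = FALSE]
    if (!nrow(sub))
      stop("forest type ", tp, " has positive null-model proportion but no ",
           "eligible patch (>= ", cfg$min_patch_ha, " ha and <= ",
           cfg$max_elevation_m, " m)", call. = FALSE)
    list(patches = sub, area_prob = sub$area_ha / sum(sub$area_ha))
  })
  names(sets) <- types
  sets
}

#' Draw one null nest under the habitat constraints
#'
#' Samples a forest type at the configured proportions, an eligible patch of
#' that type with probability proportional to area, and a uniform point
#' within the patch. Consumes the current RNG stream; seed handling is done
#' by the caller (\code{\link{simulate_null_nnds}} seeds once per set).
#'
#' @param landscape a \code{\link{landscape}}.
#' @param cfg a \code{\link{null_model_config}}.
#' @return numeric c(x, y) with attributes \code{forest_type} and
#'   \code{patch_id}.
#' @export
sample_null_nest <- function(landscape, cfg) {
  sets <- eligible_patch_sets(landscape, cfg)
  draw_null_nest(sets, cfg$type_proportions)
}

draw_null_nest <- function(sets, props, type = NULL) {
  types <- names(sets)
  if (is.null(type)) {
    pr <- props[types]
    type <- types[sample.int(length(types), 1, prob = pr)]
  }
  s <- sets[[type]]
  j <- if (nrow(s$patches) == 1L) 1L else
    sample.int(nrow(s$patches), 1, prob = s$area_prob)
  pt <- sample_point_in_polygon(s$patches$geometry[[j]])
  attr(pt, "forest_type") <- as.integer(type)
  attr(pt, "patch_id") <- s$patches$patch_id[j]
  pt
}

#' Simulated chance-expected NNDs for one nest set
#'
#' For each Monte-Carlo iteration, places (n - 1) random nests under the
#' habitat constraints and records, for every observed nest, the distance to
#' the nearest random nest of that iteration. With n observed nests and I
#' iterations the result is an I x n matrix.
#'
#' @param observed the observed point set (data.frame with \code{x},
#'   \code{y}, optional \code{nest_id}, or a two-column matrix); needs
#'   n >= 2.
#' @param landscape a \code{\link{landscape}}.
#' @param cfg a \code{\link{null_model_config}}.
#' @return object of class \code{sim_nnd_set}: list with \code{values_m}
#'   (iterations x nests matrix, columns named by nest id), \code{config},
#'   and \code{null_points} (list of per-iteration data.frames) when
#'   \code{cfg$store_points} is TRUE.
#' @export
simulate_null_nnds <- function(observed, landscape, cfg) {
  stopifnot(inherits(landscape, "landscape"), inherits(cfg, "null_model_config"))
  obs <- as_point_matrix(observed)
  n <- nrow(obs)
  if (n < 2)
    stop("need at least 2 observed nests to simulate chance-expected NNDs",
         call. = FALSE)
  sets <- eligible_patch_sets(landscape, cfg)
  set.seed(substream_seed(cfg$seed, "null_model"))
  n_null <- n - 1L
  vals <- matrix(NA_real_, cfg$n_iterations, n,
                 dimnames = list(NULL, rownames(obs)))
  pts_store <- if (cfg$store_points) vector("list", cfg$n_iterations) else NULL
  types <- names(sets)
  for (it in seq_len(cfg$n_iterations)) {
    type_seq <- if (cfg$quota) {
      counts <- largest_remainder(cfg$type_proportions[types], n_null)
      sample(rep(types, counts))
    } else NULL
    null_xy <- matrix(NA_real_, n_null, 2)
    null_meta <- data.frame(forest_type = integer(n_null),
                            patch_id = character(n_null),
                            stringsAsFactors = FALSE)
    for (k in seq_len(n_null)) {
      pt <- draw_null_nest(sets, cfg$type_proportions,
                           type = if (is.null(type_seq)) NULL else type_seq[k])
      null_xy[k, ] <- pt
      null_meta$forest_type[k] <- attr(pt, "forest_type")
      null_meta$patch_id[k] <- attr(pt, "patch_id")
    }
    # distance from each observed nest to its nearest null nest
    for (i in seq_len(n)) {
      vals[it, i] <- sqrt(min((null_xy[, 1] - obs[i, 1])^2 +
                              (null_xy[, 2] - obs[i, 2])^2))
    }
    if (cfg$store_points) {
      null_meta$x <- null_xy[, 1]; null_meta$y <- null_xy[, 2]
      pts_store[[it]] <- null_meta
    }
  }
  structure(list(values_m = vals, config = cfg, null_points = pts_store),
            class = "sim_nnd_set")
}

#' @export
print.sim_nnd_set <- function(x, ...) {
  cat(sprintf("<sim_nnd_set> %d iterations x %d nests, mean %.1f m\n",
              nrow(x$values_m), ncol(x$values_m), mean(x$values_m)))
  invisible(x)
}

#' Observed vs chance-expected NND frequency histogram
#'
#' Bins NNDs into distance classes, computes the percentage of nests per bin
#' separately for every year (each year's percentages sum to 100), then
#' averages across years with standard errors — the construction behind the
#' frequency bar graphs used to locate exclusion ranges. Exclusion bins are
#' the leading distance classes in which no observed nest ever falls while
#' the null model places nests there.
#'
#' @param observed_by_year list (by year) of \code{nnd_result} objects or
#'   numeric NND vectors.
#' @param simulated_by_year list (same years) of \code{sim_nnd_set} objects
#'   or numeric matrices/vectors of simulated NNDs.
#' @param bin_width_m histogram bin width in metres (default 500).
#' @return object of class \code{histogram_comparison}: list with
#'   \code{bin_edges_m}, \code{observed_mean_pct}, \code{observed_se_pct},
#'   \code{simulated_mean_pct}, \code{simulated_se_pct},
#'   \code{exclusion_bins} (integer bin indices).
#' @export
histogram_comparison <- function(observed_by_year, simulated_by_year,
                                 bin_width_m = 500) {
  if (bin_width_m <= 0) stop("bin_width_m must be positive", call. = FALSE)
  if (!length(observed_by_year) || !length(simulated_by_year))
    stop("need at least one year of observed and simulated NNDs", call. = FALSE)
  if (length(observed_by_year) != length(simulated_by_year))
    stop("observed and simulated year lists differ in length", call. = FALSE)
  obs_vals <- lapply(observed_by_year, function(o)
    if (inherits(o, "nnd_result")) o$per_point_nnd_m else as.numeric(o))
  sim_vals <- lapply(simulated_by_year, function(s)
    if (inherits(s, "sim_nnd_set")) as.numeric(s$values_m) else as.numeric(s))
  if (any(vapply(obs_vals, length, 1L) == 0) || any(vapply(sim_vals, length, 1L) == 0))
    stop("empty NND set supplied", call. = FALSE)
  top <- max(unlist(obs_vals), unlist(sim_vals))
  edges <- seq(0, bin_width_m * ceiling(top / bin_width_m + 1e-9), bin_width_m)
  nb <- length(edges) - 1L
  pct <- function(v) {
    cnt <- tabulate(pmin(nb, findInterval(v, edges, left.open = TRUE,
                                          rightmost.closed = TRUE)), nbins = nb)
    100 * cnt / length(v)
  }
  obs_p <- do.call(rbind, lapply(obs_vals, pct))
  sim_p <- do.call(rbind, lapply(sim_vals, pct))
  ny <- nrow(obs_p)
  # across-year SE; a single year has no between-year spread
  se <- function(m) if (ny < 2) rep(0, ncol(m)) else
    apply(m, 2, stats::sd) / sqrt(ny)
  obs_mean <- colMeans(obs_p); sim_mean <- colMeans(sim_p)
  lead <- which(cumsum(obs_mean) == 0)  # leading run of observed-empty bins
  exclusion <- lead[sim_mean[lead] > 0]
  structure(list(bin_edges_m = edges,
                 observed_mean_pct = obs_mean, observed_se_pct = se(obs_p),
                 simulated_mean_pct = sim_mean, simulated_se_pct = se(sim_p),
                 exclusion_bins = as.integer(exclusion),
                 n_years = ny),
            class = "histogram_comparison")
}

#' @export
print.histogram_comparison <- function(x, ...) {
  cat("<histogram_comparison>", length(x$bin_edges_m) - 1L, "bins of",
      diff(x$bin_edges_m)[1], "m,", x$n_years, "year(s)\n")
  if (length(x$exclusion_bins))
    cat("  exclusion range: below",
        x$bin_edges_m[max(x$exclusion_bins) + 1L], "m\n")
  else cat("  no exclusion range detected\n")
  invisible(x)
}
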