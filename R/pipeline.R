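# End-to-end orchestration: synthetic or user data in, consolidated
# territoriality report out. Every number in the report is produced by the
# stage functions exported elsewhere in the package; the pipeline only
# sequences them.

#' Pipeline run configuration
#'
#' @param mode "synthetic" (generate landscape, nest patterns and a
#'   literature table) or "user-data" (read them from \code{landscape_path},
#'   \code{nests_path}, \code{literature_path}).
#' @param landscape_path,nests_path,literature_path input files for
#'   user-data mode (GeoJSON / CSV dialects of the io module);
#'   \code{literature_path} may be NULL in either mode, in which case a
#'   synthetic literature table is generated.
#' @param species_constraints data.frame with columns \code{species,
#'   min_patch_ha, max_elevation_m}, or NULL to derive both constraints from
#'   the data (smallest patch used and highest nest elevation per species —
#'   the procedure the constraints come from in the first place).
#' @param n_iterations Monte-Carlo iterations of the null spatial model.
#' @param bin_width_m histogram bin width (m).
#' @param backend mixed-model backend, see
#'   \code{\link{compare_observed_vs_null}}.
#' @param quota exact per-iteration forest-type quota in the null model
#'   (default FALSE: multinomial matching in expectation).
#' @param landscape_cfg,pattern_cfgs synthetic-mode generator
#'   configurations; defaults are \code{\link{landscape_config}} and
#'   \code{\link{default_species_patterns}} seeded from \code{seed}.
#' @param out_dir directory for the report and tables (NULL: nothing
#'   written).
#' @param seed root seed; every random stage draws a named substream.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(mode = c("synthetic", "user-data"),
                       landscape_path = NULL, nests_path = NULL,
                       literature_path = NULL,
                       species_constraints = NULL,
                       n_iterations = 100L, bin_width_m = 500,
                       backend = "auto", quota = FALSE,
                       landscape_cfg = NULL, pattern_cfgs = NULL,
                       out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "user-data") {
    for (p in c(landscape_path, nests_path))
      if (is.null(p) || !file.exists(p))
        stop("user-data mode requires existing landscape and nest files (missing: ",
             if (is.null(p)) "<unset>" else p, ")", call. = FALSE)
    if (!is.null(literature_path) && !file.exists(literature_path))
      stop("literature file not found: ", literature_path, call. = FALSE)
  }
  if (!is.null(species_constraints)) {
    stopifnot(all(c("species", "min_patch_ha", "max_elevation_m") %in%
                    names(species_constraints)))
    if (any(species_constraints$min_patch_ha <= 0) ||
        any(species_constraints$max_elevation_m <= 0))
      stop("species constraints must be positive", call. = FALSE)
  }
  structure(list(mode = mode, landscape_path = landscape_path,
                 nests_path = nests_path, literature_path = literature_path,
                 species_constraints = species_constraints,
                 n_iterations = as.integer(n_iterations),
                 bin_width_m = bin_width_m, backend = backend,
                 quota = isTRUE(quota),
                 landscape_cfg = landscape_cfg, pattern_cfgs = pattern_cfgs,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full territoriality pipeline
#'
#' Loads or generates the landscape, nest records and literature table, then
#' for each species: annual and multi-annual nearest-neighbour distances,
#' habitat-constrained null-model simulations, observed-vs-null frequency
#' histogram, G indices, mixed-model comparison, electivity table, breeding
#' densities, literature percentile ranks, across-year ANOVA and the
#' nest-count trend. Deterministic given \code{cfg$seed}.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return object of class \code{analysis_report}: a nested list with one
#'   entry per species plus a provenance block; also written as JSON and CSV
#'   tables under \code{cfg$out_dir} when set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log_lines <- character()
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  if (cfg$mode == "synthetic") {
    lcfg <- cfg$landscape_cfg
    if (is.null(lcfg)) lcfg <- landscape_config(seed = cfg$seed)
    land <- generate_landscape(lcfg)
    say("stage landscape: generated ", nrow(land$patches), " patches")
    pcfgs <- cfg$pattern_cfgs
    if (is.null(pcfgs)) pcfgs <- default_species_patterns(seed = cfg$seed)
    nest_list <- lapply(pcfgs, function(pc) generate_nest_pattern(land, pc))
    nests <- do.call(rbind, c(nest_list, list(make.row.names = FALSE)))
    say("stage nests: generated ", nrow(nests), " nest records for ",
        length(nest_list), " species")
  } else {
    land <- load_landscape(cfg$landscape_path)
    nests <- load_nests(cfg$nests_path)
    say("stage load: ", nrow(land$patches), " patches, ", nrow(nests),
        " nest records")
  }

  avail <- availability_proportions(land)
  nests <- assign_nests_to_patches(nests, land)
  say("stage assign: ", sum(!nests$unassigned), "/", nrow(nests),
      " nests inside forest patches")

  species <- unique(nests$species)
  report <- list(species = stats::setNames(vector("list", length(species)),
                                           species))

  for (si in seq_along(species)) {
    sp <- species[si]
    report$species[[sp]] <- tryCatch(
      analyse_species(sp, si, nests[nests$species == sp, , drop = FALSE],
                      land, avail, cfg, say),
      error = function(e) list(skipped = TRUE, reason = conditionMessage(e))
    )
    if (isTRUE(report$species[[sp]]$skipped))
      say("stage species ", sp, ": SKIPPED (", report$species[[sp]]$reason, ")")
  }

  report$availability_pct <- as.list(avail)
  report$provenance <- list(
    mode = cfg$mode, seed = cfg$seed, n_iterations = cfg$n_iterations,
    bin_width_m = cfg$bin_width_m, backend = cfg$backend, quota = cfg$quota,
    package_version = as.character(utils::packageVersion("nestspacing"))
  )
  report$log <- log_lines
  class(report) <- "analysis_report"

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(strip_classes(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (sp in names(report$species)) {
      s <- report$species[[sp]]
      if (!isTRUE(s$skipped) && !is.null(s$electivity))
        utils::write.csv(s$electivity,
                         file.path(cfg$out_dir, paste0("electivity_", sp, ".csv")),
                         row.names = FALSE)
    }
    writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  }
  report
}

# one species' full analysis; `si` indexes the seed substreams
analyse_species <- function(sp, si, sp_nests, land, avail, cfg, say) {
  sets <- annual_nest_sets(sp_nests)
  if (!length(sets))
    stop("no year with >= 2 active nests for ", sp, call. = FALSE)
  obs_by_year <- lapply(sets, nearest_neighbour_distances)

  cents <- territory_centroids(sp_nests)
  terr_of <- stats::setNames(sp_nests$territory_id, sp_nests$nest_id)

  # null-model constraints: supplied, or derived from the data as the
  # survey-based constraints were
  con <- cfg$species_constraints
  if (!is.null(con) && sp %in% con$species) {
    con <- con[con$species == sp, ]
    min_patch <- con$min_patch_ha[1]; max_elev <- con$max_elevation_m[1]
  } else {
    used <- sp_nests[!sp_nests$unassigned, ]
    if (!nrow(used)) stop("no assigned nests for ", sp, call. = FALSE)
    used_areas <- land$patches$area_ha[match(used$patch_id, land$patches$patch_id)]
    min_patch <- min(used_areas)
    max_elev <- max(used$elevation_m)
  }
  props <- observed_type_proportions(sp_nests)
  say("stage null-model ", sp, ": constraints >= ", signif(min_patch, 3),
      " ha, <= ", signif(max_elev, 4), " m; ", length(props), " used types")

  sims_by_year <- lapply(seq_along(sets), function(k) {
    ncfg <- null_model_config(
      type_proportions = props, min_patch_ha = min_patch,
      max_elevation_m = max_elev, n_iterations = cfg$n_iterations,
      seed = cfg$seed + 1000L * si + k, quota = cfg$quota)
    simulate_null_nnds(sets[[k]], land, ncfg)
  })
  names(sims_by_year) <- names(sets)

  hist_cmp <- histogram_comparison(obs_by_year, sims_by_year, cfg$bin_width_m)
  tab_annual <- nnd_observation_table(obs_by_year, sims_by_year, terr_of)
  glmm_annual <- compare_observed_vs_null(tab_annual, backend = cfg$backend)

  # multi-annual scale: territory centroids
  multi <- NULL
  if (nrow(cents) >= 2) {
    cent_pts <- data.frame(nest_id = cents$territory_id,
                           x = cents$x, y = cents$y)
    multi_obs <- nearest_neighbour_distances(cent_pts)
    ncfg_T <- null_model_config(
      type_proportions = props, min_patch_ha = min_patch,
      max_elevation_m = max_elev, n_iterations = cfg$n_iterations,
      seed = cfg$seed + 1000L * si + 999L, quota = cfg$quota)
    multi_sim <- simulate_null_nnds(cent_pts, land, ncfg_T)
    tab_T <- nnd_observation_table(list(all = multi_obs), list(all = multi_sim))
    glmm_T <- compare_observed_vs_null(tab_T, random = "territory_id",
                                       backend = cfg$backend)
    multi <- list(
      nnd = summary_of_nnd(multi_obs),
      g_index = unclass(g_index(multi_obs)),
      model_comparison = unclass(glmm_T),
      density_pairs_per_100km2 = breeding_density(nrow(cents), land$study_area_km2)
    )
  }

  counts_by_year <- table(unlist(sp_nests$years))
  counts_df <- data.frame(year = as.integer(names(counts_by_year)),
                          n = as.integer(counts_by_year))
  trend <- if (nrow(counts_df) >= 3 && stats::sd(counts_df$n) > 0)
    count_trend(counts_df) else list(skipped = TRUE, reason = "too few years or constant counts")
  anova_res <- if (length(obs_by_year) >= 2)
    annual_nnd_anova(obs_by_year) else list(skipped = TRUE, reason = "single year")

  g_annual <- vapply(obs_by_year, function(o) g_index(o)$g, numeric(1))

  lit <- load_or_make_literature(cfg, sp)
  annual_mean <- mean(vapply(obs_by_year, function(o) o$mean_m, numeric(1)))
  pct_annual <- percentile_rank(annual_mean, lit[lit$scale == "annual", ])
  pct_multi <- if (!is.null(multi))
    percentile_rank(multi$nnd$mean_m, lit[lit$scale == "multiannual", ]) else NULL

  list(
    skipped = FALSE,
    annual = list(
      years = names(sets),
      n_per_year = as.list(vapply(sets, nrow, 1L)),
      nnd_per_year = lapply(obs_by_year, summary_of_nnd),
      mean_nnd_m = annual_mean,
      density_per_year = lapply(sets, function(s)
        breeding_density(nrow(s), land$study_area_km2)),
      g_per_year = as.list(g_annual),
      g_mean = mean(g_annual),
      model_comparison = unclass(glmm_annual)
    ),
    multiannual = multi,
    histogram = unclass(hist_cmp),
    electivity = electivity_table(props, avail),
    constraints = list(min_patch_ha = min_patch, max_elevation_m = max_elev),
    trend = trend,
    anova = anova_res,
    percentile = list(annual = unclass(pct_annual),
                      multiannual = if (is.null(pct_multi)) NULL else unclass(pct_multi))
  )
}

summary_of_nnd <- function(o) {
  list(mean_m = o$mean_m, se_m = o$se_m, min_m = o$min_m, max_m = o$max_m,
       n = o$n)
}

load_or_make_literature <- function(cfg, sp) {
  if (!is.null(cfg$literature_path)) return(load_literature(cfg$literature_path))
  rbind(
    generate_literature_nnds(sp, 20, c(500, 8000), seed = cfg$seed, scale = "annual"),
    generate_literature_nnds(sp, 20, c(400, 6000), seed = cfg$seed + 1L,
                             scale = "multiannual")
  )
}

# lists keep their structure in JSON; S3 wrappers and data.frames are fine,
# but drop classes jsonlite does not know
strip_classes <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, strip_classes)
  }
  x
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>", length(x$species), "species |",
      x$provenance$mode, "mode, seed", x$provenance$seed, "\n")
  for (sp in names(x$species)) {
    s <- x$species[[sp]]
    if (isTRUE(s$skipped)) { cat("  ", sp, ": skipped (", s$reason, ")\n"); next }
    cat(sprintf("  %s: annual mean NND %.0f m, G %.2f, delta_i %.1f (%s)\n",
                sp, s$annual$mean_nnd_m, s$annual$g_mean,
                s$annual$model_comparison$delta_i,
                if (s$annual$model_comparison$territorial) "territorial" else "not territorial"))
  }
  invisible(x)
}
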