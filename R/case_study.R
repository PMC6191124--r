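# Bundled survey summaries from the case study: an eight-year census
# (2004-2011) of goshawk, sparrowhawk and buzzard breeding territories on a
# 183.3 km^2 eucalyptus-dominated peninsula in NW Spain. Only published
# aggregate tables are shipped (forest-type use and availability
# percentages, annual active-nest counts, territory totals); the underlying
# nest coordinates were never deposited, which is why the synthetic
# generator exists.

case_file <- function(name) {
  system.file("extdata", name, package = "nestspacing", mustWork = TRUE)
}

#' Case-study forest-type use and availability
#'
#' Percentages of nests of each species per forest type, and the percentage
#' of total forest area each type occupies, for the 12 forest types of the
#' case-study mosaic. Note the goshawk and forest-area columns sum to 100.1
#' as printed (rounding in the source table).
#'
#' @return data.frame with columns \code{forest_type, label, goshawk_pct,
#'   sparrowhawk_pct, buzzard_pct, forest_area_pct}.
#' @export
case_study_forest_use <- function() {
  utils::read.csv(case_file("raptor_forest_use.csv"), stringsAsFactors = FALSE)
}

#' Case-study annual active-nest counts
#'
#' @return data.frame with columns \code{species, year, n}.
#' @export
case_study_counts <- function() {
  utils::read.csv(case_file("raptor_annual_counts.csv"), stringsAsFactors = FALSE)
}

#' Case-study territory totals
#'
#' Number of nesting territories active for at least one year of the study
#' period.
#'
#' @return data.frame with columns \code{species, n_territories}.
#' @export
case_study_territories <- function() {
  utils::read.csv(case_file("raptor_territory_counts.csv"), stringsAsFactors = FALSE)
}

#' Case-study study area
#'
#' @return study area in km^2 (183.3).
#' @export
case_study_area_km2 <- function() 183.3

#' Case-study null-model constraints
#'
#' The realised habitat constraints of the three species: smallest forest
#' patch used (ha) and highest nest elevation (m a.s.l.).
#'
#' @return data.frame with columns \code{species, min_patch_ha,
#'   max_elevation_m}.
#' @export
case_study_constraints <- function() {
  data.frame(species = c("goshawk", "sparrowhawk", "buzzard"),
             min_patch_ha = c(4.1, 4.1, 6.0),
             max_elevation_m = c(340, 370, 370),
             stringsAsFactors = FALSE)
}

#' Default synthetic pattern configurations per species
#'
#' Pattern generator settings that emulate the case-study populations:
#' territory numbers from the census totals, hard-core distances just below
#' each species' minimum observed inter-nest distance (1034 / 467 / 178 m),
#' and habitat-selection weights equal to each species' observed forest-type
#' use percentages.
#'
#' @param years breeding seasons to simulate (default 2004:2011; the
#'   sparrowhawk series starts in 2006 as in the census).
#' @param seed root seed; each species draws a distinct substream seed.
#' @return named list of \code{\link{pattern_config}} objects.
#' @export
default_species_patterns <- function(years = 2004:2011, seed = 1L) {
  use <- case_study_forest_use()
  terr <- case_study_territories()
  hard_core <- c(goshawk = 1000, sparrowhawk = 450, buzzard = 175)
  use_col <- c(goshawk = "goshawk_pct", sparrowhawk = "sparrowhawk_pct",
               buzzard = "buzzard_pct")
  cfgs <- lapply(seq_len(nrow(terr)), function(i) {
    sp <- terr$species[i]
    w <- stats::setNames(use[[use_col[[sp]]]], use$forest_type)
    yrs <- if (sp == "sparrowhawk") intersect(years, 2006:max(years)) else years
    pattern_config(
      species = sp,
      n_territories = terr$n_territories[i],
      hard_core_m = hard_core[[sp]],
      preferred_types = w[w > 0],
      years = yrs,
      seed = as.integer(seed) + i
    )
  })
  stats::setNames(cfgs, terr$species)
}
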