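# Reading/writing landscapes, nest records and literature tables, habitat
# availability, and point-in-patch assignment.

#' Forest-type catalogue
#'
#' The twelve forest types of the eucalyptus-dominated case-study mosaic.
#' Codes 1-12 are the categorical levels accepted everywhere a
#' \code{forest_type} is expected.
#'
#' @return data.frame with columns \code{forest_type} (integer) and
#'   \code{label}.
#' @export
forest_type_catalog <- function() {
  data.frame(
    forest_type = 1:12,
    label = c("Old mixed eucalyptus stands", "Mixed eucalyptus stands",
              "Burned eucalyptus stands", "Monospecific eucalyptus stands",
              "Forests with scattered trees", "Deciduous riverbank forests",
              "Oak, chestnut and cork oak woods", "Pine forests",
              "Burned pine forests", "Acacia forests",
              "Young plantations", "Recently logged forests"),
    stringsAsFactors = FALSE
  )
}

#' Construct a landscape object
#'
#' A landscape is a set of forest patches, each a planar polygon with a
#' categorical forest type and a single representative elevation, embedded in
#' a (possibly larger) study area.
#'
#' @param patches data.frame with columns \code{patch_id}, \code{forest_type},
#'   \code{area_ha}, \code{elevation_m} and a list column \code{geometry} of
#'   two-column vertex matrices.
#' @param study_area_km2 total study area (forest plus non-forest), km^2.
#' @return object of class \code{landscape}.
#' @export
landscape <- function(patches, study_area_km2) {
  stopifnot(is.data.frame(patches))
  req <- c("patch_id", "forest_type", "area_ha", "elevation_m", "geometry")
  missing_cols <- setdiff(req, names(patches))
  if (length(missing_cols))
    stop("patches is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(patches$patch_id))
    stop("patch_ids must be unique", call. = FALSE)
  if (any(patches$area_ha <= 0))
    stop("all patch areas must be positive", call. = FALSE)
  if (any(patches$elevation_m < 0))
    stop("patch elevations must be non-negative", call. = FALSE)
  total_forest_km2 <- sum(patches$area_ha) / 100
  if (total_forest_km2 > study_area_km2 * (1 + 1e-9))
    stop("total forest area (", round(total_forest_km2, 2),
         " km^2) exceeds the study area (", study_area_km2, " km^2)",
         call. = FALSE)
  structure(list(patches = patches, study_area_km2 = study_area_km2),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat("<landscape>", nrow(x$patches), "patches,",
      round(sum(x$patches$area_ha), 1), "ha forest in",
      x$study_area_km2, "km^2 study area\n")
  tab <- sort(table(x$patches$forest_type), decreasing = TRUE)
  cat("  forest types:", paste(names(tab), collapse = " "), "\n")
  invisible(x)
}

#' Read a landscape from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features with properties
#' \code{patch_id}, \code{forest_type} (integer code) and \code{elevation_m};
#' \code{area_ha} is honoured when present (and checked against the polygon
#' geometry to 1%) or computed from the geometry otherwise. A top-level
#' \code{study_area_km2} member gives the full study area; without it the
#' study area is the summed forest area.
#'
#' @param path GeoJSON file path.
#' @return a \code{landscape}.
#' @export
load_landscape <- function(path) {
  if (!file.exists(path)) stop("landscape file not found: ", path, call. = FALSE)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- gj$features
  if (is.null(feats) || !length(feats))
    stop("GeoJSON contains no features: ", path, call. = FALSE)
  rows <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    props <- f$properties
    for (attr in c("forest_type", "elevation_m"))
      if (is.null(props[[attr]]))
        stop("feature ", i, " (patch_id: ",
             if (is.null(props$patch_id)) "<missing>" else props$patch_id,
             ") lacks required attribute '", attr, "'", call. = FALSE)
    if (is.null(f$geometry) || !identical(f$geometry$type, "Polygon"))
      stop("feature ", i, ": geometry must be a Polygon", call. = FALSE)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    if (nrow(unique(ring)) < 3L)
      stop("feature ", i, ": degenerate polygon (fewer than 3 distinct vertices)",
           call. = FALSE)
    geom_ha <- polygon_area_m2(ring) / 1e4
    if (geom_ha <= 0)
      stop("feature ", i, ": polygon has zero area", call. = FALSE)
    area_ha <- if (is.null(props$area_ha)) geom_ha else as.numeric(props$area_ha)
    if (abs(area_ha - geom_ha) > 0.01 * geom_ha)
      stop("feature ", i, ": declared area_ha (", area_ha,
           ") disagrees with geometry area (", signif(geom_ha, 6),
           " ha) by more than 1%", call. = FALSE)
    rows[[i]] <- data.frame(
      patch_id = if (is.null(props$patch_id)) paste0("P", i) else as.character(props$patch_id),
      forest_type = as.integer(props$forest_type),
      area_ha = area_ha,
      elevation_m = as.numeric(props$elevation_m),
      stringsAsFactors = FALSE
    )
    rows[[i]]$geometry <- I(list(ring))
  }
  patches <- do.call(rbind, rows)
  study_km2 <- if (!is.null(gj$study_area_km2)) as.numeric(gj$study_area_km2)
               else sum(patches$area_ha) / 100
  landscape(patches, study_km2)
}

#' Write a landscape to GeoJSON
#'
#' @param x a \code{landscape}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_landscape <- function(x, path) {
  stopifnot(inherits(x, "landscape"))
  feats <- lapply(seq_len(nrow(x$patches)), function(i) {
    p <- x$patches[i, ]
    ring <- close_ring(p$geometry[[1]])
    list(
      type = "Feature",
      properties = list(patch_id = p$patch_id,
                        forest_type = p$forest_type,
                        area_ha = p$area_ha,
                        elevation_m = p$elevation_m),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(j) as.numeric(ring[j, ]))))
    )
  })
  obj <- list(type = "FeatureCollection",
              study_area_km2 = x$study_area_km2,
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read nest records from CSV
#'
#' Columns: \code{species, territory_id, nest_id, x, y, years}; \code{years}
#' holds semicolon-separated integers (breeding seasons in which incubation
#' was observed at that nest).
#'
#' @param path CSV file path.
#' @return data.frame of nest records with a list column \code{years}.
#' @export
load_nests <- function(path) {
  if (!file.exists(path)) stop("nest file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("species", "territory_id", "nest_id", "x", "y", "years")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("nest CSV is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df$years <- lapply(strsplit(as.character(df$years), ";", fixed = TRUE),
                     function(v) sort(as.integer(v)))
  validate_nests(df)
  df
}

validate_nests <- function(nests) {
  if (any(lengths(nests$years) == 0))
    stop("every nest needs at least one active year", call. = FALSE)
  dup <- stats::aggregate(seq_len(nrow(nests)),
                          by = list(species = nests$species, nest_id = nests$nest_id),
                          FUN = length)
  if (any(dup$x > 1))
    stop("nest_id values must be unique within species", call. = FALSE)
  invisible(nests)
}

#' Write nest records to CSV
#'
#' @param nests nest-record data.frame (list column \code{years}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_nests <- function(nests, path) {
  out <- nests[, c("species", "territory_id", "nest_id", "x", "y")]
  out$years <- vapply(nests$years, function(v) paste(v, collapse = ";"), "")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a literature nearest-neighbour distance table
#'
#' Columns: \code{population, species, scale, mean_nnd_m}; \code{scale} is
#' \code{"annual"} (between active nests within a season) or
#' \code{"multiannual"} (between territory centroids).
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
load_literature <- function(path) {
  if (!file.exists(path)) stop("literature file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("population", "species", "scale", "mean_nnd_m")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("literature CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (any(df$mean_nnd_m <= 0))
    stop("literature mean NNDs must be positive", call. = FALSE)
  df
}

#' Habitat availability by forest type
#'
#' Percentage of the total forest area (non-forest land is excluded from the
#' denominator) occupied by each forest type.
#'
#' @param x a \code{landscape}.
#' @return named numeric vector of percentages summing to 100; names are
#'   forest-type codes, sorted.
#' @export
availability_proportions <- function(x) {
  stopifnot(inherits(x, "landscape"))
  if (!nrow(x$patches)) stop("landscape has no patches", call. = FALSE)
  areas <- tapply(x$patches$area_ha, x$patches$forest_type, sum)
  areas <- areas[order(as.numeric(names(areas)))]
  pct <- 100 * as.vector(areas) / sum(areas)
  names(pct) <- names(areas)
  pct
}

#' Assign nests to containing forest patches
#'
#' Annotates each nest with the patch that contains it (point-in-polygon),
#' its forest type and the patch's representative elevation. Nests outside
#' every patch are flagged unassigned (NA patch) rather than erroring.
#'
#' @param nests nest-record data.frame with \code{x}, \code{y}.
#' @param landscape a \code{landscape}.
#' @return \code{nests} with columns \code{patch_id}, \code{forest_type},
#'   \code{elevation_m}, \code{unassigned} added/overwritten.
#' @export
assign_nests_to_patches <- function(nests, landscape) {
  stopifnot(inherits(landscape, "landscape"))
  pat <- landscape$patches
  bbs <- t(vapply(pat$geometry, ring_bbox, numeric(4)))
  n <- nrow(nests)
  patch_id <- rep(NA_character_, n)
  ftype <- rep(NA_integer_, n)
  elev <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    x <- nests$x[i]; y <- nests$y[i]
    cand <- which(bbs[, 1] <= x & x <= bbs[, 3] & bbs[, 2] <= y & y <= bbs[, 4])
    for (j in cand) {
      if (point_in_polygon(x, y, pat$geometry[[j]])) {
        patch_id[i] <- pat$patch_id[j]
        ftype[i] <- pat$forest_type[j]
        elev[i] <- pat$elevation_m[j]
        break
      }
    }
  }
  nests$patch_id <- patch_id
  nests$forest_type <- ftype
  nests$elevation_m <- elev
  nests$unassigned <- is.na(patch_id)
  n_out <- sum(nests$unassigned)
  if (n_out) message(n_out, " nest(s) fall outside all forest patches (unassigned)")
  nests
}

#' Observed forest-type use proportions of a set of nests
#'
#' Percentage of assigned nests in each forest type; the input for the
#' habitat-matching constraint of the null spatial model and for the use
#' column r of Ivlev's electivity.
#'
#' @param nests nest records already passed through
#'   \code{\link{assign_nests_to_patches}}.
#' @return named numeric vector of percentages summing to 100.
#' @export
observed_type_proportions <- function(nests) {
  if (!"forest_type" %in% names(nests))
    stop("nests must be assigned to patches first", call. = FALSE)
  ft <- nests$forest_type[!is.na(nests$forest_type)]
  if (!length(ft)) stop("no assigned nests", call. = FALSE)
  tab <- table(ft)
  pct <- 100 * as.vector(tab) / sum(tab)
  names(pct) <- names(tab)
  pct
}
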