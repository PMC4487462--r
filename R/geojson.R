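#' Export a choropleth-ready GeoJSON of classified regions
#'
#' Joins a classification onto a GeoJSON FeatureCollection by region name
#' (exact match after whitespace trim and case fold) and writes a new
#' FeatureCollection in which every matched feature carries the properties
#' `total_score`, `tier`, `rank` and one property per cluster score.
#' Geometries whose name matches no classified region keep their geometry
#' and get `tier = "not_assessed"` (e.g. districts outside the assessment's
#' catchment); classified regions with no geometry are omitted from the file
#' but reported back to the caller.
#'
#' @param result A [scalogram_rank()] result or a
#'   `scalogram_classification` from [rank_and_summarize()].
#' @param geometries Path to a GeoJSON FeatureCollection, or the equivalent
#'   parsed list.
#' @param path Output GeoJSON path.
#' @param region_property Feature property holding the region name; the
#'   first of `region_property`, `"name"`, `"region"` present is used.
#' @return Invisibly, a list with `path`, `matched` (region names joined),
#'   `unmatched_regions` (classified but no geometry) and
#'   `unmatched_geometries` (geometry but not assessed).
#' @export
write_choropleth <- function(result, geometries, path,
                             region_property = "name") {
  regions <- classification_regions(result)
  geo <- if (is.character(geometries) && length(geometries) == 1L) {
    jsonlite::fromJSON(geometries, simplifyVector = FALSE)
  } else {
    geometries
  }
  if (!is.list(geo) || !identical(geo$type, "FeatureCollection") ||
      !is.list(geo$features)) {
    stop("geometries must be a GeoJSON FeatureCollection", call. = FALSE)
  }
  cluster_cols <- setdiff(names(regions), c("region", "total", "tier", "rank"))
  keys <- region_key(regions$region)
  matched <- character(0)
  unmatched_geo <- character(0)
  geo$features <- lapply(geo$features, function(feat) {
    if (!identical(feat$type, "Feature")) {
      stop("every element of 'features' must be a Feature", call. = FALSE)
    }
    props <- feat$properties %||% list()
    name_field <- intersect(c(region_property, "name", "region"), names(props))
    if (length(name_field) == 0L) {
      stop("feature without a '", region_property, "' property", call. = FALSE)
    }
    fname <- as.character(props[[name_field[1L]]])
    i <- match(region_key(fname), keys)
    if (is.na(i)) {
      props$tier <- "not_assessed"
      unmatched_geo <<- c(unmatched_geo, fname)
    } else {
      props$total_score <- regions$total[i]
      props$tier <- as.character(regions$tier[i])
      props$rank <- regions$rank[i]
      for (cl in cluster_cols) props[[paste0(cl, "_score")]] <- regions[[cl]][i]
      matched <<- c(matched, regions$region[i])
    }
    feat$properties <- props
    feat
  })
  unmatched_regions <- setdiff(regions$region, matched)
  if (length(unmatched_regions)) {
    warning("region(s) without geometry, omitted from the map: ",
            paste(unmatched_regions, collapse = ", "), call. = FALSE)
  }
  jsonlite::write_json(geo, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(path = path, matched = matched,
                 unmatched_regions = unmatched_regions,
                 unmatched_geometries = unmatched_geo))
}

classification_regions <- function(result) {
  if (inherits(result, "scalogram_result")) {
    return(result$classification$regions)
  }
  if (inherits(result, "scalogram_classification")) {
    return(result$regions)
  }
  if (is.data.frame(result) &&
      all(c("region", "total", "tier", "rank") %in% names(result))) {
    return(result)
  }
  stop("expected a scalogram_result, scalogram_classification, or a data ",
       "frame with region/total/tier/rank columns", call. = FALSE)
}

#' Build a synthetic square-grid FeatureCollection for given region names
#'
#' Lays unit-square polygons on a grid, one per region, so that choropleth
#' export can be exercised and rendered without real administrative
#' boundaries. Purely synthetic geometry; coordinates are arbitrary planar
#' units.
#'
#' @param regions Character vector of region names.
#' @param ncol Number of grid columns (default: near-square layout).
#' @return A GeoJSON-structured list (FeatureCollection).
#' @export
synthetic_grid_geometry <- function(regions,
                                    ncol = ceiling(sqrt(length(regions)))) {
  stopifnot(length(regions) >= 1L, ncol >= 1L)
  features <- lapply(seq_along(regions), function(i) {
    x0 <- (i - 1L) %% ncol
    y0 <- (i - 1L) %/% ncol
    ring <- list(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1),
                 c(x0, y0 + 1), c(x0, y0))
    list(type = "Feature",
         properties = list(name = regions[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(ring, as.list))))
  })
  list(type = "FeatureCollection", features = features)
}
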