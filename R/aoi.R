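#' Area-of-interest polygon
#'
#' A planar polygon (one or more rings, even-odd interior rule) carrying a CRS
#' identifier. Used to delimit the landscape the initial communities are built
#' for.
#'
#' @param rings A two-column matrix of (x, y) vertices, or a list of such
#'   matrices for multi-ring geometries. Rings need not repeat the first
#'   vertex.
#' @param crs CRS identifier string, e.g. `"EPSG:4326"`.
#' @return An `aoi_polygon` object.
#' @export
aoi_polygon <- function(rings, crs) {
  if (is.matrix(rings)) rings <- list(rings)
  if (!length(rings)) ricb_stop("ricb_geometry_error", "AOI has no rings")
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) < 2L) ricb_stop("ricb_geometry_error", "ring must have x and y columns")
    r <- r[, 1:2, drop = FALSE]
    storage.mode(r) <- "double"
    if (!all(is.finite(r))) {
      ricb_stop("ricb_geometry_error", "corrupt geometry: non-finite coordinate")
    }
    # drop an explicit closing vertex
    n <- nrow(r)
    if (n > 1L && all(r[1, ] == r[n, ])) r <- r[-n, , drop = FALSE]
    if (nrow(unique(r)) < 3L) {
      ricb_stop("ricb_geometry_error",
                "corrupt geometry: ring has fewer than 3 distinct vertices")
    }
    if (abs(ring_area(r)) < .Machine$double.eps) {
      ricb_stop("ricb_geometry_error", "corrupt geometry: ring has zero area")
    }
    r
  })
  structure(list(rings = rings, crs = as.character(crs)), class = "aoi_polygon")
}

#' @export
print.aoi_polygon <- function(x, ...) {
  bb <- aoi_bbox(x)
  cat(sprintf("aoi_polygon: %d ring(s) [%s], bbox x [%g, %g] y [%g, %g]\n",
              length(x$rings), x$crs, bb[1], bb[3], bb[2], bb[4]))
  invisible(x)
}

ring_area <- function(r) {
  x <- r[, 1]; y <- r[, 2]
  n <- nrow(r)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

aoi_bbox <- function(aoi) {
  xy <- do.call(rbind, aoi$rings)
  c(xmin = min(xy[, 1]), ymin = min(xy[, 2]),
    xmax = max(xy[, 1]), ymax = max(xy[, 2]))
}

# --- CRS support ------------------------------------------------------------
# Supported pair: geographic WGS84 (EPSG:4326) and spherical Web Mercator
# (EPSG:3857), via the exact closed-form transform. The imputation raster is
# never resampled; only the AOI is reprojected.

normalize_crs <- function(crs) {
  c0 <- toupper(gsub("\\s+", "", crs))
  if (c0 %in% c("EPSG:4326", "4326", "WGS84", "CRS84", "OGC:CRS84")) return("EPSG:4326")
  if (c0 %in% c("EPSG:3857", "3857", "WEBMERCATOR")) return("EPSG:3857")
  c0
}

.wm_radius <- 6378137

lonlat_to_webmerc <- function(xy) {
  cbind(.wm_radius * xy[, 1] * pi / 180,
        .wm_radius * log(tan(pi / 4 + xy[, 2] * pi / 360)))
}

webmerc_to_lonlat <- function(xy) {
  cbind(xy[, 1] / .wm_radius * 180 / pi,
        (2 * atan(exp(xy[, 2] / .wm_radius)) - pi / 2) * 180 / pi)
}

#' Reproject an AOI polygon
#'
#' Transforms vertex coordinates between WGS84 geographic coordinates
#' (EPSG:4326) and spherical Web Mercator (EPSG:3857). Identity when source
#' and target CRS match; any other pair is rejected.
#'
#' @param aoi An [aoi_polygon()].
#' @param to_crs Target CRS identifier.
#' @return The reprojected `aoi_polygon`.
#' @export
transform_aoi <- function(aoi, to_crs) {
  from <- normalize_crs(aoi$crs); to <- normalize_crs(to_crs)
  if (from == to) return(aoi)
  f <- if (from == "EPSG:4326" && to == "EPSG:3857") {
    lonlat_to_webmerc
  } else if (from == "EPSG:3857" && to == "EPSG:4326") {
    webmerc_to_lonlat
  } else {
    ricb_stop("ricb_crs_error", "unsupported CRS transform: %s -> %s", from, to)
  }
  aoi_polygon(lapply(aoi$rings, f), crs = to)
}

# Even-odd containment of points in the (possibly multi-ring) polygon;
# boundary points count as inside.
points_in_aoi <- function(x, y, aoi) {
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  for (r in aoi$rings) {
    hit <- pracma::inpolygon(x, y, r[, 1], r[, 2], boundary = FALSE)
    edge <- pracma::inpolygon(x, y, r[, 1], r[, 2], boundary = TRUE) & !hit
    inside <- xor(inside, hit)
    on_edge <- on_edge | edge
  }
  inside | on_edge
}

# --- Readers ----------------------------------------------------------------

#' Read an AOI polygon from GeoJSON or KML
#'
#' Format is chosen by file extension: `.geojson`/`.json` or `.kml`. GeoJSON
#' coordinates are WGS84 per RFC 7946; KML is always WGS84. Polygon and
#' MultiPolygon geometries (first feature of a FeatureCollection) are
#' supported; interior rings are honoured with the even-odd rule.
#'
#' @param path Path to the vector file.
#' @return An [aoi_polygon()] in EPSG:4326.
#' @export
read_aoi <- function(path) {
  if (!file.exists(path)) ricb_stop("ricb_io_error", "AOI file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "geojson" = , "json" = read_aoi_geojson(path),
    "kml" = read_aoi_kml(path),
    ricb_stop("ricb_format_error",
              "unsupported AOI format '.%s' (use GeoJSON or KML)", ext))
}

read_aoi_geojson <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    ricb_stop("ricb_geometry_error", "unreadable GeoJSON: %s",
                              conditionMessage(e))
                  })
  geom <- obj
  if (identical(obj$type, "FeatureCollection")) {
    if (!length(obj$features)) ricb_stop("ricb_geometry_error", "GeoJSON has no features")
    geom <- obj$features[[1]]$geometry
  } else if (identical(obj$type, "Feature")) {
    geom <- obj$geometry
  }
  if (is.null(geom$type)) ricb_stop("ricb_geometry_error", "GeoJSON geometry has no type")
  ring_mat <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt))[1:2]))
  }
  rings <- switch(geom$type,
    "Polygon" = lapply(geom$coordinates, ring_mat),
    "MultiPolygon" = unlist(lapply(geom$coordinates,
                                   function(poly) lapply(poly, ring_mat)),
                            recursive = FALSE),
    ricb_stop("ricb_geometry_error", "unsupported GeoJSON geometry type '%s'",
              geom$type))
  aoi_polygon(rings, crs = "EPSG:4326")
}

read_aoi_kml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    ricb_stop("ricb_geometry_error", "unreadable KML: %s",
                              conditionMessage(e))
                  })
  xml2::xml_ns_strip(doc)
  coord_nodes <- xml2::xml_find_all(doc, ".//Polygon//coordinates")
  if (!length(coord_nodes)) {
    ricb_stop("ricb_geometry_error", "KML contains no Polygon coordinates")
  }
  rings <- lapply(coord_nodes, function(node) {
    toks <- strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]]
    do.call(rbind, lapply(strsplit(toks, ","),
                          function(p) as.numeric(p)[1:2]))
  })
  aoi_polygon(rings, crs = "EPSG:4326")
}

# --- Writers (used by the synthetic-landscape generator) --------------------

write_aoi_geojson <- function(aoi, path) {
  close_ring <- function(r) rbind(r, r[1, , drop = FALSE])
  coords <- lapply(aoi$rings, function(r) {
    rc <- close_ring(r)
    lapply(seq_len(nrow(rc)), function(i) c(rc[i, 1], rc[i, 2]))
  })
  obj <- list(type = "Feature",
              properties = list(name = "aoi"),
              geometry = list(type = "Polygon", coordinates = coords))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_aoi_kml <- function(aoi, path) {
  close_ring <- function(r) rbind(r, r[1, , drop = FALSE])
  coord_str <- function(r) {
    rc <- close_ring(r)
    paste(sprintf("%.10f,%.10f,0", rc[, 1], rc[, 2]), collapse = " ")
  }
  outer <- sprintf(
    "<outerBoundaryIs><LinearRing><coordinates>%s</coordinates></LinearRing></outerBoundaryIs>",
    coord_str(aoi$rings[[1]]))
  inner <- vapply(aoi$rings[-1], function(r) sprintf(
    "<innerBoundaryIs><LinearRing><coordinates>%s</coordinates></LinearRing></innerBoundaryIs>",
    coord_str(r)), character(1))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<kml xmlns="http://www.opengis.net/kml/2.2"><Document><Placemark><name>aoi</name>',
    "<Polygon>", outer, inner, "</Polygon>",
    "</Placemark></Document></kml>"), path)
  invisible(path)
}
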