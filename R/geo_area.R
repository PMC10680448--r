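#' Read occurrence records from CSV
#'
#' @param path CSV with columns `species`, `latitude`, `longitude` and
#'   optionally `source`.
#' @param hosts Optional character vector of known host names;
#'   occurrences of other species are kept but flagged in the
#'   `unknown_species` attribute.
#' @return Data.frame of valid occurrences (out-of-bounds coordinates
#'   are dropped with a warning).
#' @export
read_occurrences <- function(path, hosts = NULL) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("species", "latitude", "longitude")
  if (!all(need %in% names(occ))) {
    stop("occurrence file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- is.na(occ$latitude) | is.na(occ$longitude) |
    abs(occ$latitude) > 90 | abs(occ$longitude) > 180
  if (any(bad)) {
    warning(sum(bad), " occurrence(s) with invalid coordinates dropped",
            call. = FALSE)
    occ <- occ[!bad, , drop = FALSE]
  }
  if (!is.null(hosts)) {
    unk <- setdiff(unique(occ$species), hosts)
    if (length(unk)) attr(occ, "unknown_species") <- unk
  }
  rownames(occ) <- NULL
  occ
}

#' Read reef polygons from GeoJSON
#'
#' Accepts a FeatureCollection (or bare geometry) of `Polygon` /
#' `MultiPolygon` in WGS84. Rings are closed if the source left them
#' open; degenerate rings (fewer than three distinct vertices, or zero
#' area) are skipped with a message.
#'
#' @param path GeoJSON file path.
#' @return A `reef_polygons` object: a list of polygons, each a list of
#'   rings (first outer, rest holes), each ring an n x 2 matrix of
#'   (longitude, latitude).
#' @export
read_reefs <- function(path) {
  gj <- jsonlite::read_json(path)
  geoms <- if (identical(gj$type, "FeatureCollection")) {
    lapply(gj$features, `[[`, "geometry")
  } else if (identical(gj$type, "Feature")) {
    list(gj$geometry)
  } else {
    list(gj)
  }
  ring_mat <- function(r) {
    M <- do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
    storage.mode(M) <- "double"
    if (!all(M[1, ] == M[nrow(M), ])) M <- rbind(M, M[1, ])
    M
  }
  polys <- list()
  skipped <- 0L
  add_poly <- function(rings) {
    rings <- lapply(rings, ring_mat)
    ok <- vapply(rings, function(M) {
      nrow(unique(M)) >= 3 && abs(.shoelace(M)) > 0
    }, logical(1))
    if (!ok[1]) {
      skipped <<- skipped + 1L
      return(invisible())
    }
    polys[[length(polys) + 1L]] <<- rings[ok]
  }
  for (g in geoms) {
    if (is.null(g)) next
    if (identical(g$type, "Polygon")) {
      add_poly(g$coordinates)
    } else if (identical(g$type, "MultiPolygon")) {
      for (p in g$coordinates) add_poly(p)
    }
  }
  if (skipped > 0) {
    message(skipped, " degenerate reef polygon(s) skipped")
  }
  structure(polys, class = "reef_polygons")
}

#' @export
print.reef_polygons <- function(x, ...) {
  cat("Reef polygons: ", length(x), " polygon(s)\n", sep = "")
  invisible(x)
}

# signed shoelace area of a closed ring (n x 2 matrix)
.shoelace <- function(M) {
  n <- nrow(M)
  x <- M[, 1]
  y <- M[, 2]
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

# Sutherland-Hodgman: clip an arbitrary subject ring against a convex
# clip ring (counter-clockwise). Returns the clipped ring or NULL.
.clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc - 1)) {
    if (is.null(out) || nrow(out) < 3) return(NULL)
    a <- clip[e, ]
    b <- clip[e + 1, ]
    ex <- b[1] - a[1]
    ey <- b[2] - a[2]
    # inside = left of the directed edge a -> b
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    n <- nrow(out)
    res <- vector("list", n)
    for (i in seq_len(n - 1)) {
      p <- out[i, ]; q <- out[i + 1, ]
      sp <- side[i]; sq <- side[i + 1]
      seg <- NULL
      if (sp >= 0) seg <- rbind(seg, p)
      if ((sp > 0 && sq < 0) || (sp < 0 && sq > 0)) {
        t <- sp / (sp - sq)
        seg <- rbind(seg, p + t * (q - p))
      }
      res[[i]] <- seg
    }
    out <- do.call(rbind, res)
    if (is.null(out) || nrow(out) < 3) return(NULL)
    out <- rbind(out, out[1, ])
  }
  out
}

# regular n-gon whose area equals `area` exactly (radius inflated to
# compensate for the inscribed-polygon deficit), counter-clockwise
.circle_polygon <- function(cx, cy, area, n = 64L) {
  r <- sqrt(area / (0.5 * n * sin(2 * pi / n)))
  th <- seq(0, 2 * pi, length.out = n + 1)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# project lon/lat (degrees) to a local tangent plane in metres,
# centred on (lon0, lat0); area-true at buffer scale
.local_xy <- function(lon, lat, lon0, lat0) {
  mpd <- pi * 6371008.8 / 180  # metres per degree of latitude
  cbind((lon - lon0) * mpd * cos(lat0 * pi / 180), (lat - lat0) * mpd)
}

# area (m^2) of one record's buffer intersected with the reefs, in the
# record's local frame; holes subtract
.buffer_reef_area <- function(lon, lat, reefs, buffer_area, n_circle) {
  circ <- .circle_polygon(0, 0, buffer_area, n_circle)
  r_m <- sqrt(buffer_area / pi) * 1.1  # generous bounding radius
  total <- 0
  for (poly in reefs) {
    area_p <- 0
    for (ri in seq_along(poly)) {
      ring <- .local_xy(poly[[ri]][, 1], poly[[ri]][, 2], lon, lat)
      # cheap reject: ring bounding box vs buffer bounding box
      if (min(ring[, 1]) > r_m || max(ring[, 1]) < -r_m ||
          min(ring[, 2]) > r_m || max(ring[, 2]) < -r_m) {
        if (ri == 1 && !.point_in_ring(0, 0, ring)) break
        next
      }
      # fast path: buffer entirely inside the ring (centre inside and
      # every ring edge farther than the buffer radius)
      r_buf <- sqrt(max(circ[, 1]^2 + circ[, 2]^2))
      if (.min_edge_dist(ring) > r_buf && .point_in_ring(0, 0, ring)) {
        if (ri == 1) area_p <- buffer_area else area_p <- area_p - buffer_area
        next
      }
      cl <- .clip_convex(ring, circ)
      a <- if (is.null(cl)) {
        # no crossing: either the buffer is wholly inside the ring or
        # wholly outside it
        if (.point_in_ring(0, 0, ring)) buffer_area else 0
      } else {
        abs(.shoelace(cl))
      }
      if (ri == 1) area_p <- a else area_p <- area_p - a
    }
    total <- total + max(0, area_p)
  }
  min(total, buffer_area)
}

# minimum distance from the origin to the edges of a closed ring
.min_edge_dist <- function(ring) {
  n <- nrow(ring)
  ax <- ring[-n, 1]; ay <- ring[-n, 2]
  bx <- ring[-1, 1]; by <- ring[-1, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  t <- pmin(1, pmax(0, ifelse(len2 == 0, 0, -(ax * dx + ay * dy) / len2)))
  sqrt(min((ax + t * dx)^2 + (ay + t * dy)^2))
}

# even-odd point-in-polygon test for a closed ring
.point_in_ring <- function(px, py, ring) {
  x <- ring[, 1]
  y <- ring[, 2]
  n <- nrow(ring)
  inside <- FALSE
  for (i in seq_len(n - 1)) {
    if ((y[i] > py) != (y[i + 1] > py)) {
      xint <- x[i] + (py - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
      if (px < xint) inside <- !inside
    }
  }
  inside
}

#' Accumulated reef-cropped geographic area per host species
#'
#' Around every occurrence record a circular buffer of `buffer_area`
#' square metres is built in a local tangent-plane projection centred
#' on the record, intersected with the reef polygons, and the per-record
#' reef areas are summed per species ("accumulated"). With
#' `union_overlaps = TRUE` overlapping buffers of the same species are
#' counted once, via grid integration over each cluster of mutually
#' overlapping records (exact duplicates always collapse to one).
#'
#' @param occurrences Data.frame with `species`, `latitude`,
#'   `longitude`.
#' @param reefs A `reef_polygons` object from [read_reefs()] (an empty
#'   list gives zero areas with a warning).
#' @param buffer_area Buffer size in square metres (default 10).
#' @param union_overlaps Union overlapping buffers instead of summing.
#' @param n_circle Vertices of the buffer polygon; its area is
#'   calibrated to equal `buffer_area` exactly.
#' @return Data.frame with `species`, `accumulated_area` (km^2),
#'   `n_records`, `n_records_on_reef` (records whose buffer touches any
#'   reef).
#' @export
accumulated_area <- function(occurrences, reefs, buffer_area = 10,
                             union_overlaps = FALSE, n_circle = 64L) {
  stopifnot(buffer_area > 0)
  if (length(reefs) == 0) {
    warning("no reef polygons: all accumulated areas are zero",
            call. = FALSE)
  }
  species <- sort(unique(occurrences$species), method = "radix")
  if (length(species) == 0) {
    return(data.frame(species = character(0),
                      accumulated_area = numeric(0),
                      n_records = integer(0),
                      n_records_on_reef = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(species, function(sp) {
    rec <- occurrences[occurrences$species == sp, , drop = FALSE]
    areas <- mapply(.buffer_reef_area, rec$longitude, rec$latitude,
                    MoreArgs = list(reefs = reefs,
                                    buffer_area = buffer_area,
                                    n_circle = n_circle))
    total_m2 <- if (union_overlaps) {
      .union_area(rec$longitude, rec$latitude, areas, reefs,
                  buffer_area, n_circle)
    } else {
      sum(areas)
    }
    data.frame(species = sp,
               accumulated_area = total_m2 / 1e6,
               n_records = nrow(rec),
               n_records_on_reef = sum(areas > 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# union-mode species total: cluster records whose buffers can overlap
# (centres closer than two radii); singleton clusters keep their exact
# clipped area, larger clusters are integrated on a fine grid
.union_area <- function(lon, lat, areas, reefs, buffer_area, n_circle,
                        grid_n = 151L) {
  r <- sqrt(buffer_area / pi)
  n <- length(lon)
  if (n == 1) return(areas)
  xy <- .local_xy(lon, lat, mean(lon), mean(lat))
  d <- as.matrix(stats::dist(xy))
  g <- igraph::graph_from_adjacency_matrix(d < 2.2 * r, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  total <- 0
  for (cl in unique(comp)) {
    idx <- which(comp == cl)
    if (length(idx) == 1) {
      total <- total + areas[idx]
      next
    }
    # integrate the union of the cluster's buffers clipped to the reefs
    cx <- xy[idx, 1]
    cy <- xy[idx, 2]
    gx <- seq(min(cx) - r, max(cx) + r, length.out = grid_n)
    gy <- seq(min(cy) - r, max(cy) + r, length.out = grid_n)
    cell <- (gx[2] - gx[1]) * (gy[2] - gy[1])
    pts <- expand.grid(x = gx, y = gy)
    in_union <- rep(FALSE, nrow(pts))
    for (j in seq_along(idx)) {
      in_union <- in_union |
        ((pts$x - cx[j])^2 + (pts$y - cy[j])^2 <= r^2)
    }
    pts <- pts[in_union, , drop = FALSE]
    if (nrow(pts) == 0) next
    # back to lon/lat for the reef test (local inverse projection)
    mpd <- pi * 6371008.8 / 180
    plon <- mean(lon) + pts$x / (mpd * cos(mean(lat) * pi / 180))
    plat <- mean(lat) + pts$y / mpd
    on_reef <- vapply(seq_len(nrow(pts)), function(i) {
      .on_any_reef(plon[i], plat[i], reefs)
    }, logical(1))
    total <- total + sum(on_reef) * cell
  }
  total
}

.on_any_reef <- function(lon, lat, reefs) {
  for (poly in reefs) {
    ring0 <- poly[[1]]
    if (lon < min(ring0[, 1]) || lon > max(ring0[, 1]) ||
        lat < min(ring0[, 2]) || lat > max(ring0[, 2])) next
    if (.point_in_ring(lon, lat, ring0)) {
      in_hole <- FALSE
      for (h in poly[-1]) {
        if (.point_in_ring(lon, lat, h)) {
          in_hole <- TRUE
          break
        }
      }
      if (!in_hole) return(TRUE)
    }
  }
  FALSE
}

#' Write reef polygons to GeoJSON
#'
#' @param reefs A `reef_polygons` object (or plain list of polygons).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_reefs_geojson <- function(reefs, path) {
  feat <- lapply(reefs, function(poly) {
    coords <- lapply(poly, function(ring) {
      lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
    })
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
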