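#' Thiessen (Voronoi) polygons and their adjacency
#'
#' Each locality is represented by the region of the plane closer to it than
#' to any other locality, clipped to the localities' bounding box expanded by
#' `margin` times its span on each side. Two localities are adjacent when
#' their polygons share an edge of positive length.
#'
#' @param localities a `locality_tbl` or a tibble (locality, x, y).
#' @param margin bounding-box expansion fraction (default 0.10).
#' @return list of class `thiessen_map`: `polygons` (tibble locality, x, y in
#'   vertex order), `adjacency` (tibble locality_a, locality_b, one row per
#'   unordered pair), `areas` (tibble locality, area), `bbox` (xmin, xmax,
#'   ymin, ymax).
#' @export
build_thiessen <- function(localities, margin = 0.10) {
  pts <- if ("individual" %in% names(localities)) {
    locality_points(localities)
  } else {
    dplyr::distinct(localities, .data$locality, .data$x, .data$y)
  }
  if (nrow(pts) < 2) abort("need at least 2 localities")
  dup <- duplicated(pts[c("x", "y")]) | duplicated(pts[c("x", "y")], fromLast = TRUE)
  if (any(dup)) {
    abort(paste("duplicate coordinates for localities:",
                paste(pts$locality[dup], collapse = ", ")))
  }
  rx <- range(pts$x); ry <- range(pts$y)
  span <- max(diff(rx), diff(ry), 1)   # degenerate axes still get a window
  mx <- margin * max(diff(rx), 0.2 * span)
  my <- margin * max(diff(ry), 0.2 * span)
  rw <- c(rx[1] - mx, rx[2] + mx, ry[1] - my, ry[2] + my)
  dd <- deldir::deldir(pts$x, pts$y, rw = rw, suppressMsge = TRUE)
  tiles <- deldir::tile.list(dd)
  polygons <- purrr::map2_dfr(tiles, pts$locality, function(tl, id) {
    tibble::tibble(locality = id, x = tl$x, y = tl$y)
  })
  areas <- tibble::tibble(locality = pts$locality,
                          area = vapply(tiles, function(tl) tl$area, 0))
  seg <- dd$dirsgs
  len <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  pos <- len > sqrt(.Machine$double.eps)
  adjacency <- tibble::tibble(
    locality_a = pts$locality[pmin(seg$ind1, seg$ind2)[pos]],
    locality_b = pts$locality[pmax(seg$ind1, seg$ind2)[pos]]
  ) |> dplyr::distinct()
  structure(list(polygons = polygons, adjacency = adjacency, areas = areas,
                 bbox = setNames(rw, c("xmin", "xmax", "ymin", "ymax")),
                 points = pts),
            class = "thiessen_map")
}

#' Interpolate a scattered locality value onto a regular grid
#'
#' Piecewise-linear interpolation on the Delaunay triangulation of the
#' localities, evaluated on a regular grid over the bounding box; grid nodes
#' outside the convex hull are `NA`. With `at` given, returns point
#' evaluations instead of a grid.
#'
#' @param localities tibble (locality, x, y) or a `locality_tbl`.
#' @param values named vector or tibble (locality, value) of the quantity to
#'   interpolate (e.g. hybrid index `h`).
#' @param resolution grid cells per axis (default 200).
#' @param at optional tibble (x, y) of evaluation points.
#' @return with `at = NULL`, a list of class `surface_grid` with `x`, `y`
#'   (axis vectors) and `z` (matrix, `NA` outside the hull); otherwise a
#'   numeric vector of interpolated values at `at`.
#' @export
interpolate_surface <- function(localities, values, resolution = 200L, at = NULL) {
  pts <- if ("individual" %in% names(localities)) {
    locality_points(localities)
  } else {
    dplyr::distinct(localities, .data$locality, .data$x, .data$y)
  }
  if (is.data.frame(values)) {
    vcol <- setdiff(names(values), "locality")[1]
    values <- setNames(values[[vcol]], values$locality)
  }
  z <- unname(values[pts$locality])
  keep <- !is.na(z)
  pts <- pts[keep, , drop = FALSE]; z <- z[keep]
  if (nrow(pts) < 3) abort("need >= 3 localities with values")
  if (all_collinear(pts$x, pts$y)) abort("localities are collinear; surface undefined")
  if (!is.null(at)) {
    out <- interp::interp(pts$x, pts$y, z, xo = at$x, yo = at$y,
                          linear = TRUE, output = "points")
    return(as.numeric(out$z))
  }
  xo <- seq(min(pts$x), max(pts$x), length.out = resolution)
  yo <- seq(min(pts$y), max(pts$y), length.out = resolution)
  out <- interp::interp(pts$x, pts$y, z, xo = xo, yo = yo, linear = TRUE,
                        output = "grid")
  structure(list(x = out$x, y = out$y, z = out$z), class = "surface_grid")
}

all_collinear <- function(x, y) {
  if (length(x) < 3) return(TRUE)
  dx <- x - x[1]; dy <- y - y[1]
  cross <- dx[2] * dy - dy[2] * dx
  span <- max(abs(c(dx, dy)))
  all(abs(cross) <= 1e-9 * span^2)
}

#' Extract the 0.5 isoline of an interpolated surface
#'
#' Marching-squares contour lines at the given level; polylines are returned
#' in grid order with duplicates removed.
#'
#' @param field a `surface_grid` from [interpolate_surface()].
#' @param level contour level (default 0.5).
#' @return tibble of class `contour_set` with columns `line` (polyline id),
#'   `x`, `y`. Zero rows (with a warning) when the field never crosses the
#'   level.
#' @export
extract_half_contour <- function(field, level = 0.5) {
  stopifnot(inherits(field, "surface_grid"))
  cl <- grDevices::contourLines(field$x, field$y, field$z, levels = level)
  if (!length(cl)) {
    warn(sprintf("field does not cross level %g: empty contour", level))
    out <- tibble::tibble(line = integer(0), x = numeric(0), y = numeric(0))
  } else {
    out <- purrr::imap_dfr(cl, function(li, i)
      tibble::tibble(line = i, x = li$x, y = li$y)) |>
      dplyr::distinct()
  }
  attr(out, "level") <- level
  class(out) <- c("contour_set", class(out))
  out
}

#' Principal polyline of a contour set
#'
#' Returns the polyline with the greatest total arc length — the main
#' contact front. Secondary closed isolines (e.g. the ring around an
#' enclave) alias far-away localities onto small transect distances, so
#' cline transects are measured against the principal line.
#'
#' @param contour a `contour_set`.
#' @return a `contour_set` containing one polyline.
#' @export
principal_contour <- function(contour) {
  if (nrow(contour) == 0) return(contour)
  lens <- vapply(split(contour, contour$line), function(ln) {
    if (nrow(ln) < 2) return(0)
    sum(sqrt(diff(ln$x)^2 + diff(ln$y)^2))
  }, 0)
  keep <- names(lens)[which.max(lens)]
  out <- contour[contour$line == as.integer(keep), ]
  attr(out, "level") <- attr(contour, "level")
  class(out) <- class(contour)
  out
}

# minimum distance from points to a polyline set (vectorized per segment)
min_dist_to_polylines <- function(px, py, contour) {
  best <- rep(Inf, length(px))
  for (ln in split(contour, contour$line)) {
    n <- nrow(ln)
    if (n == 1) {
      d <- sqrt((px - ln$x)^2 + (py - ln$y)^2)
      best <- pmin(best, d)
      next
    }
    for (i in seq_len(n - 1)) {
      x1 <- ln$x[i]; y1 <- ln$y[i]; x2 <- ln$x[i + 1]; y2 <- ln$y[i + 1]
      vx <- x2 - x1; vy <- y2 - y1
      L2 <- vx^2 + vy^2
      t <- if (L2 == 0) rep(0, length(px)) else
        pmin(pmax(((px - x1) * vx + (py - y1) * vy) / L2, 0), 1)
      d <- sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
      best <- pmin(best, d)
    }
  }
  best
}

#' Signed transect distances to the 0.5 hybrid-index contour
#'
#' For each locality, the minimum straight-line distance to any contour
#' polyline, signed positive when the locality's genetically dominant
#' species is the focal species and negative otherwise.
#'
#' @param localities tibble (locality, x, y) or `locality_tbl`.
#' @param contour a `contour_set`.
#' @param dominant named vector or tibble (locality, dominant).
#' @param focal focal species label.
#' @param hybrid optional hybrid-index table (locality, h, n_genotypes) to
#'   join, yielding a cline-ready transect.
#' @return tibble of class `transect_tbl`: `locality`, `distance` (signed,
#'   km), plus `h`, `n_genotypes` when `hybrid` is given.
#' @export
signed_transect <- function(localities, contour, dominant, focal, hybrid = NULL) {
  if (nrow(contour) == 0) abort("empty contour: transect undefined")
  pts <- if ("individual" %in% names(localities)) {
    locality_points(localities)
  } else {
    dplyr::distinct(localities, .data$locality, .data$x, .data$y)
  }
  if (is.data.frame(dominant)) dominant <- setNames(dominant$dominant, dominant$locality)
  lab <- dominant[pts$locality]
  if (anyNA(lab)) {
    abort(paste("localities without a dominant-species label:",
                paste(pts$locality[is.na(lab)], collapse = ", ")))
  }
  d <- min_dist_to_polylines(pts$x, pts$y, contour)
  out <- tibble::tibble(
    locality = pts$locality,
    distance = unname(ifelse(lab == focal, d, -d))
  )
  if (!is.null(hybrid)) out <- dplyr::inner_join(out, hybrid, by = "locality")
  class(out) <- c("transect_tbl", class(out))
  out
}

#' Write Thiessen polygons or contour lines as GeoJSON
#'
#' @param x a `thiessen_map` or `contour_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(x, path) {
  feats <- if (inherits(x, "thiessen_map")) {
    lapply(split(x$polygons, x$polygons$locality), function(p) {
      ring <- cbind(p$x, p$y)
      ring <- rbind(ring, ring[1, ])
      list(type = "Feature",
           properties = list(locality = p$locality[1]),
           geometry = list(type = "Polygon",
                           coordinates = list(lapply(seq_len(nrow(ring)),
                                                     function(i) ring[i, ]))))
    })
  } else if (inherits(x, "contour_set")) {
    lapply(split(x, x$line), function(p) {
      list(type = "Feature",
           properties = list(line = p$line[1], level = attr(x, "level") %||% 0.5),
           geometry = list(type = "LineString",
                           coordinates = lapply(seq_len(nrow(p)),
                                                function(i) c(p$x[i], p$y[i]))))
    })
  } else {
    abort("write_geojson handles thiessen_map and contour_set objects")
  }
  gj <- list(type = "FeatureCollection", features = unname(feats))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
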