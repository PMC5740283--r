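
test_that("two points give half-plane tiles that neighbour each other", {
  loc <- tibble::tibble(locality = c("P", "Q"), x = c(0, 10), y = c(0, 0))
  tm <- build_thiessen(loc)
  expect_equal(nrow(tm$adjacency), 1)
  expect_setequal(unlist(tm$adjacency[1, ]), c("P", "Q"))
  # the shared edge is the perpendicular bisector x = 5
  pp <- tm$polygons[tm$polygons$locality == "P", ]
  expect_equal(max(pp$x), 5)
  # tile areas partition the clipped bounding region
  bb <- tm$bbox
  expect_equal(sum(tm$areas$area),
               unname((bb["xmax"] - bb["xmin"]) * (bb["ymax"] - bb["ymin"])))
})

test_that("unit square plus centre has the known adjacency structure", {
  loc <- tibble::tibble(locality = c("c", "sw", "se", "nw", "ne"),
                        x = c(0.5, 0, 1, 0, 1), y = c(0.5, 0, 0, 1, 1))
  tm <- build_thiessen(loc)
  adj <- dplyr::arrange(tm$adjacency, locality_a, locality_b)
  has <- function(a, b) any(adj$locality_a == min(a, b) & adj$locality_b == max(a, b))
  expect_true(all(vapply(c("sw", "se", "nw", "ne"), has, TRUE, a = "c")))
  expect_false(has("sw", "ne"))   # opposite corners never touch
  expect_false(has("se", "nw"))
  clash <- dplyr::bind_rows(loc, tibble::tibble(locality = "c2", x = 0.5, y = 0.5))
  expect_error(build_thiessen(clash), "duplicate")
})

test_that("Thiessen adjacency matches the brute-force nearest-site oracle", {
  set.seed(42)
  for (trial in 1:4) {
    n <- sample(4:10, 1)
    pts <- tibble::tibble(locality = sprintf("L%02d", 1:n),
                          x = round(runif(n, 0, 100), 2),
                          y = round(runif(n, 0, 100), 2))
    got <- dplyr::arrange(build_thiessen(pts)$adjacency, locality_a, locality_b)
    want <- brute_force_adjacency(pts)
    expect_equal(as.data.frame(got), as.data.frame(want), info = paste("trial", trial))
  }
})

test_that("surface interpolation is exact for linear fields and at the nodes", {
  set.seed(5)
  loc <- tibble::tibble(locality = sprintf("L%02d", 1:30),
                        x = runif(30, 0, 100), y = runif(30, 0, 100))
  h <- loc$x / 100
  # linear reproduction on grid nodes inside the hull
  surf <- interpolate_surface(loc, setNames(h, loc$locality), resolution = 60)
  want <- matrix(rep(surf$x / 100, length(surf$y)), length(surf$x))
  inside <- !is.na(surf$z)
  expect_lt(max(abs(surf$z[inside] - want[inside])), 1e-9)
  # exact at the locality nodes
  at <- interpolate_surface(loc, setNames(h, loc$locality),
                            at = loc[c("x", "y")])
  expect_equal(at, h, tolerance = 1e-9)
  # constant field stays constant
  sc <- interpolate_surface(loc, setNames(rep(0.6, 30), loc$locality), resolution = 30)
  expect_true(all(abs(sc$z[!is.na(sc$z)] - 0.6) < 1e-12))
  # collinear input is rejected
  col <- tibble::tibble(locality = c("a", "b", "c"), x = 1:3, y = 1:3 * 2)
  expect_error(interpolate_surface(col, setNames(1:3 / 3, col$locality)),
               "collinear")
})

test_that("half contour tracks the 0.5 level and splits around enclaves", {
  set.seed(6)
  loc <- tibble::tibble(locality = sprintf("L%02d", 1:40),
                        x = runif(40, 0, 100), y = runif(40, 0, 100))
  surf <- interpolate_surface(loc, setNames(loc$x / 100, loc$locality),
                              resolution = 120)
  ct <- extract_half_contour(surf)
  expect_gt(nrow(ct), 0)
  expect_true(all(abs(ct$x - 50) < diff(range(loc$x)) / 120 + 1e-6))
  # constant field above the level: empty contour with warning
  sc <- interpolate_surface(loc, setNames(rep(0.6, 40), loc$locality), resolution = 30)
  expect_warning(empty <- extract_half_contour(sc), "empty contour")
  expect_equal(nrow(empty), 0)
  # a bubble of high values inside a low field yields >= 2 polylines
  gx <- seq(0, 100, length.out = 80)
  z <- outer(gx, gx, function(x, y) 0.2 + 0.7 * exp(-((x - 30)^2 + (y - 50)^2) / 100))
  z <- z + outer(gx, gx, function(x, y) 0.7 * exp(-((x - 80)^2 + (y - 50)^2) / 100))
  bubble <- structure(list(x = gx, y = gx, z = z), class = "surface_grid")
  cb <- extract_half_contour(bubble)
  expect_gte(length(unique(cb$line)), 2)
})

test_that("signed transect distances carry dominance signs and rigid-motion invariance", {
  # linear field: contour at x = 50, |distance| = |x - 50| within grid tol
  set.seed(7)
  loc <- tibble::tibble(locality = sprintf("L%02d", 1:40),
                        x = runif(40, 0, 100), y = runif(40, 0, 100))
  h <- setNames(loc$x / 100, loc$locality)
  surf <- interpolate_surface(loc, h, resolution = 150)
  ct <- extract_half_contour(surf)
  dom <- setNames(ifelse(loc$x > 50, "focal", "other"), loc$locality)
  tr <- signed_transect(loc, ct, dom, "focal")
  expect_equal(tr$distance, loc$x[match(tr$locality, loc$locality)] - 50,
               tolerance = 0.05)
  # locality on the contour: distance ~ 0
  on <- tibble::tibble(locality = "on", x = 50, y = 50)
  tr0 <- signed_transect(on, ct, c(on = "focal"), "focal")
  expect_lt(abs(tr0$distance), 1)
  # rigid motion: rotate everything by 35 degrees and translate
  th <- 35 * pi / 180
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y + 12,
                             y = sin(th) * x + cos(th) * y - 7)
  locr <- loc; p <- rot(loc$x, loc$y); locr$x <- p$x; locr$y <- p$y
  ctr <- ct; p <- rot(ct$x, ct$y); ctr$x <- p$x; ctr$y <- p$y
  trr <- signed_transect(locr, ctr, dom, "focal")
  expect_equal(trr$distance, tr$distance, tolerance = 1e-6)
  # missing dominance label is an error
  expect_error(signed_transect(loc, ct, dom[-1], "focal"), "dominant")
})

test_that("geojson writers emit valid feature collections", {
  loc <- tibble::tibble(locality = c("a", "b", "c"), x = c(0, 1, 0), y = c(0, 0, 1))
  tm <- build_thiessen(loc)
  f <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(tm, f)
  gj <- jsonlite::read_json(f)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), 3)
  expect_equal(gj$features[[1]]$geometry$type, "Polygon")
})
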