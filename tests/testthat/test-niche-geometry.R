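grid_points <- function(nx, ny, spacing = 10, x0 = 0, y0 = 0) {
  as.matrix(expand.grid(x = x0 + (seq_len(nx) - 1) * spacing,
                        y = y0 + (seq_len(ny) - 1) * spacing))
}

test_that("a uniform single-niche grid gives one hole-free component whose
           area equals the sum of retained triangle areas", {
  pts <- grid_points(10, 10)
  g <- build_graph(pts, max_edge_length = 40)
  comp <- extract_niche_polygons(g, rep("stroma", nrow(pts)))
  expect_length(comp, 1)
  expect_length(comp[[1]]$holes, 0)
  expect_equal(comp[[1]]$area, comp[[1]]$triangle_area, tolerance = 1e-6)
  expect_equal(comp[[1]]$n_cells, 100)
})

test_that("an annulus around a core yields a hole in the outer niche", {
  th <- 2 * pi * (0:23) / 24
  outer1 <- cbind(60 * cos(th), 60 * sin(th))
  outer2 <- cbind(75 * cos(th + pi / 24), 75 * sin(th + pi / 24))
  core <- rbind(grid_points(3, 3, 12, -12, -12), c(5, 5))
  pts <- rbind(outer1, outer2, core)
  niche <- c(rep("A", 48), rep("B", nrow(core)))
  g <- build_graph(pts, max_edge_length = 40)
  comp <- extract_niche_polygons(g, niche)
  labs <- vapply(comp, `[[`, character(1), "niche")
  A <- comp[[which(labs == "A")]]
  B <- comp[[which(labs == "B")]]
  expect_length(A$holes, 1)
  expect_length(B$holes, 0)
  expect_equal(A$area, A$triangle_area, tolerance = 1e-6)
  expect_equal(B$area, B$triangle_area, tolerance = 1e-6)
})

test_that("two isolated same-niche clusters count as two occurrences", {
  pts <- rbind(grid_points(4, 4), grid_points(4, 4, x0 = 500))
  g <- build_graph(pts, max_edge_length = 40)
  comp <- extract_niche_polygons(g, rep("tumour", nrow(pts)))
  expect_length(comp, 2)
  st <- niche_stats(comp)
  expect_equal(st$occurrences, 2L)
})

test_that("components below 5% of the largest are filtered from stats", {
  mk <- function(area, n = 4) list(niche = "g", exterior = sq(0, 0, sqrt(area)),
                                   holes = list(), area = area,
                                   perimeter = 4 * sqrt(area),
                                   roundness = pi / 4, n_cells = n,
                                   triangle_area = area)
  st <- niche_stats(list(mk(100), mk(6), mk(4)))
  expect_equal(st$occurrences, 2L)     # the area-4 component dropped
  expect_equal(st$mean_area, mean(c(100, 6)))
  st_all <- niche_stats(list(mk(100), mk(6), mk(4)), min_area_fraction = 0)
  expect_equal(st_all$occurrences, 3L)
})

test_that("roundness approaches 1 for regular n-gons and never exceeds it", {
  r_of <- function(p) 4 * pi * poly_area(p) / poly_perimeter(p)^2
  rs <- vapply(c(3, 4, 6, 12, 24, 64), function(n) r_of(ngon(0, 0, 10, n)),
               numeric(1))
  expect_true(all(diff(rs) > 0))       # monotone toward the disc limit
  expect_true(all(rs <= 1))
  expect_gt(rs[length(rs)], 1 - 0.002) # 64-gon within 0.2% of 1
})

test_that("per-component roundness lies in (0, 1]", {
  tis <- small_tissue()
  g <- build_graph(tis$truth$cells, max_edge_length = 40)
  comp <- extract_niche_polygons(g, tis$truth$niche)
  R <- vapply(comp, `[[`, numeric(1), "roundness")
  expect_true(all(R > 0 & R <= 1))
})

test_that("border rings are closed and components conserve area on tissue", {
  tis <- small_tissue(seed = 13)
  g <- build_graph(tis$truth$cells, max_edge_length = 40)
  comp <- extract_niche_polygons(g, tis$truth$niche)
  expect_gte(length(comp), 2)
  for (cc in comp) {
    expect_equal(cc$area, cc$triangle_area, tolerance = 1e-6)
    # closed ring: tracing ends where it starts (implicitly closed matrix);
    # all vertices distinct
    expect_false(any(duplicated(cc$exterior)))
  }
})

test_that("components without a simplex are skipped with a warning", {
  pts <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10), c(300, 300), c(310, 300))
  g <- build_graph(pts, max_edge_length = 40)
  niche <- rep("A", 6)
  expect_warning(comp <- extract_niche_polygons(g, niche), "skipped")
  expect_length(comp, 1)
})

test_that("niche components survive a GeoJSON round trip structurally", {
  tis <- small_tissue()
  g <- build_graph(tis$truth$cells, max_edge_length = 40)
  comp <- extract_niche_polygons(g, tis$truth$niche)
  f <- file.path(withr::local_tempdir(), "niches.geojson")
  write_niches(comp, f)
  doc <- jsonlite::read_json(f)
  expect_length(doc$features, length(comp))
  expect_equal(doc$features[[1]]$properties$niche, comp[[1]]$niche)
})
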