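test_that("ioma matches hand-computed overlap scores", {
  a <- sq(0, 0, 1)
  expect_equal(ioma(a, a), 1)
  expect_equal(ioma(a, sq(5, 5, 1)), 0)
  expect_equal(ioma(a, sq(0.4, 0, 1, 1)), 0.6)  # intersection 0.6, min area 1
  expect_equal(ioma(sq(0.4, 0, 1, 1), a), 0.6)  # symmetric
  degen <- cbind(c(0, 1, 2), c(0, 0, 0))
  expect_error(ioma(a, degen), class = "cellpatch_validation_error")
})

test_that("conflict classification uses the 0.07 / 0.8 cutoffs", {
  expect_equal(as.character(classify_conflict(c(0.05, 0.9, 0.5))),
               c("good_distinct", "good_duplicate", "ambiguous"))
  # boundary behavior: cutoffs belong to the middle band
  expect_equal(as.character(classify_conflict(c(0.069999, 0.07, 0.8, 0.80001))),
               c("good_distinct", "ambiguous", "ambiguous", "good_duplicate"))
  expect_error(classify_conflict(1.2), class = "cellpatch_validation_error")
  expect_error(classify_conflict(-0.1), class = "cellpatch_validation_error")
})

test_that("near-identical cells merge; barely-touching cells are kept", {
  # same cell seen from two patches, slightly shifted: ioma ~ 0.96
  a <- cell_collection(list(ngon(10, 10, 5, 24)), provenance = list(1L))
  b <- cell_collection(list(ngon(10.2, 10, 5, 24)), provenance = list(2L))
  merged <- resolve_conflicts(list(a, b))
  expect_equal(length(merged), 1)
  expect_equal(sort(merged$provenance[[1]]), c(1L, 2L))

  # overlap 0.2 of the smaller square: both kept
  c1 <- cell_collection(list(sq(0, 0, 1)), provenance = list(1L))
  c2 <- cell_collection(list(sq(0.8, 0, 1, 1)), provenance = list(2L))
  kept <- resolve_conflicts(list(c1, c2))
  expect_equal(length(kept), 2)
  tab <- conflict_table(kept)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$ioma, 0.2)
  expect_equal(tab$decision, "keep")
})

test_that("transitive chains merge into one union via union-find", {
  # A-B ioma 0.6, B-C ioma 0.6, A-C disjoint
  A <- sq(0, 0, 1)
  B <- sq(0.4, 0, 1, 1)    # A-B intersection 0.6
  C <- sq(0.8, 0, 1, 1)    # B-C intersection 0.6; A-C intersection 0.2 <= 0.5
  pp <- list(cell_collection(list(A), provenance = list(1L)),
             cell_collection(list(B), provenance = list(2L)),
             cell_collection(list(C), provenance = list(3L)))
  res <- resolve_conflicts(pp)
  expect_equal(length(res), 1)
  expect_equal(poly_area(res$polygons[[1]]), 1.8)  # union of the three
  expect_equal(sort(res$provenance[[1]]), 1:3)
})

test_that("resolution is idempotent and patch-order invariant", {
  tis <- small_tissue()
  grid <- make_patches(image_extent(tis$image), patch_width = 80, overlap = 25)
  per <- run_segmentation(tis$image, grid,
                          params = list(channel = "nuclear", threshold = 0.3,
                                        sigma = 1, min_area_px = 20))
  res <- resolve_conflicts(per)
  again <- resolve_conflicts(res)
  expect_equal(length(again), length(res))
  expect_equal(again$polygons, res$polygons)

  res_rev <- resolve_conflicts(rev(per))
  key <- function(cc) sort(vapply(cc$polygons, function(p)
    paste(round(sort(as.vector(p)), 6), collapse = ","), character(1)))
  expect_equal(key(res_rev), key(res))
})

test_that("no cross-patch pair exceeds the threshold after resolution", {
  tis <- small_tissue()
  grid <- make_patches(image_extent(tis$image), patch_width = 80, overlap = 25)
  per <- run_segmentation(tis$image, grid,
                          params = list(channel = "nuclear", threshold = 0.3,
                                        sigma = 1, min_area_px = 20))
  res <- resolve_conflicts(per)
  n <- length(res)
  worst <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    worst <- max(worst, ioma(res$polygons[[i]], res$polygons[[j]]))
  }
  expect_lte(worst, 0.5)
})

test_that("end-to-end recovery: resolved count equals ground truth", {
  tis <- small_tissue()
  grid <- make_patches(image_extent(tis$image), patch_width = 80, overlap = 25)
  expect_equal(nrow(grid), 4)  # 2 x 2 overlapping grid
  per <- run_segmentation(tis$image, grid,
                          params = list(channel = "nuclear", threshold = 0.3,
                                        sigma = 1, min_area_px = 20))
  res <- resolve_conflicts(per)
  expect_equal(length(res), length(tis$truth$cells))
  expect_true(all(diff(res$id) > 0))
  expect_false(anyDuplicated(res$id) > 0)
})

test_that("empty input resolves to an empty collection", {
  res <- resolve_conflicts(list())
  expect_equal(length(res), 0)
  expect_equal(nrow(conflict_table(res)), 0)
})
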