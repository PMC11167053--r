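disc_mask_image <- function(centers, radius_px, dim_px, value = 0.9,
                            background = 0.02) {
  m <- matrix(background, dim_px[1], dim_px[2])
  g <- expand.grid(r = seq_len(dim_px[1]), c = seq_len(dim_px[2]))
  for (k in seq_len(nrow(centers))) {
    inside <- (g$r - centers[k, 1])^2 + (g$c - centers[k, 2])^2 <= radius_px^2
    m[cbind(g$r[inside], g$c[inside])] <- value
  }
  m
}

test_that("a blank patch yields an all-zero mask", {
  blank <- matrix(0, 32, 32)
  expect_equal(builtin_segment_patch(blank, list(sigma = 0)), matrix(0L, 32, 32))
  expect_equal(builtin_segment_patch(blank, list(threshold = 0.5, sigma = 1)),
               matrix(0L, 32, 32))
})

test_that("well-separated discs are each labelled once", {
  centers <- rbind(c(15, 15), c(15, 45), c(45, 15), c(45, 45), c(30, 30))
  img <- disc_mask_image(centers, 5, c(60, 60))
  mask <- builtin_segment_patch(img, list(threshold = 0.3, sigma = 0,
                                          min_area_px = 10))
  expect_equal(max(mask), 5)
  expect_equal(sort(unique(as.vector(mask))), 0:5)
})

test_that("split_touching separates merged blobs via watershed", {
  img <- disc_mask_image(rbind(c(20, 22), c(20, 38)), 10, c(40, 60))
  merged <- builtin_segment_patch(img, list(threshold = 0.3, sigma = 0,
                                            min_area_px = 10,
                                            split_touching = FALSE))
  split <- builtin_segment_patch(img, list(threshold = 0.3, sigma = 0,
                                           min_area_px = 10,
                                           split_touching = TRUE))
  expect_equal(max(merged), 1)
  expect_equal(max(split), 2)
})

test_that("mask polygons trace pixel boundaries exactly", {
  mask <- matrix(0L, 20, 20)
  mask[6:15, 4:13] <- 1L   # 10 x 10 square
  cells <- mask_to_polygons(mask, window_origin = c(0, 0), pixel_size = 1)
  expect_equal(length(cells), 1)
  expect_equal(poly_area(cells$polygons[[1]]), 100)
  expect_equal(poly_perimeter(cells$polygons[[1]]), 40)
  # empty mask
  expect_equal(length(mask_to_polygons(matrix(0L, 5, 5))), 0)
})

test_that("mask polygon area equals pixel count for irregular labels", {
  set.seed(12)
  for (rep in 1:10) {
    mask <- matrix(0L, 30, 30)
    # random blob: union of a few rectangles (4-connected)
    for (k in 1:3) {
      r0 <- sample(5:20, 1); c0 <- sample(5:20, 1)
      mask[r0:(r0 + sample(3:8, 1)), c0:(c0 + sample(3:8, 1))] <- 1L
    }
    lab <- matrix(as.integer(as.matrix(EBImage::bwlabel(mask))), 30, 30)
    cells <- mask_to_polygons(lab, pixel_size = 1)
    for (i in seq_len(length(cells))) {
      npx <- sum(lab == cells$id[i])
      # holes are filled, so area >= pixel count; equal when no holes
      expect_gte(poly_area(cells$polygons[[i]]) + 1e-9, npx)
    }
    expect_equal(sum(cell_areas(cells)) >= sum(lab > 0), TRUE)
  }
})

test_that("labels touching the window edge stay valid and clipped", {
  mask <- matrix(0L, 10, 10)
  mask[1:4, 1:5] <- 1L  # touches top-left corner
  cells <- mask_to_polygons(mask, window_origin = c(10, 20), pixel_size = 0.5)
  expect_equal(length(cells), 1)
  expect_equal(poly_area(cells$polygons[[1]]), 20 * 0.25)
  bb <- poly_bbox(cells$polygons[[1]])
  expect_equal(unname(bb[1]), 10 - 0.25)  # clipped at window start
  expect_equal(unname(bb[2]), 20 - 0.25)
})

test_that("a 1-patch grid equals segmenting the whole image", {
  tis <- small_tissue()
  grid1 <- make_patches(image_extent(tis$image), patch_width = 1000,
                        overlap = 10)
  expect_equal(nrow(grid1), 1)
  params <- list(channel = "nuclear", threshold = 0.3, sigma = 1,
                 min_area_px = 20)
  via_grid <- run_segmentation(tis$image, grid1, params = params)[[1]]
  d <- image_dim(tis$image)
  direct <- mask_to_polygons(
    builtin_segment_patch(tis$image$data,
                          utils::modifyList(params, list(channel = 1L))),
    window_origin = c(0, 0), pixel_size = tis$image$pixel_size)
  expect_equal(length(via_grid), length(direct))
  expect_equal(via_grid$polygons, direct$polygons)
})

test_that("patch results are order-independent and cells complete somewhere", {
  tis <- small_tissue()
  grid <- make_patches(image_extent(tis$image), patch_width = 80, overlap = 25)
  params <- list(channel = "nuclear", threshold = 0.3, sigma = 1,
                 min_area_px = 20)
  res <- run_segmentation(tis$image, grid, params = params)
  perm <- rev(seq_len(nrow(grid)))
  res_perm <- run_segmentation(tis$image, grid, params = params,
                               patches = perm)
  key <- function(cc) sort(vapply(cc$polygons, function(p)
    paste(round(as.vector(p), 6), collapse = ","), character(1)))
  expect_equal(sort(unlist(lapply(res, key))),
               sort(unlist(lapply(res_perm, key))))

  # overlap (25 um) >= 2 x cell diameter (10 um): every ground-truth cell is
  # fully inside at least one patch rectangle
  bb <- cell_bboxes(tis$truth$cells)
  complete <- vapply(seq_len(nrow(bb)), function(i) {
    any(grid$xmin <= bb[i, 1] & grid$xmax >= bb[i, 3] &
        grid$ymin <= bb[i, 2] & grid$ymax >= bb[i, 4])
  }, logical(1))
  expect_true(all(complete))
})

test_that("segmenter errors carry patch context", {
  tis <- small_tissue()
  grid <- make_patches(image_extent(tis$image), patch_width = 80, overlap = 25)
  bad <- function(window, params, transcripts) stop("boom")
  expect_error(run_segmentation(tis$image, grid, segmenter = bad),
               "patch 1")
})
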