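mk_img <- function(h, w, c = 1, seed = 1, chunk = c(256L, 256L)) {
  set.seed(seed)
  raster_image(array(runif(h * w * c), c(h, w, c)),
               paste0("ch", seq_len(c)), pixel_size = 0.5, chunk = chunk)
}

test_that("pyramid level schedule halves until one tile fits", {
  td <- withr::local_tempdir()
  expect_equal(export_image_pyramid(mk_img(512, 512), file.path(td, "a")),
               list(c(512, 512)))
  levels <- export_image_pyramid(mk_img(2500, 1400), file.path(td, "b"))
  expect_equal(levels, list(c(2500, 1400), c(1250, 700), c(625, 350)))
  m <- jsonlite::read_json(file.path(td, "b", "images", "level_0", "meta.json"),
                           simplifyVector = TRUE)
  expect_equal(m$tile_px, 1024)
  expect_equal(nrow(m$tiles), 3 * 2)  # 2500x1400 -> 3 x 2 tiles of 1024
})

test_that("level 0 reads back exactly; level 1 equals the block-mean oracle", {
  td <- withr::local_tempdir()
  img <- mk_img(130, 70, c = 2, seed = 5)
  # tiny tile size not possible (constant), so use a small image vs oracle
  b <- file.path(td, "bundle")
  export_image_pyramid(img, b)
  expect_equal(read_image_level(b, 0), unname(img$data))

  big <- mk_img(1100, 1030, seed = 6)
  b2 <- file.path(td, "b2")
  export_image_pyramid(big, b2)
  l1 <- read_image_level(b2, 1)
  # independent 2x2 block mean
  oi <- ceiling(seq_len(1100) / 2); oj <- ceiling(seq_len(1030) / 2)
  oracle <- t(rowsum(t(rowsum(big$data[, , 1], oi)), oj)) /
    outer(tabulate(oi), tabulate(oj))
  expect_equal(l1[, , 1], unname(oracle), tolerance = 1e-12)
})

test_that("tile generation touches only the source pixels a tile covers", {
  img <- mk_img(1100, 1030, seed = 6)
  reset_read_stats(img)
  export_image_pyramid(img, file.path(withr::local_tempdir(), "b"))
  expect_equal(image_read_stats(img)$pixels_read, 1100 * 1030)
})

test_that("transcript pyramid sizes follow floor division by 4", {
  td <- withr::local_tempdir()
  set.seed(2)
  n <- 1000
  t <- transcript_table(runif(n, 0, 800), runif(n, 0, 800),
                        sample(c("g1", "g2"), n, TRUE))
  counts <- export_transcript_pyramid(t, file.path(td, "b"),
                                      extent = c(0, 0, 800, 800))
  expect_equal(counts, c(1000, 250, 62))
  # levels: 250 um (4x4 grid), 500 um (2x2), 1000 um (1 tile >= extent)
  m0 <- jsonlite::read_json(file.path(td, "b", "transcripts", "level_0",
                                      "meta.json"), simplifyVector = TRUE)
  expect_equal(m0$tile_width_um, 250)
  expect_equal(c(m0$nx, m0$ny), c(4, 4))
})

test_that("a 400 um extent gives a 2x2 base grid then a single covering tile", {
  td <- withr::local_tempdir()
  set.seed(3)
  t <- transcript_table(runif(50, 0, 400), runif(50, 0, 400), rep("g", 50))
  export_transcript_pyramid(t, file.path(td, "b"), extent = c(0, 0, 400, 400))
  meta <- jsonlite::read_json(file.path(td, "b", "transcripts", "meta.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$n_levels, 2)
  m0 <- jsonlite::read_json(file.path(td, "b", "transcripts", "level_0",
                                      "meta.json"), simplifyVector = TRUE)
  m1 <- jsonlite::read_json(file.path(td, "b", "transcripts", "level_1",
                                      "meta.json"), simplifyVector = TRUE)
  expect_equal(c(m0$nx, m0$ny), c(2, 2))
  expect_equal(c(m1$nx, m1$ny), c(1, 1))
  expect_equal(m1$tile_width_um, 500)
})

test_that("concatenated level-0 tiles reproduce the input table", {
  td <- withr::local_tempdir()
  set.seed(4)
  n <- 777
  t <- transcript_table(runif(n, 0, 600), runif(n, 0, 600),
                        sample(c("a", "b", "c"), n, TRUE))
  export_transcript_pyramid(t, file.path(td, "b"), extent = c(0, 0, 600, 600))
  back <- read_transcript_level(file.path(td, "b"), 0)
  back <- back[order(back$id), ]
  expect_equal(back$x, t$x)
  expect_equal(back$y, t$y)
  expect_equal(back$gene_index, as.integer(t$gene) - 1L)
})

test_that("boundary export pads, keeps 13-vertex rings, simplifies long rings", {
  td <- withr::local_tempdir()
  tri <- cbind(c(0, 10, 0), c(0, 0, 10))
  tridecagon <- ngon(0, 0, 5, 13)
  circle60 <- ngon(50, 50, 8, 60)
  cells <- cell_collection(list(tri, tridecagon, circle60))
  arr <- export_boundaries(cells, file.path(td, "b"))
  expect_equal(dim(arr), c(3, 13, 2))
  # triangle: last vertex repeated 11 times
  expect_equal(arr[1, 3:13, 1], rep(0, 11))
  expect_equal(arr[1, 3:13, 2], rep(10, 11))
  # 13-vertex polygon unchanged
  expect_equal(arr[2, , ], unname(tridecagon))
  # 60-gon simplified to <= 13 distinct vertices, area within 10%
  uniq <- unique(arr[3, , ])
  expect_lte(nrow(uniq), 13)
  expect_equal(poly_area(uniq), poly_area(circle60), tolerance = 0.1)
  # round trip
  back <- read_boundaries(file.path(td, "b"))
  expect_equal(unname(back[, , ]), unname(arr[, , ]))
  expect_equal(attr(back, "cell_ids"), 1:3)
})

test_that("sparse tables match the hand-compressed layout and round-trip", {
  td <- withr::local_tempdir()
  m <- matrix(c(1, 0, 0, 2), 2, 2,
              dimnames = list(c("c1", "c2"), c("g1", "g2")))
  export_tables(m, list(), file.path(td, "b"))
  dirc <- file.path(td, "b", "tables", "counts")
  data <- cellpatch:::read_bin(file.path(dirc, "data.bin"), 2, "double")
  ci <- cellpatch:::read_bin(file.path(dirc, "cell_index.bin"), 2, "integer")
  gp <- cellpatch:::read_bin(file.path(dirc, "gene_pointer.bin"), 3, "integer")
  expect_equal(data, c(1, 2))
  expect_equal(ci, c(0L, 1L))
  expect_equal(gp, c(0L, 1L, 2L))

  # all-zero counts: empty data, pointers all zero
  z <- matrix(0, 3, 2, dimnames = list(paste0("c", 1:3), c("g1", "g2")))
  export_tables(z, list(), file.path(td, "z"))
  gpz <- cellpatch:::read_bin(file.path(td, "z", "tables", "counts",
                                        "gene_pointer.bin"), 3, "integer")
  expect_equal(gpz, c(0L, 0L, 0L))

  for (seed in 1:20) {
    set.seed(seed)
    mm <- Matrix::rsparsematrix(sample(2:30, 1), sample(2:12, 1), 0.25,
                                rand.x = function(k)
                                  as.numeric(sample(1:9, k, TRUE)))
    dimnames(mm) <- list(paste0("c", seq_len(nrow(mm))),
                         paste0("g", seq_len(ncol(mm))))
    cats <- list(ct = sample(c("x", "y", "z"), nrow(mm), TRUE))
    bdir <- file.path(td, paste0("r", seed))
    export_tables(mm, cats, bdir)
    back <- read_tables(bdir)
    expect_equal(as.matrix(back$counts), as.matrix(mm))
    expect_equal(back$categories$ct, cats$ct)
    # cell indices ascend within each gene slice
    gp <- cellpatch:::read_bin(file.path(bdir, "tables", "counts",
                                         "gene_pointer.bin"),
                               ncol(mm) + 1L, "integer")
    ci <- cellpatch:::read_bin(file.path(bdir, "tables", "counts",
                                         "cell_index.bin"),
                               gp[length(gp)], "integer")
    for (g in seq_len(ncol(mm))) {
      sl <- if (gp[g + 1] > gp[g]) ci[(gp[g] + 1):gp[g + 1]] else integer(0)
      expect_true(!is.unsorted(sl, strictly = TRUE))
    }
  }
})

test_that("category fields with missing labels are rejected", {
  td <- withr::local_tempdir()
  m <- matrix(1, 2, 1, dimnames = list(c("c1", "c2"), "g"))
  expect_error(export_tables(m, list(ct = c("a", NA)), file.path(td, "b")),
               class = "cellpatch_validation_error")
})

test_that("bundles honour presence flags and are byte-identical on re-run", {
  td <- withr::local_tempdir()
  img <- mk_img(128, 128, c = 2, seed = 9)
  cells <- cell_collection(list(ngon(10, 10, 4, 24), ngon(30, 30, 4, 24)))
  # imaging-only: no transcripts part, flag false
  b1 <- file.path(td, "imaging")
  write_bundle(b1, image = img, cells = cells)
  meta <- read_bundle_meta(b1)
  expect_false(meta$parts$transcripts)
  expect_true(meta$parts$image)
  expect_false(dir.exists(file.path(b1, "transcripts")))

  expect_error(write_bundle(file.path(td, "none")),
               class = "cellpatch_validation_error")

  # full bundle: all parts present with matching shapes
  set.seed(10)
  t <- transcript_table(runif(200, 0, 64), runif(200, 0, 64),
                        sample(c("g1", "g2"), 200, TRUE))
  counts <- count_transcripts(t, cells)
  b2 <- file.path(td, "full1")
  b3 <- file.path(td, "full2")
  for (b in c(b2, b3)) {
    write_bundle(b, image = img, transcripts = t, cells = cells,
                 counts = counts, categories = list(ct = c("a", "b")))
  }
  meta2 <- read_bundle_meta(b2)
  expect_true(all(unlist(meta2$parts)))
  expect_equal(meta2$shapes$n_cells, 2)
  expect_equal(unlist(meta2$constants),
               c(tile_px = 1024, transcript_tile_um = 250,
                 boundary_vertices = 13))
  # determinism: byte-identical files
  files <- list.files(b2, recursive = TRUE)
  expect_equal(files, list.files(b3, recursive = TRUE))
  h2 <- vapply(files, function(f) unname(tools::md5sum(file.path(b2, f))),
               character(1))
  h3 <- vapply(files, function(f) unname(tools::md5sum(file.path(b3, f))),
               character(1))
  expect_equal(unname(h2), unname(h3))
})
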