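# Export to an open visualizer bundle.
#
# The bundle is a directory holding five parts in a simple chunked layout
# (per-chunk little-endian binary blobs plus JSON metadata; the full schema
# is recorded in experiment.json):
#   * an image pyramid: level 0 at full resolution, each next level a 2x2
#     mean-downsample, until both dimensions fit in one 1024 px tile; every
#     level stored as 1024 x 1024 px tiles, generated one at a time from
#     only the source pixels the tile covers;
#   * a transcript pyramid: level-0 tiles are 250 um squares holding all
#     transcripts; per level the tile width doubles and one fourth of the
#     previous level's points are retained (deterministic stride over the
#     stable input order), until a single tile covers the slide;
#   * cell boundaries as a fixed-width N x 13 x 2 vertex array (simplified
#     when needed, padded by repeating the last vertex; ring implicitly
#     closed);
#   * the cell-by-gene table in gene-major compressed sparse layout
#     (data / cell_index / gene_pointer) plus per-category index/pointer
#     arrays;
#   * experiment.json metadata.

TILE_PX <- 1024L
TRANSCRIPT_TILE_UM <- 250
BOUNDARY_VERTICES <- 13L

write_bin <- function(x, path, what = c("double", "float", "integer")) {
  what <- match.arg(what)
  con <- file(path, "wb")
  on.exit(close(con))
  switch(what,
         double = writeBin(as.numeric(x), con, size = 8, endian = "little"),
         float = writeBin(as.numeric(x), con, size = 4, endian = "little"),
         integer = writeBin(as.integer(x), con, size = 4, endian = "little"))
  invisible(path)
}

read_bin <- function(path, n, what = c("double", "float", "integer")) {
  what <- match.arg(what)
  con <- file(path, "rb")
  on.exit(close(con))
  switch(what,
         double = readBin(con, "numeric", n = n, size = 8, endian = "little"),
         float = readBin(con, "numeric", n = n, size = 4, endian = "little"),
         integer = readBin(con, "integer", n = n, size = 4, endian = "little"))
}

write_json_meta <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
}

read_json_meta <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

# 2x2 block mean of an H x W x C array; odd trailing rows/cols average the
# available pixels.
downsample2 <- function(a) {
  d <- dim(a)
  oi <- ceiling(seq_len(d[1]) / 2)
  oj <- ceiling(seq_len(d[2]) / 2)
  cnt <- outer(tabulate(oi), tabulate(oj))
  out <- array(0, c(max(oi), max(oj), d[3]))
  for (ch in seq_len(d[3])) {
    s <- rowsum(a[, , ch], oi)
    out[, , ch] <- t(rowsum(t(s), oj)) / cnt
  }
  out
}

tile_ranges <- function(extent_px, tile) {
  starts <- seq(1L, extent_px, by = tile)
  lapply(starts, function(s) s:min(s + tile - 1L, extent_px))
}

# Write one pyramid level given a reader function(rows, cols) -> array.
# Returns the 2x2-downsampled level as an in-memory array, built tile by
# tile so the working set never exceeds one tile.
write_image_level <- function(dir, level, shape, reader) {
  lev_dir <- file.path(dir, sprintf("level_%d", level))
  dir.create(lev_dir, recursive = TRUE, showWarnings = FALSE)
  rws <- tile_ranges(shape[1], TILE_PX)
  cls <- tile_ranges(shape[2], TILE_PX)
  nxt <- array(0, c(ceiling(shape[1] / 2), ceiling(shape[2] / 2), shape[3]))
  tiles <- list()
  for (tr in seq_along(rws)) {
    for (tc in seq_along(cls)) {
      block <- reader(rws[[tr]], cls[[tc]])
      f <- sprintf("tile_%d_%d.bin", tr - 1L, tc - 1L)
      write_bin(block, file.path(lev_dir, f), "double")
      ds <- downsample2(block)
      ri <- (rws[[tr]][1] + 1L) %/% 2
      ci <- (cls[[tc]][1] + 1L) %/% 2
      nxt[ri:(ri + dim(ds)[1] - 1L), ci:(ci + dim(ds)[2] - 1L), ] <- ds
      tiles[[length(tiles) + 1L]] <-
        list(r = tr - 1L, c = tc - 1L,
             rows = c(rws[[tr]][1], rws[[tr]][length(rws[[tr]])]),
             cols = c(cls[[tc]][1], cls[[tc]][length(cls[[tc]])]),
             file = f)
    }
  }
  write_json_meta(list(level = level, shape = shape, tile_px = TILE_PX,
                       dtype = "float64", order = "column-major-per-channel",
                       tiles = tiles),
                  file.path(lev_dir, "meta.json"))
  nxt
}

#' Export a tiled image pyramid
#'
#' Level 0 is the full-resolution image; each next level is a 2x2 mean
#' downsample; levels are added until both dimensions are at most one
#' 1024 px tile. Level-0 tiles are produced one at a time from exactly the
#' source pixels they cover (verifiable through [image_read_stats()]);
#' smaller levels are held in memory.
#'
#' @param image A [raster_image].
#' @param bundle_dir Bundle directory.
#' @return Invisibly, the per-level dimensions (list of `c(rows, cols)`).
#' @export
export_image_pyramid <- function(image, bundle_dir) {
  dir <- file.path(bundle_dir, "images")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- image_dim(image)
  shapes <- list(c(d, n_channels(image)))
  while (any(shapes[[length(shapes)]][1:2] > TILE_PX)) {
    prev <- shapes[[length(shapes)]]
    shapes[[length(shapes) + 1L]] <- c(ceiling(prev[1:2] / 2), prev[3])
  }
  current <- write_image_level(dir, 0L, shapes[[1]],
                               function(rows, cols) read_block(image, rows, cols))
  lev <- 1L
  while (lev < length(shapes)) {
    arr <- current
    current <- write_image_level(dir, lev, shapes[[lev + 1L]],
                                 function(rows, cols) arr[rows, cols, , drop = FALSE])
    lev <- lev + 1L
  }
  write_json_meta(list(n_levels = length(shapes), tile_px = TILE_PX,
                       pixel_size = image$pixel_size,
                       channel_names = image$channel_names,
                       shapes = shapes),
                  file.path(dir, "meta.json"))
  invisible(lapply(shapes, function(s) s[1:2]))
}

#' @rdname export_image_pyramid
#' @param level Pyramid level to read back (0-based).
#' @export
read_image_level <- function(bundle_dir, level) {
  lev_dir <- file.path(bundle_dir, "images", sprintf("level_%d", level))
  meta <- read_json_meta(file.path(lev_dir, "meta.json"))
  shape <- unlist(meta$shape)
  out <- array(NA_real_, shape)
  for (k in seq_len(nrow(meta$tiles))) {
    ti <- meta$tiles[k, ]
    rows <- ti$rows[[1]][1]:ti$rows[[1]][2]
    cols <- ti$cols[[1]][1]:ti$cols[[1]][2]
    v <- read_bin(file.path(lev_dir, ti$file),
                  length(rows) * length(cols) * shape[3], "double")
    out[rows, cols, ] <- array(v, c(length(rows), length(cols), shape[3]))
  }
  out
}

#' Export a pyramidal, subsampled transcript layout
#'
#' Level-0 tiles are 250 um squares holding every transcript; at each next
#' level the tile width doubles and every fourth point of the previous
#' level (in stable input order) is retained; the last level is the first
#' whose single tile covers the slide extent.
#'
#' @param t A [transcript_table].
#' @param bundle_dir Bundle directory.
#' @param extent Slide extent `c(xmin, ymin, xmax, ymax)`; defaults to the
#'   transcript bounding box anchored at the origin.
#' @return Invisibly, the number of transcripts retained per level.
#' @export
export_transcript_pyramid <- function(t, bundle_dir, extent = NULL) {
  dir <- file.path(bundle_dir, "transcripts")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(extent)) {
    extent <- c(0, 0, max(t$x, TRANSCRIPT_TILE_UM), max(t$y, TRANSCRIPT_TILE_UM))
  }
  ew <- extent[3] - extent[1]
  eh <- extent[4] - extent[2]
  sel <- seq_len(nrow(t))
  level <- 0L
  counts <- integer(0)
  repeat {
    width <- TRANSCRIPT_TILE_UM * 2^level
    nx <- max(1L, as.integer(ceiling(ew / width)))
    ny <- max(1L, as.integer(ceiling(eh / width)))
    lev_dir <- file.path(dir, sprintf("level_%d", level))
    dir.create(lev_dir, showWarnings = FALSE)
    tiles <- list()
    if (length(sel)) {
      ix <- pmin(floor((t$x[sel] - extent[1]) / width), nx - 1L)
      iy <- pmin(floor((t$y[sel] - extent[2]) / width), ny - 1L)
      for (key in split(seq_along(sel), paste(ix, iy))) {
        rows <- sel[key]
        tx <- ix[key[1]]; ty <- iy[key[1]]
        f <- sprintf("tile_%d_%d.bin", ty, tx)
        con <- file(file.path(lev_dir, f), "wb")
        writeBin(as.integer(t$id[rows]), con, size = 4, endian = "little")
        writeBin(as.integer(t$gene[rows]) - 1L, con, size = 4, endian = "little")
        writeBin(as.numeric(t$x[rows]), con, size = 8, endian = "little")
        writeBin(as.numeric(t$y[rows]), con, size = 8, endian = "little")
        close(con)
        tiles[[length(tiles) + 1L]] <- list(r = ty, c = tx, n = length(rows),
                                            file = f)
      }
    }
    write_json_meta(list(level = level, tile_width_um = width, nx = nx, ny = ny,
                         n = length(sel), tiles = tiles),
                    file.path(lev_dir, "meta.json"))
    counts <- c(counts, length(sel))
    if (nx == 1L && ny == 1L && width >= ew && width >= eh) break
    sel <- sel[seq_len(length(sel) %/% 4L) * 4L]
    level <- level + 1L
  }
  write_json_meta(list(n_levels = level + 1L, counts = counts,
                       base_tile_um = TRANSCRIPT_TILE_UM, extent = extent,
                       gene_levels = levels(t$gene)),
                  file.path(dir, "meta.json"))
  invisible(counts)
}

#' @rdname export_transcript_pyramid
#' @param level Pyramid level to read back (0-based).
#' @export
read_transcript_level <- function(bundle_dir, level) {
  dir <- file.path(bundle_dir, "transcripts")
  meta <- read_json_meta(file.path(dir, "meta.json"))
  lev_dir <- file.path(dir, sprintf("level_%d", level))
  lmeta <- read_json_meta(file.path(lev_dir, "meta.json"))
  if (lmeta$n == 0L || length(lmeta$tiles) == 0L) {
    return(data.frame(id = integer(0), gene_index = integer(0),
                      x = numeric(0), y = numeric(0),
                      tile_r = integer(0), tile_c = integer(0)))
  }
  tiles <- lmeta$tiles
  parts <- lapply(seq_len(nrow(tiles)), function(k) {
    ti <- tiles[k, ]
    con <- file(file.path(lev_dir, ti$file), "rb")
    on.exit(close(con))
    id <- readBin(con, "integer", ti$n, size = 4, endian = "little")
    gi <- readBin(con, "integer", ti$n, size = 4, endian = "little")
    x <- readBin(con, "numeric", ti$n, size = 8, endian = "little")
    y <- readBin(con, "numeric", ti$n, size = 8, endian = "little")
    data.frame(id = id, gene_index = gi, x = x, y = y,
               tile_r = ti$r, tile_c = ti$c)
  })
  do.call(rbind, parts)
}

# Douglas-Peucker simplification of an open polyline, keeping endpoints.
dp_open <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  a <- pts[1, ]; b <- pts[n, ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  d <- if (len < 1e-12) {
    sqrt(rowSums(sweep(pts, 2, a)^2))
  } else {
    abs((pts[, 1] - a[1]) * ab[2] - (pts[, 2] - a[2]) * ab[1]) / len
  }
  k <- which.max(d)
  if (d[k] <= tol) return(pts[c(1L, n), , drop = FALSE])
  left <- dp_open(pts[1:k, , drop = FALSE], tol)
  right <- dp_open(pts[k:n, , drop = FALSE], tol)
  rbind(left[-nrow(left), , drop = FALSE], right)
}

# Simplify a closed ring with geometrically increasing tolerance until it
# has at most max_v vertices; falls back to regular vertex subsampling.
simplify_ring <- function(p, max_v = BOUNDARY_VERTICES,
                          tol0 = 0.1, max_attempts = 20L) {
  if (nrow(p) <= max_v) return(p)
  far <- which.max(rowSums(sweep(p, 2, p[1, ])^2))
  tol <- tol0
  for (a in seq_len(max_attempts)) {
    c1 <- dp_open(p[1:far, , drop = FALSE], tol)
    c2 <- dp_open(p[c(far:nrow(p), 1L), , drop = FALSE], tol)
    q <- rbind(c1[-nrow(c1), , drop = FALSE], c2[-nrow(c2), , drop = FALSE])
    if (nrow(q) <= max_v && nrow(q) >= 3L) return(q)
    tol <- tol * 2
  }
  warning("polygon simplification fell back to vertex subsampling")
  idx <- unique(round(seq(1, nrow(p), length.out = max_v)))
  p[idx, , drop = FALSE]
}

#' Export cell boundaries as a fixed-width vertex array
#'
#' Polygons with more than 13 vertices are simplified (tolerance sweep
#' starting at 0.1 um, doubling, at most 20 attempts); all polygons are
#' then padded by repeating their final vertex to exactly 13 vertices and
#' stored as an N x 13 x 2 array (no closing duplicate; the ring is
#' implicitly closed).
#'
#' @param cells A resolved [cell_collection].
#' @param bundle_dir Bundle directory.
#' @return Invisibly, the N x 13 x 2 boundary array.
#' @export
export_boundaries <- function(cells, bundle_dir) {
  dir <- file.path(bundle_dir, "cells")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(cells)
  arr <- array(0, c(n, BOUNDARY_VERTICES, 2))
  for (i in seq_len(n)) {
    q <- simplify_ring(cells$polygons[[i]])
    pad <- BOUNDARY_VERTICES - nrow(q)
    if (pad > 0) {
      q <- rbind(q, q[rep(nrow(q), pad), , drop = FALSE])
    }
    arr[i, , ] <- q
  }
  write_bin(aperm(arr, c(3, 2, 1)), file.path(dir, "boundaries.bin"), "double")
  write_json_meta(list(n = n, vertices = BOUNDARY_VERTICES,
                       cell_ids = cells$id,
                       order = "xy-per-vertex, vertex-major, cell-outer"),
                  file.path(dir, "meta.json"))
  invisible(arr)
}

#' @rdname export_boundaries
#' @export
read_boundaries <- function(bundle_dir) {
  dir <- file.path(bundle_dir, "cells")
  meta <- read_json_meta(file.path(dir, "meta.json"))
  v <- read_bin(file.path(dir, "boundaries.bin"),
                meta$n * meta$vertices * 2, "double")
  arr <- aperm(array(v, c(2, meta$vertices, meta$n)), c(3, 2, 1))
  attr(arr, "cell_ids") <- meta$cell_ids
  arr
}

#' Export the counts table and per-cell categories in sparse layout
#'
#' Counts are stored gene-major: `data` holds all non-zero counts,
#' `cell_index` the (0-based) cell of each count, and `gene_pointer`
#' (length G + 1) delimits each gene's slice, with cell indices ascending
#' within a gene. Each category field is stored as sorted unique `values`
#' plus cell `indices` grouped by label and `pointers` delimiting groups.
#'
#' @param counts N x G counts matrix (dense or sparse) with dimnames.
#' @param categories Named list of per-cell label vectors (each length N,
#'   no missing values).
#' @param bundle_dir Bundle directory.
#' @export
export_tables <- function(counts, categories = list(), bundle_dir) {
  dir <- file.path(bundle_dir, "tables")
  dir.create(file.path(dir, "counts"), recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  write_bin(m@x, file.path(dir, "counts", "data.bin"), "double")
  write_bin(m@i, file.path(dir, "counts", "cell_index.bin"), "integer")
  write_bin(m@p, file.path(dir, "counts", "gene_pointer.bin"), "integer")
  write_json_meta(list(n_cells = nrow(m), n_genes = ncol(m), nnz = length(m@x),
                       cells = rownames(m), genes = colnames(m)),
                  file.path(dir, "counts", "meta.json"))
  for (field in names(categories)) {
    lab <- as.character(categories[[field]])
    if (length(lab) != nrow(m) || anyNA(lab)) {
      stop_validation("category '", field, "' must label every cell")
    }
    fdir <- file.path(dir, "categories", field)
    dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
    values <- sort(unique(lab))
    ord <- order(match(lab, values), seq_along(lab))
    pointers <- c(0L, cumsum(tabulate(match(lab, values), length(values))))
    write_bin(ord - 1L, file.path(fdir, "indices.bin"), "integer")
    write_bin(pointers, file.path(fdir, "pointers.bin"), "integer")
    write_json_meta(list(field = field, values = values, n = length(lab)),
                    file.path(fdir, "meta.json"))
  }
  invisible(dir)
}

#' @rdname export_tables
#' @export
read_tables <- function(bundle_dir) {
  dir <- file.path(bundle_dir, "tables")
  meta <- read_json_meta(file.path(dir, "counts", "meta.json"))
  x <- read_bin(file.path(dir, "counts", "data.bin"), meta$nnz, "double")
  i <- read_bin(file.path(dir, "counts", "cell_index.bin"), meta$nnz, "integer")
  p <- read_bin(file.path(dir, "counts", "gene_pointer.bin"),
                meta$n_genes + 1L, "integer")
  counts <- Matrix::sparseMatrix(i = i + 1L, p = p, x = x,
                                 dims = c(meta$n_cells, meta$n_genes),
                                 dimnames = list(meta$cells, meta$genes))
  cat_dir <- file.path(dir, "categories")
  categories <- list()
  if (dir.exists(cat_dir)) {
    for (field in list.dirs(cat_dir, recursive = FALSE, full.names = FALSE)) {
      fmeta <- read_json_meta(file.path(cat_dir, field, "meta.json"))
      idx <- read_bin(file.path(cat_dir, field, "indices.bin"), fmeta$n, "integer")
      ptr <- read_bin(file.path(cat_dir, field, "pointers.bin"),
                      length(fmeta$values) + 1L, "integer")
      lab <- character(fmeta$n)
      for (k in seq_along(fmeta$values)) {
        sel <- if (ptr[k + 1L] > ptr[k]) idx[(ptr[k] + 1L):ptr[k + 1L]] + 1L
               else integer(0)
        lab[sel] <- fmeta$values[k]
      }
      categories[[field]] <- lab
    }
  }
  list(counts = methods::as(counts, "CsparseMatrix"), categories = categories)
}

#' Write a complete visualizer bundle
#'
#' Requires at least an image or a cell set. The transcripts part is
#' omitted for imaging-only datasets; `experiment.json` records presence
#' flags, shapes and the format constants. Re-running on unchanged inputs
#' produces a byte-identical bundle.
#'
#' @param bundle_dir Output directory (created if needed).
#' @param image Optional [raster_image].
#' @param transcripts Optional [transcript_table].
#' @param cells Optional [cell_collection].
#' @param counts Optional counts matrix (needs `cells`).
#' @param categories Optional named list of per-cell label vectors.
#' @param name Experiment name written to the metadata.
#' @return Invisibly, the bundle directory.
#' @export
write_bundle <- function(bundle_dir, image = NULL, transcripts = NULL,
                         cells = NULL, counts = NULL, categories = list(),
                         name = "experiment") {
  if (is.null(image) && is.null(cells)) {
    stop_validation("nothing to write: need at least an image or cells")
  }
  dir.create(bundle_dir, recursive = TRUE, showWarnings = FALSE)
  extent <- if (!is.null(image)) image_extent(image) else {
    bb <- cell_bboxes(cells)
    c(0, 0, max(bb[, 3]), max(bb[, 4]))
  }
  shapes <- list()
  if (!is.null(image)) {
    export_image_pyramid(image, bundle_dir)
    shapes$image <- c(image_dim(image), n_channels(image))
  }
  if (!is.null(transcripts)) {
    export_transcript_pyramid(transcripts, bundle_dir, extent = extent)
    shapes$n_transcripts <- nrow(transcripts)
  }
  if (!is.null(cells)) {
    export_boundaries(cells, bundle_dir)
    shapes$n_cells <- length(cells)
  }
  if (!is.null(counts)) {
    export_tables(counts, categories, bundle_dir)
    shapes$counts <- dim(counts)
  }
  write_json_meta(
    list(schema_version = "1.0", name = name,
         pixel_size = if (!is.null(image)) image$pixel_size else NULL,
         extent = extent,
         parts = list(image = !is.null(image),
                      transcripts = !is.null(transcripts),
                      cells = !is.null(cells),
                      tables = !is.null(counts)),
         shapes = shapes,
         constants = list(tile_px = TILE_PX,
                          transcript_tile_um = TRANSCRIPT_TILE_UM,
                          boundary_vertices = BOUNDARY_VERTICES)),
    file.path(bundle_dir, "experiment.json")
  )
  invisible(bundle_dir)
}

#' @rdname write_bundle
#' @export
read_bundle_meta <- function(bundle_dir) {
  read_json_meta(file.path(bundle_dir, "experiment.json"))
}
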