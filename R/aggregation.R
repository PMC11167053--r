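# Per-cell aggregation: channel intensity means by chunk-local bounding-box
# rasterization, and transcript counting by a partitioned point-in-polygon
# join. Both are exactly equivalent to their naive whole-image / whole-table
# counterparts; chunking and partitioning only bound the working set.

#' Average each image channel inside each cell
#'
#' For every image chunk: find the cells whose bounding boxes intersect the
#' chunk, read only the bounding-box-within-chunk sub-array for each such
#' cell, rasterize the polygon over those pixel centers (half-open
#' membership rule) and accumulate per-cell, per-channel sums and pixel
#' counts. Chunks partition the pixel grid, so cells spanning several
#' chunks accumulate each pixel exactly once; the final mean is the global
#' sum divided by the global count.
#'
#' @param image A [raster_image].
#' @param cells A [cell_collection]; cells partially outside the image are
#'   clipped to the extent.
#' @return An N x P matrix of mean intensities (rows: cell ids, columns:
#'   channel names). Cells covering no pixel center get mean 0, with a
#'   warning.
#' @export
average_channels <- function(image, cells) {
  n <- length(cells)
  P <- n_channels(image)
  sums <- matrix(0, n, P)
  npx <- numeric(n)
  if (n > 0) {
    ps <- image$pixel_size
    bb <- cell_bboxes(cells)
    for (win in chunk_windows(image)) {
      r0 <- win$rows[1] - 1L; r1 <- win$rows[length(win$rows)] - 1L  # 0-based
      c0 <- win$cols[1] - 1L; c1 <- win$cols[length(win$cols)] - 1L
      wx <- c(c0, c1) * ps; wy <- c(r0, r1) * ps
      hit <- which(bb[, 1] <= wx[2] + ps & bb[, 3] >= wx[1] - ps &
                   bb[, 2] <= wy[2] + ps & bb[, 4] >= wy[1] - ps)
      for (i in hit) {
        rows <- max(r0, floor(bb[i, 2] / ps)):min(r1, ceiling(bb[i, 4] / ps))
        cols <- max(c0, floor(bb[i, 1] / ps)):min(c1, ceiling(bb[i, 3] / ps))
        if (rows[1] > rows[length(rows)] || cols[1] > cols[length(cols)]) next
        cover <- rasterize_polygon(cells$polygons[[i]], rows, cols, ps)
        if (!any(cover)) next
        sub <- read_block(image, rows + 1L, cols + 1L)
        for (ch in seq_len(P)) {
          sums[i, ch] <- sums[i, ch] + sum(sub[, , ch][cover])
        }
        npx[i] <- npx[i] + sum(cover)
      }
    }
  }
  zero <- npx == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) cover no pixel center; their means are 0")
    npx[zero] <- 1
  }
  out <- sums / npx
  dimnames(out) <- list(as.character(cells$id), image$channel_names)
  out
}

#' Count transcripts inside each cell
#'
#' Transcripts are split into square spatial partitions; each partition is
#' joined point-in-polygon against only the cells whose bounding boxes
#' intersect it. A point on a shared boundary covered by several cells is
#' assigned to the cell with the smallest id; points in no cell stay
#' unassigned. The result is independent of the partition size.
#'
#' @param t A [transcript_table].
#' @param cells A resolved (non-redundant) [cell_collection].
#' @param partition_size Partition square width in micrometers (default 100).
#' @return A sparse N x G integer matrix (`Matrix::dgCMatrix`; rows: cell
#'   ids, columns: gene levels) with an `unassigned` attribute counting
#'   points inside no cell.
#' @export
count_transcripts <- function(t, cells, partition_size = 100) {
  stopifnot(inherits(t, "transcript_table"))
  if (anyNA(t$gene)) stop_validation("transcripts with unknown gene labels")
  n <- length(cells)
  genes <- levels(t$gene)
  npts <- nrow(t)
  assigned_cell <- rep(NA_integer_, npts)  # row index into cells
  if (npts > 0 && n > 0) {
    bb <- cell_bboxes(cells)
    x0 <- min(t$x); y0 <- min(t$y)
    px <- pmin(floor((t$x - x0) / partition_size),
               ceiling((max(t$x) - x0) / partition_size))
    py <- pmin(floor((t$y - y0) / partition_size),
               ceiling((max(t$y) - y0) / partition_size))
    buckets <- split(seq_len(npts), paste(px, py))
    ord <- order(cells$id)   # evaluate in ascending id order: first hit wins
    for (b in buckets) {
      bx <- range(t$x[b]); by <- range(t$y[b])
      hit <- ord[bb[ord, 1] <= bx[2] & bb[ord, 3] >= bx[1] &
                 bb[ord, 2] <= by[2] & bb[ord, 4] >= by[1]]
      left <- b
      for (i in hit) {
        if (length(left) == 0L) break
        inside <- points_in_poly(t$x[left], t$y[left], cells$polygons[[i]])
        assigned_cell[left[inside]] <- i
        left <- left[!inside]
      }
    }
  }
  ok <- !is.na(assigned_cell)
  counts <- Matrix::sparseMatrix(
    i = assigned_cell[ok],
    j = as.integer(t$gene)[ok],
    x = 1,
    dims = c(n, length(genes)),
    dimnames = list(as.character(cells$id), genes)
  )
  counts <- methods::as(counts, "CsparseMatrix")
  attr(counts, "unassigned") <- sum(!ok)
  counts
}
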