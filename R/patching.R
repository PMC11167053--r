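# Overlapping patch grids over a slide extent, and transcript partitioning.
#
# Segmentation runs per patch; the overlap is chosen at least twice the
# average cell diameter so every cell is complete in at least one patch.
# Patch rectangles are closed on their min edges and open on their max
# edges, except the last patch per axis which is closed, giving exact
# coverage with deterministic multiple assignment inside overlaps.

#' Build an overlapping patch grid
#'
#' Per axis, patch k starts at `k * (patch_width - overlap)`; the number of
#' patches is `ceil((L - patch_width) / (patch_width - overlap)) + 1` (one
#' patch when the extent fits inside a single patch) and the last patch is
#' clamped to end at the extent boundary.
#'
#' @param extent `c(xmin, ymin, xmax, ymax)` in micrometers, or a
#'   [raster_image] (its extent is used).
#' @param patch_width Patch width in micrometers (default 200).
#' @param overlap Overlap between adjacent patches in micrometers
#'   (default 40, twice a typical 20 um cell diameter); must satisfy
#'   `0 <= overlap < patch_width`.
#' @return A data frame of class `patch_grid` with columns
#'   `patch, xmin, ymin, xmax, ymax, last_x, last_y`.
#' @export
make_patches <- function(extent, patch_width = 200, overlap = 40) {
  if (inherits(extent, "raster_image")) extent <- image_extent(extent)
  extent <- as.numeric(extent)
  if (length(extent) != 4L || extent[3] <= extent[1] || extent[4] <= extent[2]) {
    stop_validation("extent must be a non-degenerate c(xmin, ymin, xmax, ymax)")
  }
  if (!is_scalar_number(patch_width) || !is_scalar_number(overlap) ||
      overlap < 0 || overlap >= patch_width) {
    stop_validation("need 0 <= overlap < patch_width")
  }
  axis_spans <- function(lo, hi) {
    L <- hi - lo
    if (L <= patch_width) {
      return(data.frame(min = lo, max = hi, last = TRUE))
    }
    step <- patch_width - overlap
    n <- ceiling((L - patch_width) / step) + 1
    starts <- lo + (seq_len(n) - 1) * step
    ends <- pmin(starts + patch_width, hi)
    data.frame(min = starts, max = ends, last = seq_len(n) == n)
  }
  xs <- axis_spans(extent[1], extent[3])
  ys <- axis_spans(extent[2], extent[4])
  grid <- expand.grid(ix = seq_len(nrow(xs)), iy = seq_len(nrow(ys)))
  out <- data.frame(
    patch = seq_len(nrow(grid)),
    xmin = xs$min[grid$ix], ymin = ys$min[grid$iy],
    xmax = xs$max[grid$ix], ymax = ys$max[grid$iy],
    last_x = xs$last[grid$ix], last_y = ys$last[grid$iy]
  )
  attr(out, "patch_width") <- patch_width
  attr(out, "overlap") <- overlap
  attr(out, "extent") <- extent
  class(out) <- c("patch_grid", "data.frame")
  out
}

# Membership of points in one patch rectangle, honoring the half-open
# convention (min edges closed, max edges open unless last patch per axis).
patch_contains <- function(grid, k, x, y) {
  p <- grid[k, ]
  in_x <- x >= p$xmin & (if (p$last_x) x <= p$xmax else x < p$xmax)
  in_y <- y >= p$ymin & (if (p$last_y) y <= p$ymax else y < p$ymax)
  in_x & in_y
}

#' Assign transcripts to patches
#'
#' A transcript appears in every patch whose rectangle contains it, so
#' points in overlap zones are assigned to multiple patches; the union of
#' the per-patch lists covers all transcripts.
#'
#' @param t A [transcript_table].
#' @param grid A [make_patches()] grid.
#' @return A list (one element per patch) of integer row indices into `t`.
#' @export
assign_transcripts <- function(t, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  lapply(seq_len(nrow(grid)), function(k) {
    if (nrow(t) == 0L) return(integer(0))
    which(patch_contains(grid, k, t$x, t$y))
  })
}

#' Write a patch grid as GeoJSON rectangles (for inspection)
#' @param grid A [patch_grid][make_patches()].
#' @param path Output path.
#' @export
write_patches <- function(grid, path) {
  polys <- lapply(seq_len(nrow(grid)), function(k) {
    p <- grid[k, ]
    cbind(c(p$xmin, p$xmax, p$xmax, p$xmin),
          c(p$ymin, p$ymin, p$ymax, p$ymax))
  })
  write_cells(cell_collection(polys, ids = grid$patch), path)
}
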