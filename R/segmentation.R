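# Per-patch segmentation: a pluggable contract, a built-in intensity
# segmenter (Gaussian smooth -> threshold -> 4-connected components ->
# optional distance-transform watershed), and exact conversion of label
# masks to polygons traced along outer pixel edges, so a label's polygon
# area equals its pixel count times pixel_size^2 (holes filled).

#' Built-in intensity-based patch segmenter
#'
#' A deterministic, dependency-light stand-in for external segmentation
#' models, sufficient to exercise the patch/resolve machinery: Gaussian
#' smoothing, global thresholding (fixed value or Otsu), 4-connected
#' component labelling, an optional distance-transform watershed to split
#' touching blobs, and a minimum-area filter.
#'
#' @param window An H x W x C array (or H x W matrix) of patch intensities.
#' @param params List: `channel` (index into the window's third dimension),
#'   `sigma` (smoothing, px; 0 disables), `threshold` (numeric in intensity
#'   units, or `"otsu"`), `min_area_px`, `split_touching` (logical).
#' @param transcripts Ignored (present to satisfy the segmenter contract).
#' @return An integer label mask (H x W matrix; 0 = background).
#' @export
builtin_segment_patch <- function(window,
                                  params = list(),
                                  transcripts = NULL) {
  p <- utils::modifyList(
    list(channel = 1L, sigma = 1, threshold = "otsu",
         min_area_px = 20L, split_touching = FALSE),
    params
  )
  if (is.matrix(window)) window <- array(window, dim = c(dim(window), 1L))
  if (p$channel < 1L || p$channel > dim(window)[3]) {
    stop_validation("segmentation channel ", p$channel, " out of range")
  }
  m <- window[, , p$channel]
  if (!is.matrix(m)) m <- matrix(m, dim(window)[1], dim(window)[2])
  if (p$sigma > 0 && min(dim(m)) > 4) {
    m <- as.matrix(EBImage::gblur(m, sigma = p$sigma))
  }
  rng <- range(m)
  if (identical(p$threshold, "otsu")) {
    if (rng[1] == rng[2]) return(matrix(0L, nrow(m), ncol(m)))
    scaled <- (m - rng[1]) / (rng[2] - rng[1])
    thr <- rng[1] + EBImage::otsu(EBImage::Image(scaled)) * (rng[2] - rng[1])
  } else {
    thr <- p$threshold
  }
  bin <- m > thr
  if (!any(bin)) return(matrix(0L, nrow(m), ncol(m)))
  lab <- if (isTRUE(p$split_touching)) {
    EBImage::watershed(EBImage::distmap(bin))
  } else {
    EBImage::bwlabel(bin)
  }
  lab <- matrix(as.integer(as.matrix(lab)), nrow(m), ncol(m))
  keep <- which(tabulate(lab) >= p$min_area_px)
  relab <- integer(max(lab, 1L))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

# Trace the boundary of a set of 0-based pixels (2-col matrix r, c) along
# pixel edges. Returns a list of rings in pixel-corner coordinates (x = col
# corner, y = row corner). Directed edges keep the interior on the
# consistent side; ambiguous (checkerboard) corners are resolved by
# preferring the sharpest right turn, deterministically.
trace_pixel_boundary <- function(rc) {
  r <- rc[, 1]; c <- rc[, 2]
  r0 <- min(r); c0 <- min(c)
  h <- max(r) - r0 + 1L; w <- max(c) - c0 + 1L
  M <- matrix(FALSE, h + 2L, w + 2L)        # 1-pixel pad
  M[cbind(r - r0 + 2L, c - c0 + 2L)] <- TRUE
  i <- r - r0 + 2L; j <- c - c0 + 2L

  top    <- !M[cbind(i - 1L, j)]
  right  <- !M[cbind(i, j + 1L)]
  bottom <- !M[cbind(i + 1L, j)]
  left   <- !M[cbind(i, j - 1L)]

  # edges as (from_x, from_y, to_x, to_y, dir); dirs 0=R,1=D,2=L,3=U
  ex <- c(c[top],     c[right] + 1L, c[bottom] + 1L, c[left])
  ey <- c(r[top],     r[right],      r[bottom] + 1L, r[left] + 1L)
  tx <- c(c[top] + 1L, c[right] + 1L, c[bottom],     c[left])
  ty <- c(r[top],      r[right] + 1L, r[bottom] + 1L, r[left])
  dir <- rep.int(c(0L, 1L, 2L, 3L), c(sum(top), sum(right), sum(bottom), sum(left)))

  n <- length(ex)
  key <- function(x, y) x * (max(r) + 3) + y
  from_key <- key(ex, ey)
  lookup <- split(seq_len(n), from_key)
  used <- logical(n)
  rings <- list()

  for (start in seq_len(n)) {
    if (used[start]) next
    e <- start
    ring_x <- ex[e]; ring_y <- ey[e]
    repeat {
      used[e] <- TRUE
      vx <- tx[e]; vy <- ty[e]
      if (vx == ring_x[1] && vy == ring_y[1]) break
      ring_x <- c(ring_x, vx); ring_y <- c(ring_y, vy)
      cand <- lookup[[as.character(key(vx, vy))]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break  # should not happen on valid masks
      if (length(cand) > 1L) {
        pref <- match(dir[cand], c((dir[e] + 1L) %% 4L, dir[e], (dir[e] + 3L) %% 4L))
        cand <- cand[order(pref)]
      }
      e <- cand[1]
    }
    # merge collinear runs
    m <- cbind(ring_x, ring_y)
    if (nrow(m) > 2) {
      keep <- rep(TRUE, nrow(m))
      for (v in seq_len(nrow(m))) {
        prev <- if (v == 1) nrow(m) else v - 1L
        nxt <- if (v == nrow(m)) 1L else v + 1L
        keep[v] <- !((m[v, 1] - m[prev, 1]) * (m[nxt, 2] - m[v, 2]) ==
                     (m[v, 2] - m[prev, 2]) * (m[nxt, 1] - m[v, 1]))
      }
      m <- m[keep, , drop = FALSE]
    }
    rings[[length(rings) + 1L]] <- m
  }
  rings
}

#' Convert a label mask to a polygonal cell collection
#'
#' One polygon per positive label, traced exactly along outer pixel edges
#' (holes are filled: segmented cells are modelled as simple polygons),
#' then placed in world micrometers.
#'
#' @param mask Integer H x W matrix; 0 = background.
#' @param window_origin World coordinates (um) of the center of the mask's
#'   top-left pixel.
#' @param pixel_size Micrometers per pixel.
#' @return A [cell_collection] with ids equal to the mask label values.
#' @export
mask_to_polygons <- function(mask, window_origin = c(0, 0), pixel_size = 1) {
  labels <- sort(unique(mask[mask > 0L]))
  if (length(labels) == 0L) {
    return(structure(list(polygons = list(), id = integer(0),
                          provenance = list()),
                     class = "cell_collection"))
  }
  polys <- lapply(labels, function(k) {
    rc <- which(mask == k, arr.ind = TRUE) - 1L   # 0-based (r, c)
    rings <- trace_pixel_boundary(rc)
    areas <- vapply(rings, poly_area, numeric(1))
    ring <- rings[[which.max(areas)]]             # outer ring; holes filled
    cbind(window_origin[1] + (ring[, 1] - 0.5) * pixel_size,
          window_origin[2] + (ring[, 2] - 0.5) * pixel_size)
  })
  cell_collection(polys, ids = labels)
}

#' Run a segmenter over every patch of a grid
#'
#' Patch results are independent of processing order. Each patch is cut as
#' the pixel window whose centers fall inside the patch rectangle; the
#' segmenter receives that window (plus the transcripts falling in the
#' patch, if provided) and must return either an integer label mask in
#' window coordinates or a [cell_collection] already in world micrometers.
#'
#' @param image A [raster_image].
#' @param grid A [make_patches()] grid covering the image extent.
#' @param segmenter A function `(window, params, transcripts)`; defaults to
#'   [builtin_segment_patch()].
#' @param params Parameter list forwarded to the segmenter. A character
#'   `channel` is translated to its index in `image$channel_names`.
#' @param transcripts Optional [transcript_table]; each patch's subset is
#'   forwarded to the segmenter.
#' @param patches Patch indices to process (default: all), enabling
#'   per-patch job arrays.
#' @return A list of [cell_collection]s, one per processed patch, each cell
#'   tagged with its patch index in `provenance`.
#' @export
run_segmentation <- function(image, grid, segmenter = builtin_segment_patch,
                             params = list(), transcripts = NULL,
                             patches = seq_len(nrow(grid))) {
  stopifnot(inherits(image, "raster_image"), inherits(grid, "patch_grid"))
  if (is.character(params$channel)) {
    idx <- match(params$channel, image$channel_names)
    if (is.na(idx)) stop_validation("unknown channel '", params$channel, "'")
    params$channel <- idx
  }
  d <- image_dim(image)
  ps <- image$pixel_size
  lapply(patches, function(k) {
    g <- grid[k, ]
    rows <- max(0, ceiling(g$ymin / ps - 1e-9)):min(d[1] - 1, floor(g$ymax / ps + 1e-9))
    cols <- max(0, ceiling(g$xmin / ps - 1e-9)):min(d[2] - 1, floor(g$xmax / ps + 1e-9))
    win <- read_block(image, rows + 1L, cols + 1L)
    tsub <- if (!is.null(transcripts)) {
      transcripts[patch_contains(grid, k, transcripts$x, transcripts$y), , drop = FALSE]
    }
    res <- tryCatch(
      segmenter(win, params, tsub),
      error = function(e) {
        stop("segmentation failed on patch ", k, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    cells <- if (inherits(res, "cell_collection")) {
      res
    } else if (is.matrix(res)) {
      mask_to_polygons(res, window_origin = c(cols[1] * ps, rows[1] * ps),
                       pixel_size = ps)
    } else {
      stop("segmenter for patch ", k,
           " returned neither a label mask nor a cell_collection", call. = FALSE)
    }
    cells$provenance <- rep(list(k), length(cells))
    cells
  })
}
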