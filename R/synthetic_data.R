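# Deterministic synthetic tissue generator.
#
# Emulates an image-based spatial omics acquisition at desk scale: disc-like
# cells (regular 24-gons, so area and perimeter have closed forms) placed by
# rejection sampling with a minimum spacing, a nuclear channel bright in
# every cell plus one marker channel per cell type, per-cell transcripts
# drawn Poisson(lambda) uniformly inside the cell polygon, and uniform
# background transcripts. Niches are assigned by a known spatial partition
# so niche adjacency is available as ground truth.

#' Generate a synthetic tissue
#'
#' @param n_cells Number of cells to place (>= 0).
#' @param cell_radius Cell circumradius in micrometers.
#' @param image_size Image size in pixels, `c(rows, cols)`.
#' @param pixel_size Micrometers per pixel.
#' @param cell_types Character vector of type labels.
#' @param marker_channels One marker channel name per type.
#' @param marker_intensity In-cell intensity of a cell's own marker channel.
#' @param off_marker_intensity In-cell intensity of other types' markers.
#' @param nuclear_intensity In-cell intensity of the nuclear channel
#'   (bright for every cell; the built-in segmenter runs on it).
#' @param background_level,noise_sd Background intensity and Gaussian noise
#'   standard deviation (intensities are clamped to [0, 1]).
#' @param min_spacing Minimum center-to-center distance between cells
#'   (default 2.8 x radius, i.e. a clear gap between boundaries).
#' @param niche_layout `"halves"` (left/right split at the extent midline),
#'   `"quadrants"`, or `"none"` (single niche).
#' @param transcripts_per_cell Poisson mean of per-cell transcript counts.
#' @param signature_prob Probability that a cell transcript carries its
#'   type's signature gene (otherwise a uniformly random gene).
#' @param background_rate Background transcripts per square micrometer.
#' @param chunk Chunk sizes of the generated image.
#' @param seed Master seed; all randomness fans out from it through fixed
#'   per-component substreams.
#' @param max_tries Placement attempts per cell before giving up.
#' @return A list of class `synthetic_tissue` with elements `image`
#'   ([raster_image]), `transcripts` ([transcript_table]) and `truth`
#'   (cells, cell_type, niche, transcript_cell with NA for background,
#'   type_profiles).
#' @export
generate_tissue <- function(n_cells = 120,
                            cell_radius = 5,
                            image_size = c(512L, 512L),
                            pixel_size = 0.5,
                            cell_types = c("T_cell", "B_cell", "tumour"),
                            marker_channels = c("CD3", "CD20", "PanCK"),
                            marker_intensity = 0.85,
                            off_marker_intensity = 0.05,
                            nuclear_intensity = 0.9,
                            background_level = 0.02,
                            noise_sd = 0.01,
                            min_spacing = 2.8 * cell_radius,
                            niche_layout = c("halves", "quadrants", "none"),
                            transcripts_per_cell = 30,
                            signature_prob = 0.9,
                            background_rate = 2e-4,
                            chunk = c(128L, 128L),
                            seed,
                            max_tries = 200L) {
  if (missing(seed)) stop_validation("a seed is required for reproducibility")
  niche_layout <- match.arg(niche_layout)
  if (n_cells < 0 || cell_radius <= 0 || pixel_size <= 0 ||
      transcripts_per_cell < 0 || background_rate < 0) {
    stop_validation("generator parameters must be positive")
  }
  if (length(cell_types) != length(marker_channels)) {
    stop_validation("one marker channel per cell type is required")
  }
  seeds <- derive_seeds(seed, 4L)

  H <- as.integer(image_size[1]); W <- as.integer(image_size[2])
  ext <- c(0, 0, W * pixel_size, H * pixel_size)
  margin <- cell_radius + 2 * pixel_size

  ## -- cell placement (substream 1)
  set.seed(seeds[1])
  centers <- matrix(numeric(0), 0, 2)
  if (n_cells > 0) {
    if (ext[3] - 2 * margin <= 0 || ext[4] - 2 * margin <= 0) {
      stop_validation("image too small for the requested cell radius")
    }
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- c(stats::runif(1, margin, ext[3] - margin),
                  stats::runif(1, margin, ext[4] - margin))
        if (nrow(centers) == 0 ||
            min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= min_spacing) {
          centers <- rbind(centers, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop_validation("could not place ", n_cells, " cells of radius ",
                        cell_radius, " in the extent; packing infeasible")
      }
    }
  }
  ngon <- 24L
  theta <- 2 * pi * (seq_len(ngon) - 1) / ngon
  polys <- lapply(seq_len(nrow(centers)), function(i) {
    cbind(centers[i, 1] + cell_radius * cos(theta),
          centers[i, 2] + cell_radius * sin(theta))
  })
  cells <- if (length(polys)) cell_collection(polys) else
    structure(list(polygons = list(), id = integer(0), provenance = list()),
              class = "cell_collection")

  ## -- type / niche assignment (substream 2)
  set.seed(seeds[2])
  type_idx <- if (n_cells > 0) sample.int(length(cell_types), n_cells, replace = TRUE)
              else integer(0)
  cell_type <- cell_types[type_idx]
  niche <- character(n_cells)
  if (n_cells > 0) {
    niche <- switch(
      niche_layout,
      none = rep("niche_A", n_cells),
      halves = ifelse(centers[, 1] < ext[3] / 2, "niche_A", "niche_B"),
      quadrants = paste0("niche_", c("A", "B", "C", "D")[
        1L + (centers[, 1] >= ext[3] / 2) + 2L * (centers[, 2] >= ext[4] / 2)])
    )
  }

  ## -- image rendering (substream 3)
  set.seed(seeds[3])
  channels <- c("nuclear", marker_channels)
  P <- length(channels)
  profiles <- matrix(off_marker_intensity, length(cell_types), P,
                     dimnames = list(cell_types, channels))
  profiles[, "nuclear"] <- nuclear_intensity
  for (k in seq_along(cell_types)) profiles[k, marker_channels[k]] <- marker_intensity
  data <- array(background_level, dim = c(H, W, P))
  for (i in seq_len(n_cells)) {
    bb <- poly_bbox(cells$polygons[[i]])
    rows <- max(0L, floor(bb[2] / pixel_size)):min(H - 1L, ceiling(bb[4] / pixel_size))
    cols <- max(0L, floor(bb[1] / pixel_size)):min(W - 1L, ceiling(bb[3] / pixel_size))
    cover <- rasterize_polygon(cells$polygons[[i]], rows, cols, pixel_size)
    idx <- which(cover, arr.ind = TRUE)
    for (ch in seq_len(P)) {
      data[cbind(rows[idx[, 1]] + 1L, cols[idx[, 2]] + 1L, ch)] <-
        profiles[type_idx[i], ch]
    }
  }
  if (noise_sd > 0) {
    data <- data + array(stats::rnorm(length(data), 0, noise_sd), dim = dim(data))
  }
  data[data < 0] <- 0
  data[data > 1] <- 1
  img <- raster_image(data, channel_names = channels, pixel_size = pixel_size,
                      chunk = chunk)

  ## -- transcripts (substream 4)
  set.seed(seeds[4])
  genes <- c(paste0(cell_types, "_sig"), "noise_gene")
  tx <- ty <- numeric(0)
  tg <- character(0)
  tcell <- integer(0)
  for (i in seq_len(n_cells)) {
    n_i <- stats::rpois(1, transcripts_per_cell)
    if (n_i == 0) next
    pts <- sample_in_polygon(cells$polygons[[i]], n_i)
    g <- ifelse(stats::runif(n_i) < signature_prob,
                genes[type_idx[i]],
                genes[sample.int(length(genes), n_i, replace = TRUE)])
    tx <- c(tx, pts[, 1]); ty <- c(ty, pts[, 2])
    tg <- c(tg, g); tcell <- c(tcell, rep.int(cells$id[i], n_i))
  }
  n_bg <- stats::rpois(1, background_rate * (ext[3] * ext[4]))
  if (n_bg > 0) {
    tx <- c(tx, stats::runif(n_bg, 0, ext[3]))
    ty <- c(ty, stats::runif(n_bg, 0, ext[4]))
    tg <- c(tg, genes[sample.int(length(genes), n_bg, replace = TRUE)])
    tcell <- c(tcell, rep.int(NA_integer_, n_bg))
  }
  transcripts <- transcript_table(tx, ty, factor(tg, levels = genes))

  structure(
    list(image = img,
         transcripts = transcripts,
         truth = list(cells = cells, cell_type = cell_type, niche = niche,
                      transcript_cell = tcell, type_profiles = profiles,
                      genes = genes, extent = ext)),
    class = "synthetic_tissue"
  )
}

# Uniform points strictly inside a polygon by rejection from its bounding box.
sample_in_polygon <- function(p, n) {
  bb <- poly_bbox(p)
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- 2L * (n - nrow(out)) + 8L
    cand <- cbind(stats::runif(m, bb[1], bb[3]), stats::runif(m, bb[2], bb[4]))
    keep <- sp::point.in.polygon(cand[, 1], cand[, 2], p[, 1], p[, 2]) == 1
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf("<synthetic_tissue> %d cell(s), %d transcript(s)\n",
              length(x$truth$cells), nrow(x$transcripts)))
  print(x$image)
  invisible(x)
}
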