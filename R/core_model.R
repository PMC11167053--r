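# Shared data model: multi-channel raster images, transcript point tables
# and polygonal cell collections, plus readers/writers for the standard
# on-disk formats (TIFF, CSV, GeoJSON, MatrixMarket).
#
# Coordinate conventions:
#  * world frame in micrometers, origin at the image top-left,
#    x rightward (columns), y downward (rows);
#  * pixel (r, c), 0-based, has world center (c * pixel_size, r * pixel_size);
#  * polygons and transcripts always live in world micrometers.

#' Multi-channel raster image
#'
#' A dense intensity array with channel names, a micrometer pixel scale and a
#' declared chunk grid. All block access goes through [read_block()], which
#' also counts the pixels read so that streaming contracts (e.g. tile export)
#' can be verified.
#'
#' @param data A numeric H x W x C array (or H x W matrix for one channel).
#' @param channel_names Character vector of length C.
#' @param pixel_size Micrometers per pixel; finite scalar > 0.
#' @param chunk Chunk (block) sizes, `c(rows, cols)`; both >= 1.
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(data, channel_names = NULL, pixel_size,
                         chunk = c(256L, 256L)) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_validation("image data must be an H x W x C array")
  }
  d <- dim(data)
  if (any(d < 1L)) stop_validation("all image dimensions must be >= 1")
  if (is.null(channel_names)) channel_names <- paste0("channel_", seq_len(d[3]))
  if (length(channel_names) != d[3]) {
    stop_validation("length(channel_names) must equal the number of channels (",
                    d[3], "), got ", length(channel_names))
  }
  if (!is_scalar_number(pixel_size) || pixel_size <= 0) {
    stop_validation("pixel_size must be a finite scalar > 0")
  }
  chunk <- as.integer(chunk)
  if (length(chunk) != 2L || any(chunk < 1L)) {
    stop_validation("chunk sizes must be two integers >= 1")
  }
  structure(
    list(data = data, channel_names = channel_names,
         pixel_size = pixel_size, chunk = chunk,
         .stats = new.env(parent = emptyenv())),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<raster_image> %d x %d px, %d channel(s) [%s], %.3g um/px, chunks %d x %d\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", "),
              x$pixel_size, x$chunk[1], x$chunk[2]))
  invisible(x)
}

#' @rdname raster_image
#' @param img A `raster_image`.
#' @export
image_dim <- function(img) dim(img$data)[1:2]

#' @rdname raster_image
#' @export
n_channels <- function(img) dim(img$data)[3]

#' World extent of an image, `c(xmin, ymin, xmax, ymax)` in micrometers
#' @param img A [raster_image].
#' @export
image_extent <- function(img) {
  d <- image_dim(img)
  c(xmin = 0, ymin = 0, xmax = d[2] * img$pixel_size, ymax = d[1] * img$pixel_size)
}

#' Read a block of image data
#'
#' The only sanctioned access path to pixel data; increments the image's
#' read counter by the number of pixels touched.
#'
#' @param img A [raster_image].
#' @param rows,cols 1-based index vectors (contiguous ranges).
#' @return An array length(rows) x length(cols) x C.
#' @export
read_block <- function(img, rows, cols) {
  img$.stats$pixels_read <- (img$.stats$pixels_read %||% 0) +
    length(rows) * length(cols)
  img$data[rows, cols, , drop = FALSE]
}

#' @rdname read_block
#' @export
image_read_stats <- function(img) list(pixels_read = img$.stats$pixels_read %||% 0)

#' @rdname read_block
#' @export
reset_read_stats <- function(img) {
  img$.stats$pixels_read <- 0
  invisible(img)
}

# Iterate over the chunk grid; returns a list of list(rows=, cols=) with
# 1-based contiguous ranges covering the image exactly once.
chunk_windows <- function(img) {
  d <- image_dim(img)
  rs <- split(seq_len(d[1]), ceiling(seq_len(d[1]) / img$chunk[1]))
  cs <- split(seq_len(d[2]), ceiling(seq_len(d[2]) / img$chunk[2]))
  out <- vector("list", length(rs) * length(cs))
  k <- 1L
  for (r in rs) for (cc in cs) {
    out[[k]] <- list(rows = r, cols = cc)
    k <- k + 1L
  }
  out
}

#' World <-> pixel index conversion
#'
#' Pixel (r, c), 0-based, has world center (c * pixel_size, r * pixel_size);
#' the two functions are inverse bijections on pixel centers.
#'
#' @param x,y World coordinates (um).
#' @param r,c 0-based pixel indices.
#' @param pixel_size Micrometers per pixel.
#' @export
world_to_pixel <- function(x, y, pixel_size) {
  cbind(r = as.integer(round(y / pixel_size)),
        c = as.integer(round(x / pixel_size)))
}

#' @rdname world_to_pixel
#' @export
pixel_to_world <- function(r, c, pixel_size) {
  cbind(x = c * pixel_size, y = r * pixel_size)
}

#' Transcript point table
#'
#' @param x,y World coordinates in micrometers (finite).
#' @param gene Gene labels (coerced to factor).
#' @param id Optional stable row ids (default sequential).
#' @return A data frame of class `transcript_table`.
#' @export
transcript_table <- function(x, y, gene, id = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) != length(gene)) {
    stop_validation("x, y and gene must have equal length")
  }
  if (length(x) && (!all(is.finite(x)) || !all(is.finite(y)))) {
    stop_validation("transcript coordinates must be finite")
  }
  if (!is.factor(gene)) gene <- factor(gene)
  if (is.null(id)) id <- seq_along(x)
  out <- data.frame(x = x, y = y, gene = gene, id = as.integer(id))
  class(out) <- c("transcript_table", "data.frame")
  out
}

#' Polygonal cell collection
#'
#' @param polygons List of n x 2 vertex matrices (world um, open rings).
#' @param ids Stable unique integer ids (default sequential).
#' @param provenance List of integer vectors: the patch indices each cell was
#'   observed in (empty for cells of unknown origin).
#' @return An object of class `cell_collection`.
#' @export
cell_collection <- function(polygons, ids = NULL, provenance = NULL) {
  if (!is.list(polygons)) stop_validation("polygons must be a list")
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L) {
      stop_validation("each polygon needs >= 3 vertices and 2 columns")
    }
    storage.mode(p) <- "double"
    dimnames(p) <- NULL
    p
  })
  areas <- vapply(polygons, poly_area, numeric(1))
  if (any(areas <= 0)) stop_validation("every polygon must have area > 0")
  n <- length(polygons)
  if (is.null(ids)) ids <- seq_len(n)
  ids <- as.integer(ids)
  if (length(ids) != n || anyDuplicated(ids)) {
    stop_validation("cell ids must be unique and match the number of polygons")
  }
  if (is.null(provenance)) provenance <- rep(list(integer(0)), n)
  structure(list(polygons = polygons, id = ids,
                 provenance = lapply(provenance, as.integer)),
            class = "cell_collection")
}

#' @export
length.cell_collection <- function(x) length(x$polygons)

#' @export
`[.cell_collection` <- function(x, i) {
  cell_collection(x$polygons[i], ids = x$id[i], provenance = x$provenance[i])
}

#' @export
print.cell_collection <- function(x, ...) {
  cat(sprintf("<cell_collection> %d cell(s)\n", length(x)))
  invisible(x)
}

#' Per-cell geometry summaries
#' @param cells A [cell_collection].
#' @return `cell_areas`/`cell_perimeters`: numeric vectors; `cell_centroids`:
#'   an n x 2 matrix; `cell_bboxes`: an n x 4 matrix (xmin, ymin, xmax, ymax).
#' @export
cell_areas <- function(cells) vapply(cells$polygons, poly_area, numeric(1))

#' @rdname cell_areas
#' @export
cell_perimeters <- function(cells) vapply(cells$polygons, poly_perimeter, numeric(1))

#' @rdname cell_areas
#' @export
cell_centroids <- function(cells) {
  t(vapply(cells$polygons, poly_centroid, numeric(2)))
}

#' @rdname cell_areas
#' @export
cell_bboxes <- function(cells) {
  t(vapply(cells$polygons, poly_bbox, numeric(4)))
}

## ---------------------------------------------------------------- writers

#' Write / read cell boundaries as GeoJSON
#'
#' A FeatureCollection of Polygon features with `cell_id` (and optionally
#' `patches`) properties. The round trip is lossless to within 1e-9 on
#' vertex coordinates.
#'
#' @param cells A [cell_collection].
#' @param path Output file path.
#' @export
write_cells <- function(cells, path) {
  check_writable(path)
  features <- lapply(seq_len(length(cells)), function(i) {
    ring <- rbind(cells$polygons[[i]], cells$polygons[[i]][1, , drop = FALSE])
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = list(cell_id = cells$id[i],
                        patches = as.list(cells$provenance[[i]]))
    )
  })
  doc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- doc$features
  if (length(feats) == 0L) {
    return(structure(list(polygons = list(), id = integer(0),
                          provenance = list()),
                     class = "cell_collection"))
  }
  polys <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    m[-nrow(m), , drop = FALSE]  # drop closing duplicate
  })
  ids <- vapply(feats, function(f) as.integer(f$properties$cell_id), integer(1))
  prov <- lapply(feats, function(f) {
    as.integer(unlist(f$properties$patches %||% list()))
  })
  cell_collection(polys, ids = ids, provenance = prov)
}

#' Write / read a sparse counts matrix as MatrixMarket triplets
#'
#' Writes `<prefix>.mtx` plus `<prefix>.cells.tsv` and `<prefix>.genes.tsv`
#' holding the dimnames; the round trip is exact.
#'
#' @param counts A cells x genes matrix (dense or `Matrix` sparse) with
#'   dimnames.
#' @param prefix Path prefix for the three files.
#' @export
write_counts <- function(counts, prefix) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  check_writable(paste0(prefix, ".mtx"))
  Matrix::writeMM(counts, paste0(prefix, ".mtx"))
  writeLines(rownames(counts) %||% as.character(seq_len(nrow(counts))),
             paste0(prefix, ".cells.tsv"))
  writeLines(colnames(counts) %||% as.character(seq_len(ncol(counts))),
             paste0(prefix, ".genes.tsv"))
  invisible(prefix)
}

#' @rdname write_counts
#' @export
read_counts <- function(prefix) {
  f <- paste0(prefix, ".mtx")
  if (!file.exists(f)) stop_io("no such file: ", f)
  m <- methods::as(Matrix::readMM(f), "CsparseMatrix")
  dimnames(m) <- list(readLines(paste0(prefix, ".cells.tsv")),
                      readLines(paste0(prefix, ".genes.tsv")))
  m
}

#' Write / read a multi-channel image as multi-page TIFF
#'
#' One 32-bit float page per channel, values in [0, 1]. A JSON sidecar
#' (`<path>.meta.json`) records pixel size and channel names.
#'
#' @param img A [raster_image] with intensities in [0, 1].
#' @param path Output `.tiff` path.
#' @export
write_image <- function(img, path) {
  check_writable(path)
  if (min(img$data) < 0 || max(img$data) > 1) {
    stop_validation("TIFF writer requires intensities in [0, 1]")
  }
  pages <- lapply(seq_len(n_channels(img)), function(ch) img$data[, , ch])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(pixel_size = img$pixel_size, channel_names = img$channel_names,
         chunk = img$chunk),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_image
#' @param pixel_size,channel_names Override / supply metadata when no sidecar
#'   file is present.
#' @param chunk Chunk sizes for the loaded image.
#' @export
read_image <- function(path, pixel_size = NULL, channel_names = NULL,
                       chunk = NULL) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  data <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  pixel_size <- pixel_size %||% meta$pixel_size
  if (is.null(pixel_size)) {
    stop_validation("pixel_size not given and no metadata sidecar found for ", path)
  }
  raster_image(data,
               channel_names = channel_names %||% meta$channel_names,
               pixel_size = pixel_size,
               chunk = chunk %||% meta$chunk %||% c(256L, 256L))
}

#' Write / read transcripts as CSV (columns x, y, gene, id)
#' @param t A [transcript_table].
#' @param path Output file path.
#' @export
write_transcripts <- function(t, path) {
  check_writable(path)
  utils::write.csv(as.data.frame(t), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transcripts
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("x", "y", "gene")) {
    if (!col %in% names(df)) stop_validation("transcript CSV lacks column '", col, "'")
  }
  transcript_table(df$x, df$y, df$gene, id = df$id %||% NULL)
}

check_writable <- function(path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io("directory does not exist: ", dir)
  invisible(TRUE)
}

#' Load a dataset from a configuration record
#'
#' The config is a list (or a YAML/JSON file path) with fields `image`
#' (TIFF path), optional `pixel_size` and `channel_names`, optional
#' `transcripts` (CSV path) and optional `cells` (GeoJSON path). All layers
#' are returned in one world coordinate frame (micrometers, origin at the
#' image top-left).
#'
#' @param config List or path to a YAML/JSON config file.
#' @return A list with elements `image` ([raster_image] or NULL),
#'   `transcripts` ([transcript_table] or NULL), `cells`
#'   ([cell_collection] or NULL).
#' @export
load_dataset <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_io("no such config file: ", config)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  img <- NULL
  if (!is.null(config$image)) {
    img <- read_image(config$image,
                      pixel_size = config$pixel_size,
                      channel_names = config$channel_names,
                      chunk = config$chunk)
  } else if (!is.null(config$pixel_size) && config$pixel_size <= 0) {
    stop_validation("pixel_size must be > 0")
  }
  tr <- if (!is.null(config$transcripts)) read_transcripts(config$transcripts)
  cl <- if (!is.null(config$cells)) read_cells(config$cells)
  list(image = img, transcripts = tr, cells = cl)
}
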