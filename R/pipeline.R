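# End-to-end orchestration: patchify -> segment -> resolve -> aggregate ->
# annotate -> stats -> niches -> export -> report. Every stage is a thin
# wrapper over one module operation, writes standard-format artifacts into
# the output directory, and is skipped when its outputs already exist
# (making runs resumable and idempotent).

pipeline_stages <- c("patchify", "segment", "resolve", "aggregate",
                     "annotate", "stats", "niches", "export", "report")

default_config <- function() {
  list(
    patch = list(width = 200, overlap = 40),
    segmentation = list(channel = "nuclear", sigma = 1, threshold = 0.3,
                        min_area_px = 20, split_touching = FALSE),
    resolve = list(merge_threshold = 0.5),
    aggregate = list(partition_size = 100),
    graph = list(max_edge_length = 40),
    niches = list(min_area_fraction = 0.05)
  )
}

#' Run the full pipeline
#'
#' @param config A list or a YAML/JSON file path. Required fields: `outdir`
#'   and `input` (either `input$generate` with [generate_tissue()]
#'   parameters including a `seed`, or `input$image`/`input$transcripts`
#'   paths as for [load_dataset()]). Optional fields override the defaults
#'   of each stage (`patch`, `segmentation`, `resolve`, `aggregate`,
#'   `annotate$markers`, `graph`, `niches`). Per-cell niche labels come
#'   from the generator's ground truth or from `input$niches` (a CSV with
#'   a `niche` column); without them the niche stages are skipped with a
#'   notice.
#' @param stages Subset of stages to run (default: all, in order).
#' @param patch_index When running only the `segment` stage, restrict to a
#'   single patch (enables per-patch job arrays).
#' @param force Re-run stages even when their outputs exist.
#' @return Invisibly, a list with the artifact paths and a run summary.
#' @export
run_pipeline <- function(config, stages = pipeline_stages, patch_index = NULL,
                         force = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_io("no such config file: ", config)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  if (is.null(cfg$outdir)) stop_validation("config needs an 'outdir'")
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    patches = file.path(outdir, "patches.geojson"),
    raw_cells = file.path(outdir, "cells_per_patch.geojson"),
    cells = file.path(outdir, "cells.geojson"),
    conflicts = file.path(outdir, "conflicts.csv"),
    channels = file.path(outdir, "channel_means.csv"),
    counts = file.path(outdir, "counts"),
    labels = file.path(outdir, "cell_labels.csv"),
    graph = file.path(outdir, "graph_edges.csv"),
    dist = file.path(outdir, "distances"),
    network = file.path(outdir, "network.csv"),
    niches_geo = file.path(outdir, "niches.geojson"),
    niche_stats = file.path(outdir, "niche_stats.csv"),
    bundle = file.path(outdir, "bundle"),
    report = file.path(outdir, "report.html")
  )

  t_stage <- function(name, outputs, fun) {
    if (!name %in% stages) return(invisible(NULL))
    if (!force && all(file.exists(outputs))) {
      message("[", name, "] outputs exist; skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    tryCatch(fun(), error = function(e) {
      cond <- structure(
        class = c("cellpatch_stage_error", "error", "condition"),
        list(message = paste0("stage '", name, "' failed: ",
                              conditionMessage(e)), call = NULL))
      stop(cond)
    })
    message(sprintf("[%s] done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
  }

  ## ---- input
  truth <- NULL
  if (!is.null(cfg$input$generate)) {
    gen <- cfg$input$generate
    tissue <- do.call(generate_tissue, gen)
    image <- tissue$image
    transcripts <- tissue$transcripts
    truth <- tissue$truth
    niche_labels_src <- function(cells) {
      # nearest ground-truth cell center carries the niche label
      tc <- cell_centroids(truth$cells)
      cc <- cell_centroids(cells)
      idx <- apply(cc, 1, function(p) {
        which.min((tc[, 1] - p[1])^2 + (tc[, 2] - p[2])^2)
      })
      truth$niche[idx]
    }
  } else {
    ds <- load_dataset(cfg$input)
    image <- ds$image
    transcripts <- ds$transcripts
    niche_labels_src <- if (!is.null(cfg$input$niches)) {
      function(cells) {
        df <- utils::read.csv(cfg$input$niches)
        df$niche[match(cells$id, df$cell_id)]
      }
    } else NULL
  }
  if (is.null(image)) stop_validation("the pipeline requires an image")

  grid <- make_patches(image, patch_width = cfg$patch$width,
                       overlap = cfg$patch$overlap)

  t_stage("patchify", paths$patches, function() {
    write_patches(grid, paths$patches)
  })

  seg_file <- function(k) file.path(outdir, sprintf("cells_patch_%03d.geojson", k))
  t_stage("segment", vapply(seq_len(nrow(grid)), seg_file, character(1)),
          function() {
    ks <- patch_index %||% seq_len(nrow(grid))
    res <- run_segmentation(image, grid, params = cfg$segmentation,
                            transcripts = transcripts, patches = ks)
    for (i in seq_along(ks)) write_cells(res[[i]], seg_file(ks[i]))
  })

  t_stage("resolve", c(paths$cells, paths$conflicts), function() {
    per_patch <- lapply(seq_len(nrow(grid)), function(k) read_cells(seg_file(k)))
    resolved <- resolve_conflicts(per_patch,
                                  merge_threshold = cfg$resolve$merge_threshold)
    write_cells(resolved, paths$cells)
    utils::write.csv(conflict_table(resolved), paths$conflicts, row.names = FALSE)
  })

  t_stage("aggregate", c(paths$channels, paste0(paths$counts, ".mtx")),
          function() {
    cells <- read_cells(paths$cells)
    ch <- average_channels(image, cells)
    utils::write.csv(data.frame(cell_id = cells$id, ch, check.names = FALSE),
                     paths$channels, row.names = FALSE)
    counts <- if (!is.null(transcripts)) {
      count_transcripts(transcripts, cells,
                        partition_size = cfg$aggregate$partition_size)
    } else {
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = c(length(cells), 0L),
                           dimnames = list(as.character(cells$id), character(0)))
    }
    write_counts(counts, paths$counts)
    if (!is.null(transcripts)) {
      write_transcripts(transcripts, file.path(outdir, "transcripts.csv"))
    }
  })

  t_stage("annotate", paths$labels, function() {
    cells <- read_cells(paths$cells)
    ch <- utils::read.csv(paths$channels, check.names = FALSE)
    X <- as.matrix(ch[, -1, drop = FALSE])
    marker_map <- unlist(cfg$annotate$markers %||% default_marker_map(colnames(X)))
    labels <- annotate_by_markers(preprocess_intensities(X), marker_map)
    df <- data.frame(cell_id = cells$id, label = labels)
    if (!is.null(niche_labels_src)) df$niche <- niche_labels_src(cells)
    utils::write.csv(df, paths$labels, row.names = FALSE)
  })

  t_stage("stats", c(paths$graph, paths$network), function() {
    cells <- read_cells(paths$cells)
    lab <- utils::read.csv(paths$labels)
    graph <- build_graph(cells, max_edge_length = cfg$graph$max_edge_length)
    utils::write.csv(
      data.frame(from = cells$id[graph$edges[, 1]],
                 to = cells$id[graph$edges[, 2]],
                 length_um = graph$edge_lengths),
      paths$graph, row.names = FALSE)
    dir.create(paths$dist, showWarnings = FALSE)
    types <- lab$label
    mats <- list(type_type = hop_distance_matrix(graph, types, types))
    if (!is.null(lab$niche)) {
      mats$type_niche <- hop_distance_matrix(graph, types, lab$niche)
      mats$niche_type <- hop_distance_matrix(graph, lab$niche, types)
      mats$niche_niche <- hop_distance_matrix(graph, lab$niche, lab$niche)
    }
    for (nm in names(mats)) {
      utils::write.csv(as.data.frame(mats[[nm]]),
                       file.path(paths$dist, paste0(nm, ".csv")))
    }
    utils::write.csv(build_network(mats), paths$network, row.names = FALSE)
  })

  t_stage("niches", c(paths$niches_geo, paths$niche_stats), function() {
    lab <- utils::read.csv(paths$labels)
    if (is.null(lab$niche)) {
      message("[niches] no niche labels available; stage skipped")
      return(invisible(NULL))
    }
    cells <- read_cells(paths$cells)
    graph <- build_graph(cells, max_edge_length = cfg$graph$max_edge_length)
    comp <- extract_niche_polygons(graph, lab$niche)
    write_niches(comp, paths$niches_geo)
    utils::write.csv(
      niche_stats(comp, min_area_fraction = cfg$niches$min_area_fraction),
      paths$niche_stats, row.names = FALSE)
  })

  t_stage("export", file.path(paths$bundle, "experiment.json"), function() {
    cells <- read_cells(paths$cells)
    counts <- read_counts(paths$counts)
    lab <- utils::read.csv(paths$labels)
    categories <- list(cell_type = lab$label)
    if (!is.null(lab$niche)) categories$niche <- lab$niche
    write_bundle(paths$bundle, image = image, transcripts = transcripts,
                 cells = cells, counts = counts, categories = categories,
                 name = cfg$name %||% "cellpatch-run")
  })

  t_stage("report", paths$report, function() {
    make_report(outdir, paths$report)
  })

  invisible(list(paths = paths, grid = grid, truth = truth))
}

# When no marker map is configured, map every non-nuclear channel to itself.
default_marker_map <- function(channels) {
  ch <- setdiff(channels, "nuclear")
  stats::setNames(as.list(ch), ch)
}

#' Assemble a single-file HTML quality-control report
#'
#' Sections: resolved cell count and area distribution, the conflict-quality
#' histogram (counts of good_distinct / ambiguous / good_duplicate scores),
#' the fraction of transcripts assigned to cells, per-channel intensity
#' summaries and annotation label counts. Sections whose artifacts are
#' missing are omitted with a notice.
#'
#' @param outdir Pipeline output directory.
#' @param path Output HTML file (default `report.html` inside `outdir`).
#' @return Invisibly, the report path.
#' @export
make_report <- function(outdir, path = file.path(outdir, "report.html")) {
  esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", as.character(x)))
  html_table <- function(df) {
    paste0("<table border='1' cellpadding='4'><tr>",
           paste0("<th>", esc(names(df)), "</th>", collapse = ""), "</tr>",
           paste0(apply(df, 1, function(r) {
             paste0("<tr>", paste0("<td>", esc(r), "</td>", collapse = ""), "</tr>")
           }), collapse = ""),
           "</table>")
  }
  sections <- character(0)
  add <- function(title, body) {
    sections <<- c(sections, paste0("<h2>", esc(title), "</h2>", body))
  }
  omit <- function(title) {
    add(title, "<p><em>artifacts missing; section omitted</em></p>")
  }

  cells_path <- file.path(outdir, "cells.geojson")
  n_cells <- NA
  if (file.exists(cells_path)) {
    cells <- read_cells(cells_path)
    n_cells <- length(cells)
    areas <- cell_areas(cells)
    add("Cells", paste0(
      "<p>Resolved cell count: <b id='cell-count'>", n_cells, "</b></p>",
      "<p>Area (um^2) quantiles:</p>",
      html_table(as.data.frame(t(round(stats::quantile(areas), 2))))))
  } else omit("Cells")

  conf_path <- file.path(outdir, "conflicts.csv")
  if (file.exists(conf_path)) {
    conf <- utils::read.csv(conf_path)
    bins <- table(classify_conflict(conf$ioma))
    add("Segmentation conflicts", paste0(
      "<p>", nrow(conf), " cross-patch conflict(s)</p>",
      html_table(as.data.frame(bins))))
  } else omit("Segmentation conflicts")

  counts_path <- file.path(outdir, "counts.mtx")
  if (file.exists(counts_path)) {
    counts <- read_counts(file.path(outdir, "counts"))
    tr_path <- file.path(outdir, "transcripts.csv")
    total <- if (file.exists(tr_path)) nrow(read_transcripts(tr_path)) else NA
    assigned <- sum(counts)
    frac <- if (!is.na(total) && total > 0) sprintf(" (%.1f%% of %d)",
                                                    100 * assigned / total, total)
            else ""
    add("Transcripts", paste0("<p>Assigned transcripts: ", assigned, frac, "</p>"))
  } else omit("Transcripts")

  ch_path <- file.path(outdir, "channel_means.csv")
  if (file.exists(ch_path)) {
    ch <- utils::read.csv(ch_path, check.names = FALSE)
    X <- as.matrix(ch[, -1, drop = FALSE])
    add("Channel intensities", html_table(data.frame(
      channel = colnames(X),
      mean = round(colMeans(X), 4),
      q50 = round(apply(X, 2, stats::median), 4))))
  } else omit("Channel intensities")

  lab_path <- file.path(outdir, "cell_labels.csv")
  if (file.exists(lab_path)) {
    lab <- utils::read.csv(lab_path)
    add("Annotation", html_table(as.data.frame(table(label = lab$label))))
  } else omit("Annotation")

  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>cellpatch QC report</title></head><body>",
    "<h1>cellpatch pipeline report</h1>",
    paste0(sections, collapse = ""),
    "</body></html>")
  writeLines(html, path)
  invisible(path)
}
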