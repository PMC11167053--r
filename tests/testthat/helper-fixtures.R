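# Shared fixtures, built in code.

# Axis-aligned rectangle polygon.
sq <- function(x0, y0, w, h = w) {
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
}

# Regular n-gon of circumradius r.
ngon <- function(cx, cy, r, n) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# A small synthetic tissue reused across files (cached per parameter set).
.fixture_cache <- new.env(parent = emptyenv())
small_tissue <- function(seed = 7, n_cells = 30) {
  key <- paste0("t", seed, "_", n_cells)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_tissue(
      n_cells = n_cells, image_size = c(256L, 256L), seed = seed
    )
  }
  .fixture_cache[[key]]
}

# Match segmented cells to ground-truth cells by nearest centroid.
match_to_truth <- function(cells, truth) {
  tc <- cell_centroids(truth$cells)
  cc <- cell_centroids(cells)
  apply(cc, 1, function(p) which.min((tc[, 1] - p[1])^2 + (tc[, 2] - p[2])^2))
}

# Naive whole-image channel averaging: rasterize every cell over the full
# pixel grid with the same pixel-center rule, independent of chunking.
naive_average_channels <- function(image, cells) {
  d <- dim(image$data)
  ps <- image$pixel_size
  out <- matrix(0, length(cells), d[3])
  for (i in seq_len(length(cells))) {
    p <- cells$polygons[[i]]
    bb <- cbind(range(p[, 1]), range(p[, 2]))
    rows <- max(0, floor(bb[1, 2] / ps)):min(d[1] - 1, ceiling(bb[2, 2] / ps))
    cols <- max(0, floor(bb[1, 1] / ps)):min(d[2] - 1, ceiling(bb[2, 1] / ps))
    g <- expand.grid(y = rows * ps, x = cols * ps)
    inside <- sp::point.in.polygon(g$x + 1e-6 * ps, g$y + 1e-6 * ps,
                                   p[, 1], p[, 2]) > 0
    if (!any(inside)) next
    rr <- rep(rows, times = length(cols))[inside] + 1L
    cc <- rep(cols, each = length(rows))[inside] + 1L
    for (ch in seq_len(d[3])) {
      out[i, ch] <- mean(image$data[cbind(rr, cc, ch)])
    }
  }
  dimnames(out) <- list(as.character(cells$id), image$channel_names)
  out
}

# Brute-force transcript counting over all (point, cell) pairs; smallest
# covering cell id wins.
brute_count_transcripts <- function(t, cells) {
  genes <- levels(t$gene)
  out <- matrix(0, length(cells), length(genes),
                dimnames = list(as.character(cells$id), genes))
  ord <- order(cells$id)
  for (k in seq_len(nrow(t))) {
    for (i in ord) {
      p <- cells$polygons[[i]]
      if (sp::point.in.polygon(t$x[k], t$y[k], p[, 1], p[, 2]) > 0) {
        out[i, as.integer(t$gene[k])] <- out[i, as.integer(t$gene[k])] + 1
        break
      }
    }
  }
  out
}

# Random connected-ish geometric graph for BFS oracle tests.
random_graph_fixture <- function(seed, n_max = 120) {
  set.seed(seed)
  n <- sample(10:n_max, 1)
  coords <- cbind(runif(n, 0, 150), runif(n, 0, 150))
  build_graph(coords, max_edge_length = 40)
}

# Per-node single-source hop distances via igraph (independent oracle).
igraph_hop_matrix <- function(graph, C, Cp) {
  g <- igraph::make_empty_graph(n = nrow(graph$coords), directed = FALSE)
  if (nrow(graph$edges)) g <- igraph::add_edges(g, t(graph$edges))
  dmat <- igraph::distances(g)
  G <- sort(unique(as.character(C)))
  Gp <- sort(unique(as.character(Cp)))
  D <- matrix(NaN, length(G), length(Gp), dimnames = list(G, Gp))
  for (g2 in Gp) {
    src <- which(Cp == g2)
    mind <- apply(dmat[, src, drop = FALSE], 1, min)
    for (g1 in G) {
      d <- mind[C == g1]
      d <- d[is.finite(d)]
      if (length(d)) D[g1, g2] <- mean(d)
    }
  }
  D
}
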