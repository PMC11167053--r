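# Spatial statistics on a pruned Delaunay cell graph.
#
# Cells are reduced to their centroids; a Delaunay triangulation connects
# physical neighbours, and edges longer than a cutoff (default 40 um) are
# pruned because they cannot correspond to a cell-cell interaction. The
# mean hop distance from category g to category g' is
#
#   D(g, g') = (1 / #{i : C_i = g}) * sum_{i : C_i = g} min_{j : C'_j = g'} d_ij
#
# with d_ij the hop distance (edge count) in the pruned graph. For each g'
# a single multi-source breadth-first traversal from all nodes of category
# g' yields min_j d_ij for every node i at once. The matrix is asymmetric
# in general because of the minimum.

#' Build a pruned Delaunay graph over cell centroids
#'
#' @param cells A [cell_collection], or an n x 2 matrix of centroid
#'   coordinates (um).
#' @param max_edge_length Prune Delaunay edges longer than this (um,
#'   default 40).
#' @return An object of class `spatial_graph`: `coords` (n x 2), `ids`,
#'   `edges` (m x 2 node indices), `edge_lengths`, `simplices` (t x 3 node
#'   indices of triangles whose three edges were all retained).
#' @export
build_graph <- function(cells, max_edge_length = 40) {
  coords <- if (inherits(cells, "cell_collection")) cell_centroids(cells)
            else as.matrix(cells)
  ids <- if (inherits(cells, "cell_collection")) cells$id
         else seq_len(nrow(coords))
  n <- nrow(coords)
  dup <- duplicated(coords)
  if (any(dup)) {
    warning(sum(dup), " duplicated centroid(s) perturbed by ~1e-9 um")
    k <- which(dup)
    coords[k, 1] <- coords[k, 1] + seq_along(k) * 1e-9
    coords[k, 2] <- coords[k, 2] + seq_along(k) * 1.3e-9
  }
  edges <- matrix(integer(0), 0, 2)
  simplices <- matrix(integer(0), 0, 3)
  if (n == 2) {
    edges <- matrix(c(1L, 2L), 1, 2)
  } else if (n >= 3) {
    ctr <- sweep(coords, 2, colMeans(coords))
    collinear <- svd(ctr)$d[2] < 1e-9 * max(1, svd(ctr)$d[1])
    if (collinear) {
      # degenerate triangulation: chain consecutive points along the line
      v <- svd(ctr)$v[, 1]
      ord <- order(ctr %*% v)
      edges <- cbind(ord[-n], ord[-1])
    } else {
      dd <- deldir::deldir(coords[, 1], coords[, 2], suppressMsge = TRUE)
      edges <- cbind(dd$delsgs$ind1, dd$delsgs$ind2)
      tl <- deldir::triang.list(dd)
      if (length(tl)) {
        simplices <- t(vapply(tl, function(tr) sort(tr$ptNum), integer(3)))
      }
    }
  }
  if (nrow(edges)) {
    edges <- t(apply(edges, 1, sort))
    len <- sqrt(rowSums((coords[edges[, 1], , drop = FALSE] -
                         coords[edges[, 2], , drop = FALSE])^2))
    keep <- len <= max_edge_length
    edges <- edges[keep, , drop = FALSE]
    len <- len[keep]
  } else len <- numeric(0)
  if (nrow(simplices)) {
    edge_key <- paste(edges[, 1], edges[, 2])
    tri_ok <- vapply(seq_len(nrow(simplices)), function(k) {
      s <- simplices[k, ]
      all(paste(c(s[1], s[1], s[2]), c(s[2], s[3], s[3])) %in% edge_key)
    }, logical(1))
    simplices <- simplices[tri_ok, , drop = FALSE]
  }
  structure(
    list(coords = coords, ids = ids,
         edges = matrix(as.integer(edges), ncol = 2),
         edge_lengths = len,
         simplices = matrix(as.integer(simplices), ncol = 3),
         max_edge_length = max_edge_length),
    class = "spatial_graph"
  )
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %d node(s), %d edge(s), %d simplex(es), cutoff %g um\n",
              nrow(x$coords), nrow(x$edges), nrow(x$simplices),
              x$max_edge_length))
  invisible(x)
}

graph_adjacency <- function(graph) {
  n <- nrow(graph$coords)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(graph$edges)) {
    for (r in seq_len(nrow(graph$edges))) {
      a <- graph$edges[r, 1]; b <- graph$edges[r, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# Multi-source BFS: minimum hop distance from any source to every node
# (NA when unreachable).
bfs_multi <- function(adj, sources) {
  n <- length(adj)
  dist <- rep.int(NA_integer_, n)
  queue <- integer(n)
  queue[seq_along(sources)] <- sources
  dist[sources] <- 0L
  head <- 1L; tail <- length(sources)
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        tail <- tail + 1L
        queue[tail] <- w
      }
    }
  }
  dist
}

#' Mean hop-distance matrix between two category assignments
#'
#' @param graph A [build_graph()] result.
#' @param C Primary category per node (rows of the result).
#' @param Cp Secondary category per node (columns); defaults to `C`.
#' @return A |G| x |G'| matrix `D` with `D[g, g'] = mean over {i : C_i = g}`
#'   of the hop distance from node i to the nearest node of category g'.
#'   Nodes with no finite path are excluded from the mean (counts in
#'   `attr(, "excluded")`); a category pair with no finite path at all is
#'   `NaN`. When `Cp` is `C`, the diagonal is 0.
#' @export
hop_distance_matrix <- function(graph, C, Cp = C) {
  n <- nrow(graph$coords)
  if (length(C) != n || length(Cp) != n) {
    stop_validation("category assignments must cover all graph nodes")
  }
  G <- sort(unique(as.character(C)))
  Gp <- sort(unique(as.character(Cp)))
  adj <- graph_adjacency(graph)
  D <- matrix(NaN, length(G), length(Gp), dimnames = list(G, Gp))
  excluded <- matrix(0L, length(G), length(Gp), dimnames = list(G, Gp))
  for (gp in Gp) {
    sources <- which(Cp == gp)
    mind <- bfs_multi(adj, sources)
    for (g in G) {
      rows <- which(C == g)
      d <- mind[rows]
      finite <- !is.na(d)
      excluded[g, gp] <- sum(!finite)
      if (any(finite)) D[g, gp] <- mean(d[finite])
    }
  }
  attr(D, "excluded") <- excluded
  D
}

#' Combine distance matrices into an inverse-distance network
#'
#' Takes the four directed mean hop-distance matrices (type-type,
#' type-niche, niche-type, niche-niche), symmetrizes each node pair by
#' averaging the available directed entries, and sets the edge weight to
#' `1 / max(D_bar, eps)`; `eps` (default 0.5 hops) keeps weights finite for
#' categories fully nested in one another. Undefined distances yield no
#' edge; there are no self-edges.
#'
#' @param matrices A list of distance matrices as returned by
#'   [hop_distance_matrix()] (any number; typically four).
#' @param eps Clamp for near-zero distances, in hops.
#' @return A data frame edge list: `from`, `to`, `distance`, `weight`.
#' @export
build_network <- function(matrices, eps = 0.5) {
  if (inherits(matrices, "matrix")) matrices <- list(matrices)
  nodes <- sort(unique(unlist(lapply(matrices, function(m) c(rownames(m), colnames(m))))))
  directed <- function(u, v) {
    vals <- numeric(0)
    for (m in matrices) {
      if (u %in% rownames(m) && v %in% colnames(m) && is.finite(m[u, v])) {
        vals <- c(vals, m[u, v])
      }
    }
    vals
  }
  from <- character(0); to <- character(0); dist <- numeric(0)
  nn <- length(nodes)
  for (a in seq_len(nn - 1L)) {
    for (b in (a + 1L):nn) {
      u <- nodes[a]; v <- nodes[b]
      vals <- c(directed(u, v), directed(v, u))
      if (length(vals) == 0L) next
      from <- c(from, u); to <- c(to, v); dist <- c(dist, mean(vals))
    }
  }
  data.frame(from = from, to = to, distance = dist,
             weight = 1 / pmax(dist, eps))
}
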