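# Niche polygonization and geometry statistics.
#
# Per-cell niche labels are turned into polygons on the pruned Delaunay
# graph: edges joining cells of different niches are dropped, connected
# components are extracted (one niche may occur as several components),
# and each component's triangulated region is bounded by its border edges
# (edges incident to exactly one retained triangle), linked into closed
# rings. One ring gives a plain polygon; several give an exterior (largest
# ring) with holes. Statistics per niche: occurrence count, mean area,
# perimeter and roundness R = 4*pi*A / L^2 (1 for a disc), cell density —
# with area and perimeter net of holes, after discarding components smaller
# than 5% of the niche's largest component.

#' Convert per-cell niche labels into polygon components
#'
#' @param graph A [build_graph()] result (with simplices).
#' @param niche Character vector: niche label per graph node.
#' @return A list of components, each a list with `niche`, `exterior`
#'   (largest outer ring matrix), `holes` (list of ring matrices), `lobes`
#'   (additional outer rings when the component touches itself at a pinch
#'   vertex; usually empty), `area` (outer rings minus holes, um^2),
#'   `perimeter` (all rings, um), `roundness`, `n_cells`. Components
#'   without any triangle (fewer than 3 cells or no simplex) are skipped
#'   with a warning.
#' @export
extract_niche_polygons <- function(graph, niche) {
  n <- nrow(graph$coords)
  if (length(niche) != n) stop_validation("niche labels must cover all nodes")
  niche <- as.character(niche)
  edges <- graph$edges
  keep_e <- niche[edges[, 1]] == niche[edges[, 2]]
  edges <- edges[keep_e, , drop = FALSE]
  simp <- graph$simplices
  if (nrow(simp)) {
    keep_s <- niche[simp[, 1]] == niche[simp[, 2]] &
              niche[simp[, 2]] == niche[simp[, 3]]
    simp <- simp[keep_s, , drop = FALSE]
  }

  # connected components over retained edges
  parent <- uf_new(n)
  for (r in seq_len(nrow(edges))) {
    parent <- uf_union(parent, edges[r, 1], edges[r, 2])
  }
  comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  simp_comp <- if (nrow(simp)) comp[simp[, 1]] else integer(0)

  components <- list()
  skipped <- 0L
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    tri <- simp[simp_comp == cid, , drop = FALSE]
    if (nrow(tri) == 0L) {
      skipped <- skipped + 1L
      next
    }
    rings <- component_border_rings(tri, graph$coords)
    signed <- vapply(rings, poly_signed_area, numeric(1))
    pos <- which(signed > 0)
    ext_i <- pos[which.max(signed[pos])]
    A <- sum(signed)                 # outer rings minus holes, net area
    L <- sum(vapply(rings, poly_perimeter, numeric(1)))
    components[[length(components) + 1L]] <- list(
      niche = niche[members[1]],
      exterior = rings[[ext_i]],
      holes = rings[signed < 0],
      lobes = rings[setdiff(pos, ext_i)],  # extra outer rings at pinch points
      area = A,
      perimeter = L,
      roundness = 4 * pi * A / L^2,
      n_cells = length(members),
      triangle_area = sum(apply(tri, 1, function(s) poly_area(graph$coords[s, ])))
    )
  }
  if (skipped > 0L) {
    warning(skipped, " component(s) without a triangle were skipped")
  }
  components
}

# Border edges (edges incident to exactly one triangle of the component)
# linked into closed rings of node coordinates. Each border edge is oriented
# by its unique triangle (all triangles oriented counterclockwise), so outer
# rings come out with positive signed area and hole rings negative.
# Non-manifold "pinch" vertices (more than one outgoing border edge) are
# resolved deterministically by taking the sharpest turn, keeping every
# ring simple; a warning is raised.
component_border_rings <- function(tri, coords) {
  # orient every triangle counterclockwise (positive signed area)
  tri <- t(apply(tri, 1, function(s) {
    sa <- poly_signed_area(coords[s, , drop = FALSE])
    if (sa < 0) s[c(1, 3, 2)] else s
  }))
  # directed triangle edges a->b, b->c, c->a
  de <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  ek <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  cnt <- table(ek)
  border <- de[ek %in% names(cnt)[cnt == 1], , drop = FALSE]

  m <- nrow(border)
  used <- logical(m)
  out_of <- split(seq_len(m), border[, 1])  # vertex -> outgoing border edges
  rings <- list()
  for (start in seq_len(m)) {
    if (used[start]) next
    v0 <- border[start, 1]
    used[start] <- TRUE
    prev_v <- v0
    cur_v <- border[start, 2]
    path <- c(v0, cur_v)
    while (cur_v != v0) {
      cands <- out_of[[as.character(cur_v)]]
      cands <- cands[!used[cands]]
      if (length(cands) == 0L) break  # open chain: degenerate, drop below
      if (length(cands) > 1L) {
        warning("non-manifold niche border vertex; rings split by smallest turn")
        din <- coords[cur_v, ] - coords[prev_v, ]
        ang <- vapply(cands, function(ei) {
          dout <- coords[border[ei, 2], ] - coords[cur_v, ]
          atan2(din[1] * dout[2] - din[2] * dout[1],
                din[1] * dout[1] + din[2] * dout[2])
        }, numeric(1))
        cands <- cands[order(ang)]
      }
      nxt <- cands[1]
      used[nxt] <- TRUE
      prev_v <- cur_v
      cur_v <- border[nxt, 2]
      if (cur_v != v0) path <- c(path, cur_v)
    }
    if (cur_v == v0 && length(path) >= 3L) {
      rings[[length(rings) + 1L]] <- coords[path, , drop = FALSE]
    }
  }
  rings
}

#' Per-niche geometry statistics
#'
#' Components smaller than `min_area_fraction` of the same niche's largest
#' component are discarded as clustering artefacts; the remaining
#' components yield occurrence counts, mean area/perimeter/roundness and
#' cell density (total retained cells / total retained area).
#'
#' @param components Output of [extract_niche_polygons()].
#' @param min_area_fraction Relative area cutoff (default 0.05).
#' @return A data frame with one row per niche: `niche`, `occurrences`,
#'   `mean_area`, `mean_perimeter`, `mean_roundness`, `n_cells`, `density`,
#'   `empty` (TRUE when no component survived the filter).
#' @export
niche_stats <- function(components, min_area_fraction = 0.05) {
  niches <- sort(unique(vapply(components, `[[`, character(1), "niche")))
  rows <- lapply(niches, function(g) {
    comp <- components[vapply(components, function(cc) cc$niche == g, logical(1))]
    areas <- vapply(comp, `[[`, numeric(1), "area")
    keep <- areas >= min_area_fraction * max(areas)
    comp <- comp[keep]
    if (length(comp) == 0L) {
      return(data.frame(niche = g, occurrences = 0L, mean_area = 0,
                        mean_perimeter = 0, mean_roundness = 0, n_cells = 0L,
                        density = 0, empty = TRUE))
    }
    A <- vapply(comp, `[[`, numeric(1), "area")
    L <- vapply(comp, `[[`, numeric(1), "perimeter")
    R <- vapply(comp, `[[`, numeric(1), "roundness")
    ncell <- vapply(comp, `[[`, numeric(1), "n_cells")
    data.frame(niche = g, occurrences = length(comp), mean_area = mean(A),
               mean_perimeter = mean(L), mean_roundness = mean(R),
               n_cells = as.integer(sum(ncell)), density = sum(ncell) / sum(A),
               empty = FALSE)
  })
  do.call(rbind, rows)
}

#' Write niche components as GeoJSON polygons with holes
#' @param components Output of [extract_niche_polygons()].
#' @param path Output file path.
#' @export
write_niches <- function(components, path) {
  check_writable(path)
  close_ring <- function(r) rbind(r, r[1, , drop = FALSE])
  features <- lapply(components, function(cc) {
    outers <- c(list(cc$exterior), cc$lobes %||% list())
    # assign each hole to the outer ring that contains it
    owner <- vapply(cc$holes, function(h) {
      hit <- which(vapply(outers, function(o)
        points_in_poly(h[1, 1], h[1, 2], o), logical(1)))
      if (length(hit)) hit[1] else 1L
    }, integer(1))
    polys <- lapply(seq_along(outers), function(k) {
      c(list(close_ring(outers[[k]])),
        lapply(cc$holes[owner == k], close_ring))
    })
    geometry <- if (length(polys) == 1L) {
      list(type = "Polygon", coordinates = polys[[1]])
    } else {
      list(type = "MultiPolygon", coordinates = polys)
    }
    list(
      type = "Feature",
      geometry = geometry,
      properties = list(niche = cc$niche, area = cc$area,
                        perimeter = cc$perimeter, roundness = cc$roundness,
                        n_cells = cc$n_cells)
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
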