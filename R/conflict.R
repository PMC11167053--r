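# Conflict resolution across overlapping patches.
#
# Cells segmented on different patches may describe the same physical cell.
# The score used to decide is the intersection-over-min-area (IOMA):
# intersection area divided by the smaller cell's area. Pairs whose IOMA
# exceeds half (the intersection exceeds half of the smaller cell) are
# merged; smaller scores indicate distinct, barely-touching cells which are
# both kept. Transitive chains are closed with a union-find, and each merge
# group is replaced by the geometric union of its members.

#' Intersection-over-min-area of two polygons
#'
#' @param a,b Polygons (n x 2 matrices) with positive area.
#' @return `area(a intersect b) / min(area(a), area(b))`, in [0, 1];
#'   symmetric in its arguments.
#' @export
ioma <- function(a, b) {
  aa <- poly_area(a); ab <- poly_area(b)
  if (aa <= 0 || ab <= 0) stop_validation("ioma needs polygons of positive area")
  min(poly_intersection_area(a, b) / min(aa, ab), 1)
}

#' Classify a conflict score for quality control
#'
#' Scores below 0.07 are clear "two distinct cells" cases and scores above
#' 0.8 are clear "same cell twice" cases; everything in between is
#' ambiguous. These cutoffs only describe resolution quality (for the QC
#' report); they are not merge parameters.
#'
#' @param score Numeric vector of IOMA scores in [0, 1].
#' @param low,high Classifier cutoffs (defaults 0.07 and 0.8).
#' @return Factor with levels `good_distinct`, `ambiguous`, `good_duplicate`.
#' @export
classify_conflict <- function(score, low = 0.07, high = 0.8) {
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1)) {
    stop_validation("conflict scores must lie in [0, 1]")
  }
  out <- rep("ambiguous", length(score))
  out[score < low] <- "good_distinct"
  out[score > high] <- "good_duplicate"
  factor(out, levels = c("good_distinct", "ambiguous", "good_duplicate"))
}

# Minimal union-find with path compression.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, a, b) {
  ra <- uf_find(parent, a); rb <- uf_find(parent, b)
  if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  parent
}

#' Resolve segmentation conflicts across patches
#'
#' Candidate pairs are cells with overlapping bounding boxes and differing
#' patch provenance; pairs with IOMA strictly above `merge_threshold` are
#' joined transitively (union-find) and each group is replaced by the
#' geometric union of its members (repaired; largest part kept when the
#' union is multi-part). Pairs at or below the threshold are both kept.
#' The pass is repeated until no cross-patch pair exceeds the threshold,
#' so the operation is idempotent.
#'
#' @param per_patch A list of [cell_collection]s (one per patch, provenance
#'   set), or a single already-combined collection.
#' @param merge_threshold Merge when IOMA exceeds this (default 0.5,
#'   i.e. the intersection exceeds half the smaller cell's area).
#' @return A [cell_collection] with unique sequential ids, provenance equal
#'   to the union of each group's source patches, and a `conflicts`
#'   attribute: a data frame (a, b, ioma, decision) of the first-pass
#'   candidate pairs (retrievable with [conflict_table()]).
#' @export
resolve_conflicts <- function(per_patch, merge_threshold = 0.5) {
  cells <- if (inherits(per_patch, "cell_collection")) per_patch
           else combine_collections(per_patch)
  conflicts <- data.frame(a = integer(0), b = integer(0), ioma = numeric(0),
                          decision = character(0))
  pass <- 0L
  repeat {
    pass <- pass + 1L
    n <- length(cells)
    if (n <= 1L) break
    pairs <- candidate_pairs(cells)
    if (nrow(pairs) == 0L) break
    scores <- vapply(seq_len(nrow(pairs)), function(r) {
      ioma(cells$polygons[[pairs$i[r]]], cells$polygons[[pairs$j[r]]])
    }, numeric(1))
    if (pass == 1L) {
      conflicts <- data.frame(
        a = cells$id[pairs$i], b = cells$id[pairs$j], ioma = scores,
        decision = ifelse(scores > merge_threshold, "merge", "keep")
      )
    }
    to_merge <- which(scores > merge_threshold)
    if (length(to_merge) == 0L) break
    parent <- uf_new(n)
    for (r in to_merge) parent <- uf_union(parent, pairs$i[r], pairs$j[r])
    roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
    groups <- split(seq_len(n), roots)
    polys <- vector("list", length(groups))
    prov <- vector("list", length(groups))
    minid <- integer(length(groups))
    for (g in seq_along(groups)) {
      members <- groups[[g]]
      polys[[g]] <- if (length(members) == 1L) {
        cells$polygons[[members]]
      } else {
        poly_repair(poly_union(cells$polygons[members]))
      }
      prov[[g]] <- sort(unique(unlist(cells$provenance[members])))
      minid[g] <- min(cells$id[members])
    }
    ord <- order(minid)
    cells <- cell_collection(polys[ord], ids = minid[ord], provenance = prov[ord])
  }
  # stable, unique sequential ids ordered by original minimum id
  out <- cell_collection(cells$polygons, ids = seq_len(length(cells)),
                         provenance = cells$provenance)
  attr(out, "conflicts") <- conflicts
  out
}

#' @rdname resolve_conflicts
#' @param resolved The output of `resolve_conflicts()`.
#' @export
conflict_table <- function(resolved) {
  attr(resolved, "conflicts") %||%
    data.frame(a = integer(0), b = integer(0), ioma = numeric(0),
               decision = character(0))
}

# Concatenate per-patch collections into one, assigning fresh unique ids in
# patch order.
combine_collections <- function(per_patch) {
  per_patch <- per_patch[vapply(per_patch, length, integer(1)) > 0]
  if (length(per_patch) == 0L) {
    return(structure(list(polygons = list(), id = integer(0),
                          provenance = list()),
                     class = "cell_collection"))
  }
  polys <- unlist(lapply(per_patch, `[[`, "polygons"), recursive = FALSE)
  prov <- unlist(lapply(per_patch, `[[`, "provenance"), recursive = FALSE)
  cell_collection(polys, ids = seq_along(polys), provenance = prov)
}

# Pairs of cells with overlapping bounding boxes and differing provenance
# sets (instances from a single identical patch set are trusted).
candidate_pairs <- function(cells) {
  n <- length(cells)
  bb <- cell_bboxes(cells)
  prov_key <- vapply(cells$provenance, function(p) paste(p, collapse = ","),
                     character(1))
  ord <- order(bb[, 1])
  is <- integer(0); js <- integer(0)
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in (a + 1L):n) {
      j <- ord[b]
      if (bb[j, 1] > bb[i, 3]) break
      if (prov_key[i] == prov_key[j] && nzchar(prov_key[i])) next
      if (bb[i, 2] <= bb[j, 4] && bb[j, 2] <= bb[i, 4]) {
        is <- c(is, min(i, j)); js <- c(js, max(i, j))
      }
    }
  }
  data.frame(i = is, j = js)
}
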