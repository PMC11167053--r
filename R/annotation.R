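# Staining-based cell-type annotation.
#
# Raw per-cell channel means X (N cells x P channels) are variance-
# stabilized channel by channel:
#
#   X'_j = arcsinh( X_j / (5 * Q(0.2, X_j)) )
#
# where Q(0.2, X_j) is the 20th percentile of channel j (linear-
# interpolation quantile). The transform is strictly monotone per channel
# and invariant to rescaling a channel by any k > 0, since the percentile
# scales with the data. Each cell is then labelled by the marker channel
# with the highest preprocessed intensity.

#' Preprocess a per-cell intensity matrix
#'
#' Applies the arcsinh transform above. When a channel's 20th percentile is
#' zero, the divisor falls back to 5 x the smallest positive value of the
#' channel; an entirely zero channel is left at zero.
#'
#' @param X Non-negative N x P matrix of per-cell channel means.
#' @return The transformed matrix X' (same shape and dimnames).
#' @export
preprocess_intensities <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop_validation("need at least one cell")
  if (any(X < 0)) stop_validation("raw intensities must be non-negative")
  Xp <- X
  for (j in seq_len(ncol(X))) {
    q <- stats::quantile(X[, j], 0.2, type = 7, names = FALSE)
    if (q == 0) {
      pos <- X[, j][X[, j] > 0]
      if (length(pos) == 0L) next           # all-zero channel stays zero
      q <- min(pos)
    }
    Xp[, j] <- asinh(X[, j] / (5 * q))
  }
  Xp
}

#' Annotate cells by their strongest marker channel
#'
#' Restricted to the marker channels, each cell is labelled with the
#' population mapped from the channel of maximal preprocessed intensity;
#' exact ties go to the lowest-indexed channel, and cells with all-zero
#' marker signal are labelled `"unassigned"`.
#'
#' @param Xp Preprocessed matrix from [preprocess_intensities()] with
#'   channel column names.
#' @param marker_map Named character vector: `c(channel = population, ...)`.
#' @return Character vector of population labels, one per cell.
#' @export
annotate_by_markers <- function(Xp, marker_map) {
  if (length(marker_map) == 0L) stop_validation("marker_map must not be empty")
  missing_ch <- setdiff(names(marker_map), colnames(Xp))
  if (length(missing_ch)) {
    stop_validation("marker channels absent from the matrix: ",
                    paste(missing_ch, collapse = ", "))
  }
  sub <- Xp[, names(marker_map), drop = FALSE]
  labels <- vapply(seq_len(nrow(sub)), function(i) {
    v <- sub[i, ]
    if (all(v == 0)) return("unassigned")
    unname(marker_map[which.max(v)])        # which.max: first max, lowest index
  }, character(1))
  labels
}

#' Refine labels by majority vote within clusters
#'
#' Every cluster is relabelled to its most prevalent label; ties go to the
#' lexicographically smallest label. Accepts any clustering (e.g. Leiden
#' cluster ids computed elsewhere).
#'
#' @param labels Character vector of per-cell labels.
#' @param clusters Per-cell cluster ids (same length).
#' @return Character vector of refined labels.
#' @export
refine_by_clusters <- function(labels, clusters) {
  if (length(labels) != length(clusters)) {
    stop_validation("labels and clusters must have the same length")
  }
  out <- labels
  for (cl in unique(clusters)) {
    idx <- which(clusters == cl)
    tab <- table(labels[idx])
    winners <- sort(names(tab)[tab == max(tab)])
    out[idx] <- winners[1]
  }
  out
}
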