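#' Dendrogram cut configuration
#'
#' @param height_ratio cut threshold as a fraction of the root merge height
#'   of the dendrogram, in (0, 1]; default 0.30.
#' @param min_cluster_size smallest cluster retained for selectivity
#'   analysis; default 5.
#' @param td_cutoff optional absolute Tanimoto-distance cut; when given it
#'   overrides `height_ratio` (absolute-threshold mode).
#' @return A list of class `cut_config`.
#' @export
cut_config <- function(height_ratio = 0.30, min_cluster_size = 5,
                       td_cutoff = NULL) {
  stopifnot(height_ratio > 0, height_ratio <= 1, min_cluster_size >= 1)
  if (!is.null(td_cutoff)) stopifnot(td_cutoff >= 0, td_cutoff <= 1)
  structure(list(height_ratio = height_ratio,
                 min_cluster_size = as.integer(min_cluster_size),
                 td_cutoff = td_cutoff),
            class = "cut_config")
}

#' Single-linkage clustering of a Tanimoto distance matrix
#'
#' Agglomerative clustering in which the distance between two clusters is
#' the smallest Tanimoto distance between any pair of their members, so a
#' cluster grows by chaining through its most similar neighbours. Merge
#' heights are therefore non-decreasing.
#'
#' @param distance a `selprof_matrices` object (its `distance` component is
#'   used), a symmetric distance matrix, or a `stats::dist` object.
#' @return A `stats::hclust` object with an extra `ligand_order` attribute
#'   (CIDs in leaf-index order); for a single ligand, a degenerate object
#'   with no merges.
#' @export
single_linkage <- function(distance) {
  if (inherits(distance, "selprof_matrices")) {
    d <- stats::as.dist(distance$distance)
  } else if (inherits(distance, "dist")) {
    d <- distance
  } else {
    m <- as.matrix(distance)
    stopifnot(isSymmetric(unname(m)))
    d <- stats::as.dist(m)
  }
  n <- attr(d, "Size")
  labels <- attr(d, "Labels")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 2) {
    hc <- structure(list(merge = matrix(integer(), 0, 2), height = numeric(),
                         order = seq_len(n), labels = labels,
                         method = "single"),
                    class = "hclust")
  } else {
    hc <- stats::hclust(d, method = "single")
  }
  attr(hc, "ligand_order") <- labels
  hc
}

#' Cut a dendrogram into clusters
#'
#' Ratio mode (default): the threshold is `height_ratio` times the root
#' merge height, and clusters are the connected components joined by merges
#' strictly below that threshold. Absolute mode (`td_cutoff` set): the
#' threshold is the given Tanimoto distance itself.
#'
#' @param dendrogram an `hclust` from [single_linkage()].
#' @param config a [cut_config()].
#' @return A list of character vectors (member labels per cluster), ordered
#'   by decreasing size then lowest leaf index; singletons included.
#' @export
cut_at_height_ratio <- function(dendrogram, config = cut_config()) {
  stopifnot(inherits(dendrogram, "hclust"))
  labels <- dendrogram$labels
  n <- length(labels)
  if (n == 1) return(list(labels))
  if (is.null(config$td_cutoff) && config$height_ratio >= 1) {
    return(list(labels))  # cut at the root: everything in one cluster
  }
  threshold <- if (!is.null(config$td_cutoff)) {
    config$td_cutoff
  } else {
    config$height_ratio * max(dendrogram$height)
  }
  # union-find over merges strictly below the threshold
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  node_rep <- integer(nrow(dendrogram$merge))  # leaf representative per merge
  for (k in seq_len(nrow(dendrogram$merge))) {
    a <- dendrogram$merge[k, 1]; b <- dendrogram$merge[k, 2]
    ra <- if (a < 0) -a else node_rep[a]
    rb <- if (b < 0) -b else node_rep[b]
    node_rep[k] <- ra
    if (dendrogram$height[k] < threshold) {
      parent[find(rb)] <- find(ra)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  # order: decreasing size, ties by lowest member leaf index
  sz <- vapply(groups, length, integer(1))
  lo <- vapply(groups, min, integer(1))
  groups <- unname(groups[order(-sz, lo)])
  lapply(groups, function(ix) labels[sort(ix)])
}

#' Filter clusters by minimum size
#'
#' @param clusters list of clusters from [cut_at_height_ratio()].
#' @param config a [cut_config()].
#' @return The clusters with at least `min_cluster_size` members, order
#'   preserved; warns when nothing survives.
#' @export
filter_clusters <- function(clusters, config = cut_config()) {
  out <- clusters[vapply(clusters, length, integer(1)) >= config$min_cluster_size]
  if (length(out) == 0) warning("no cluster reaches the minimum size")
  out
}

#' Export a dendrogram as Newick text
#'
#' Nested-parenthesis serialisation with merge heights as internal-node
#' branch support values; leaf branch lengths are measured from the leaf
#' (height 0) to its first merge.
#'
#' @param dendrogram an `hclust` from [single_linkage()].
#' @param path optional file to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(dendrogram, path = NULL) {
  labels <- dendrogram$labels
  m <- dendrogram$merge
  h <- dendrogram$height
  node_txt <- character(nrow(m))
  node_h <- numeric(nrow(m))
  txt_of <- function(x) if (x < 0) labels[-x] else node_txt[x]
  h_of <- function(x) if (x < 0) 0 else node_h[x]
  for (k in seq_len(nrow(m))) {
    bl <- function(x) sprintf("%s:%g", txt_of(x), h[k] - h_of(x))
    node_txt[k] <- paste0("(", bl(m[k, 1]), ",", bl(m[k, 2]), ")")
    node_h[k] <- h[k]
  }
  s <- if (nrow(m) == 0) paste0(labels, ";") else paste0(node_txt[nrow(m)], ";")
  if (!is.null(path)) { writeLines(s, path); return(invisible(s)) }
  s
}
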