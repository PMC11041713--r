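#' Euclidean distance matrix between community profiles
#'
#' Distances are computed on per-sample relative abundances by default
#' (depth artifacts removed); set `use_relative = FALSE` for raw counts.
#'
#' @param table an [otu_table()] with at least 2 samples, or a plain
#'   numeric matrix of abundances (samples in rows).
#' @param use_relative convert counts to proportions first (default TRUE;
#'   ignored for plain matrices, which are used as given).
#' @return symmetric matrix of pairwise Euclidean distances, zero diagonal.
#' @export
euclidean_distance_matrix <- function(table, use_relative = TRUE) {
  m <- if (inherits(table, "otu_table") && use_relative)
    relative_abundance(table) else unclass(table)
  if (nrow(m) < 2)
    stop("euclidean_distance_matrix: need at least 2 samples", call. = FALSE)
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' UPGMA (average-linkage) hierarchical clustering
#'
#' Agglomerates samples by unweighted pair-group average linkage: the
#' distance between two clusters is the mean of all between-cluster pairwise
#' distances, so merges are weighted by cluster sizes and merge heights are
#' non-decreasing (the tree is ultrametric).
#'
#' @param dist_matrix symmetric distance matrix (no NAs) or a `dist`.
#' @return an `hclust` object of class `c("upgma", "hclust")`; heights are
#'   average-linkage merge distances.
#' @export
upgma <- function(dist_matrix) {
  d <- if (inherits(dist_matrix, "dist")) dist_matrix else stats::as.dist(dist_matrix)
  if (anyNA(d)) stop("upgma: NA in distance matrix", call. = FALSE)
  h <- stats::hclust(d, method = "average")
  class(h) <- c("upgma", "hclust")
  h
}

#' Cut a UPGMA tree and summarize cluster composition against labels
#'
#' Cuts the dendrogram into `k` clusters and reports, per cluster, its
#' members and the fraction of samples in each group (e.g. above-kimberlite
#' vs background) — the wedge/pie summary used to ask whether clusters are
#' enriched in on-deposit soils.
#'
#' @param tree an `hclust`/`upgma` tree.
#' @param k number of clusters, between 1 and the number of samples. The
#'   default is chosen by the largest gap in merge heights.
#' @param metadata metadata data frame with `sample_id` and `group`.
#' @return data frame: one row per cluster with `cluster_id`, `n`,
#'   comma-separated `members`, and one `frac_<group>` column per group
#'   label present; fractions sum to 1 within each cluster.
#' @export
cut_and_summarize <- function(tree, k = NULL, metadata) {
  n <- length(tree$labels)
  if (is.null(k)) {
    hs <- sort(tree$height)
    gap <- which.max(diff(c(0, hs)))
    k <- n - gap + 1L
  }
  if (k < 1 || k > n)
    stop("cut_and_summarize: k must be in [1, ", n, "]", call. = FALSE)
  cl <- stats::cutree(tree, k = k)
  groups <- metadata$group[match(names(cl), metadata$sample_id)]
  lvls <- sort(unique(metadata$group))
  out <- lapply(sort(unique(cl)), function(ci) {
    sel <- cl == ci
    fr <- vapply(lvls, function(g) mean(groups[sel] == g), numeric(1))
    cbind(data.frame(cluster_id = ci, n = sum(sel),
                     members = paste(names(cl)[sel], collapse = ","),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(fr, paste0("frac_", lvls)))))
  })
  do.call(rbind, out)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths encode the UPGMA merge heights (leaf-to-root path length
#' equals half the cophenetic distance to the farthest leaf).
#'
#' @param tree an `hclust`/`upgma` tree.
#' @param path optional file to write; with `NULL` the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(stats::as.hclust(tree))
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Cophenetic distances of a UPGMA tree
#'
#' @param tree an `hclust`/`upgma` tree.
#' @return symmetric matrix of cophenetic distances (merge heights).
#' @export
cophenetic_distances <- function(tree) {
  as.matrix(stats::cophenetic(stats::as.hclust(tree)))
}
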