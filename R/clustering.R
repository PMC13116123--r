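# Structural clustering of compounds from binary fingerprints: Jaccard
# distance + agglomerative hierarchical clustering cut at k groups.

#' Jaccard distance matrix between binary fingerprints
#'
#' `d(a, b) = 1 - |a AND b| / |a OR b|` (the complement of the Tanimoto
#' similarity used for structural fingerprints). Two all-zero vectors are at
#' distance 0 by convention.
#'
#' @param fp A binary (0/1) matrix, compounds in rows; rownames are compound
#'   ids.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
fingerprint_distance <- function(fp) {
  fp <- as.matrix(fp)
  if (nrow(fp) < 2L) abort_arg("need at least 2 compounds")
  if (anyDuplicated(rownames(fp))) abort_arg("duplicate compound ids")
  if (!all(fp %in% c(0, 1))) abort_arg("fingerprint entries must be 0/1")
  storage.mode(fp) <- "double"
  inter <- tcrossprod(fp)
  rs <- rowSums(fp)
  uni <- outer(rs, rs, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0        # pair of empty fingerprints
  diag(d) <- 0
  dimnames(d) <- list(rownames(fp), rownames(fp))
  d
}

#' Agglomerative hierarchical clustering of compounds
#'
#' Builds the merge tree under the chosen linkage and cuts it into exactly
#' `k` clusters. Merging is deterministic: `stats::hclust` breaks equal-height
#' ties by the order pairs appear in the distance object, so a fixed input
#' yields a fixed tree.
#'
#' @param dist A symmetric distance matrix (e.g. from
#'   [fingerprint_distance()]) or a [stats::dist] object.
#' @param k Number of clusters (<= number of compounds).
#' @param linkage `"average"` (default), `"complete"`, or `"single"`.
#' @return An object of class `compound_clusters`: list with `assignment`
#'   (named integer vector of labels 1..k, numbered in order of first
#'   appearance), `k`, `linkage`, and `tree` (the `hclust` object, whose
#'   `merge` and `height` components are the merge list).
#' @examples
#' sim <- gen_fingerprints(3, 5, 64, 0.02, seed = 1)
#' cl <- hierarchical_cluster(fingerprint_distance(sim$fingerprints), k = 3)
#' table(cl$assignment, sim$truth$cluster)
#' @export
hierarchical_cluster <- function(dist, k,
                                 linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  d <- if (inherits(dist, "dist")) dist else stats::as.dist(as.matrix(dist))
  n <- attr(d, "Size")
  k <- check_count(k, "k", min = 1L)
  if (k > n) abort_arg("`k` cannot exceed the number of compounds")
  tree <- stats::hclust(d, method = linkage)
  raw <- stats::cutree(tree, k = k)
  # relabel so cluster 1 is the first compound's cluster, etc.
  lev <- unique(raw)
  assignment <- match(raw, lev)
  names(assignment) <- names(raw)
  structure(list(assignment = assignment, k = k, linkage = linkage,
                 tree = tree),
            class = "compound_clusters")
}

#' @export
print.compound_clusters <- function(x, ...) {
  cat("Hierarchical clustering (", x$linkage, " linkage): ",
      length(x$assignment), " compounds in ", x$k, " clusters\n", sep = "")
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Write a cluster assignment as CSV
#' @param clusters A `compound_clusters` object.
#' @param path Output path; columns compound_id, cluster.
#' @return `path`, invisibly.
#' @export
write_cluster_assignment <- function(clusters, path) {
  df <- data.frame(compound_id = names(clusters$assignment),
                   cluster = unname(clusters$assignment),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
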