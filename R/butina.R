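#' Butina sphere-exclusion clustering
#'
#' Deterministic diversity clustering on a Tanimoto similarity matrix:
#' molecules are ranked by how many neighbours they have at or above the
#' similarity threshold (ties broken by input order); the highest-ranked
#' unassigned molecule becomes a cluster centroid and claims all of its
#' still-unassigned neighbours; the sweep continues until every molecule
#' belongs to exactly one cluster.  Singletons are ordinary clusters of
#' size one.
#'
#' @param x Either a 0/1 fingerprint matrix (rows = molecules, e.g. from
#'   [morgan_fingerprints()]) or a symmetric similarity matrix with unit
#'   diagonal.
#' @param similarity_threshold Inclusion threshold for the Tanimoto
#'   coefficient, in (0, 1] (default 0.5).
#' @return Data frame in input order with columns `ligand_id`,
#'   `cluster_id` (numbered in order of cluster creation) and
#'   `is_centroid`.
#' @examples
#' fp <- morgan_fingerprints(c(a = "c1ccccc1O", b = "c1ccccc1N",
#'                             c = "CCCCS"))
#' butina_cluster(fp, 0.5)
#' @export
butina_cluster <- function(x, similarity_threshold = 0.5) {
  if (!is.numeric(similarity_threshold) ||
      length(similarity_threshold) != 1L ||
      similarity_threshold <= 0 || similarity_threshold > 1)
    stop("similarity_threshold must lie in (0, 1]", call. = FALSE)
  x <- as.matrix(x)
  if (nrow(x) == ncol(x) && isSymmetric(unname(x)) &&
      all(abs(diag(x) - 1) < 1e-12) && all(x >= 0) && all(x <= 1)) {
    sim <- x
  } else {
    sim <- tanimoto_matrix(x)
  }
  n <- nrow(sim)
  if (n < 1L) stop("need at least one molecule", call. = FALSE)
  ids <- rownames(sim)
  if (is.null(ids)) ids <- paste0("mol", seq_len(n))

  nbr <- lapply(seq_len(n), function(i)
    setdiff(which(sim[i, ] >= similarity_threshold), i))
  counts <- lengths(nbr)
  cand_order <- order(-counts, seq_len(n))  # ties: input order

  cluster_id <- integer(n)
  centroid <- logical(n)
  next_cluster <- 0L
  for (i in cand_order) {
    if (cluster_id[i] != 0L) next
    next_cluster <- next_cluster + 1L
    members <- c(i, nbr[[i]][cluster_id[nbr[[i]]] == 0L])
    cluster_id[members] <- next_cluster
    centroid[i] <- TRUE
  }
  data.frame(ligand_id = ids, cluster_id = cluster_id,
             is_centroid = centroid, stringsAsFactors = FALSE)
}

#' Cluster-size summary
#'
#' @param clusters Result of [butina_cluster()].
#' @return List with the number of clusters, number of singletons and
#'   the largest cluster size.
#' @export
cluster_summary <- function(clusters) {
  sizes <- table(clusters$cluster_id)
  list(n_clusters = length(sizes),
       n_singletons = sum(sizes == 1L),
       max_size = max(sizes))
}
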