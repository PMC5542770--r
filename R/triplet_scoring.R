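# Scoring a single position triplet: one-hot encoding of the reduced
# three-column alignment, PCA projection, hierarchical clustering with a
# data-driven cutoff, and the cluster-purity mixing entropy H.

#' One-hot encode a position triplet
#'
#' Builds the reduced alignment consisting only of the three given columns
#' and encodes each sequence as the concatenation of three indicator
#' vectors over the fixed 22-symbol alphabet (20 amino acids, \code{'X'},
#' gap).  Non-standard residue letters (B, Z, J, U, O, ...) are mapped to
#' \code{'X'}.
#'
#' @param aln A \code{pda_alignment}.
#' @param positions Integer vector of three distinct 1-based column indices.
#' @return A \code{pda_encoding}: list with \code{coordinates} (an
#'   \code{n_seq x 66} 0/1 matrix whose rows each sum to 3), \code{ids}
#'   and \code{positions}.
#' @export
encode_triplet <- function(aln, positions) {
  stopifnot(inherits(aln, "pda_alignment"))
  positions <- as.integer(positions)
  if (length(positions) != 3L || anyNA(positions))
    stop_input("positions must be three column indices")
  if (anyDuplicated(positions))
    stop_input("positions must be distinct")
  if (any(positions < 1L | positions > aln$width))
    stop_input(sprintf("positions out of range [1, %d]", aln$width))
  q <- length(AA_ALPHABET_ENC)
  n <- length(aln$ids)
  X <- matrix(0, n, 3L * q)
  for (j in seq_len(3L)) {
    col <- substr(aln$seqs, positions[j], positions[j])
    idx <- match(col, AA_ALPHABET_ENC)
    idx[is.na(idx)] <- match("X", AA_ALPHABET_ENC)
    X[cbind(seq_len(n), (j - 1L) * q + idx)] <- 1
  }
  colnames(X) <- paste0(rep(positions, each = q), ".",
                        rep(AA_ALPHABET_ENC, 3L))
  structure(list(coordinates = X, ids = aln$ids, positions = positions),
            class = "pda_encoding")
}

#' Project an encoding onto its maximum-variance subspace
#'
#' Mean-centers the encoding and computes principal-component scores,
#' keeping the smallest number of leading components whose cumulative
#' explained variance reaches \code{variance_kept}.  Component signs are
#' fixed by the convention that each component's largest-magnitude loading
#' is positive.  If the encoding has zero total variance (all rows
#' identical) a single all-zero coordinate is returned.
#'
#' @param enc A \code{pda_encoding} (or any list with a numeric
#'   \code{coordinates} matrix and \code{ids}).
#' @param variance_kept Fraction of total variance to retain, in
#'   \eqn{(0, 1]}. Default 0.95; use 1.0 to keep all components (a
#'   distance-preserving rotation of the raw encoding).
#' @return A \code{pda_projection}: list with \code{coordinates}
#'   (\code{n_seq x d'} scores), \code{explained_variance_fraction} and
#'   \code{ids}.
#' @export
project_pca <- function(enc, variance_kept = 0.95) {
  X <- enc$coordinates
  if (!is.matrix(X)) stop_input("encoding must contain a coordinates matrix")
  if (!is.numeric(variance_kept) || variance_kept <= 0 || variance_kept > 1)
    stop_input("variance_kept must be in (0, 1]")
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  e <- eigen(crossprod(Xc), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  tot <- sum(ev)
  if (tot <= .Machine$double.eps * n) {
    S <- matrix(0, n, 1L)
    return(structure(list(coordinates = S,
                          explained_variance_fraction = 1,
                          ids = enc$ids),
                     class = "pda_projection"))
  }
  cum <- cumsum(ev) / tot
  dprime <- which(cum >= variance_kept - 1e-12)[1L]
  V <- e$vectors[, seq_len(dprime), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (k in seq_len(dprime)) {
    pivot <- which.max(abs(V[, k]))
    if (V[pivot, k] < 0) V[, k] <- -V[, k]
  }
  structure(list(coordinates = Xc %*% V,
                 explained_variance_fraction = cum[dprime],
                 ids = enc$ids),
            class = "pda_projection")
}

# Lower-triangle Euclidean distance matrix via BLAS; returns "dist".
euclid_dist_ <- function(S) {
  G <- tcrossprod(S)
  dg <- diag(G)
  D2 <- outer(dg, dg, "+") - 2 * G
  D2[D2 < 0] <- 0
  stats::as.dist(sqrt(D2))
}

#' Cluster sequences in the projected subspace
#'
#' Agglomerative hierarchical clustering of the projected coordinates on
#' Euclidean distances.  The dendrogram is cut at a height equal to the
#' average of all pairwise sequence distances, so the number of clusters
#' is set by the data rather than chosen explicitly; merges at exactly the
#' cutoff height are kept merged (ties merge), so two points at exactly
#' the average distance form one cluster.
#'
#' @param proj A \code{pda_projection}.
#' @param linkage Agglomeration method: \code{"average"} (default),
#'   \code{"complete"}, \code{"single"} or \code{"ward"} (Ward's method on
#'   distances, \code{hclust}'s \code{"ward.D2"}).
#' @return A \code{pda_clusters}: list with integer \code{labels} (1-based,
#'   contiguous), \code{n_clusters}, \code{weights} (fraction of sequences
#'   per cluster, summing to 1), \code{cutoff} and \code{ids}.
#' @export
cluster_sequences <- function(proj,
                              linkage = c("average", "ward", "complete",
                                          "single")) {
  linkage <- match.arg(linkage)
  S <- proj$coordinates
  n <- nrow(S)
  if (n < 1L) stop_input("projection contains no sequences")
  if (n == 1L) {
    labels <- 1L
    cutoff <- 0
  } else {
    dd <- euclid_dist_(S)
    cutoff <- mean(dd)
    method <- if (linkage == "ward") "ward.D2" else linkage
    hc <- stats::hclust(dd, method = method)
    labels <- unname(stats::cutree(hc, h = cutoff))
    # relabel contiguously in order of first appearance
    labels <- match(labels, unique(labels))
  }
  w <- as.numeric(tabulate(labels)) / n
  structure(list(labels = labels, n_clusters = max(labels),
                 weights = w, cutoff = cutoff, ids = proj$ids),
            class = "pda_clusters")
}

#' Shannon entropy of a group-label multiset
#'
#' \eqn{h(c) = -\sum_i P(i_c) \log P(i_c)} with natural logarithm and
#' \eqn{0 \log 0 = 0}, where \eqn{P(i_c)} is the fraction of members
#' belonging to phylogenetic group \eqn{i}.
#'
#' @param groups Non-empty vector of group labels.
#' @return Non-negative entropy in nats.
#' @examples
#' cluster_entropy(c("A", "A", "A"))  # 0
#' cluster_entropy(c("A", "B"))       # log(2)
#' @export
cluster_entropy <- function(groups) {
  if (length(groups) == 0L) stop_input("cluster_entropy: empty group multiset")
  p <- as.numeric(table(groups)) / length(groups)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Cluster-weighted mixing entropy of a clustering
#'
#' The mixing score \eqn{H(C) = \sum_{c \in C} w(c)\, h(c)}: the average,
#' weighted by cluster size fraction \eqn{w(c)}, of the Shannon entropies
#' of the phylogenetic group labels within each cluster.  Lower H means
#' less mixing of groups within clusters, i.e. the underlying position
#' triplet discriminates the groups better.
#'
#' @param assign A \code{pda_clusters}.
#' @param ann Annotation data frame (columns \code{id}, \code{group},
#'   \code{organism}) covering every clustered sequence, or a character
#'   vector of group labels named by sequence id.
#' @return A \code{pda_mixing}: list with \code{H},
#'   \code{per_cluster_entropy} and \code{weights}.
#' @export
mixing_score <- function(assign, ann) {
  stopifnot(inherits(assign, "pda_clusters"))
  groups <- if (is.data.frame(ann)) {
    annotation_groups(ann, assign$ids)
  } else {
    idx <- match(assign$ids, names(ann))
    if (anyNA(idx))
      stop_lookup(sprintf("no annotation for sequence id '%s'",
                          assign$ids[which(is.na(idx))[1L]]))
    unname(ann[idx])
  }
  hs <- vapply(seq_len(assign$n_clusters), function(c)
    cluster_entropy(groups[assign$labels == c]), numeric(1))
  structure(list(H = sum(assign$weights * hs),
                 per_cluster_entropy = hs,
                 weights = assign$weights),
            class = "pda_mixing")
}

#' Mixing score of one position triplet
#'
#' Convenience composition: encode the three columns, project by PCA,
#' cluster with the average-distance cutoff, and return the mixing
#' entropy H.
#'
#' @inheritParams encode_triplet
#' @inheritParams project_pca
#' @inheritParams cluster_sequences
#' @param ann Annotation data frame or named group-label vector.
#' @return Numeric mixing score H.
#' @export
score_triplet <- function(aln, ann, positions, variance_kept = 0.95,
                          linkage = "average") {
  enc <- encode_triplet(aln, positions)
  proj <- project_pca(enc, variance_kept = variance_kept)
  cl <- cluster_sequences(proj, linkage = linkage)
  mixing_score(cl, ann)$H
}
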