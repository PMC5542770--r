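# Scanning position triplets: enumeration/sampling, the mixing-score table,
# empirical p-values, position selection frequencies and the uniform-prior
# null model for calling discriminating positions.

#' Enumerate all position triplets
#'
#' All \eqn{\binom{N_{pos}}{3}} strictly increasing triples
#' \eqn{(i < j < k)} of 1-based column indices, in lexicographic order.
#'
#' @param N_pos Alignment width (number of columns), at least 3.
#' @return Integer matrix with 3 columns \code{i}, \code{j}, \code{k}.
#' @examples
#' nrow(enumerate_triplets(70))  # 54740
#' @export
enumerate_triplets <- function(N_pos) {
  N_pos <- as.integer(N_pos)
  if (is.na(N_pos) || N_pos < 3L)
    stop_input("N_pos must be an integer >= 3")
  m <- t(utils::combn(N_pos, 3L))
  colnames(m) <- c("i", "j", "k")
  m
}

# Lexicographic unranking of 3-combinations of 1..N (rank 1-based).
unrank_triplet_ <- function(rank, N) {
  r <- rank - 1
  i <- 1L
  while (TRUE) {
    block <- choose(N - i, 2)
    if (r < block) break
    r <- r - block
    i <- i + 1L
  }
  j <- i + 1L
  while (TRUE) {
    block <- N - j
    if (r < block) break
    r <- r - block
    j <- j + 1L
  }
  as.integer(c(i, j, j + 1 + r))
}

#' Sample distinct position triplets uniformly
#'
#' Draws \code{m_sample} distinct triplets uniformly without replacement
#' from the \eqn{\binom{N_{pos}}{3}} possibilities, reproducibly for a
#' fixed seed.  Used to limit the computational burden on wide alignments
#' where the exhaustive scan is impractical.
#'
#' @param N_pos Alignment width, at least 3.
#' @param m_sample Number of triplets to draw.
#' @param seed Integer RNG seed.
#' @return Integer matrix with columns \code{i}, \code{j}, \code{k}, rows
#'   in lexicographic order.
#' @export
sample_triplets <- function(N_pos, m_sample, seed = 1L) {
  N_pos <- as.integer(N_pos)
  if (is.na(N_pos) || N_pos < 3L) stop_input("N_pos must be an integer >= 3")
  total <- choose(N_pos, 3)
  if (m_sample < 1 || m_sample > total)
    stop_input(sprintf("m_sample must be in [1, %d]", total))
  ranks <- sort(with_seed_(seed, sample.int(total, m_sample)))
  m <- t(vapply(ranks, unrank_triplet_, integer(3), N = N_pos))
  storage.mode(m) <- "integer"
  colnames(m) <- c("i", "j", "k")
  m
}

# Internal scan engine.  Equivalent to score_triplet() per row but reuses
# per-column indicator blocks (over observed symbols only; dropping the
# all-zero one-hot columns changes neither the PCA spectrum nor any
# pairwise distance) and computes distances via BLAS.
scan_engine_ <- function(mat, groups_int, triplets, variance_kept, linkage) {
  n <- nrow(mat)
  method <- if (linkage == "ward") "ward.D2" else linkage
  blocks <- lapply(seq_len(ncol(mat)), function(j) {
    f <- factor(mat[, j])
    if (nlevels(f) == 1L) matrix(1, n, 1L)
    else diag(nlevels(f))[as.integer(f), , drop = FALSE]
  })
  G <- max(groups_int)
  vapply(seq_len(nrow(triplets)), function(r) {
    tr <- triplets[r, ]
    X <- cbind(blocks[[tr[1L]]], blocks[[tr[2L]]], blocks[[tr[3L]]])
    Xc <- sweep(X, 2L, colMeans(X))
    e <- eigen(crossprod(Xc), symmetric = TRUE)
    ev <- pmax(e$values, 0)
    tot <- sum(ev)
    if (tot <= .Machine$double.eps * n) {
      labels <- rep(1L, n)
    } else {
      cum <- cumsum(ev) / tot
      dprime <- which(cum >= variance_kept - 1e-12)[1L]
      S <- Xc %*% e$vectors[, seq_len(dprime), drop = FALSE]
      dd <- euclid_dist_(S)
      hc <- stats::hclust(dd, method = method)
      labels <- stats::cutree(hc, h = mean(dd))
    }
    H <- 0
    for (c in unique(labels)) {
      g <- groups_int[labels == c]
      p <- tabulate(g, nbins = G) / length(g)
      p <- p[p > 0]
      H <- H - (length(g) / n) * sum(p * log(p))
    }
    H
  }, numeric(1))
}

#' Score a set of position triplets
#'
#' Computes the mixing score H for each triplet by the
#' encode / project / cluster / entropy pipeline of
#' \code{\link{score_triplet}}.  Deterministic given the alignment,
#' annotations and configuration.
#'
#' @param aln A \code{pda_alignment}.
#' @param ann Annotation data frame covering every alignment sequence.
#' @param triplets Integer matrix of distinct triplets (columns i, j, k,
#'   1-based, strictly increasing), e.g. from
#'   \code{\link{enumerate_triplets}} or \code{\link{sample_triplets}}.
#' @param variance_kept Fraction of PCA variance retained. Default 0.95.
#' @param linkage Clustering linkage. Default \code{"average"}.
#' @param scan_mode Recorded provenance tag: \code{"exhaustive"} or
#'   \code{"sampled"}.
#' @param seed Seed recorded for sampled scans (provenance only).
#' @return A \code{pda_score_table}: data frame with columns \code{i},
#'   \code{j}, \code{k}, \code{H} and attributes \code{N_pos},
#'   \code{n_scanned}, \code{scan_mode}, \code{seed}.
#' @export
scan_triplets <- function(aln, ann, triplets, variance_kept = 0.95,
                          linkage = c("average", "ward", "complete",
                                      "single"),
                          scan_mode = "exhaustive", seed = NULL) {
  stopifnot(inherits(aln, "pda_alignment"))
  linkage <- match.arg(linkage)
  triplets <- as.matrix(triplets)
  if (ncol(triplets) != 3L) stop_input("triplets must have three columns")
  if (any(triplets[, 1L] >= triplets[, 2L] | triplets[, 2L] >= triplets[, 3L]))
    stop_input("triplets must be strictly increasing (i < j < k)")
  if (any(triplets < 1L | triplets > aln$width))
    stop_input(sprintf("triplet positions out of range [1, %d]", aln$width))
  key <- paste(triplets[, 1L], triplets[, 2L], triplets[, 3L])
  if (anyDuplicated(key))
    stop_input(sprintf("duplicate triplet in input: (%s)",
                       key[duplicated(key)][1L]))
  groups <- annotation_groups(ann, aln$ids)
  groups_int <- as.integer(factor(groups))
  mat <- as.matrix(aln)
  H <- scan_engine_(mat, groups_int, triplets, variance_kept, linkage)
  out <- data.frame(i = as.integer(triplets[, 1L]),
                    j = as.integer(triplets[, 2L]),
                    k = as.integer(triplets[, 3L]),
                    H = H)
  attr(out, "N_pos") <- aln$width
  attr(out, "n_scanned") <- nrow(out)
  attr(out, "scan_mode") <- scan_mode
  attr(out, "seed") <- seed
  class(out) <- c("pda_score_table", "data.frame")
  out
}

#' Empirical p-value of a mixing score
#'
#' The fraction of scanned triplets with mixing score less than or equal
#' to \code{H_ref} (self-inclusive, so the minimum attainable p-value is
#' \eqn{1/T} when \code{H_ref} is itself a scanned score).
#'
#' @param table A \code{pda_score_table}.
#' @param H_ref Reference mixing score.
#' @return p-value in \eqn{(0, 1]} for scanned reference scores.
#' @export
empirical_pvalue <- function(table, H_ref) {
  if (nrow(table) < 1L) stop_input("empty score table")
  mean(table$H <= H_ref)
}

#' Reference mixing-score threshold
#'
#' Either the score of a designated biologically motivated reference
#' triplet (which must have been scanned), or, when no reference triplet
#' is available, the score delimiting a lower percentile of the empirical
#' score distribution (no interpolation; ties at the cut value included,
#' so for a table of 100 scores the 5th percentile is the 5th-smallest
#' score).
#'
#' @param table A \code{pda_score_table}.
#' @param mode \code{"reference_triplet"} or \code{"percentile"}.
#' @param ref For mode \code{"reference_triplet"}: length-3 integer vector
#'   (i, j, k).  For mode \code{"percentile"}: percentile in (0, 100].
#' @return The reference mixing score H.
#' @export
reference_threshold <- function(table,
                                mode = c("reference_triplet", "percentile"),
                                ref) {
  mode <- match.arg(mode)
  if (nrow(table) < 1L) stop_input("empty score table")
  if (mode == "reference_triplet") {
    ref <- sort(as.integer(ref))
    if (length(ref) != 3L) stop_input("reference triplet must have 3 positions")
    hit <- which(table$i == ref[1L] & table$j == ref[2L] & table$k == ref[3L])
    if (length(hit) != 1L)
      stop_lookup(sprintf("reference triplet (%d,%d,%d) was not scanned",
                          ref[1L], ref[2L], ref[3L]))
    table$H[hit]
  } else {
    p <- as.numeric(ref)
    if (is.na(p) || p <= 0 || p > 100)
      stop_input("percentile must be in (0, 100]")
    sorted <- sort(table$H)
    idx <- max(1L, floor(p / 100 * length(sorted)))
    sorted[idx]
  }
}

#' Per-position selection frequency among strongly discriminating triplets
#'
#' Selects the strongly discriminating triplets and computes, for every
#' alignment position, the fraction of selected triplets in which it
#' appears.  With \code{inclusive = FALSE} (the reference-triplet
#' convention) only triplets scoring strictly lower than the reference
#' are selected, so a reference triplet is never in its own selected set;
#' with \code{inclusive = TRUE} (the percentile convention) ties at the
#' cut value are included.  Each selected triplet contributes three
#' position appearances, so the frequencies sum to exactly 3 when any
#' triplet is selected.
#'
#' @param table A \code{pda_score_table}.
#' @param reference_H Reference mixing score (selection cutoff).
#' @param inclusive Include triplets tied with \code{reference_H}?
#'   Default \code{FALSE} (strict).
#' @return List with \code{frequency} (numeric vector of length
#'   \code{N_pos}) and \code{m} (number of selected triplets).  When no
#'   triplet beats the reference a warning is emitted and all frequencies
#'   are 0.
#' @export
position_selection_frequency <- function(table, reference_H,
                                         inclusive = FALSE) {
  if (nrow(table) < 1L) stop_input("empty score table")
  N_pos <- attr(table, "N_pos")
  if (is.null(N_pos)) N_pos <- max(table$k)
  sel <- if (inclusive) table$H <= reference_H else table$H < reference_H
  m <- sum(sel)
  if (m == 0L) {
    warning("no triplet scores below the reference; all frequencies are 0")
    return(list(frequency = numeric(N_pos), m = 0L))
  }
  counts <- tabulate(c(table$i[sel], table$j[sel], table$k[sel]),
                     nbins = N_pos)
  list(frequency = counts / m, m = as.integer(m))
}

#' Uniform-prior null model for position selection frequencies
#'
#' Under a null in which selected triplets are uniformly distributed over
#' positions, each position's expected selection frequency is
#' \eqn{p_{null} = 3 / N_{pos}}, with standard error of the mean
#' \eqn{\sigma_p = \sqrt{p_{null}(1 - p_{null}) / m}} for \eqn{m} selected
#' triplets.  Positions whose frequency exceeds
#' \eqn{p_{null} + k\,\sigma_p} are outliers at the \eqn{k\sigma} level;
#' the conservative default calls 10-sigma outliers significant and the
#' less restrictive 3-sigma level is also reported.
#'
#' @param N_pos Alignment width, at least 3.
#' @param m Number of selected high-ranked triplets, at least 1.
#' @param k_sigmas Numeric vector of sigma multipliers. Default
#'   \code{c(3, 10)}.
#' @return A \code{pda_null_model}: list with \code{N_pos}, \code{m},
#'   \code{p_null}, \code{sigma_p} and named vector \code{thresholds}.
#' @export
null_model <- function(N_pos, m, k_sigmas = c(3, 10)) {
  N_pos <- as.integer(N_pos)
  if (is.na(N_pos) || N_pos < 3L) stop_input("N_pos must be an integer >= 3")
  if (length(m) != 1L || is.na(m) || m < 1)
    stop_input("m must be a positive count (sigma_p undefined for m = 0)")
  p_null <- 3 / N_pos
  sigma_p <- sqrt(p_null * (1 - p_null) / m)
  thresholds <- p_null + k_sigmas * sigma_p
  names(thresholds) <- as.character(k_sigmas)
  structure(list(N_pos = N_pos, m = as.integer(m), p_null = p_null,
                 sigma_p = sigma_p, thresholds = thresholds),
            class = "pda_null_model")
}

#' Select discriminating positions against the null model
#'
#' @param frequencies Numeric vector of per-position selection frequencies
#'   (length \code{N_pos}).
#' @param null A \code{pda_null_model} built for the same \code{N_pos}.
#' @param k_sigma Sigma multiplier for the outlier call. Default 10.
#' @return Integer vector of 1-based positions with frequency strictly
#'   above \eqn{p_{null} + k\,\sigma_p}.
#' @export
select_positions <- function(frequencies, null, k_sigma = 10) {
  stopifnot(inherits(null, "pda_null_model"))
  if (length(frequencies) != null$N_pos)
    stop_input("frequencies and null model disagree on N_pos")
  which(frequencies > null$p_null + k_sigma * null$sigma_p)
}

#' Run a full phylogenetic discriminant analysis
#'
#' Scans position triplets of an annotated alignment (exhaustively or by
#' uniform subsampling), scores each by the cluster-purity mixing entropy
#' H, computes the empirical p-value of the reference score, the
#' per-position selection frequencies among triplets scoring strictly
#' below the reference, and calls discriminating positions against the
#' uniform-prior null model.
#'
#' @param aln A \code{pda_alignment}.
#' @param ann Annotation data frame covering every sequence.
#' @param mode \code{"exhaustive"} (all \eqn{\binom{N}{3}} triplets) or
#'   \code{"sampled"}.
#' @param n_sample Number of triplets for \code{mode = "sampled"}.
#'   Default 50000.
#' @param seed RNG seed for triplet sampling. Default 1.
#' @param reference_triplet Optional length-3 integer vector; when given,
#'   its score is the selection cutoff, otherwise the \code{percentile}
#'   cut of the score distribution is used.
#' @param percentile Reference percentile used when no reference triplet
#'   is available. Default 5.
#' @param k_sigmas Sigma levels at which positions are called. Default
#'   \code{c(3, 10)}.
#' @param variance_kept Fraction of PCA variance retained. Default 0.95.
#' @param linkage Clustering linkage. Default \code{"average"}.
#' @return A \code{pda_result}: list with \code{score_table},
#'   \code{reference_H}, \code{reference_mode}, \code{empirical_p},
#'   \code{selection_frequency}, \code{m_selected}, \code{null},
#'   \code{selected_positions} (list keyed by sigma level) and
#'   \code{config}.
#' @export
run_pda <- function(aln, ann, mode = c("exhaustive", "sampled"),
                    n_sample = 50000L, seed = 1L,
                    reference_triplet = NULL, percentile = 5,
                    k_sigmas = c(3, 10), variance_kept = 0.95,
                    linkage = "average") {
  mode <- match.arg(mode)
  triplets <- if (mode == "exhaustive") enumerate_triplets(aln$width)
              else sample_triplets(aln$width, n_sample, seed = seed)
  tab <- scan_triplets(aln, ann, triplets, variance_kept = variance_kept,
                       linkage = linkage, scan_mode = mode,
                       seed = if (mode == "sampled") seed else NULL)
  if (!is.null(reference_triplet)) {
    ref_mode <- "reference_triplet"
    reference_H <- reference_threshold(tab, "reference_triplet",
                                       reference_triplet)
  } else {
    ref_mode <- "percentile"
    reference_H <- reference_threshold(tab, "percentile", percentile)
  }
  empirical_p <- empirical_pvalue(tab, reference_H)
  freq <- position_selection_frequency(tab, reference_H,
                                       inclusive = (ref_mode == "percentile"))
  if (freq$m >= 1L) {
    null <- null_model(aln$width, freq$m, k_sigmas = k_sigmas)
    selected <- lapply(k_sigmas, function(k)
      select_positions(freq$frequency, null, k_sigma = k))
    names(selected) <- as.character(k_sigmas)
  } else {
    null <- NULL
    selected <- stats::setNames(
      rep(list(integer(0)), length(k_sigmas)), as.character(k_sigmas))
  }
  structure(list(score_table = tab,
                 reference_H = reference_H,
                 reference_mode = ref_mode,
                 empirical_p = empirical_p,
                 selection_frequency = freq$frequency,
                 m_selected = freq$m,
                 null = null,
                 selected_positions = selected,
                 config = list(mode = mode,
                               n_sample = if (mode == "sampled") n_sample,
                               seed = if (mode == "sampled") seed,
                               reference_triplet = reference_triplet,
                               percentile = percentile,
                               k_sigmas = k_sigmas,
                               variance_kept = variance_kept,
                               linkage = linkage)),
            class = "pda_result")
}

#' @export
print.pda_result <- function(x, ...) {
  cat(sprintf("Phylogenetic discriminant analysis (%s scan, %d triplets)\n",
              attr(x$score_table, "scan_mode"),
              attr(x$score_table, "n_scanned")))
  cat(sprintf("  reference H = %.6f (%s), empirical p = %.4g\n",
              x$reference_H, x$reference_mode, x$empirical_p))
  cat(sprintf("  selected triplets m = %d\n", x$m_selected))
  for (k in names(x$selected_positions)) {
    pos <- x$selected_positions[[k]]
    cat(sprintf("  positions above %s-sigma: %s\n", k,
                if (length(pos)) paste(pos, collapse = ", ") else "(none)"))
  }
  invisible(x)
}

#' Re-run the analysis under an alternative group partition
#'
#' Robustness check: relabels the phylogenetic groups through a total
#' mapping (coarser or finer partition) and repeats the full scan with an
#' otherwise identical configuration.
#'
#' @inheritParams run_pda
#' @param grouping_map Named character vector mapping every observed group
#'   label to its new label.
#' @param grouping_name Optional tag recorded on the result.
#' @param ... Passed to \code{\link{run_pda}}.
#' @return A \code{pda_result} with an added \code{grouping} element.
#' @export
regroup_and_rescan <- function(aln, ann, grouping_map, grouping_name = NULL,
                               ...) {
  observed <- unique(ann$group)
  unmapped <- setdiff(observed, names(grouping_map))
  if (length(unmapped))
    stop_lookup(sprintf("grouping_map does not cover group(s): %s",
                        paste(unmapped, collapse = ", ")))
  ann2 <- ann
  ann2$group <- unname(grouping_map[ann$group])
  res <- run_pda(aln, ann2, ...)
  res$grouping <- grouping_name %||% "relabeled"
  res
}
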