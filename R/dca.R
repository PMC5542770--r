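# Ensemble random-paralog-matching direct coupling analysis: per-organism
# one-to-one matchings, concatenated alignments, sequence reweighting, a
# regularized mean-field coupling scorer with average-product correction,
# and aggregation of inter-protein pairs recurring across realizations.

#' Bundle two annotated families sharing an organism universe
#'
#' @param aln_a,aln_b \code{pda_alignment}s for family A and family B.
#' @param ann_a,ann_b Annotation data frames (columns \code{id},
#'   \code{group}, \code{organism}) covering the respective alignments.
#' @return A \code{pda_paired_family}: list with the four inputs plus
#'   \code{organisms} (the union of organism ids) and widths \code{N_a},
#'   \code{N_b}.
#' @export
paired_family <- function(aln_a, ann_a, aln_b, ann_b) {
  stopifnot(inherits(aln_a, "pda_alignment"), inherits(aln_b, "pda_alignment"))
  org_a <- annotation_organisms(ann_a, aln_a$ids)
  org_b <- annotation_organisms(ann_b, aln_b$ids)
  structure(list(aln_a = aln_a, ann_a = ann_a,
                 aln_b = aln_b, ann_b = ann_b,
                 organisms = union(org_a, org_b),
                 N_a = aln_a$width, N_b = aln_b$width),
            class = "pda_paired_family")
}

#' Sequence weights by identity-based reweighting
#'
#' Down-weights redundant sequences: each sequence receives weight
#' \eqn{1 / n_s} where \eqn{n_s} is the number of alignment sequences
#' (itself included) whose full-width identity with it is at least
#' \code{identity_threshold}.  Identity is the fraction of columns with
#' identical symbols over the full alignment width (gap-gap columns count
#' as matches).  The sum of the weights is the effective number of
#' sequences.
#'
#' @param aln A \code{pda_alignment}.
#' @param identity_threshold Identity fraction above which sequences are
#'   considered redundant. Default 0.90.
#' @return Numeric weight vector named by sequence id, with attributes
#'   \code{identity_threshold} and \code{n_effective}.
#' @export
sequence_weights <- function(aln, identity_threshold = 0.90) {
  stopifnot(inherits(aln, "pda_alignment"))
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop_input("identity_threshold must be in (0, 1]")
  mat <- as.matrix(aln)
  n <- nrow(mat)
  symbols <- unique(as.vector(mat))
  matches <- matrix(0, n, n)
  for (s in symbols) {
    ind <- mat == s
    storage.mode(ind) <- "double"
    matches <- matches + tcrossprod(ind)
  }
  neighbors <- rowSums(matches / aln$width >= identity_threshold - 1e-12)
  w <- 1 / neighbors
  names(w) <- aln$ids
  attr(w, "identity_threshold") <- identity_threshold
  attr(w, "n_effective") <- sum(w)
  w
}

#' Draw one random per-organism paralog matching
#'
#' Within each organism, pairs class A sequences one-to-one with class B
#' sequences chosen uniformly at random: every matched pair shares an
#' organism, no sequence of either family is used twice, and each
#' organism contributes exactly \code{min(#A, #B)} pairs (when one family
#' has more paralogs, a uniformly random subset of the excess side is
#' used).  Organisms present in only one family contribute no pairs.
#'
#' @param pf A \code{pda_paired_family}.
#' @param seed Integer RNG seed; the matching is reproducible per seed.
#' @return A \code{pda_matching}: data frame with character columns
#'   \code{a_id}, \code{b_id}, \code{organism} and attribute
#'   \code{realization_seed}.
#' @export
random_matching <- function(pf, seed = 1L) {
  stopifnot(inherits(pf, "pda_paired_family"))
  org_a <- annotation_organisms(pf$ann_a, pf$aln_a$ids)
  org_b <- annotation_organisms(pf$ann_b, pf$aln_b$ids)
  by_a <- split(pf$aln_a$ids, org_a)
  by_b <- split(pf$aln_b$ids, org_b)
  shared <- intersect(names(by_a), names(by_b))
  pairs <- with_seed_(seed, {
    res <- lapply(shared, function(org) {
      a <- by_a[[org]]
      b <- by_b[[org]]
      k <- min(length(a), length(b))
      if (length(a) > k) a <- sample(a, k)
      b <- sample(b, k)
      data.frame(a_id = a, b_id = b, organism = org,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  if (is.null(pairs))
    pairs <- data.frame(a_id = character(0), b_id = character(0),
                        organism = character(0), stringsAsFactors = FALSE)
  attr(pairs, "realization_seed") <- as.integer(seed)
  class(pairs) <- c("pda_matching", "data.frame")
  pairs
}

#' Concatenate matched sequence pairs into a joint alignment
#'
#' One record per matched pair: family A residues followed by family B
#' residues, id \code{"a_id|b_id"}, width \eqn{N_a + N_b}.
#'
#' @param pf A \code{pda_paired_family}.
#' @param matching A \code{pda_matching} (or data frame with columns
#'   \code{a_id}, \code{b_id}).
#' @return A \code{pda_alignment}, or a zero-record alignment marker for
#'   an empty matching.
#' @export
concatenate_pair <- function(pf, matching) {
  stopifnot(inherits(pf, "pda_paired_family"))
  if (nrow(matching) == 0L)
    return(structure(list(ids = character(0), seqs = character(0),
                          width = pf$N_a + pf$N_b),
                     class = "pda_alignment"))
  ia <- match(matching$a_id, pf$aln_a$ids)
  ib <- match(matching$b_id, pf$aln_b$ids)
  if (anyNA(ia))
    stop_lookup(sprintf("matched id '%s' not in family A alignment",
                        matching$a_id[which(is.na(ia))[1L]]))
  if (anyNA(ib))
    stop_lookup(sprintf("matched id '%s' not in family B alignment",
                        matching$b_id[which(is.na(ib))[1L]]))
  alignment(paste0(matching$a_id, "|", matching$b_id),
            paste0(pf$aln_a$seqs[ia], pf$aln_b$seqs[ib]))
}

# Map residues to integer states 1..21 (20 amino acids, then gap; 'X' and
# any non-standard letter are treated as gap for coupling estimation).
dca_states_ <- function(mat) {
  q <- length(AA20) + 1L
  idx <- match(mat, AA20)
  idx[is.na(idx)] <- q
  matrix(idx, nrow(mat), ncol(mat))
}

#' Mean-field direct coupling scores for a joint alignment
#'
#' The built-in coupling scorer: weighted single- and pairwise residue
#' frequencies with a relative pseudocount, the regularized mean-field
#' coupling estimate \eqn{J = -C^{-1}} from the inverse of the excess
#' covariance over the 20 non-gap states, a zero-sum-gauge Frobenius norm
#' per position pair, and the average-product correction (APC).  Returns
#' scores for the inter-protein block (family A columns x family B
#' columns); higher scores indicate stronger direct coupling.
#'
#' @param joint A \code{pda_alignment} of concatenated pairs, width
#'   \eqn{N_a + N_b}.
#' @param n_a Width of the family A block.
#' @param weights Optional sequence weights from
#'   \code{\link{sequence_weights}}; equal weights when omitted.
#' @param pseudocount Relative pseudocount weight in \eqn{(0, 1)}.
#'   Default 0.5, the customary mean-field choice.
#' @param min_seqs Minimum number of sequences required. Default 10.
#' @return Data frame with columns \code{pos_a}, \code{pos_b} (1-based
#'   within each family) and \code{score}; attribute \code{full_scores}
#'   holds the APC-corrected score matrix over all column pairs.
#' @export
coupling_scores <- function(joint, n_a, weights = NULL, pseudocount = 0.5,
                            min_seqs = 10L) {
  stopifnot(inherits(joint, "pda_alignment"))
  n_a <- as.integer(n_a)
  L <- joint$width
  if (n_a < 1L || n_a >= L)
    stop_input("n_a must split the joint alignment into two non-empty blocks")
  n <- length(joint$ids)
  if (n < min_seqs)
    stop_input(sprintf("too few sequences for coupling estimation (%d < %d)",
                       n, min_seqs))
  if (pseudocount <= 0 || pseudocount >= 1)
    stop_input("pseudocount must be in (0, 1)")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop_input("one weight per sequence required")
  w <- weights / sum(weights)
  states <- dca_states_(as.matrix(joint))
  q <- length(AA20) + 1L
  qm1 <- q - 1L           # modeled states: the 20 non-gap residues
  # indicator matrix over non-gap states, n x (L * 20)
  A <- matrix(0, n, L * qm1)
  for (i in seq_len(L)) {
    s <- states[, i]
    ok <- s < q
    A[cbind(which(ok), (i - 1L) * qm1 + s[ok])] <- 1
  }
  fi <- colSums(A * w)
  fij <- crossprod(A * w, A)          # weighted pair frequencies
  pc <- pseudocount
  fi_t <- (1 - pc) * fi + pc / q
  # shrinkage covariance: the empirical cross-column covariance scaled
  # by (1 - pc), with pseudocount-smoothed multinomial diagonal blocks.
  # Smoothing the joint and marginal frequencies separately would leave
  # a spurious covariance pc(1-pc)(f_i - 1/q)(f_j - 1/q) between
  # independent columns -- largest for conserved ones -- so the
  # off-diagonal blocks shrink the empirical covariance directly and
  # vanish exactly for independent or strictly conserved column pairs.
  C <- (1 - pc) * (fij - tcrossprod(fi))
  for (i in seq_len(L)) {
    idx <- (i - 1L) * qm1 + seq_len(qm1)
    C[idx, idx] <- diag(fi_t[idx], qm1) - tcrossprod(fi_t[idx])
  }
  J <- -solve(C)
  # zero-sum gauge Frobenius norm per position pair, then APC
  FN <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    ri <- (i - 1L) * qm1 + seq_len(qm1)
    for (j in (i + 1L):L) {
      rj <- (j - 1L) * qm1 + seq_len(qm1)
      blk <- J[ri, rj]
      blk <- blk - outer(rowMeans(blk), rep(1, qm1)) -
        outer(rep(1, qm1), colMeans(blk)) + mean(blk)
      FN[i, j] <- FN[j, i] <- sqrt(sum(blk^2))
    }
  }
  # average-product correction over off-diagonal entries
  rm_ <- rowSums(FN) / (L - 1L)
  mm <- sum(FN) / (L * (L - 1L))
  APC <- FN - outer(rm_, rm_) / mm
  diag(APC) <- 0
  inter <- expand.grid(pos_a = seq_len(n_a),
                       pos_b = seq_len(L - n_a))
  inter$score <- APC[cbind(inter$pos_a, n_a + inter$pos_b)]
  out <- inter[order(-inter$score), ]
  rownames(out) <- NULL
  attr(out, "full_scores") <- APC
  attr(out, "n_a") <- n_a
  out
}

#' Min-max normalize coupling scores within a realization
#'
#' Affine map of the inter-protein scores onto \eqn{[0, 1]} so that the
#' strongest coupling maps to 1 and score thresholds are scale-free
#' (invariant under positive affine transforms of the raw scores).  A
#' single pair maps to 1 by convention; if all scores are equal they all
#' map to 0 (no pair stands out); both degenerate cases warn.
#'
#' @param scores Numeric vector of inter-protein coupling scores.
#' @return Numeric vector of normalized scores in \eqn{[0, 1]}.
#' @export
normalize_scores <- function(scores) {
  if (length(scores) < 1L) stop_input("no scores to normalize")
  if (length(scores) == 1L) {
    warning("single score: normalized to 1 by convention")
    return(1)
  }
  rng <- range(scores)
  if (rng[1L] == rng[2L]) {
    warning("all coupling scores equal: normalized scores all 0")
    return(rep(0, length(scores)))
  }
  (scores - rng[1L]) / (rng[2L] - rng[1L])
}

#' Ensemble DCA over random paralog-matching realizations
#'
#' Repeats, for \code{R} realizations: draw a random per-organism
#' one-to-one matching, concatenate the matched pairs, reweight sequences
#' at the identity threshold, compute inter-protein coupling scores,
#' min-max normalize them, and record every pair whose normalized score
#' reaches \code{score_threshold}.  Pairs are finally selected when they
#' recur in at least the fraction \code{appearance_threshold} of the
#' realizations (the defaults reproduce the 0.8-score / 5\%-of-300-MSAs
#' rule).  Realizations that produce identical matchings reuse cached
#' scores.
#'
#' @param pf A \code{pda_paired_family}.
#' @param R Number of matching realizations. Default 300.
#' @param score_threshold Normalized-score significance threshold.
#'   Default 0.8.
#' @param appearance_threshold Minimum appearance fraction for final
#'   selection. Default 0.05.
#' @param base_seed Base RNG seed; realization \eqn{r} uses seed
#'   \code{base_seed + r}. Default 1.
#' @param identity_threshold Reweighting identity threshold. Default 0.90.
#' @param pseudocount,min_seqs Passed to \code{\link{coupling_scores}}.
#' @param scorer Optional pluggable coupling scorer with signature
#'   \code{function(joint, n_a, weights)} returning a data frame with
#'   columns \code{pos_a}, \code{pos_b}, \code{score}; defaults to the
#'   built-in mean-field scorer.
#' @return A \code{pda_ensemble}: list with \code{appearance_fraction}
#'   (an \code{N_a x N_b} matrix), \code{selected_pairs} (data frame
#'   \code{pos_a}, \code{pos_b}, \code{appearance_fraction}), \code{R},
#'   the thresholds, \code{base_seed} and \code{scorer_name}.
#' @export
ensemble_dca <- function(pf, R = 300L, score_threshold = 0.8,
                         appearance_threshold = 0.05, base_seed = 1L,
                         identity_threshold = 0.90, pseudocount = 0.5,
                         min_seqs = 10L, scorer = NULL) {
  stopifnot(inherits(pf, "pda_paired_family"))
  R <- as.integer(R)
  if (is.na(R) || R < 1L) stop_input("R must be a positive integer")
  scorer_name <- if (is.null(scorer)) "mean_field" else "custom"
  score_fun <- scorer %||% function(joint, n_a, weights)
    coupling_scores(joint, n_a, weights = weights,
                    pseudocount = pseudocount, min_seqs = min_seqs)
  counts <- matrix(0L, pf$N_a, pf$N_b)
  cache <- new.env(parent = emptyenv())
  for (r in seq_len(R)) {
    m <- random_matching(pf, seed = base_seed + r)
    key <- paste(m$a_id, m$b_id, sep = "|", collapse = ";")
    hits <- if (!is.null(cache[[key]])) {
      cache[[key]]
    } else {
      joint <- concatenate_pair(pf, m)
      wts <- sequence_weights(joint,
                              identity_threshold = identity_threshold)
      sc <- score_fun(joint, pf$N_a, wts)
      norm <- suppressWarnings(normalize_scores(sc$score))
      h <- cbind(sc$pos_a, sc$pos_b)[norm >= score_threshold, ,
                                     drop = FALSE]
      cache[[key]] <- h
      h
    }
    if (nrow(hits)) counts[hits] <- counts[hits] + 1L
  }
  frac <- counts / R
  sel <- which(frac >= appearance_threshold, arr.ind = TRUE)
  selected <- data.frame(pos_a = as.integer(sel[, 1L]),
                         pos_b = as.integer(sel[, 2L]),
                         appearance_fraction = frac[sel])
  selected <- selected[order(-selected$appearance_fraction,
                             selected$pos_a, selected$pos_b), ]
  rownames(selected) <- NULL
  structure(list(appearance_fraction = frac,
                 selected_pairs = selected,
                 R = R,
                 score_threshold = score_threshold,
                 appearance_threshold = appearance_threshold,
                 base_seed = as.integer(base_seed),
                 identity_threshold = identity_threshold,
                 scorer_name = scorer_name),
            class = "pda_ensemble")
}

#' @export
print.pda_ensemble <- function(x, ...) {
  cat(sprintf(
    "Ensemble DCA: %d realizations, score >= %.2f, appearance >= %.2f\n",
    x$R, x$score_threshold, x$appearance_threshold))
  cat(sprintf("  %d inter-protein pair(s) selected\n",
              nrow(x$selected_pairs)))
  if (nrow(x$selected_pairs))
    print(utils::head(x$selected_pairs, 10L))
  invisible(x)
}
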