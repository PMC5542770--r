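# Synthetic annotated alignments and paired families with planted ground
# truth, so that every analysis stage is testable without external data.

#' Generate a group-structured alignment with a planted triplet
#'
#' Background columns are drawn independently and uniformly from the 20
#' amino acids for all groups.  At each planted position, a sequence
#' carries its group's signature residue with probability \code{purity}
#' and a background draw otherwise, so \code{purity = 1} makes the
#' planted triplet a perfect discriminator and \code{purity = 0} makes it
#' statistically indistinguishable from background.  Signature residues
#' are assigned deterministically from the fixed amino-acid ordering
#' (group \eqn{g}, planted position \eqn{j} gets residue
#' \eqn{(g + j - 2) \bmod 20 + 1}), so fixtures are stable across runs.
#' Gaps are injected independently per cell at rate \code{gap_rate}.
#'
#' @param n_per_group Named integer vector: sequences per phylogenetic
#'   group (names are the group labels).
#' @param N_pos Alignment width.
#' @param planted_triplet Integer vector of three distinct 1-based planted
#'   positions, or \code{NULL} for a pure-background alignment.
#' @param purity Probability that a sequence carries its group signature
#'   at each planted position. Default 1.0.
#' @param gap_rate Per-cell gap probability. Default 0.
#' @param seed Integer RNG seed; output is reproducible per seed.
#' @return List with \code{alignment} (a \code{pda_alignment}),
#'   \code{annotations} (data frame; organism ids are synthetic, one per
#'   sequence) and \code{truth} (planted positions, signature residues,
#'   purity, seed).
#' @export
make_grouped_msa <- function(n_per_group, N_pos, planted_triplet = NULL,
                             purity = 1.0, gap_rate = 0, seed = 1L) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group))))
    stop_input("n_per_group must be named by group label")
  if (any(n_per_group < 1)) stop_input("group sizes must be positive")
  N_pos <- as.integer(N_pos)
  if (is.na(N_pos) || N_pos < 1L) stop_input("N_pos must be >= 1")
  if (!is.null(planted_triplet)) {
    planted_triplet <- as.integer(planted_triplet)
    if (length(planted_triplet) != 3L || anyDuplicated(planted_triplet) ||
        any(planted_triplet < 1L | planted_triplet > N_pos))
      stop_input("planted_triplet must be three distinct positions in range")
  }
  if (purity < 0 || purity > 1) stop_input("purity must be in [0, 1]")
  if (gap_rate < 0 || gap_rate >= 1) stop_input("gap_rate must be in [0, 1)")
  groups <- names(n_per_group)
  n <- sum(n_per_group)
  group_of <- rep(groups, times = n_per_group)
  # deterministic signatures: distinct across groups within each column
  signatures <- NULL
  if (!is.null(planted_triplet)) {
    signatures <- outer(seq_along(groups), seq_len(3L), function(g, j)
      AA20[(g + j - 2L) %% 20L + 1L])
    dimnames(signatures) <- list(groups, paste0("pos", planted_triplet))
  }
  mat <- with_seed_(seed, {
    m <- matrix(sample(AA20, n * N_pos, replace = TRUE), n, N_pos)
    if (!is.null(planted_triplet) && purity > 0) {
      for (j in seq_len(3L)) {
        carry <- stats::runif(n) < purity
        m[carry, planted_triplet[j]] <-
          signatures[match(group_of[carry], groups), j]
      }
    }
    if (gap_rate > 0) {
      gap <- matrix(stats::runif(n * N_pos) < gap_rate, n, N_pos)
      m[gap] <- "-"
    }
    m
  })
  ids <- sprintf("%s_s%04d", group_of,
                 as.integer(stats::ave(seq_len(n), group_of,
                                       FUN = seq_along)))
  aln <- alignment(ids, apply(mat, 1L, paste, collapse = ""))
  ann <- data.frame(id = ids, group = group_of,
                    organism = sprintf("org%04d", seq_len(n)),
                    stringsAsFactors = FALSE)
  list(alignment = aln, annotations = ann,
       truth = list(planted_triplet = planted_triplet,
                    signatures = signatures, purity = purity,
                    gap_rate = gap_rate, seed = as.integer(seed)))
}

#' Generate a paired two-family dataset with planted coupled columns
#'
#' Emulates the inter-protein coevolution structure that random paralog
#' matching is designed to recover.  Each organism carries
#' \code{paralogs_a} family A and \code{paralogs_b} family B sequences;
#' paralogs are paired in order up to the smaller count to define the
#' true interaction partners.  At every planted \code{(pos_a, pos_b)}
#' column pair both columns keep the uniform 20-residue background
#' marginal, and the coupling is purely in the joint distribution: in
#' true partners the family B residue is a fixed one-to-one mapping
#' (a residue permutation) of the family A residue with probability
#' \code{coupling_strength}, and an independent background draw
#' otherwise.  Non-partner sequences are always independent.  At
#' \code{coupling_strength = 0} the planted columns are therefore
#' exactly background -- no marginal statistic distinguishes them.
#'
#' @param n_organisms Number of organisms.
#' @param paralogs_a,paralogs_b Paralog count per organism for each
#'   family; a scalar or a length-\code{n_organisms} vector. Default 1.
#' @param N_a,N_b Family alignment widths.
#' @param planted_pairs List of length-2 integer vectors
#'   \code{c(pos_a, pos_b)}, or \code{NULL} for no planted coupling.
#' @param coupling_strength Probability that coupled states co-occur in
#'   true partners. Default 0.9.
#' @param seed Integer RNG seed.
#' @return List with \code{family} (a \code{pda_paired_family}) and
#'   \code{truth} (data frame \code{partners} of true pairs, the planted
#'   pairs, the residue mapping used at coupled columns, the coupling
#'   strength and seed).
#' @export
make_paired_family <- function(n_organisms, paralogs_a = 1L,
                               paralogs_b = 1L, N_a = 20L, N_b = 20L,
                               planted_pairs = NULL,
                               coupling_strength = 0.9, seed = 1L) {
  n_organisms <- as.integer(n_organisms)
  if (is.na(n_organisms) || n_organisms < 1L)
    stop_input("n_organisms must be a positive integer")
  pa <- rep_len(as.integer(paralogs_a), n_organisms)
  pb <- rep_len(as.integer(paralogs_b), n_organisms)
  if (any(pa < 1L) || any(pb < 1L))
    stop_input("paralog counts must be positive")
  N_a <- as.integer(N_a); N_b <- as.integer(N_b)
  if (!is.null(planted_pairs)) {
    if (!is.list(planted_pairs)) planted_pairs <- list(planted_pairs)
    for (p in planted_pairs) {
      if (length(p) != 2L || p[1L] < 1L || p[1L] > N_a ||
          p[2L] < 1L || p[2L] > N_b)
        stop_input("planted pair positions out of range")
    }
  }
  if (coupling_strength < 0 || coupling_strength > 1)
    stop_input("coupling_strength must be in [0, 1]")
  # deterministic residue mapping at coupled columns: a fixed cyclic
  # shift of the amino-acid ordering, so truth is stable across versions
  couple_map <- stats::setNames(AA20[c(2:20, 1)], AA20)
  orgs <- sprintf("org%03d", seq_len(n_organisms))
  ids_a <- unlist(lapply(seq_len(n_organisms), function(o)
    sprintf("%s_A%d", orgs[o], seq_len(pa[o]))))
  ids_b <- unlist(lapply(seq_len(n_organisms), function(o)
    sprintf("%s_B%d", orgs[o], seq_len(pb[o]))))
  org_of_a <- rep(orgs, times = pa)
  org_of_b <- rep(orgs, times = pb)
  na <- length(ids_a); nb <- length(ids_b)
  out <- with_seed_(seed, {
    ma <- matrix(sample(AA20, na * N_a, replace = TRUE), na, N_a)
    mb <- matrix(sample(AA20, nb * N_b, replace = TRUE), nb, N_b)
    partners <- do.call(rbind, lapply(seq_len(n_organisms), function(o) {
      k <- min(pa[o], pb[o])
      data.frame(a_id = sprintf("%s_A%d", orgs[o], seq_len(k)),
                 b_id = sprintf("%s_B%d", orgs[o], seq_len(k)),
                 organism = orgs[o], stringsAsFactors = FALSE)
    }))
    if (!is.null(planted_pairs)) {
      for (p in planted_pairs) {
        # both columns are background draws; in true partners the B
        # residue follows the fixed mapping of the A residue with
        # probability coupling_strength
        ia <- match(partners$a_id, ids_a)
        ib <- match(partners$b_id, ids_b)
        copy <- stats::runif(nrow(partners)) < coupling_strength
        mb[ib[copy], p[2L]] <- unname(couple_map[ma[ia[copy], p[1L]]])
      }
    }
    list(ma = ma, mb = mb, partners = partners)
  })
  aln_a <- alignment(ids_a, apply(out$ma, 1L, paste, collapse = ""))
  aln_b <- alignment(ids_b, apply(out$mb, 1L, paste, collapse = ""))
  ann_a <- data.frame(id = ids_a, group = "A", organism = org_of_a,
                      stringsAsFactors = FALSE)
  ann_b <- data.frame(id = ids_b, group = "B", organism = org_of_b,
                      stringsAsFactors = FALSE)
  list(family = paired_family(aln_a, ann_a, aln_b, ann_b),
       truth = list(partners = out$partners,
                    planted_pairs = planted_pairs,
                    couple_map = couple_map,
                    coupling_strength = coupling_strength,
                    seed = as.integer(seed)))
}

#' Write a grouped-MSA fixture to disk
#'
#' FASTA alignment, TSV annotations and a JSON ground-truth sidecar, so
#' downstream tests never re-derive the planted truth.
#'
#' @param fixture Output of \code{\link{make_grouped_msa}}.
#' @param prefix Output path prefix; writes \code{<prefix>.fasta},
#'   \code{<prefix>.tsv}, \code{<prefix>.truth.json}.
#' @return Invisibly, the three paths.
#' @export
write_grouped_fixture <- function(fixture, prefix) {
  fa <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, ".truth.json")
  write_alignment(fixture$alignment, fa)
  write_annotations(fixture$annotations, tsv)
  truth <- fixture$truth
  if (!is.null(truth$signatures))
    truth$signatures <- as.data.frame(truth$signatures)
  jsonlite::write_json(truth, js, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(fa, tsv, js))
}

#' Write a paired-family fixture to disk
#'
#' @param fixture Output of \code{\link{make_paired_family}}.
#' @param prefix Output path prefix; writes \code{<prefix>_A.fasta},
#'   \code{<prefix>_B.fasta}, the two annotation TSVs and
#'   \code{<prefix>.truth.json}.
#' @return Invisibly, the five paths.
#' @export
write_paired_fixture <- function(fixture, prefix) {
  pf <- fixture$family
  paths <- c(paste0(prefix, "_A.fasta"), paste0(prefix, "_B.fasta"),
             paste0(prefix, "_A.tsv"), paste0(prefix, "_B.tsv"),
             paste0(prefix, ".truth.json"))
  write_alignment(pf$aln_a, paths[1L])
  write_alignment(pf$aln_b, paths[2L])
  write_annotations(pf$ann_a, paths[3L])
  write_annotations(pf$ann_b, paths[4L])
  jsonlite::write_json(fixture$truth, paths[5L], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
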