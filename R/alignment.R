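#' Construct an alignment object
#'
#' An alignment is an ordered set of equal-width residue strings over the
#' amino-acid alphabet plus \code{'X'} and the gap character \code{'-'}.
#' Residues are upper-cased and \code{'.'} gaps are normalized to \code{'-'}
#' on construction.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character vector of aligned residue strings, one per id.
#' @return An object of class \code{pda_alignment} with fields \code{ids},
#'   \code{seqs} and \code{width}.
#' @examples
#' aln <- alignment(c("s1", "s2"), c("ACD-E", "ACDFE"))
#' aln$width
#' @export
alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (length(ids) != length(seqs))
    stop_input("ids and seqs must have the same length")
  if (length(ids) < 1L)
    stop_input("alignment must contain at least one sequence")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop_format(sprintf("duplicate sequence id '%s'", dup))
  }
  w <- nchar(seqs)
  if (any(w != w[1L])) {
    bad <- ids[which(w != w[1L])[1L]]
    stop_format(sprintf(
      "unequal sequence lengths: sequence '%s' has length %d, expected %d",
      bad, w[which(w != w[1L])[1L]], w[1L]))
  }
  if (w[1L] < 1L) stop_input("alignment width must be at least 1")
  structure(list(ids = ids, seqs = seqs, width = as.integer(w[1L])),
            class = "pda_alignment")
}

#' @export
print.pda_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns\n",
              length(x$ids), x$width))
  show <- utils::head(seq_along(x$ids), 5L)
  for (i in show) {
    s <- x$seqs[i]
    if (nchar(s) > 50) s <- paste0(substr(s, 1, 50), "...")
    cat(sprintf("  %-20s %s\n", x$ids[i], s))
  }
  if (length(x$ids) > 5L) cat(sprintf("  ... and %d more\n", length(x$ids) - 5L))
  invisible(x)
}

#' @export
as.matrix.pda_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or Stockholm file into a \code{pda_alignment}.
#' FASTA identifiers are truncated at the first whitespace; \code{'.'} gaps
#' are normalized to \code{'-'} and residues upper-cased.
#'
#' @param path Path to the alignment file.
#' @param format One of \code{"fasta"} or \code{"stockholm"}.
#' @return A \code{pda_alignment}.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readAAStringSet(path, format = "fasta"),
                    error = function(e) stop_format(conditionMessage(e)))
    if (length(set) == 0L) stop_input(sprintf("empty alignment file: %s", path))
    ids <- sub("\\s.*$", "", names(set))
    seqs <- as.character(set)
  } else {
    msa <- tryCatch(
      Biostrings::readAAMultipleAlignment(path, format = "stockholm"),
      error = function(e) stop_format(conditionMessage(e)))
    set <- Biostrings::unmasked(msa)
    if (length(set) == 0L) stop_input(sprintf("empty alignment file: %s", path))
    ids <- names(set)
    seqs <- as.character(set)
  }
  alignment(ids, seqs)
}

#' Write an alignment to FASTA
#'
#' @param aln A \code{pda_alignment}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "pda_alignment"))
  set <- Biostrings::AAStringSet(stats::setNames(aln$seqs, aln$ids))
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta")
  invisible(path)
}

#' Read a per-sequence annotation table
#'
#' Expects a UTF-8 tab-delimited file with a header row containing at least
#' the columns \code{id}, \code{group} and \code{organism}: the phylogenetic
#' group label and organism identifier of each sequence.
#'
#' @param path Path to the TSV file.
#' @return A data frame with character columns \code{id}, \code{group},
#'   \code{organism}.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE),
    error = function(e) stop_format(conditionMessage(e)))
  need <- c("id", "group", "organism")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop_schema(sprintf("annotation table is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  if (nrow(df) == 0L) stop_input(sprintf("empty annotation table: %s", path))
  if (anyDuplicated(df$id))
    stop_format(sprintf("duplicate annotation id '%s'",
                        df$id[duplicated(df$id)][1L]))
  df[, need]
}

#' Write an annotation table to TSV
#' @param ann Data frame with columns id, group, organism.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann[, c("id", "group", "organism")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Look up group labels for a vector of ids; error names the first missing id.
annotation_groups <- function(ann, ids) {
  idx <- match(ids, ann$id)
  if (anyNA(idx))
    stop_lookup(sprintf("no annotation for sequence id '%s'",
                        ids[which(is.na(idx))[1L]]))
  ann$group[idx]
}

annotation_organisms <- function(ann, ids) {
  idx <- match(ids, ann$id)
  if (anyNA(idx))
    stop_lookup(sprintf("no annotation for sequence id '%s'",
                        ids[which(is.na(idx))[1L]]))
  ann$organism[idx]
}

#' Filter alignment records by gap fraction
#'
#' Removes every record whose gap fraction strictly exceeds
#' \code{max_gap_fraction}; records at exactly the threshold are retained.
#' The default reproduces the conventional pre-processing step of dropping
#' hits with more than 20\% gaps.
#'
#' @param aln A \code{pda_alignment}.
#' @param max_gap_fraction Maximum tolerated fraction of gap characters per
#'   record, in \eqn{[0, 1]}. Default 0.20.
#' @return A \code{pda_alignment} with the surviving records in their
#'   original order, or a zero-record marker list if none survive.
#' @export
filter_by_gap_fraction <- function(aln, max_gap_fraction = 0.20) {
  stopifnot(inherits(aln, "pda_alignment"))
  if (!is.numeric(max_gap_fraction) || max_gap_fraction < 0 ||
      max_gap_fraction > 1)
    stop_input("max_gap_fraction must be in [0, 1]")
  gaps <- nchar(aln$seqs) - nchar(gsub("-", "", aln$seqs, fixed = TRUE))
  keep <- (gaps / aln$width) <= max_gap_fraction
  if (!any(keep)) {
    return(structure(list(ids = character(0), seqs = character(0),
                          width = aln$width),
                     class = "pda_alignment"))
  }
  alignment(aln$ids[keep], aln$seqs[keep])
}

#' Remove gaps from an alignment
#'
#' Returns the unaligned (gap-free) sequences as a named character vector,
#' e.g. for motif counting on complete sequences.
#'
#' @param aln A \code{pda_alignment}.
#' @return Named character vector of gap-free sequences.
#' @export
remove_gaps <- function(aln) {
  stopifnot(inherits(aln, "pda_alignment"))
  stats::setNames(gsub("-", "", aln$seqs, fixed = TRUE), aln$ids)
}

#' Count zinc-finger CxxCxGxG motifs
#'
#' Counts (possibly overlapping) 8-residue windows matching the
#' zinc-finger signature \code{C.x.x.C.x.G.x.G}: cysteine, any two
#' residues, cysteine, any residue, glycine, any residue, glycine.  The
#' wildcard positions match any residue including \code{'X'}; the literal
#' C/G positions must be exactly \code{C} or \code{G}.
#'
#' @param seqs Character vector of gap-free residue strings.
#' @return Integer vector of motif counts, one per input string.
#' @examples
#' count_zf_motifs("CPTCSGSG")           # 1
#' count_zf_motifs("CPTCSGSGCPTCSGSG")   # 2
#' @export
count_zf_motifs <- function(seqs) {
  seqs <- toupper(as.character(seqs))
  if (any(grepl("[-.]", seqs)))
    stop_input("count_zf_motifs requires gap-free sequences")
  vapply(seqs, function(s) {
    m <- gregexpr("(?=C..C.G.G)", s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }, integer(1), USE.NAMES = !is.null(names(seqs)))
}

#' Partition sequences into classes by zinc-finger motif content
#'
#' Assigns each sequence to class A when its complete (unaligned) sequence
#' contains at least \code{class_a_min} zinc-finger CxxCxGxG motifs, to
#' class B when it contains at most \code{class_b_max}, and otherwise to
#' the unassigned set.  With the defaults this keeps as class A only
#' sequences carrying at least two motifs (tolerating zinc fingers with a
#' degenerate glycine in some of the canonical four repeats) and excludes
#' from class B any sequence containing the motif at all.
#'
#' @param seqs Named character vector of gap-free complete sequences
#'   (names are the sequence ids).
#' @param class_a_min Minimum motif count for class A membership. Default 2.
#' @param class_b_max Maximum motif count for class B membership. Default 0.
#' @return List with character-vector elements \code{class_a},
#'   \code{class_b}, \code{unassigned} (id sets partitioning the input)
#'   and the integer vector \code{counts}.
#' @export
partition_by_motif <- function(seqs, class_a_min = 2L, class_b_max = 0L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop_input("partition_by_motif requires named sequences (ids)")
  if (class_a_min <= class_b_max)
    stop_input("class_a_min must exceed class_b_max")
  counts <- count_zf_motifs(seqs)
  ids <- names(seqs)
  list(class_a    = ids[counts >= class_a_min],
       class_b    = ids[counts <= class_b_max],
       unassigned = ids[counts > class_b_max & counts < class_a_min],
       counts     = counts)
}
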