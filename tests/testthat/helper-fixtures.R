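# Shared helpers: tiny fixtures built in code, independent oracles.

# random gap-free amino-acid strings
random_seqs <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(pdatools:::AA20, len, replace = TRUE), collapse = ""),
    character(1))
}

tiny_alignment <- function(seqs, ids = sprintf("s%d", seq_along(seqs))) {
  alignment(ids, seqs)
}

write_tmp_fasta <- function(ids, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

write_tmp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent exhaustive window-scan oracle for the zinc-finger motif
zf_oracle <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  if (n < 8) return(0L)
  hits <- 0L
  for (start in seq_len(n - 7L)) {
    w <- chars[start:(start + 7L)]
    if (w[1] == "C" && w[4] == "C" && w[6] == "G" && w[8] == "G")
      hits <- hits + 1L
  }
  hits
}

# brute-force mixing entropy from raw cluster labels and group labels
mixing_oracle <- function(labels, groups) {
  n <- length(labels)
  H <- 0
  for (c in unique(labels)) {
    g <- groups[labels == c]
    p <- as.numeric(table(g)) / length(g)
    H <- H + (length(g) / n) * (-sum(p * log(p)))
  }
  H
}

# build a cluster-assignment object from raw labels (contiguous from 1)
make_clusters <- function(labels, ids = sprintf("s%d", seq_along(labels))) {
  labels <- match(labels, unique(labels))
  structure(list(labels = labels, n_clusters = max(labels),
                 weights = as.numeric(tabulate(labels)) / length(labels),
                 cutoff = NA_real_, ids = ids),
            class = "pda_clusters")
}

# brute-force triplet enumerator
enumerate_oracle <- function(N) {
  out <- NULL
  for (i in 1:(N - 2)) for (j in (i + 1):(N - 1)) for (k in (j + 1):N)
    out <- rbind(out, c(i, j, k))
  out
}
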