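test_that("identity reweighting down-weights redundant sequences", {
  aln <- tiny_alignment(c("ACDEFGHIKL", "ACDEFGHIKL", "YYWWPPQQNN"),
                        c("dup1", "dup2", "solo"))
  w <- sequence_weights(aln)
  expect_equal(as.numeric(w), c(0.5, 0.5, 1))
  expect_equal(attr(w, "n_effective"), 2)

  # three identical sequences each get weight 1/3
  tri <- tiny_alignment(rep("ACDEFGHIKL", 3))
  expect_equal(as.numeric(sequence_weights(tri)), rep(1 / 3, 3))

  # all pairwise identities below the threshold: all weights 1
  set.seed(17)
  div <- tiny_alignment(random_seqs(6, 30))
  wd <- sequence_weights(div)
  expect_equal(as.numeric(wd), rep(1, 6))
  expect_equal(attr(wd, "n_effective"), 6)

  # 9/10 identity >= 0.9 counts as redundant (threshold inclusive)
  near <- tiny_alignment(c("ACDEFGHIKL", "ACDEFGHIKW"))
  expect_equal(as.numeric(sequence_weights(near, 0.90)), c(0.5, 0.5))
})

test_that("effective sequence number is at most n, with equality iff diverse", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    aln <- tiny_alignment(random_seqs(n, 15))
    if (rep %% 2 == 0) aln$seqs[2] <- aln$seqs[1]   # inject a duplicate
    aln <- alignment(aln$ids, aln$seqs)
    w <- sequence_weights(aln)
    mat <- as.matrix(aln)
    ident <- sapply(seq_len(n), function(a) sapply(seq_len(n), function(b)
      mean(mat[a, ] == mat[b, ])))
    diverse <- all(ident[upper.tri(ident)] < 0.9)
    expect_lte(attr(w, "n_effective"), n + 1e-12)
    expect_equal(attr(w, "n_effective") == n, diverse)
  }
})

test_that("random matchings satisfy the per-organism one-to-one constraints", {
  fx <- make_paired_family(3, paralogs_a = c(2, 1, 3),
                           paralogs_b = c(3, 1, 1), N_a = 8, N_b = 8,
                           seed = 5)
  pf <- fx$family
  for (seed in 1:25) {
    m <- random_matching(pf, seed = seed)
    expect_equal(anyDuplicated(m$a_id), 0L)
    expect_equal(anyDuplicated(m$b_id), 0L)
    org_a <- pf$ann_a$organism[match(m$a_id, pf$ann_a$id)]
    org_b <- pf$ann_b$organism[match(m$b_id, pf$ann_b$id)]
    expect_equal(org_a, org_b)
    # per organism exactly min(#A, #B) pairs: 2, 1, 1
    expect_equal(as.vector(table(m$organism)[c("org001", "org002",
                                               "org003")]),
                 c(2L, 1L, 1L))
  }
  # single choice is deterministic for any seed
  m1 <- random_matching(pf, seed = 1)
  expect_true("org002_A1" %in% m1$a_id)
})

test_that("concatenation joins matched pairs character-exactly", {
  fx <- make_paired_family(4, N_a = 10, N_b = 15, seed = 2)
  pf <- fx$family
  m <- random_matching(pf, seed = 1)
  joint <- concatenate_pair(pf, m)
  expect_equal(joint$width, 25L)
  expect_equal(length(joint$ids), 4L)
  expect_equal(joint$ids, paste0(m$a_id, "|", m$b_id))
  r1 <- paste0(pf$aln_a$seqs[match(m$a_id[1], pf$aln_a$ids)],
               pf$aln_b$seqs[match(m$b_id[1], pf$aln_b$ids)])
  expect_identical(joint$seqs[1], r1)

  empty <- m[0, ]
  expect_equal(length(concatenate_pair(pf, empty)$ids), 0L)

  bad <- m
  bad$a_id[1] <- "ghost"
  expect_error(concatenate_pair(pf, bad), "ghost",
               class = "pda_lookup_error")
})

test_that("mean-field couplings rank a planted covarying pair on top", {
  fx <- make_paired_family(60, N_a = 12, N_b = 12,
                           planted_pairs = list(c(3, 7)),
                           coupling_strength = 1.0, seed = 8)
  pf <- fx$family
  joint <- concatenate_pair(pf, random_matching(pf, seed = 1))
  w <- sequence_weights(joint)
  sc <- coupling_scores(joint, pf$N_a, weights = w)
  expect_equal(unlist(sc[1, c("pos_a", "pos_b")], use.names = FALSE),
               c(3, 7))
  # permuting sequence order leaves the scores unchanged
  set.seed(1)
  perm <- sample(length(joint$ids))
  joint2 <- alignment(joint$ids[perm], joint$seqs[perm])
  sc2 <- coupling_scores(joint2, pf$N_a, weights = w[perm])
  expect_equal(sc2$score[order(sc2$pos_a, sc2$pos_b)],
               sc$score[order(sc$pos_a, sc$pos_b)], tolerance = 1e-9)
  expect_error(coupling_scores(joint, pf$N_a, min_seqs = 1000),
               class = "pda_input_error")
})

test_that("strictly conserved columns do not outscore a planted coupled pair", {
  fx <- make_paired_family(60, N_a = 12, N_b = 12,
                           planted_pairs = list(c(3, 7)),
                           coupling_strength = 1.0, seed = 15)
  pf <- fx$family
  # overwrite columns 5 (A) and 5 (B) with strict conservation
  mat_a <- as.matrix(pf$aln_a); mat_a[, 5] <- "W"
  mat_b <- as.matrix(pf$aln_b); mat_b[, 5] <- "W"
  aln_a <- alignment(pf$aln_a$ids, apply(mat_a, 1, paste, collapse = ""))
  aln_b <- alignment(pf$aln_b$ids, apply(mat_b, 1, paste, collapse = ""))
  pf2 <- paired_family(aln_a, pf$ann_a, aln_b, pf$ann_b)
  joint <- concatenate_pair(pf2, random_matching(pf2, seed = 1))
  sc <- coupling_scores(joint, pf2$N_a)
  planted <- sc$score[sc$pos_a == 3 & sc$pos_b == 7]
  conserved <- sc$score[sc$pos_a == 5 & sc$pos_b == 5]
  expect_lte(conserved, planted)
})

test_that("planted couplings are recovered in most stochastic fixtures", {
  top <- 0L
  for (seed in 1:20) {
    fx <- make_paired_family(60, N_a = 10, N_b = 10,
                             planted_pairs = list(c(2, 9)),
                             coupling_strength = 0.9, seed = seed)
    pf <- fx$family
    joint <- concatenate_pair(pf, random_matching(pf, seed = 1))
    sc <- coupling_scores(joint, pf$N_a,
                          weights = sequence_weights(joint))
    top <- top + (sc$pos_a[1] == 2 && sc$pos_b[1] == 9)
  }
  expect_gte(top, 19L)  # >= 95% of 20 fixtures
})

test_that("score normalization is an affine min-max map onto [0, 1]", {
  expect_equal(normalize_scores(c(2, 6, 10)), c(0, 0.5, 1))
  expect_warning(one <- normalize_scores(5))
  expect_equal(one, 1)
  expect_warning(flat <- normalize_scores(c(3, 3, 3)))
  expect_equal(flat, c(0, 0, 0))
  # invariance under positive affine transforms
  set.seed(31)
  x <- rnorm(40)
  expect_equal(normalize_scores(2.5 * x + 7), normalize_scores(x),
               tolerance = 1e-12)
})

test_that("single-paralog families give degenerate appearance fractions", {
  fx <- make_paired_family(30, N_a = 8, N_b = 8,
                           planted_pairs = list(c(2, 6)),
                           coupling_strength = 1.0, seed = 3)
  res <- ensemble_dca(fx$family, R = 7, base_seed = 4)
  expect_true(all(res$appearance_fraction %in% c(0, 1)))
  expect_true(any(res$selected_pairs$pos_a == 2 &
                    res$selected_pairs$pos_b == 6))
})

test_that("selection grows as either ensemble threshold is relaxed", {
  fx <- make_paired_family(40, paralogs_a = 2, paralogs_b = 2,
                           N_a = 8, N_b = 8,
                           planted_pairs = list(c(1, 1)),
                           coupling_strength = 0.9, seed = 9)
  strict <- ensemble_dca(fx$family, R = 10, score_threshold = 0.9,
                         appearance_threshold = 0.3, base_seed = 2)
  lax_score <- ensemble_dca(fx$family, R = 10, score_threshold = 0.6,
                            appearance_threshold = 0.3, base_seed = 2)
  lax_app <- ensemble_dca(fx$family, R = 10, score_threshold = 0.9,
                          appearance_threshold = 0.05, base_seed = 2)
  key <- function(r) paste(r$selected_pairs$pos_a, r$selected_pairs$pos_b)
  expect_true(all(key(strict) %in% key(lax_score)))
  expect_true(all(key(strict) %in% key(lax_app)))
})
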