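# Helper: run the full greedy construction for a probability set, checking
# graph legality after every committed insertion with the independent
# Floyd-Warshall reachability oracle.
build_checked <- function(ps, tb = 0.5, skeleton = TRUE) {
  g <- rnamea:::new_graph(ps$seqs)
  check <- function(g) {
    edges <- rnamea:::graph_edges(g)
    expect_true(oracle_is_acyclic(edges, length(g$alive)))
    for (cl in rnamea:::graph_columns(g))
      expect_false(any(duplicated(cl$seq)))
  }
  cand <- build_candidates(ps, tb)
  if (skeleton) rnamea:::build_skeleton(g, ps, cand, validate = check)
  rnamea:::insert_local_alignments(g, cand, validate = check)
  g
}

test_that("insert_pair realizes the three insertion scenarios", {
  seqs <- c(x = "ACGU", y = "ACGU", z = "ACGU")
  g <- rnamea:::new_graph(seqs)
  expect_equal(rnamea:::insert_pair(g, 1, 1, 2, 2), "new-column")
  cols <- rnamea:::graph_columns(g)
  expect_equal(cols[[1]], list(seq = c(1L, 2L), pos = c(1L, 2L)))
  expect_equal(rnamea:::insert_pair(g, 1, 1, 3, 3), "extended")
  expect_equal(sort(rnamea:::graph_columns(g)[[1]]$seq), c(1, 2, 3))
  # separate column, then merge
  expect_equal(rnamea:::insert_pair(g, 1, 2, 2, 3), "new-column")
  expect_equal(rnamea:::insert_pair(g, 2, 3, 3, 4), "extended")
  # already-aligned pair is a trivial no-op
  expect_equal(rnamea:::insert_pair(g, 1, 1, 2, 2), "merged")
})

test_that("insertions that would create a cycle are rejected", {
  seqs <- c(x = "ACGU", y = "ACGU")
  g <- rnamea:::new_graph(seqs)
  expect_equal(rnamea:::insert_pair(g, 1, 1, 2, 1), "new-column")
  expect_equal(rnamea:::insert_pair(g, 1, 2, 2, 2), "new-column")
  # aligning x_1 with y_2 now implies column2 -> column1: a cycle
  snap <- rnamea:::graph_snapshot(g)
  expect_equal(rnamea:::insert_pair(g, 1, 1, 2, 2), "rejected")
  expect_identical(rnamea:::graph_snapshot(g), snap)
  expect_true(oracle_is_acyclic(rnamea:::graph_edges(g), length(g$alive)))
  # crossing merge is likewise rejected
  expect_equal(rnamea:::insert_pair(g, 1, 2, 2, 1), "rejected")
})

test_that("candidate sets honour the threshold and a deterministic tie order", {
  seqs <- c(a = "GGGAAACCC", b = "GGGAAACCC")
  ps <- probability_set(seqs)
  # tb above every pairing probability empties B
  cand_hi <- build_candidates(ps, tb = 1)
  expect_equal(nrow(cand_hi$B), 0)
  # tb = 0 keeps every stored entry
  cand0 <- build_candidates(ps, tb = 0)
  expect_equal(nrow(cand0$B), sum(vapply(ps$pair, function(M) length(M@x),
                                         integer(1))))
  # identical probabilities (two identical sequences) sort by id, then index
  B <- cand0$B
  ord <- order(-B$p, ps$ids[B$seq], B$i, B$ip)
  expect_equal(ord, seq_len(nrow(B)))
})

test_that("two identical sequences align gaplessly", {
  seqs <- c(a = "GGGACAAACCCU", b = "GGGACAAACCCU")
  aln <- rna_align(seqs, config = align_config(refine = FALSE))
  expect_identical(unname(aln$rows[["a"]]), "GGGACAAACCCU")
  expect_identical(unname(aln$rows[["b"]]), "GGGACAAACCCU")
})

test_that("empty candidate skeleton degrades to pure sequence insertion", {
  seqs <- c(a = "AAAACAAAA", b = "AAACAAAA")  # no canonical pairs at all
  ps <- probability_set(seqs)
  cand <- build_candidates(ps, tb = 0.5)
  expect_equal(nrow(cand$B), 0)
  g <- rnamea:::new_graph(ps$seqs)
  rnamea:::build_skeleton(g, ps, cand)
  expect_equal(length(rnamea:::graph_columns(g)), 0)
  aln <- rna_align(seqs, config = align_config(refine = FALSE))
  expect_identical(degap(aln), seqs)
})

test_that("skeleton pins stem columns on a clean two-hairpin family", {
  seqs <- c(a = "GGGGAAAACCCCAUAUGGGCAAAAGCCC",
            b = "GGGGAAAACCCCAUAUGGGCAAAAGCCC")
  ps <- apply_consistency(probability_set(seqs))
  cand <- build_candidates(ps, tb = 0.5)
  expect_gt(nrow(cand$B), 0)
  g <- rnamea:::new_graph(ps$seqs)
  rnamea:::build_skeleton(g, ps, cand)
  expect_gt(length(g$paired), 0)
  expect_true(rnamea:::lr_compatible(g))
  # every skeleton column aligns the same position of both sequences
  for (cl in rnamea:::graph_columns(g))
    expect_equal(length(unique(cl$pos)), 1)
})

test_that("graph legality invariants hold across randomized runs", {
  set.seed(31)
  for (rep in 1:15) {
    m <- sample(2:3, 1)
    ps <- apply_consistency(random_prob_set(m, 10))
    g <- build_checked(ps)
    expect_true(rnamea:::lr_compatible(g))
    aln <- rnamea:::linearize(g, ps$seqs)
    expect_identical(degap(aln), ps$seqs)
    # every residue in exactly one column
    for (s in seq_along(ps$seqs))
      expect_true(all(g$col_of[[s]] > 0))
  }
})

test_that("linearization of an empty graph respects residue adjacency", {
  seqs <- c(a = "AC", b = "GGU")
  g <- rnamea:::new_graph(seqs)
  aln <- rnamea:::linearize(g, seqs)
  expect_equal(nchar(aln$rows[[1]]), 5)
  expect_identical(degap(aln), seqs)
  # each column holds exactly one residue
  cols <- rnamea:::msa_columns(aln)
  expect_true(all(vapply(cols, function(cl) length(cl$seq), integer(1)) == 1))
})

test_that("the pipeline is deterministic byte for byte", {
  fam <- simulate_family(m = 4, L = 50, seed = 9)
  a1 <- rna_align(fam$sequences)
  a2 <- rna_align(fam$sequences)
  expect_identical(write_alignment(a1, format = "fasta"),
                   write_alignment(a2, format = "fasta"))
})

test_that("greedy two-sequence alignments agree with the MEA DP oracle", {
  set.seed(33)
  hits <- 0; n <- 25
  for (rep in seq_len(n)) {
    fam <- simulate_family(m = 2, L = 20, sub_rate = 0.08, indel_rate = 0.05,
                           seed = 4000 + rep, n_hairpins = 1)
    seqs <- fam$sequences
    ps <- probability_set(seqs)
    mea <- mea_pairwise(ps$align[["1:2"]])
    mea_pairs <- mea$pairs[apply(mea$pairs, 1, function(r)
      as.matrix(ps$align[["1:2"]])[r[1], r[2]] > 0), , drop = FALSE]
    g <- rnamea:::new_graph(seqs)
    rnamea:::insert_local_alignments(g, build_candidates(ps, tb = 0.5))
    aln <- rnamea:::linearize(g, seqs)
    got <- sort(aligned_keys_2seq(aln))
    want <- sort(paste0(mea_pairs[, 1], "|", mea_pairs[, 2]))
    if (identical(got, want)) hits <- hits + 1
  }
  expect_gte(hits / n, 0.95)
})
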