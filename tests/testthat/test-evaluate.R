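test_that("SPS endpoints: identity scores 100, disjoint pairing scores 0", {
  ref <- rna_msa(c(a = "ACGU", b = "ACGU"))
  expect_equal(sps(ref, ref), 100)
  test <- rna_msa(c(a = "ACGU----", b = "----ACGU"))
  expect_equal(sps(test, ref), 0)
})

test_that("SPS counts recovered reference pairs on a three-sequence toy", {
  # reference aligns two full columns of three sequences: 6 residue pairs
  ref <- rna_msa(c(a = "AC", b = "AC", c = "AC"))
  # test keeps column 1 intact (3 pairs) but aligns column 2 for a,b only
  # after shifting c: pairs kept = 3 + 1 = 4 of 6
  test <- rna_msa(c(a = "AC-", b = "AC-", c = "A-C"))
  expect_equal(sps(test, ref), round(100 * 4 / 6, 8), tolerance = 1e-8)
})

test_that("SPS is invariant to relabeling order and all-gap columns", {
  set.seed(51)
  fam <- simulate_family(m = 3, L = 30, seed = 5)
  test <- rna_align(fam$sequences)
  ref <- fam$alignment
  s0 <- sps(test, ref)
  # permute row order
  ref_perm <- rna_msa(ref$rows[c(3, 1, 2)])
  expect_equal(sps(test, ref_perm), s0)
  # splice an all-gap column into the reference
  rows2 <- paste0(substr(ref$rows, 1, 4), "-",
                  substr(ref$rows, 5, nchar(ref$rows[1])))
  names(rows2) <- names(ref$rows)
  expect_equal(sps(test, rna_msa(rows2)), s0)
})

test_that("SPS rejects mismatched sequence sets", {
  a <- rna_msa(c(x = "AC", y = "AC"))
  b <- rna_msa(c(x = "AC", z = "AC"))
  expect_error(sps(a, b), "different sequences")
  c2 <- rna_msa(c(x = "AC", y = "AG"))
  expect_error(sps(a, c2), "different sequences")
})

test_that("structure scores match the contingency formula", {
  # perfect prediction
  r <- structure_scores(rbind(c(1, 7), c(2, 6)), rbind(c(1, 7), c(2, 6)), 7)
  expect_equal(c(r$sen, r$ppv, r$mcc), c(1, 1, 1))
  # empty prediction: conventions 0/0 -> 0
  r <- structure_scores(matrix(numeric(0), ncol = 2), rbind(c(1, 7)), 7)
  expect_equal(c(r$sen, r$ppv, r$mcc), c(0, 0, 0))
  # partial: pred {(1,7)}, ref {(1,7),(2,6)}, L = 7 -> 21 position pairs
  r <- structure_scores(rbind(c(1, 7)), rbind(c(1, 7), c(2, 6)), 7)
  expect_equal(r$sen, 0.5)
  expect_equal(r$ppv, 1.0)
  expect_equal(c(r$TP, r$FP, r$FN, r$TN), c(1, 0, 1, 19))
  expect_equal(r$mcc, (1 * 19 - 0 * 1) / sqrt(1 * 2 * 19 * 20))
})

test_that("structure scores equal a brute-force confusion count", {
  set.seed(52)
  for (rep in 1:10) {
    L <- sample(6:15, 1)
    all_pairs <- t(combn(L, 2))
    pred <- all_pairs[runif(nrow(all_pairs)) < 0.1, , drop = FALSE]
    ref <- all_pairs[runif(nrow(all_pairs)) < 0.1, , drop = FALSE]
    r <- structure_scores(pred, ref, L)
    pk <- paste(pred[, 1], pred[, 2]); rk <- paste(ref[, 1], ref[, 2])
    ak <- paste(all_pairs[, 1], all_pairs[, 2])
    tp <- sum(ak %in% pk & ak %in% rk)
    fp <- sum(ak %in% pk & !(ak %in% rk))
    fn <- sum(!(ak %in% pk) & ak %in% rk)
    tn <- sum(!(ak %in% pk) & !(ak %in% rk))
    expect_equal(c(r$TP, r$FP, r$FN, r$TN), c(tp, fp, fn, tn))
  }
})

test_that("evaluation report prints SPS and structure metrics", {
  fam <- simulate_family(m = 3, L = 30, seed = 6)
  rep1 <- evaluation_report(fam$alignment, fam$alignment)
  expect_equal(rep1$value[rep1$metric == "SPS"], 100)
  rep2 <- evaluation_report(fam$alignment, fam$alignment,
                            pred_structs = fam$structures,
                            ref_structs = fam$structures)
  expect_equal(rep2$value[rep2$metric == "SEN"], 100)
  expect_equal(rep2$value[rep2$metric == "MCC"], 100)
  f <- withr::local_tempfile(fileext = ".tsv")
  evaluation_report(fam$alignment, fam$alignment, path = f)
  expect_true(file.exists(f))
})

test_that("the SCI hook returns a number or NA depending on tool presence", {
  aln <- rna_msa(c(a = "GGGACAAACCCU", b = "GGGCCAAAGCCC"))
  have <- nzchar(Sys.which("RNAalifold")) && nzchar(Sys.which("RNAfold"))
  if (have) {
    v <- sci(aln)
    expect_true(is.na(v) || (is.numeric(v) && length(v) == 1))
  } else {
    expect_message(v <- sci(aln), "unavailable")
    expect_true(is.na(v))
  }
})
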