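test_that("with two sequences the inter-sequence transform is the identity", {
  set.seed(21)
  ps <- random_prob_set(2, 10)
  out <- inter_sequence_transform(ps)
  expect_lt(max(abs(out$align[["1:2"]] - ps$align[["1:2"]])), 1e-12)
})

test_that("alpha = 1 and beta = 0 are endpoint identities", {
  set.seed(22)
  ps <- random_prob_set(3, 10)
  out <- intra_sequence_transform(ps, alpha = 1)
  for (k in 1:3)
    expect_lt(max(abs(out$pair[[k]] - ps$pair[[k]])), 1e-12)
  out <- fourway_transform(ps, beta = 0)
  for (key in names(ps$align))
    expect_lt(max(abs(out$align[[key]] - ps$align[[key]])), 1e-12)
})

test_that("sparse transforms match their dense oracles on random instances", {
  set.seed(23)
  for (rep in 1:12) {
    m <- sample(3:4, 1)
    ps <- random_prob_set(m, 10)
    alpha <- runif(1); beta <- runif(1)

    d1 <- oracle_inter(dense_mats(ps))
    s1 <- inter_sequence_transform(ps)
    for (key in names(s1$align))
      expect_lt(max(abs(as.matrix(s1$align[[key]]) - d1$A[[key]])), 1e-12)

    d2 <- oracle_intra(d1, alpha)
    s2 <- intra_sequence_transform(s1, alpha)
    for (k in seq_len(m))
      expect_lt(max(abs(as.matrix(s2$pair[[k]]) - d2$U[[k]])), 1e-12)

    d3 <- oracle_fourway(d2, beta)
    s3 <- fourway_transform(s2, beta)
    for (key in names(s3$align))
      expect_lt(max(abs(as.matrix(s3$align[[key]]) - d3$A[[key]])), 1e-12)

    # apply_consistency composes the three in order
    comp <- apply_consistency(ps, alpha, beta, rounds = 1)
    for (key in names(comp$align))
      expect_lt(max(abs(as.matrix(comp$align[[key]]) - d3$A[[key]])), 1e-12)
  }
})

test_that("uniform homology weights reduce to the unweighted product average", {
  set.seed(24)
  ps <- random_prob_set(3, 8)
  ps$homology[] <- 0.5; diag(ps$homology) <- 0.5
  d <- dense_mats(ps)
  # plain average of relay products, weights cancel
  plain <- matrix(0, nrow(d$A[["1:2"]]), ncol(d$A[["1:2"]]))
  for (z in 1:3) {
    relay <- if (z %in% c(1, 2)) d$A[["1:2"]]
             else dget_align(d, 1, z) %*% dget_align(d, z, 2)
    plain <- plain + relay / 3
  }
  plain <- dprune(plain, ps$threshold)
  out <- inter_sequence_transform(ps)
  expect_lt(max(abs(as.matrix(out$align[["1:2"]]) - plain)), 1e-12)
})

test_that("intra transform with a perfect homolog copies its pairing matrix", {
  # y is a copy of x with an identity alignment matrix; alpha = 0 must make
  # x inherit y's (symmetrized, upper-triangular) pairing matrix exactly.
  x <- "GGGACAAACCC"
  seqs <- c(a = x, b = x)
  ps <- probability_set(seqs, threshold = 0)
  n <- nchar(x)
  ps$align[["1:2"]] <- rnamea:::as_dgc(Matrix::Diagonal(n))
  ps$homology[] <- 1
  out <- intra_sequence_transform(ps, alpha = 0)
  expect_lt(max(abs(out$pair[[1]] - ps$pair[[2]])), 1e-12)
})

test_that("empty pairing matrices zero the four-way result at beta = 1", {
  seqs <- c(a = "AAAAAAA", b = "AAAAAAA")  # no canonical pairs
  ps <- probability_set(seqs)
  out <- fourway_transform(ps, beta = 1)
  expect_equal(length(out$align[["1:2"]]@x), 0)
})

test_that("transforms keep probabilities in [0,1] and respect the threshold", {
  set.seed(25)
  for (rep in 1:5) {
    ps <- apply_consistency(random_prob_set(4, 10), runif(1), runif(1), 1)
    for (key in names(ps$align)) {
      v <- ps$align[[key]]@x
      expect_true(all(v >= ps$threshold - 1e-15 & v <= 1))
    }
    for (k in seq_along(ps$pair)) {
      v <- ps$pair[[k]]@x
      expect_true(all(v >= ps$threshold - 1e-15 & v <= 1))
    }
  }
})

test_that("zero rounds leave the probability set untouched", {
  set.seed(26)
  ps <- random_prob_set(3, 8)
  out <- apply_consistency(ps, 0.4, 0.1, rounds = 0)
  expect_identical(lapply(out$align, as.matrix), lapply(ps$align, as.matrix))
  expect_identical(lapply(out$pair, as.matrix), lapply(ps$pair, as.matrix))
})
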