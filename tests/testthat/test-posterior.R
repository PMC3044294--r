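test_that("pair-HMM posteriors match exhaustive alignment enumeration", {
  set.seed(101)
  for (rep in 1:8) {
    params <- random_phmm()
    x <- random_rna(sample(2:4, 1))
    y <- random_rna(sample(2:4, 1))
    oracle <- oracle_pairwise_posterior(x, y, params)
    got <- as.matrix(align_posteriors(x, y, params, threshold = 0))
    expect_lt(max(abs(got - oracle$post)), 1e-10)
    lz <- rnamea:::phmm_logZ(x, y, params)
    expect_lt(abs(lz[["forward"]] - log(oracle$Z)), 1e-10)
  }
  # 2x2 case marginalizes over exactly 13 global alignments
  expect_equal(count_alignments(2, 2), 13)
})

test_that("forward and backward recursions agree on long random sequences", {
  set.seed(7)
  for (rep in 1:5) {
    params <- random_phmm()
    lz <- rnamea:::phmm_logZ(random_rna(sample(20:50, 1)),
                             random_rna(sample(20:50, 1)), params)
    expect_lt(abs(lz[["forward"]] - lz[["backward"]]), 1e-8)
  }
})

test_that("match-biased posteriors on identical sequences peak on the diagonal", {
  params <- phmm_params(match_prob = 0.9, delta = 0.01)
  P <- as.matrix(align_posteriors("ACGU", "ACGU", params, threshold = 0))
  for (i in 1:4) expect_equal(which.max(P[i, ]), i)
})

test_that("posterior rows and columns are sub-stochastic", {
  set.seed(11)
  for (rep in 1:5) {
    P <- align_posteriors(random_rna(15), random_rna(12), threshold = 0)
    expect_true(all(Matrix::rowSums(P) <= 1 + 1e-9))
    expect_true(all(Matrix::colSums(P) <= 1 + 1e-9))
  }
})

test_that("posterior matrices are symmetric under argument swap", {
  set.seed(12)
  x <- random_rna(9); y <- random_rna(11)
  A <- align_posteriors(x, y, threshold = 0)
  B <- align_posteriors(y, x, threshold = 0)
  expect_lt(max(abs(A - Matrix::t(B))), 1e-12)
})

test_that("pairing posteriors match exhaustive structure enumeration", {
  set.seed(202)
  for (rep in 1:8) {
    model <- random_pairing_model()
    x <- random_rna(sample(6:12, 1))
    oracle <- oracle_pairing_posterior(x, model)
    got <- as.matrix(pairing_posteriors(x, model, threshold = 0))
    expect_lt(max(abs(got - oracle)), 1e-10)
  }
  # the classic hairpin concentrates mass on the stem
  P <- as.matrix(pairing_posteriors("GGGAAACCC"))
  expect_gt(P[1, 9] + P[2, 8] + P[3, 7], 1)
})

test_that("sequences without canonical pairs give an empty pairing matrix", {
  expect_equal(length(pairing_posteriors("AAAAAA")@x), 0)
  # N never pairs
  expect_equal(length(pairing_posteriors("GGGNNNCCC")@x),
               length(pairing_posteriors("GGGAAACCC")@x))
  expect_equal(length(pairing_posteriors("NNNNNNNNN")@x), 0)
})

test_that("each base pairs with at most one partner in expectation", {
  set.seed(13)
  for (rep in 1:5) {
    P <- pairing_posteriors(random_rna(30), threshold = 0)
    tot <- Matrix::rowSums(P) + Matrix::colSums(P)
    expect_true(all(tot <= 1 + 1e-9))
  }
})

test_that("raising the sparsity threshold only removes entries", {
  set.seed(14)
  x <- random_rna(12); y <- random_rna(12)
  lo <- align_posteriors(x, y, threshold = 0.001)
  hi <- align_posteriors(x, y, threshold = 0.05)
  lo_m <- as.matrix(lo); hi_m <- as.matrix(hi)
  kept <- hi_m > 0
  expect_true(all(lo_m[kept] == hi_m[kept]))
  expect_true(all(hi_m[!kept] == 0))
  expect_lte(length(hi@x), length(lo@x))
})

test_that("homology probability behaves like an expected alignment accuracy", {
  x <- "GGGACAAACCC"
  p_same <- homology_probability(x, x,
                                 params = phmm_params(match_prob = 0.9,
                                                      delta = 0.01))
  expect_gte(p_same, 0.9)
  expect_lte(p_same, 1)
  # all-zero posterior gives zero
  z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(5, 5))
  expect_equal(homology_probability("ACGUA", "ACGUA", posterior = z), 0)
  # symmetry
  set.seed(15)
  a <- random_rna(10); b <- random_rna(14)
  expect_lt(abs(homology_probability(a, b) - homology_probability(b, a)), 1e-12)
})

test_that("degenerate parameters are rejected", {
  p <- phmm_params()
  p$init <- c(0, 0, 0)
  expect_error(align_posteriors("AC", "GU", p))
})

test_that("pair-HMM parameters load from a YAML config file", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("match_prob: 0.7", "delta: 0.01"), f)
  p <- phmm_params_from_file(f)
  expect_equal(sum(diag(p$emit_match)), 0.7)
  expect_equal(unname(p$init[["Ix"]]), 0.01)
  expect_equal(unname(p$trans["Ix", "Ix"]), 0.7)  # epsilon default untouched
})
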