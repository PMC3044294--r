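# Posterior probabilities: pair-HMM base-alignment posteriors, partition
# function base-pairing posteriors, MEA pairwise alignment and the homology
# probability used as a consistency weight.

#' @keywords internal
encode_seq <- function(s) {
  codes <- match(strsplit(s, "", fixed = TRUE)[[1]], RNA_ALPHABET)
  if (anyNA(codes)) stop("sequence contains non-ACGUN characters", call. = FALSE)
  as.integer(codes - 1L)
}

#' @keywords internal
as_dgc <- function(M) {
  if (!methods::is(M, "Matrix")) M <- Matrix::Matrix(M, sparse = TRUE)
  as(as(as(M, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

# Drop entries below the sparsity threshold and clamp into [0, 1].
#' @keywords internal
prune_sparse <- function(M, threshold) {
  M <- as_dgc(M)
  M@x[M@x < threshold] <- 0
  M@x <- pmin(M@x, 1)
  Matrix::drop0(M)
}

#' Posterior base-alignment probabilities for a sequence pair
#'
#' Runs forward-backward over a three-state pair-HMM in log space; entry
#' `(i, j)` is the posterior probability that `x[i]` and `y[j]` are matched
#' in the (unknown) true alignment.  Entries below `threshold` are dropped,
#' which keeps the matrix at a few nonzeros per row in practice.
#'
#' @param x,y RNA residue strings (A,C,G,U,N).
#' @param params pair-HMM parameters from [phmm_params()].
#' @param threshold sparsity threshold.
#' @return sparse `dgCMatrix` of dimension `nchar(x)` by `nchar(y)`.
#' @export
#' @examples
#' round(as.matrix(align_posteriors("ACGU", "ACGU")), 2)
align_posteriors <- function(x, y, params = phmm_params(), threshold = 0.01) {
  if (nchar(x) < 1 || nchar(y) < 1) stop("sequences must be nonempty", call. = FALSE)
  validate_phmm_params(params)
  r <- phmm_posterior_cpp(encode_seq(x), encode_seq(y),
                          params$emit_match, unname(params$emit_insert),
                          unname(params$trans), unname(params$init))
  prune_sparse(r$post, threshold)
}

# Forward and backward total log-probabilities (internal; used to verify
# that the two recursions agree).
#' @keywords internal
phmm_logZ <- function(x, y, params = phmm_params()) {
  r <- phmm_posterior_cpp(encode_seq(x), encode_seq(y),
                          params$emit_match, unname(params$emit_insert),
                          unname(params$trans), unname(params$init))
  c(forward = r$logZf, backward = r$logZb)
}

#' Base-pairing probabilities for one sequence
#'
#' Inside-outside dynamic programming over the Boltzmann-weighted
#' Nussinov-style ensemble of [pairing_model()]: entry `(i, j)` (with
#' `i < j`) is the weighted fraction of nested structures in which positions
#' `i` and `j` pair.  Pairs enclosing fewer than `h` unpaired positions are
#' excluded; N never pairs.
#'
#' @param x RNA residue string.
#' @param model pairing model from [pairing_model()].
#' @param threshold sparsity threshold.
#' @return upper-triangular sparse `dgCMatrix`.
#' @export
#' @examples
#' round(as.matrix(pairing_posteriors("GGGAAACCC")), 2)
pairing_posteriors <- function(x, model = pairing_model(), threshold = 0.01) {
  if (nchar(x) < 1) stop("sequence must be nonempty", call. = FALSE)
  p <- mccaskill_cpp(encode_seq(x), model$w, model$h, model$stack)
  prune_sparse(p, threshold)
}

#' Maximum expected accuracy pairwise alignment
#'
#' Needleman-Wunsch-style dynamic program maximizing the sum of posterior
#' match probabilities over aligned positions (gap score 0).  Ties in the
#' traceback prefer match, then a gap in the second sequence, then a gap in
#' the first, so the result is deterministic.
#'
#' @param post posterior matrix from [align_posteriors()] (sparse or dense).
#' @return list with `pairs` (two-column matrix of aligned 1-based positions)
#'   and `score` (the summed posterior along the alignment).
#' @export
mea_pairwise <- function(post) {
  P <- as.matrix(post)
  n1 <- nrow(P); n2 <- ncol(P)
  D <- matrix(0, n1 + 1, n2 + 1)
  for (i in seq_len(n1))
    for (j in seq_len(n2))
      D[i + 1, j + 1] <- max(D[i, j] + P[i, j], D[i, j + 1], D[i + 1, j])
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  i <- n1; j <- n2
  while (i > 0 && j > 0) {
    if (D[i + 1, j + 1] == D[i, j] + P[i, j]) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1; j <- j - 1
    } else if (D[i + 1, j + 1] == D[i, j + 1]) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(pairs = pairs, score = D[n1 + 1, n2 + 1])
}

#' Homology probability of a sequence pair
#'
#' Expected accuracy of the maximum-expected-accuracy pairwise alignment:
#' the summed posterior over its aligned positions divided by the shorter
#' sequence length, clamped to \[0, 1\].  Used as the relay weight in the
#' consistency transformations.
#'
#' @param x,y RNA residue strings.
#' @param posterior optional precomputed posterior matrix for `(x, y)`.
#' @param params pair-HMM parameters.
#' @param threshold sparsity threshold used if the posterior is computed here.
#' @return a probability in \[0, 1\].
#' @export
homology_probability <- function(x, y, posterior = NULL,
                                 params = phmm_params(), threshold = 0.01) {
  if (is.null(posterior))
    posterior <- align_posteriors(x, y, params, threshold)
  sc <- mea_pairwise(posterior)$score
  min(1, max(0, sc / min(nchar(x), nchar(y))))
}

#' Compute the full probability set for a sequence family
#'
#' Base-alignment posteriors for every unordered pair, base-pairing
#' posteriors for every sequence, and homology probabilities (computed once,
#' from the untransformed posteriors, and reused as weights by all
#' consistency transformations).
#'
#' @param seqs named character vector of RNA sequences (length >= 1).
#' @param params pair-HMM parameters.
#' @param model pairing model.
#' @param threshold sparsity threshold.
#' @return an object of class `prob_set` with components `ids`, `seqs`,
#'   `align` (list keyed `"i:j"`, `i < j`, of sparse matrices), `pair`
#'   (per-sequence sparse upper-triangular matrices), `homology` (m x m
#'   matrix with unit diagonal), `threshold` and `h`.
#' @export
probability_set <- function(seqs, params = phmm_params(),
                            model = pairing_model(), threshold = 0.01) {
  m <- length(seqs)
  stopifnot(m >= 1, !is.null(names(seqs)))
  ids <- names(seqs)
  align <- list()
  H <- diag(1, m)
  dimnames(H) <- list(ids, ids)
  if (m >= 2) {
    for (i in seq_len(m - 1))
      for (j in seq(i + 1, m)) {
        P <- align_posteriors(seqs[[i]], seqs[[j]], params, threshold)
        align[[pair_key(i, j)]] <- P
        H[i, j] <- H[j, i] <-
          homology_probability(seqs[[i]], seqs[[j]], posterior = P)
      }
  }
  pair <- lapply(seqs, pairing_posteriors, model = model, threshold = threshold)
  structure(list(ids = ids, seqs = seqs, align = align, pair = pair,
                 homology = H, threshold = threshold, h = model$h),
            class = "prob_set")
}

#' @keywords internal
pair_key <- function(i, j) paste0(min(i, j), ":", max(i, j))

# Posterior matrix for the ordered pair (i, j); transposes the stored
# orientation when needed.
#' @keywords internal
get_align <- function(ps, i, j) {
  stopifnot(i != j)
  M <- ps$align[[pair_key(i, j)]]
  if (i < j) M else Matrix::t(M)
}

# Memoized dense views of the pairwise posterior matrices; single-element
# indexing into dgCMatrix objects is far too slow for inner DP loops.
# `anchors` (data frame s1, p1, s2, p2) saturates the listed base
# alignments to probability 1: used by refinement so that confidently
# anchored bases are never profitably broken.
#' @keywords internal
dense_align_lookup <- function(ps, anchors = NULL) {
  cache <- new.env(parent = emptyenv())
  function(i, j) {
    key <- paste0(i, ".", j)
    v <- cache[[key]]
    if (is.null(v)) {
      v <- as.matrix(get_align(ps, i, j))
      if (!is.null(anchors) && nrow(anchors) > 0) {
        fw <- anchors$s1 == i & anchors$s2 == j
        if (any(fw)) v[cbind(anchors$p1[fw], anchors$p2[fw])] <- 1
        bw <- anchors$s1 == j & anchors$s2 == i
        if (any(bw)) v[cbind(anchors$p2[bw], anchors$p1[bw])] <- 1
      }
      cache[[key]] <- v
    }
    v
  }
}

#' @method print prob_set
#' @export
print.prob_set <- function(x, ...) {
  m <- length(x$seqs)
  mu <- if (m >= 2)
    mean(vapply(x$align, function(M) length(M@x) / nrow(M), numeric(1)))
  else NA_real_
  cat(sprintf("Probability set: %d sequences (lengths %s)\n", m,
              paste(nchar(x$seqs), collapse = ", ")))
  if (!is.na(mu))
    cat(sprintf("  alignment matrices: %d, mean nonzeros/row %.2f\n",
                length(x$align), mu))
  cat(sprintf("  sparsity threshold: %g, min hairpin: %d\n", x$threshold, x$h))
  invisible(x)
}
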