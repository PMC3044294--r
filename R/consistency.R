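# Probabilistic consistency transformations.
#
# Three transforms sharpen the posterior matrices before alignment
# construction: (1) inter-sequence consistency relays base-alignment
# probabilities through third sequences, weighted by homology;
# (2) intra-sequence consistency imports base-pairing evidence from aligned
# homologs; (3) four-way consistency reinforces base alignments whose
# structural partners also align.  All three are sparse matrix products
# (Matrix package); results are clamped to [0, 1] and re-pruned at the
# sparsity threshold so no entry below it survives.

#' @keywords internal
symmetrize_pairing <- function(U) U + Matrix::t(U)

#' Inter-sequence consistency transformation
#'
#' For every pair (x, y) the new base-alignment matrix is the
#' homology-weighted average of relay products through every sequence z
#' (including x and y themselves, with identity self-relays):
#' \deqn{P'_{xy} = \sum_z w_z P_{xz} P_{zy} / \sum_z w_z,\quad
#'       w_z = P(x \diamond z) P(z \diamond y).}
#' If all weights vanish the original matrix is kept.
#'
#' @param ps a `prob_set`.
#' @return the transformed `prob_set`.
#' @export
inter_sequence_transform <- function(ps) {
  m <- length(ps$seqs)
  if (m < 2) return(ps)
  H <- ps$homology
  new_align <- ps$align
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      num <- NULL
      den <- 0
      for (z in seq_len(m)) {
        w <- H[i, z] * H[z, j]
        if (w <= 0) next
        relay <- if (z == i || z == j) ps$align[[pair_key(i, j)]]
                 else get_align(ps, i, z) %*% get_align(ps, z, j)
        num <- if (is.null(num)) w * relay else num + w * relay
        den <- den + w
      }
      if (den > 0)
        new_align[[pair_key(i, j)]] <- prune_sparse(num / den, ps$threshold)
    }
  }
  ps$align <- new_align
  ps
}

#' Intra-sequence consistency transformation
#'
#' Mixes each sequence's base-pairing matrix with the homology-weighted
#' expectation of its homologs' pairing matrices mapped through the
#' base-alignment posteriors:
#' \deqn{P'_b(x) = \alpha P_b(x) + (1-\alpha)
#'   \sum_y P(x \diamond y)\, A_{xy} \hat P_b(y) A_{xy}^T /
#'   \sum_y P(x \diamond y)}
#' with \eqn{\hat P_b} the symmetrized pairing matrix and y ranging over the
#' other sequences.  The result is restricted to the upper triangle with the
#' minimum hairpin constraint, clamped and re-pruned.  `alpha = 1` leaves
#' the pairing matrices unchanged.
#'
#' @param ps a `prob_set`.
#' @param alpha weight on the original pairing probabilities, in \[0, 1\].
#' @return the transformed `prob_set`.
#' @export
intra_sequence_transform <- function(ps, alpha = 0.4) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (alpha == 1) return(ps)
  m <- length(ps$seqs)
  if (m < 2) return(ps)
  H <- ps$homology
  new_pair <- ps$pair
  for (i in seq_len(m)) {
    acc <- NULL
    den <- 0
    for (y in seq_len(m)[-i]) {
      w <- H[i, y]
      if (w <= 0) next
      A <- get_align(ps, i, y)
      S <- A %*% symmetrize_pairing(ps$pair[[y]]) %*% Matrix::t(A)
      acc <- if (is.null(acc)) w * S else acc + w * S
      den <- den + w
    }
    if (den > 0) {
      mixed <- alpha * ps$pair[[i]] + (1 - alpha) * Matrix::triu(acc / den, k = ps$h + 1)
      new_pair[[i]] <- prune_sparse(mixed, ps$threshold)
    }
  }
  ps$pair <- new_pair
  ps
}

#' Four-way consistency transformation
#'
#' Reinforces a base alignment (x_i ~ y_j) when the structural partners of
#' i in x and of j in y also align:
#' \deqn{P'_a = (1-\beta) P_a + \beta\, \hat P_b(x)\, P_a\, \hat P_b(y)}
#' with \eqn{\hat P_b} the symmetrized pairing matrices.  `beta = 0` leaves
#' the alignment matrices unchanged; with empty pairing matrices and
#' `beta = 1` the result is everywhere zero.
#'
#' @param ps a `prob_set`.
#' @param beta weight on the structural term, in \[0, 1\].
#' @return the transformed `prob_set`.
#' @export
fourway_transform <- function(ps, beta = 0.1) {
  stopifnot(beta >= 0, beta <= 1)
  if (beta == 0) return(ps)
  m <- length(ps$seqs)
  if (m < 2) return(ps)
  new_align <- ps$align
  for (i in seq_len(m - 1)) {
    Bx <- symmetrize_pairing(ps$pair[[i]])
    for (j in seq(i + 1, m)) {
      By <- symmetrize_pairing(ps$pair[[j]])
      P <- ps$align[[pair_key(i, j)]]
      Pn <- (1 - beta) * P + beta * (Bx %*% P %*% By)
      new_align[[pair_key(i, j)]] <- prune_sparse(Pn, ps$threshold)
    }
  }
  ps$align <- new_align
  ps
}

#' Apply all three consistency transformations
#'
#' Runs the inter-sequence, intra-sequence and four-way transformations, in
#' that order, `rounds` times.  `rounds = 0` returns the input unchanged.
#'
#' @param ps a `prob_set`.
#' @param alpha intra-sequence weight.
#' @param beta four-way weight.
#' @param rounds number of rounds.
#' @return the transformed `prob_set`.
#' @export
apply_consistency <- function(ps, alpha = 0.4, beta = 0.1, rounds = 1L) {
  stopifnot(rounds >= 0)
  for (r in seq_len(rounds)) {
    ps <- inter_sequence_transform(ps)
    ps <- intra_sequence_transform(ps, alpha)
    ps <- fourway_transform(ps, beta)
  }
  ps
}
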