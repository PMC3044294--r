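# Discriminative split-and-realign refinement.
#
# For each sequence x in turn: find its cluster of similar sequences by
# k-means over homology-probability features, realign x against the profile
# of its cluster, then profile-profile align the cluster against the rest.
# A pass is kept only if it does not decrease the alignment's total
# posterior score, so the expected-accuracy objective is non-decreasing.

# Columns of an alignment as lists of (seq, pos) members, left to right.
#' @keywords internal
msa_columns <- function(aln) {
  rows <- strsplit(aln$rows, "", fixed = TRUE)
  n <- length(rows[[1]])
  m <- length(rows)
  counters <- integer(m)
  cols <- vector("list", n)
  for (ci in seq_len(n)) {
    sq <- integer(0); po <- integer(0)
    for (s in seq_len(m)) {
      if (rows[[s]][ci] != "-") {
        counters[s] <- counters[s] + 1L
        sq <- c(sq, s); po <- c(po, counters[s])
      }
    }
    cols[[ci]] <- list(seq = sq, pos = po)
  }
  cols
}

#' @keywords internal
msa_from_columns <- function(cols, seqs) {
  chars <- lapply(seqs, function(x) strsplit(x, "", fixed = TRUE)[[1]])
  keep <- vapply(cols, function(cl) length(cl$seq) > 0, logical(1))
  cols <- cols[keep]
  rows <- matrix("-", nrow = length(seqs), ncol = length(cols))
  for (ci in seq_along(cols)) {
    cl <- cols[[ci]]
    for (k in seq_along(cl$seq))
      rows[cl$seq[k], ci] <- chars[[cl$seq[k]]][cl$pos[k]]
  }
  out <- apply(rows, 1, paste0, collapse = "")
  names(out) <- names(seqs)
  rna_msa(out)
}

# Summed transformed posterior over all aligned residue pairs of the MSA:
# the expected-accuracy objective the refinement must not decrease.
#' Total posterior score of an alignment
#' @param aln an `rna_msa` over the sequences of `ps`.
#' @param ps a (transformed) `prob_set`.
#' @return the summed base-alignment posterior over aligned pairs.
#' @export
msa_posterior_score <- function(aln, ps, lookup = dense_align_lookup(ps)) {
  cols <- msa_columns(aln)
  idx <- match(names(aln$rows), ps$ids)
  total <- 0
  for (cl in cols) {
    k <- length(cl$seq)
    if (k < 2) next
    for (a in seq_len(k - 1))
      for (b in seq((a + 1), k)) {
        sa <- idx[cl$seq[a]]; sb <- idx[cl$seq[b]]
        total <- total + lookup(sa, sb)[cl$pos[a], cl$pos[b]]
      }
  }
  total
}

#' Cluster sequences similar to a target
#'
#' k-means over homology-probability feature vectors (row s of the homology
#' matrix describes sequence s); returns the cluster containing `x`.
#' Initial centers are chosen by deterministic farthest-point traversal so
#' the clustering is reproducible.  `k = 1`, a single sequence, or fewer
#' distinct feature rows than `k` all degrade gracefully.
#'
#' @param x index (or id) of the target sequence.
#' @param homology m x m homology-probability matrix with row/col names.
#' @param k number of clusters.
#' @return integer indices of the cluster containing `x` (always includes x).
#' @export
cluster_similar <- function(x, homology, k = 2L) {
  m <- nrow(homology)
  if (is.character(x)) x <- match(x, rownames(homology))
  stopifnot(!is.na(x), x >= 1, x <= m)
  if (k <= 1 || m <= 2) return(seq_len(m))
  feats <- unname(homology)
  k <- min(k, nrow(unique(feats)))
  if (k <= 1) return(seq_len(m))
  # Farthest-point initial centers, seeded at the sequence with the lowest
  # mean homology to the rest (the most peripheral row); ties by index.
  d <- as.matrix(stats::dist(feats))
  first <- which.min(rowMeans(homology))
  centers <- first
  while (length(centers) < k) {
    mind <- apply(d[, centers, drop = FALSE], 1, min)
    mind[centers] <- -1
    centers <- c(centers, which.max(mind))
  }
  km <- stats::kmeans(feats, centers = feats[centers, , drop = FALSE],
                      iter.max = 100)
  which(km$cluster == km$cluster[x])
}

# Needleman-Wunsch over two column lists; the score of aligning two columns
# is the summed posterior between their member residues; gaps score 0.
# Traceback ties prefer match, then a gap in the second profile.
#' @keywords internal
profile_align <- function(colsA, colsB, lookup) {
  nA <- length(colsA); nB <- length(colsB)
  if (nA == 0) return(colsB)
  if (nB == 0) return(colsA)
  S <- matrix(0, nA, nB)
  for (a in seq_len(nA)) {
    ca <- colsA[[a]]
    if (length(ca$seq) == 0) next
    for (b in seq_len(nB)) {
      cb <- colsB[[b]]
      sc <- 0
      for (u in seq_along(ca$seq))
        for (v in seq_along(cb$seq))
          sc <- sc + lookup(ca$seq[u], cb$seq[v])[ca$pos[u], cb$pos[v]]
      S[a, b] <- sc
    }
  }
  D <- matrix(0, nA + 1, nB + 1)
  for (a in seq_len(nA))
    for (b in seq_len(nB))
      D[a + 1, b + 1] <- max(D[a, b] + S[a, b], D[a, b + 1], D[a + 1, b])
  merged <- list()
  a <- nA; b <- nB
  while (a > 0 || b > 0) {
    if (a > 0 && b > 0 && D[a + 1, b + 1] == D[a, b] + S[a, b]) {
      merged <- c(list(list(seq = c(colsA[[a]]$seq, colsB[[b]]$seq),
                            pos = c(colsA[[a]]$pos, colsB[[b]]$pos))), merged)
      a <- a - 1; b <- b - 1
    } else if (a > 0 && D[a + 1, b + 1] == D[a, b + 1]) {
      merged <- c(list(colsA[[a]]), merged)
      a <- a - 1
    } else {
      merged <- c(list(colsB[[b]]), merged)
      b <- b - 1
    }
  }
  merged
}

#' @keywords internal
restrict_columns <- function(cols, keep_seqs) {
  out <- lapply(cols, function(cl) {
    sel <- cl$seq %in% keep_seqs
    list(seq = cl$seq[sel], pos = cl$pos[sel])
  })
  out[vapply(out, function(cl) length(cl$seq) > 0, logical(1))]
}

#' Discriminative split-and-realign refinement
#'
#' For each sequence x in turn: (1) find the set of sequences similar to x
#' by [cluster_similar()]; (2) remove x's row and realign x against the
#' profile of its cluster by posterior-sum profile dynamic programming;
#' (3) profile-profile align the cluster (now containing x) against the
#' remaining sequences.  After each full pass the total posterior score is
#' compared with the pre-pass score and the better alignment is kept, so the
#' score never decreases.
#'
#' @param aln an `rna_msa` of the sequences in `ps`.
#' @param ps the transformed `prob_set`.
#' @param passes number of refinement passes (0 returns `aln` unchanged).
#' @param k number of k-means clusters.
#' @param anchors optional data frame (`s1`, `p1`, `s2`, `p2`) of
#'   structurally anchored base alignments whose posteriors are saturated
#'   to 1 during refinement, so confidently anchored bases are not broken.
#' @return the refined `rna_msa`.
#' @export
refine_alignment <- function(aln, ps, passes = 1L, k = 2L, anchors = NULL) {
  stopifnot(inherits(aln, "rna_msa"), passes >= 0)
  m <- length(aln$rows)
  if (m < 2 || passes == 0) return(aln)
  seqs <- degap(aln)
  stopifnot(identical(sort(names(seqs)), sort(ps$ids)))
  # Work in ps index order.
  seqs <- seqs[ps$ids]
  aln <- rna_msa(aln$rows[ps$ids])
  lookup <- dense_align_lookup(ps, anchors)
  for (pass in seq_len(passes)) {
    before <- msa_posterior_score(aln, ps, lookup)
    cand <- aln
    for (x in seq_len(m)) {
      Sx <- cluster_similar(x, ps$homology, k)
      cols <- msa_columns(cand)
      colsA <- restrict_columns(cols, setdiff(Sx, x))
      colsX <- lapply(seq_len(nchar(seqs[[x]])),
                      function(p) list(seq = x, pos = p))
      withX <- profile_align(colsA, colsX, lookup)
      rest <- setdiff(seq_len(m), Sx)
      if (length(rest) > 0) {
        colsR <- restrict_columns(cols, rest)
        withX <- profile_align(withX, colsR, lookup)
      }
      cand <- msa_from_columns(withX, seqs)
    }
    after <- msa_posterior_score(cand, ps, lookup)
    if (after >= before) aln <- cand
    if (after <= before) break
  }
  aln
}
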