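# Independent brute-force oracles, deliberately written without reusing any
# package dynamic-programming code paths.

# --- pair-HMM: exhaustive enumeration of all global pairwise alignments ----
# States 1=M, 2=Ix, 3=Iy; an alignment (sequence of column types) has one
# path, whose probability is init * prod(trans) * prod(emissions).
oracle_pairwise_posterior <- function(x, y, params) {
  cx <- strsplit(x, "", fixed = TRUE)[[1]]
  cy <- strsplit(y, "", fixed = TRUE)[[1]]
  n1 <- length(cx); n2 <- length(cy)
  em <- function(a, b) {
    E <- params$emit_match
    if (a == "N" && b == "N") mean(E)
    else if (a == "N") mean(E[, b])
    else if (b == "N") mean(E[a, ])
    else E[a, b]
  }
  ei <- function(a) if (a == "N") 0.25 else params$emit_insert[[a]]
  post_num <- matrix(0, n1, n2)
  Z <- 0
  walk <- function(i, j, state, prob, matched) {
    if (i == n1 && j == n2) {
      Z <<- Z + prob
      for (r in seq_len(nrow(matched)))
        post_num[matched[r, 1], matched[r, 2]] <<-
          post_num[matched[r, 1], matched[r, 2]] + prob
      return(invisible())
    }
    step <- function(nstate, ni, nj, emis, add_match) {
      tr <- if (state == 0) params$init[nstate] else params$trans[state, nstate]
      if (tr <= 0 || emis <= 0) return(invisible())
      walk(ni, nj, nstate, prob * tr * emis,
           if (add_match) rbind(matched, c(ni, nj)) else matched)
    }
    if (i < n1 && j < n2) step(1, i + 1, j + 1, em(cx[i + 1], cy[j + 1]), TRUE)
    if (i < n1) step(2, i + 1, j, ei(cx[i + 1]), FALSE)
    if (j < n2) step(3, i, j + 1, ei(cy[j + 1]), FALSE)
    invisible()
  }
  walk(0, 0, 0, 1, matrix(0, 0, 2))
  list(post = post_num / Z, Z = Z,
       n_alignments = NA)  # path count not needed by callers
}

# Number of monotone global alignments (for sanity checks).
count_alignments <- function(n1, n2) {
  D <- matrix(0, n1 + 1, n2 + 1)
  D[1, ] <- 1; D[, 1] <- 1
  for (i in seq_len(n1))
    for (j in seq_len(n2))
      D[i + 1, j + 1] <- D[i, j] + D[i, j + 1] + D[i + 1, j]
  D[n1 + 1, n2 + 1]
}

# --- partition function: exhaustive enumeration of nested structures ------
# Returns all nested pair sets (lists of 2-col matrices) on 1..n honoring
# the pairability predicate and the minimum hairpin h.
enumerate_structures <- function(n, pairable, h) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2)))
    key <- paste0(i, "_", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- list()
    # position i unpaired
    for (s in rec(i + 1, j)) out[[length(out) + 1]] <- s
    # position i paired with k
    for (k in seq(i + h + 1, j)) {
      if (k > j || k - i - 1 < h) next
      if (!pairable(i, k)) next
      inner <- rec(i + 1, k - 1)
      outer <- rec(k + 1, j)
      for (si in inner)
        for (so in outer)
          out[[length(out) + 1]] <- rbind(c(i, k), si, so)
    }
    memo[[key]] <- out
    out
  }
  rec(1, n)
}

oracle_pairing_posterior <- function(x, model) {
  cx <- strsplit(x, "", fixed = TRUE)[[1]]
  n <- length(cx)
  w <- model$w
  pairable <- function(i, k) w[cx[i], cx[k]] > 0
  structs <- enumerate_structures(n, pairable, model$h)
  weight <- vapply(structs, function(s) {
    if (nrow(s) == 0) return(1)
    base <- prod(vapply(seq_len(nrow(s)), function(r) w[cx[s[r, 1]], cx[s[r, 2]]],
                        numeric(1)))
    keys <- paste(s[, 1], s[, 2])
    nstack <- sum(paste(s[, 1] + 1, s[, 2] - 1) %in% keys)
    base * model$stack^nstack
  }, numeric(1))
  Z <- sum(weight)
  P <- matrix(0, n, n)
  for (k in seq_along(structs)) {
    s <- structs[[k]]
    if (nrow(s) > 0)
      for (r in seq_len(nrow(s)))
        P[s[r, 1], s[r, 2]] <- P[s[r, 1], s[r, 2]] + weight[k]
  }
  P / Z
}

# --- dense consistency-transform oracles ----------------------------------
# Operate on plain dense matrices extracted from a prob_set; same formulas,
# base-R matrix algebra.
dense_mats <- function(ps) {
  m <- length(ps$seqs)
  A <- list()
  if (m >= 2)
    for (i in seq_len(m - 1))
      for (j in seq(i + 1, m))
        A[[paste0(i, ":", j)]] <- as.matrix(ps$align[[paste0(i, ":", j)]])
  U <- lapply(ps$pair, as.matrix)
  list(A = A, U = U, H = ps$homology, thr = ps$threshold, h = ps$h,
       m = m, lens = nchar(ps$seqs))
}

dget_align <- function(d, i, j) {
  if (i < j) d$A[[paste0(i, ":", j)]] else t(d$A[[paste0(j, ":", i)]])
}

dprune <- function(M, thr) {
  M[M < thr] <- 0
  pmin(M, 1)
}

oracle_inter <- function(d) {
  newA <- d$A
  for (i in seq_len(d$m - 1)) for (j in seq((i + 1), d$m)) {
    num <- matrix(0, d$lens[i], d$lens[j]); den <- 0
    for (z in seq_len(d$m)) {
      w <- d$H[i, z] * d$H[z, j]
      if (w <= 0) next
      relay <- if (z == i || z == j) d$A[[paste0(i, ":", j)]]
               else dget_align(d, i, z) %*% dget_align(d, z, j)
      num <- num + w * relay; den <- den + w
    }
    if (den > 0) newA[[paste0(i, ":", j)]] <- dprune(num / den, d$thr)
  }
  d$A <- newA
  d
}

oracle_intra <- function(d, alpha) {
  if (alpha == 1) return(d)
  newU <- d$U
  for (i in seq_len(d$m)) {
    acc <- matrix(0, d$lens[i], d$lens[i]); den <- 0
    for (y in seq_len(d$m)[-i]) {
      w <- d$H[i, y]
      if (w <= 0) next
      A <- dget_align(d, i, y)
      S <- A %*% (d$U[[y]] + t(d$U[[y]])) %*% t(A)
      acc <- acc + w * S; den <- den + w
    }
    if (den > 0) {
      avg <- acc / den
      keep <- outer(seq_len(d$lens[i]), seq_len(d$lens[i]),
                    function(a, b) b - a >= d$h + 1)
      avg[!keep] <- 0
      newU[[i]] <- dprune(alpha * d$U[[i]] + (1 - alpha) * avg, d$thr)
    }
  }
  d$U <- newU
  d
}

oracle_fourway <- function(d, beta) {
  if (beta == 0) return(d)
  for (i in seq_len(d$m - 1)) for (j in seq((i + 1), d$m)) {
    Bx <- d$U[[i]] + t(d$U[[i]])
    By <- d$U[[j]] + t(d$U[[j]])
    P <- d$A[[paste0(i, ":", j)]]
    d$A[[paste0(i, ":", j)]] <- dprune((1 - beta) * P + beta * Bx %*% P %*% By,
                                       d$thr)
  }
  d
}

# --- independent reachability oracle (Floyd-Warshall closure) -------------
oracle_is_acyclic <- function(edges, n) {
  R <- matrix(FALSE, n, n)
  if (nrow(edges) > 0) R[edges] <- TRUE
  for (k in seq_len(n))
    R <- R | (outer(R[, k], R[k, ], `&`))
  !any(diag(R))
}

# --- shared fixtures -------------------------------------------------------
random_phmm <- function() {
  phmm_params(match_prob = runif(1, 0.3, 0.9),
              delta = runif(1, 0.01, 0.3),
              epsilon = runif(1, 0.2, 0.9),
              background = runif(4, 0.5, 2))
}

random_pairing_model <- function() {
  pairing_model(weights = c(GC = runif(1, 1, 8), CG = runif(1, 1, 8),
                            AU = runif(1, 0.5, 5), UA = runif(1, 0.5, 5),
                            GU = runif(1, 0.2, 3), UG = runif(1, 0.2, 3)),
                stack = runif(1, 1, 6), h = sample(1:3, 1))
}

random_rna <- function(L) paste0(sample(c("A", "C", "G", "U"), L,
                                        replace = TRUE), collapse = "")

random_prob_set <- function(m, L, threshold = 0.01) {
  seqs <- vapply(seq_len(m), function(k) random_rna(sample(4:L, 1)),
                 character(1))
  names(seqs) <- paste0("s", seq_len(m))
  probability_set(seqs, threshold = threshold)
}

# Aligned residue pairs of a two-sequence alignment as "i|j" keys.
aligned_keys_2seq <- function(aln) {
  cols <- rnamea:::msa_columns(aln)
  keys <- character(0)
  for (cl in cols)
    if (length(cl$seq) == 2) {
      o <- order(cl$seq)
      keys <- c(keys, paste0(cl$pos[o[1]], "|", cl$pos[o[2]]))
    }
  keys
}
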