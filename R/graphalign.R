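# Greedy construction of the multiple structural alignment as a DAG of
# columns.  Vertices are alignment columns (at most one residue per
# sequence); directed edges are precedence constraints induced by residue
# adjacency within sequences.  Step 1 inserts aligned base-pairs (the
# structural skeleton, with left-right compatibility); Step 2 inserts the
# most probable base alignments (acyclicity only); linearization wraps
# leftover residues in singleton columns and emits a deterministic
# topological ordering.
#
# The graph is a mutable environment: columns are integer ids, `members`
# holds per-column (seq, pos) vectors, `col_of[[s]][p]` maps residues to
# columns (0 = not inserted), `succ`/`pred` are adjacency lists and
# `paired` records Step-1 column pairs (left id, right id).

#' Create an empty alignment graph
#' @param seqs named character vector of ungapped sequences.
#' @return an environment of class `align_graph`.
#' @keywords internal
new_graph <- function(seqs) {
  g <- new.env(parent = emptyenv())
  g$ids <- names(seqs)
  g$lens <- nchar(seqs)
  g$members <- list()
  g$col_of <- lapply(nchar(seqs), function(L) integer(L))
  g$succ <- list()
  g$pred <- list()
  g$alive <- logical(0)
  g$paired <- list()
  g$anchors <- data.frame(s1 = integer(0), p1 = integer(0),
                          s2 = integer(0), p2 = integer(0))
  class(g) <- c("align_graph", "environment")
  g
}

graph_snapshot <- function(g)
  list(members = g$members, col_of = g$col_of, succ = g$succ,
       pred = g$pred, alive = g$alive, paired = g$paired,
       anchors = g$anchors)

graph_restore <- function(g, snap) {
  for (nm in names(snap)) assign(nm, snap[[nm]], envir = g)
  invisible(g)
}

# Exact reachability by iterative DFS over successor lists.
has_path <- function(g, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(length(g$alive))
  stack <- from
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    nxt <- g$succ[[v]]
    if (to %in% nxt) return(TRUE)
    stack <- c(stack, nxt[!seen[nxt]])
  }
  FALSE
}

add_edge <- function(g, a, b) {
  if (a == b) stop("internal error: self edge", call. = FALSE)
  if (!(b %in% g$succ[[a]])) {
    g$succ[[a]] <- c(g$succ[[a]], b)
    g$pred[[b]] <- c(g$pred[[b]], a)
  }
  invisible(g)
}

drop_edge <- function(g, a, b) {
  g$succ[[a]] <- setdiff(g$succ[[a]], b)
  g$pred[[b]] <- setdiff(g$pred[[b]], a)
  invisible(g)
}

# Columns of the nearest in-graph residues of sequence s before/after pos.
prev_col <- function(g, s, pos) {
  v <- g$col_of[[s]]
  if (pos <= 1) return(0L)
  idx <- which(v[seq_len(pos - 1)] > 0L)
  if (length(idx) == 0) 0L else v[max(idx)]
}

next_col <- function(g, s, pos) {
  v <- g$col_of[[s]]
  if (pos >= length(v)) return(0L)
  idx <- which(v[seq(pos + 1, length(v))] > 0L)
  if (length(idx) == 0) 0L else v[pos + min(idx)]
}

new_column <- function(g, s, pos) {
  id <- length(g$alive) + 1L
  g$members[[id]] <- list(seq = s, pos = pos)
  g$succ[[id]] <- integer(0)
  g$pred[[id]] <- integer(0)
  g$alive[id] <- TRUE
  g$col_of[[s[1]]][pos[1]] <- id
  if (length(s) > 1) g$col_of[[s[2]]][pos[2]] <- id
  id
}

col_has_seq <- function(g, col, s) s %in% g$members[[col]]$seq

# Remove a direct edge when the same precedence is implied by another path
# (local transitive reduction around column c).
prune_redundant <- function(g, c) {
  for (p in g$pred[[c]]) {
    drop_edge(g, p, c)
    if (!has_path(g, p, c)) add_edge(g, p, c)
  }
  for (s in g$succ[[c]]) {
    drop_edge(g, c, s)
    if (!has_path(g, c, s)) add_edge(g, c, s)
  }
  invisible(g)
}

#' Insert one pairwise base alignment into the graph
#'
#' Aligning residue `p1` of sequence `s1` with residue `p2` of sequence `s2`
#' triggers one of three scenarios: a new column when neither residue is
#' placed, extension of an existing column when exactly one is, or a merge
#' of two columns.  The insertion is committed only if the graph stays
#' acyclic (checked before mutation); otherwise `"rejected"` is returned and
#' the graph is unchanged.  Aligning an already-aligned pair is a trivial
#' no-op reported as `"merged"`.
#'
#' @param g an `align_graph`.
#' @param s1,s2 sequence indices (must differ).
#' @param p1,p2 residue positions.
#' @return one of `"new-column"`, `"extended"`, `"merged"`, `"rejected"`.
#' @keywords internal
insert_pair <- function(g, s1, p1, s2, p2) {
  stopifnot(s1 != s2)
  c1 <- g$col_of[[s1]][p1]
  c2 <- g$col_of[[s2]][p2]
  if (c1 > 0L && c1 == c2) return("merged")

  if (c1 == 0L && c2 == 0L) {
    pa <- prev_col(g, s1, p1); na <- next_col(g, s1, p1)
    pb <- prev_col(g, s2, p2); nb <- next_col(g, s2, p2)
    preds <- setdiff(unique(c(pa, pb)), 0L)
    succs <- setdiff(unique(c(na, nb)), 0L)
    for (s in succs)
      for (t in preds)
        if (s == t || has_path(g, s, t)) return("rejected")
    id <- new_column(g, c(s1, s2), c(p1, p2))
    for (t in preds) add_edge(g, t, id)
    for (s in succs) add_edge(g, id, s)
    prune_redundant(g, id)
    return("new-column")
  }

  if (xor(c1 > 0L, c2 > 0L)) {
    if (c1 > 0L) { col <- c1; s <- s2; pos <- p2 }
    else { col <- c2; s <- s1; pos <- p1 }
    if (col_has_seq(g, col, s)) return("rejected")
    pb <- prev_col(g, s, pos); nb <- next_col(g, s, pos)
    if (pb == col || nb == col) return("rejected")
    if (pb > 0L && has_path(g, col, pb)) return("rejected")
    if (nb > 0L && has_path(g, nb, col)) return("rejected")
    mem <- g$members[[col]]
    g$members[[col]] <- list(seq = c(mem$seq, s), pos = c(mem$pos, pos))
    g$col_of[[s]][pos] <- col
    if (pb > 0L) add_edge(g, pb, col)
    if (nb > 0L) add_edge(g, col, nb)
    prune_redundant(g, col)
    return("extended")
  }

  # Merge two distinct columns.
  if (length(intersect(g$members[[c1]]$seq, g$members[[c2]]$seq)) > 0)
    return("rejected")
  if (has_path(g, c1, c2) || has_path(g, c2, c1)) return("rejected")
  keep <- min(c1, c2); gone <- max(c1, c2)
  mk <- g$members[[keep]]; mg <- g$members[[gone]]
  g$members[[keep]] <- list(seq = c(mk$seq, mg$seq), pos = c(mk$pos, mg$pos))
  for (k in seq_along(mg$seq)) g$col_of[[mg$seq[k]]][mg$pos[k]] <- keep
  for (s in g$succ[[gone]]) {
    g$pred[[s]] <- setdiff(g$pred[[s]], gone)
    add_edge(g, keep, s)
  }
  for (p in g$pred[[gone]]) {
    g$succ[[p]] <- setdiff(g$succ[[p]], gone)
    add_edge(g, p, keep)
  }
  g$succ[[gone]] <- integer(0)
  g$pred[[gone]] <- integer(0)
  g$members[[gone]] <- list(seq = integer(0), pos = integer(0))
  g$alive[gone] <- FALSE
  g$paired <- lapply(g$paired, function(pr) replace(pr, pr == gone, keep))
  prune_redundant(g, keep)
  "merged"
}

# Left-right compatibility: for every recorded paired column pair and every
# sequence with a residue in both, the left residue precedes the right one.
lr_compatible <- function(g) {
  for (pr in g$paired) {
    ml <- g$members[[pr[1]]]
    mr <- g$members[[pr[2]]]
    common <- intersect(ml$seq, mr$seq)
    for (s in common)
      if (ml$pos[match(s, ml$seq)] >= mr$pos[match(s, mr$seq)]) return(FALSE)
  }
  TRUE
}

#' Build the candidate sets for greedy construction
#'
#' `B` holds every base-pair whose transformed pairing probability exceeds
#' `tb`; `A` holds every stored base-alignment entry.  Both are sorted by
#' probability (descending) with a deterministic tie-break: sequence id(s)
#' lexicographically, then left index, then right index.
#'
#' @param ps a (transformed) `prob_set`.
#' @param tb base-pair probability threshold.
#' @return list with data frames `B` (`seq`, `i`, `ip`, `p`) and
#'   `A` (`s1`, `s2`, `i`, `j`, `p`).
#' @export
build_candidates <- function(ps, tb = 0.5) {
  stopifnot(tb >= 0, tb <= 1)
  m <- length(ps$seqs)
  Bl <- list()
  for (s in seq_len(m)) {
    tri <- as(ps$pair[[s]], "TsparseMatrix")
    keep <- tri@x > tb
    if (any(keep))
      Bl[[length(Bl) + 1]] <- data.frame(seq = s, i = tri@i[keep] + 1L,
                                         ip = tri@j[keep] + 1L, p = tri@x[keep])
  }
  B <- if (length(Bl) > 0) do.call(rbind, Bl)
       else data.frame(seq = integer(0), i = integer(0), ip = integer(0),
                       p = numeric(0))
  B <- B[order(-B$p, ps$ids[B$seq], B$i, B$ip), , drop = FALSE]
  Al <- list()
  if (m >= 2) {
    for (i in seq_len(m - 1))
      for (j in seq(i + 1, m)) {
        tri <- as(ps$align[[pair_key(i, j)]], "TsparseMatrix")
        if (length(tri@x) > 0)
          Al[[length(Al) + 1]] <- data.frame(s1 = i, s2 = j, i = tri@i + 1L,
                                             j = tri@j + 1L, p = tri@x)
      }
  }
  A <- if (length(Al) > 0) do.call(rbind, Al)
       else data.frame(s1 = integer(0), s2 = integer(0), i = integer(0),
                       j = integer(0), p = numeric(0))
  A <- A[order(-A$p, ps$ids[A$s1], ps$ids[A$s2], A$i, A$j), , drop = FALSE]
  rownames(A) <- rownames(B) <- NULL
  list(B = B, A = A, tb = tb)
}

#' Step 1: structural skeleton construction
#'
#' Iterates the candidate base-pairs in `B` in order; for each unused pair
#' `(x_i, x_i')` it searches `B` for an unused partner pair from another
#' sequence maximizing the product of the endpoint base-alignment
#' probabilities, tries partners in score order, and inserts both endpoint
#' alignments transactionally, subject to acyclicity and left-right
#' compatibility of all recorded paired columns.  Used pairs participate in
#' at most one skeleton match; pairs with no compatible partner are skipped.
#'
#' @param g an `align_graph`.
#' @param ps the transformed `prob_set`.
#' @param candidates from [build_candidates()].
#' @param validate optional callback `function(g)` invoked after every
#'   committed insertion (used by invariant tests).
#' @return `g`, invisibly.
#' @keywords internal
build_skeleton <- function(g, ps, candidates, validate = NULL) {
  B <- candidates$B
  if (nrow(B) == 0) return(invisible(g))
  lookup <- dense_align_lookup(ps)
  used <- rep(FALSE, nrow(B))
  for (a in seq_len(nrow(B))) {
    if (used[a]) next
    xs <- B$seq[a]; xi <- B$i[a]; xip <- B$ip[a]
    elig <- which(!used & B$seq != xs)
    if (length(elig) == 0) next
    sc <- vapply(elig, function(b) {
      A1 <- lookup(xs, B$seq[b])
      A1[xi, B$i[b]] * A1[xip, B$ip[b]]
    }, numeric(1))
    # The match score is a probability; as everywhere in the pipeline,
    # probabilities below the sparsity threshold are treated as zero, so
    # partners without meaningful support at both stem ends are skipped.
    ok <- sc >= ps$threshold
    elig <- elig[ok]; sc <- sc[ok]
    if (length(elig) == 0) next
    ord <- order(-sc, ps$ids[B$seq[elig]], B$i[elig], B$ip[elig])
    # Reciprocal-best admission: the anchor must in turn be the partner's
    # best-scoring match among unused pairs from other sequences; shifted
    # stem registers rarely survive this symmetric check.
    best_for <- function(b) {
      others <- which(!used & B$seq != B$seq[b])
      if (length(others) == 0) return(NA_integer_)
      sb <- vapply(others, function(a2) {
        A2 <- lookup(B$seq[b], B$seq[a2])
        A2[B$i[b], B$i[a2]] * A2[B$ip[b], B$ip[a2]]
      }, numeric(1))
      others[order(-sb, ps$ids[B$seq[others]], B$i[others], B$ip[others])][1]
    }
    for (b in elig[ord]) {
      if (!identical(best_for(b), a)) next
      snap <- graph_snapshot(g)
      r1 <- insert_pair(g, xs, xi, B$seq[b], B$i[b])
      if (r1 == "rejected") { graph_restore(g, snap); next }
      r2 <- insert_pair(g, xs, xip, B$seq[b], B$ip[b])
      if (r2 == "rejected") { graph_restore(g, snap); next }
      cl <- g$col_of[[xs]][xi]
      cr <- g$col_of[[xs]][xip]
      g$paired <- c(g$paired, list(c(cl, cr)))
      if (!lr_compatible(g)) {
        graph_restore(g, snap)
        next
      }
      used[a] <- used[b] <- TRUE
      g$anchors <- rbind(g$anchors,
                         data.frame(s1 = c(xs, xs), p1 = c(xi, xip),
                                    s2 = rep(B$seq[b], 2),
                                    p2 = c(B$i[b], B$ip[b])))
      if (!is.null(validate)) validate(g)
      break
    }
  }
  invisible(g)
}

#' Step 2: insert highly probable base alignments
#'
#' Iterates the candidate base alignments `A` in order of transformed
#' probability, inserting each one that keeps the graph acyclic (and, when
#' `strict_lr`, left-right compatible with the recorded paired columns).
#'
#' @inheritParams build_skeleton
#' @param strict_lr also enforce left-right compatibility here.
#' @keywords internal
insert_local_alignments <- function(g, candidates, strict_lr = FALSE,
                                    validate = NULL) {
  A <- candidates$A
  for (a in seq_len(nrow(A))) {
    if (strict_lr) {
      snap <- graph_snapshot(g)
      r <- insert_pair(g, A$s1[a], A$i[a], A$s2[a], A$j[a])
      if (r != "rejected" && !lr_compatible(g)) {
        graph_restore(g, snap)
        r <- "rejected"
      }
    } else {
      r <- insert_pair(g, A$s1[a], A$i[a], A$s2[a], A$j[a])
    }
    if (r != "rejected" && !is.null(validate)) validate(g)
  }
  invisible(g)
}

#' Linearize the alignment graph into a multiple alignment
#'
#' Residues not yet in any column are wrapped in singleton columns, residue
#' adjacency edges are completed, and the columns are emitted in a
#' deterministic topological order (Kahn's algorithm; among ready columns
#' the one whose lowest-indexed member sequence and position sort first is
#' emitted).  De-gapping any output row reproduces its input sequence.
#'
#' @param g an `align_graph`.
#' @param seqs the named input sequences.
#' @return an `rna_msa`.
#' @keywords internal
linearize <- function(g, seqs) {
  for (s in seq_along(seqs))
    for (p in which(g$col_of[[s]] == 0L))
      new_column(g, s, p)
  for (s in seq_along(seqs)) {
    cols <- g$col_of[[s]]
    if (length(cols) > 1)
      for (t in seq_len(length(cols) - 1))
        if (!(cols[t + 1] %in% g$succ[[cols[t]]]))
          add_edge(g, cols[t], cols[t + 1])
  }
  alive <- which(g$alive)
  n <- length(alive)
  key1 <- vapply(alive, function(c) min(g$members[[c]]$seq), numeric(1))
  key2 <- vapply(alive, function(c) {
    m <- g$members[[c]]
    m$pos[which.min(m$seq)]
  }, numeric(1))
  indeg <- vapply(alive, function(c) length(g$pred[[c]]), integer(1))
  names(indeg) <- alive
  emitted <- integer(0)
  ready <- alive[indeg == 0]
  chars <- lapply(seqs, function(x) strsplit(x, "", fixed = TRUE)[[1]])
  while (length(ready) > 0) {
    k1 <- key1[match(ready, alive)]
    k2 <- key2[match(ready, alive)]
    pick <- ready[order(k1, k2)][1]
    ready <- setdiff(ready, pick)
    emitted <- c(emitted, pick)
    for (s in g$succ[[pick]]) {
      indeg[as.character(s)] <- indeg[as.character(s)] - 1L
      if (indeg[as.character(s)] == 0L) ready <- c(ready, s)
    }
  }
  if (length(emitted) != n)
    stop("internal consistency error: cycle in alignment graph", call. = FALSE)
  rows <- matrix("-", nrow = length(seqs), ncol = n)
  for (ci in seq_along(emitted)) {
    m <- g$members[[emitted[ci]]]
    for (k in seq_along(m$seq))
      rows[m$seq[k], ci] <- chars[[m$seq[k]]][m$pos[k]]
  }
  out <- apply(rows, 1, paste0, collapse = "")
  names(out) <- names(seqs)
  aln <- rna_msa(out)
  attr(aln, "column_order") <- emitted
  aln
}

# Graph invariant accessors used by tests.
graph_columns <- function(g)
  lapply(which(g$alive), function(c) g$members[[c]])

graph_edges <- function(g) {
  el <- list()
  for (a in which(g$alive))
    for (b in g$succ[[a]]) el[[length(el) + 1]] <- c(a, b)
  if (length(el) == 0) matrix(integer(0), ncol = 2)
  else do.call(rbind, el)
}
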