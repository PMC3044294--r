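# Synthetic RNA family generator.
#
# Samples a nested stem-loop structure and an ancestral sequence with
# canonical base pairs at paired sites, then evolves a two-level phylogeny:
# deep branches to subfamily ancestors (heavy, largely compensatory
# substitution at stems — the covariation signal of structurally conserved,
# sequence-divergent families) and shallow branches to the descendants of
# each subfamily.  Indels are confined to unpaired (loop/spacer/flank)
# regions so the true alignment stays unambiguous at stems.  The true
# alignment, true structure, per-sequence structures and subfamily labels
# are all returned.

# Substitute a sequence given per-pair / per-site rates; paired sites
# mutate compensatorily (to another canonical pair) with prob `comp`.
mutate_sequence <- function(seq_chars, pairs, unpaired, stem_rate, loop_rate,
                            comp) {
  bases <- c("A", "C", "G", "U")
  canon <- c("GC", "CG", "AU", "UA", "GU", "UG")
  out <- seq_chars
  for (r in seq_len(nrow(pairs))) {
    if (stats::runif(1) < stem_rate) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (stats::runif(1) < comp) {
        # Watson-Crick replacements dominate; wobble pairs are rare
        # transitional states, as in real covariation.
        cur <- paste0(out[i], out[j])
        wts <- c(GC = 1, CG = 1, AU = 1, UA = 1, GU = 0.1, UG = 0.1)
        alt <- canon[canon != cur]
        t <- sample(alt, 1, prob = wts[alt])
        out[i] <- substr(t, 1, 1); out[j] <- substr(t, 2, 2)
      } else {
        side <- if (stats::runif(1) < 0.5) i else j
        out[side] <- sample(setdiff(bases, out[side]), 1)
      }
    }
  }
  for (p in unpaired)
    if (stats::runif(1) < loop_rate)
      out[p] <- sample(setdiff(bases, out[p]), 1)
  out
}

#' Simulate an RNA sequence family with known truth
#'
#' @param m number of descendant sequences (>= 2), split as evenly as
#'   possible over the subfamilies.
#' @param L ancestral sequence length (>= 10).
#' @param sub_rate deep-branch substitution probability at unpaired sites.
#' @param stem_sub_rate deep-branch substitution probability per base pair;
#'   the default, well above `sub_rate`, emulates strong compensatory
#'   covariation: stems diverge in sequence while staying paired.
#' @param indel_rate per-unpaired-site indel probability per descendant
#'   (split evenly between a deletion and an insertion after the site).
#' @param compensatory probability that a substitution hitting a paired site
#'   replaces the whole pair by another canonical pair.
#' @param within_scale shallow-branch (within-subfamily) rates as a fraction
#'   of the deep-branch rates; small values give tight subfamilies.
#' @param n_subfamilies number of subfamilies (1 gives a star phylogeny).
#' @param seed RNG seed; the same seed reproduces the sample byte for byte.
#' @param n_hairpins number of stem-loops; default scales with `L`.
#' @return object of class `rna_family`: `sequences` (named character
#'   vector), `alignment` (the true `rna_msa` with consensus structure),
#'   `structure` (ancestral pair list), `structures` (per-descendant pair
#'   matrices in descendant coordinates), `subfamily` (integer labels) and
#'   `params`.
#' @export
#' @examples
#' fam <- simulate_family(m = 4, L = 40, seed = 1)
#' fam$alignment
simulate_family <- function(m = 6, L = 80, sub_rate = 0.25,
                            stem_sub_rate = 0.7, indel_rate = 0.05,
                            compensatory = 0.95, within_scale = 0.25,
                            n_subfamilies = 2L, seed = 1,
                            n_hairpins = if (L >= 50) 2L else 1L) {
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  rates <- c(sub_rate, stem_sub_rate, indel_rate, compensatory, within_scale)
  if (any(rates < 0) || any(rates > 1))
    stop("rates must be in [0, 1]", call. = FALSE)
  if (n_subfamilies < 1 || n_subfamilies > m)
    stop("n_subfamilies must be in [1, m]", call. = FALSE)
  # Minimal stem-loop: 3 bp stem + 3 nt loop, plus a 1 nt flank.
  if (L < 10 || L < n_hairpins * 9 + 1)
    stop("L = ", L, " too small for ", n_hairpins,
         " feasible stem-loop(s)", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  # --- nested structure: n_hairpins stem-loops separated by spacers -----
  spare <- L - n_hairpins * 9
  stems <- loops <- integer(n_hairpins)
  for (k in seq_len(n_hairpins)) {
    extra_s <- if (spare > 1) sample(min(2, spare %/% 2):min(5, spare %/% 2), 1)
               else 0
    spare <- spare - 2 * extra_s
    stems[k] <- 3 + extra_s
    extra_l <- if (spare > 0) sample(0:min(3, spare), 1) else 0
    spare <- spare - extra_l
    loops[k] <- 3 + extra_l
  }
  # Distribute the remainder over flanks/spacers (n_hairpins + 1 slots).
  gaps <- rep(spare %/% (n_hairpins + 1), n_hairpins + 1)
  gaps[1] <- gaps[1] + spare %% (n_hairpins + 1)
  pairs <- matrix(integer(0), ncol = 2)
  pos <- 0
  for (k in seq_len(n_hairpins)) {
    pos <- pos + gaps[k]
    a <- pos + 1
    s <- stems[k]; l <- loops[k]
    pairs <- rbind(pairs, cbind(a + 0:(s - 1), a + 2 * s + l - 1 - 0:(s - 1)))
    pos <- pos + 2 * s + l
  }
  colnames(pairs) <- c("i", "j")
  paired_with <- integer(L)
  paired_with[pairs[, 1]] <- pairs[, 2]
  paired_with[pairs[, 2]] <- pairs[, 1]
  unpaired <- which(paired_with == 0)

  # --- ancestral sequence ----------------------------------------------
  # Structured families are under selection to fold dominantly into their
  # native structure, so candidate ancestors are resampled until the
  # designed stems dominate the Boltzmann ensemble (best of up to 40
  # draws); this suppresses accidental cross-arm helices.
  bases <- c("A", "C", "G", "U")
  canon <- rbind(c("G", "C"), c("C", "G"), c("A", "U"), c("U", "A"))
  draw_ancestor <- function() {
    anc <- character(L)
    anc[unpaired] <- sample(bases, length(unpaired), replace = TRUE)
    for (r in seq_len(nrow(pairs))) {
      t <- sample(1:4, 1, prob = c(0.4, 0.4, 0.1, 0.1))  # favour GC/CG
      anc[pairs[r, 1]] <- canon[t, 1]
      anc[pairs[r, 2]] <- canon[t, 2]
    }
    anc
  }
  viability <- function(anc) {
    P <- as.matrix(pairing_posteriors(paste0(anc, collapse = ""),
                                      threshold = 0))
    mean(P[pairs])
  }
  anc <- draw_ancestor()
  best_v <- viability(anc)
  tries <- 0
  while (best_v < 0.75 && tries < 40) {
    cand_anc <- draw_ancestor()
    v <- viability(cand_anc)
    if (v > best_v) { anc <- cand_anc; best_v <- v }
    tries <- tries + 1
  }

  # --- two-level phylogeny ---------------------------------------------
  subfamily <- rep(seq_len(n_subfamilies), length.out = m)
  subfamily <- sort(subfamily)
  sub_anc <- lapply(seq_len(n_subfamilies), function(k)
    mutate_sequence(anc, pairs, unpaired, stem_sub_rate, sub_rate,
                    compensatory))
  desc <- matrix("", m, L)
  deleted <- matrix(FALSE, m, L)
  inserts <- vector("list", m)
  for (d in seq_len(m)) {
    desc[d, ] <- mutate_sequence(sub_anc[[subfamily[d]]], pairs, unpaired,
                                 within_scale * stem_sub_rate,
                                 within_scale * sub_rate, compensatory)
    ins <- list()
    for (p in unpaired) {
      u <- stats::runif(1)
      if (u < indel_rate / 2) {
        deleted[d, p] <- TRUE
      } else if (u < indel_rate) {
        ins[[length(ins) + 1]] <- list(after = p, base = sample(bases, 1))
      }
    }
    inserts[[d]] <- ins
  }

  # --- assemble the true alignment -------------------------------------
  # Column plan: for position p, the ancestral column then, for each
  # descendant in index order, any private insertion column after p.
  ids <- sprintf("seq%02d", seq_len(m))
  width <- L + sum(lengths(inserts))
  rows <- matrix("-", m, width)
  colmap_anc <- integer(L)  # alignment column of each ancestral position
  ci <- 0
  for (p in seq_len(L)) {
    ci <- ci + 1
    colmap_anc[p] <- ci
    for (d in seq_len(m))
      if (!deleted[d, p]) rows[d, ci] <- desc[d, p]
    for (d in seq_len(m)) {
      for (insd in inserts[[d]]) {
        if (insd$after == p) {
          ci <- ci + 1
          rows[d, ci] <- insd$base
        }
      }
    }
  }
  rows <- rows[, seq_len(ci), drop = FALSE]
  gapped <- apply(rows, 1, paste0, collapse = "")
  names(gapped) <- ids
  alignment <- rna_msa(gapped, structure = {
    db <- rep(".", ci)
    db[colmap_anc[pairs[, 1]]] <- "("
    db[colmap_anc[pairs[, 2]]] <- ")"
    paste0(db, collapse = "")
  })
  sequences <- degap(alignment)

  # per-descendant structures in descendant coordinates (stems are never
  # deleted, so every pair survives in every descendant)
  structures <- lapply(seq_len(m), function(d) {
    gaprow <- strsplit(gapped[d], "", fixed = TRUE)[[1]]
    resno <- cumsum(gaprow != "-")
    cbind(i = resno[colmap_anc[pairs[, 1]]], j = resno[colmap_anc[pairs[, 2]]])
  })
  names(structures) <- ids

  structure(list(sequences = sequences, alignment = alignment,
                 structure = list(length = L, pairs = pairs),
                 structures = structures,
                 subfamily = stats::setNames(subfamily, ids),
                 params = list(m = m, L = L, sub_rate = sub_rate,
                               stem_sub_rate = stem_sub_rate,
                               indel_rate = indel_rate,
                               compensatory = compensatory,
                               within_scale = within_scale,
                               n_subfamilies = n_subfamilies, seed = seed)),
            class = "rna_family")
}

#' @method print rna_family
#' @export
print.rna_family <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("Synthetic RNA family: m=%d (%d subfamilies), ",
                     "ancestral L=%d, %d base pairs\n",
                     "  deep sub=%.2f stem=%.2f indel=%.2f comp=%.2f ",
                     "within=%.2f seed=%d\n",
                     "  mean pairwise identity (truth): %.3f\n"),
              p$m, p$n_subfamilies, p$L, nrow(x$structure$pairs), p$sub_rate,
              p$stem_sub_rate, p$indel_rate, p$compensatory, p$within_scale,
              p$seed, pairwise_identity(x$alignment)))
  invisible(x)
}
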