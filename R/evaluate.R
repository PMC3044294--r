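# Alignment and structure evaluation: sum-of-pairs score against a
# reference alignment, and sensitivity / PPV / Matthews correlation for
# predicted base-pair sets.

# Canonical keys for all aligned residue pairs in columns with >= 2
# residues; keys are id-ordered so relabeling-invariant.
#' @keywords internal
aligned_pair_keys <- function(aln) {
  cols <- msa_columns(aln)
  ids <- names(aln$rows)
  keys <- character(0)
  for (cl in cols) {
    k <- length(cl$seq)
    if (k < 2) next
    for (a in seq_len(k - 1))
      for (b in seq((a + 1), k)) {
        ia <- ids[cl$seq[a]]; ib <- ids[cl$seq[b]]
        keys <- c(keys, if (ia < ib)
          paste0(ia, ":", cl$pos[a], "|", ib, ":", cl$pos[b])
        else
          paste0(ib, ":", cl$pos[b], "|", ia, ":", cl$pos[a]))
      }
  }
  keys
}

#' Sum-of-pairs score
#'
#' Percentage of residue pairs aligned in the reference that are also
#' aligned in the test alignment.  Only reference columns with at least two
#' residues contribute to the denominator; the score is invariant to all-gap
#' columns and to sequence order.
#'
#' @param test,ref `rna_msa` objects over the same sequences (same ids and
#'   de-gapped content).
#' @return SPS in \[0, 100\].
#' @export
sps <- function(test, ref) {
  st <- degap(test); sr <- degap(ref)
  if (!setequal(names(st), names(sr)) ||
      !identical(st[sort(names(st))], sr[sort(names(sr))]))
    stop("test and reference alignments contain different sequences",
         call. = FALSE)
  refk <- aligned_pair_keys(ref)
  if (length(refk) == 0)
    stop("reference alignment aligns no residue pairs", call. = FALSE)
  testk <- aligned_pair_keys(test)
  100 * sum(refk %in% testk) / length(refk)
}

#' Structure prediction scores
#'
#' Confusion-matrix scores for a predicted base-pair set against a
#' reference, over all `choose(L, 2)` unordered position pairs:
#' sensitivity `TP/(TP+FN)`, positive predictive value `TP/(TP+FP)` and the
#' Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, each defined as
#' 0 when its denominator vanishes.
#'
#' @param pred,ref two-column matrices of 1-based pairs `(i, j)`, `i < j`.
#' @param seq_length sequence length L.
#' @return list of class `score_report` with `TP`, `FP`, `FN`, `TN`, `sen`,
#'   `ppv`, `mcc`.
#' @export
structure_scores <- function(pred, ref, seq_length) {
  pk <- if (NROW(pred) > 0) paste0(pred[, 1], ",", pred[, 2]) else character(0)
  rk <- if (NROW(ref) > 0) paste0(ref[, 1], ",", ref[, 2]) else character(0)
  stopifnot(!anyDuplicated(pk), !anyDuplicated(rk),
            all(pred <= seq_length), all(ref <= seq_length))
  TP <- sum(pk %in% rk)
  FP <- length(pk) - TP
  FN <- length(rk) - TP
  TN <- choose(seq_length, 2) - TP - FP - FN
  sen <- if (TP + FN > 0) TP / (TP + FN) else 0
  ppv <- if (TP + FP > 0) TP / (TP + FP) else 0
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den > 0) (TP * TN - FP * FN) / sqrt(den) else 0
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN,
                 sen = sen, ppv = ppv, mcc = mcc),
            class = "score_report")
}

#' @method print score_report
#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d TN=%g\nSEN=%.4f PPV=%.4f MCC=%.4f\n",
              x$TP, x$FP, x$FN, x$TN, x$sen, x$ppv, x$mcc))
  invisible(x)
}

#' Mean pairwise sequence identity of an alignment
#'
#' Fraction of columns where both sequences carry the same residue, among
#' columns where both are ungapped; averaged over all sequence pairs.
#'
#' @param aln an `rna_msa`.
#' @return identity in \[0, 1\].
#' @export
pairwise_identity <- function(aln) {
  rows <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  m <- nrow(rows)
  if (m < 2) return(1)
  vals <- c()
  for (a in seq_len(m - 1))
    for (b in seq(a + 1, m)) {
      both <- rows[a, ] != "-" & rows[b, ] != "-"
      if (sum(both) == 0) next
      vals <- c(vals, mean(rows[a, both] == rows[b, both]))
    }
  mean(vals)
}

#' Tab-separated evaluation report
#'
#' Scores a test alignment against a reference and, when structures are
#' provided, scores the predicted base pairs of each sequence.
#'
#' @param test,ref `rna_msa` objects over the same sequences.
#' @param pred_structs,ref_structs optional named lists of two-column pair
#'   matrices (one per sequence id) to evaluate structure prediction.
#' @param path optional output file for a TSV report.
#' @return data frame of metric/value rows, invisibly when written.
#' @export
evaluation_report <- function(test, ref, pred_structs = NULL,
                              ref_structs = NULL, path = NULL) {
  out <- data.frame(metric = "SPS", value = round(sps(test, ref), 2))
  if (!is.null(pred_structs) && !is.null(ref_structs)) {
    lens <- nchar(degap(ref))
    agg <- c(TP = 0, FP = 0, FN = 0, TN = 0)
    for (id in names(ref_structs)) {
      sc <- structure_scores(pred_structs[[id]], ref_structs[[id]], lens[[id]])
      agg <- agg + c(TP = sc$TP, FP = sc$FP, FN = sc$FN, TN = sc$TN)
    }
    sen <- if (agg["TP"] + agg["FN"] > 0) agg["TP"] / (agg["TP"] + agg["FN"]) else 0
    ppv <- if (agg["TP"] + agg["FP"] > 0) agg["TP"] / (agg["TP"] + agg["FP"]) else 0
    den <- prod(agg["TP"] + agg["FP"], agg["TP"] + agg["FN"],
                agg["TN"] + agg["FP"], agg["TN"] + agg["FN"])
    mcc <- if (den > 0)
      (agg["TP"] * agg["TN"] - agg["FP"] * agg["FN"]) / sqrt(den) else 0
    out <- rbind(out,
                 data.frame(metric = c("SEN", "PPV", "MCC"),
                            value = round(100 * c(sen, ppv, mcc), 2)))
  }
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Structure conservation index (external-tool hook)
#'
#' SCI is the ratio of the consensus minimum free energy of the alignment
#' (RNAalifold) to the mean single-sequence minimum free energy (RNAfold).
#' It is not computed natively: this hook shells out to the Vienna tools
#' when they are on the PATH and returns `NA` with a message otherwise.
#'
#' @param aln an `rna_msa`.
#' @return SCI as a single number, or `NA` if the tools are unavailable.
#' @export
sci <- function(aln) {
  alifold <- Sys.which("RNAalifold")
  fold <- Sys.which("RNAfold")
  if (!nzchar(alifold) || !nzchar(fold)) {
    message("SCI unavailable: RNAalifold/RNAfold not found on PATH")
    return(NA_real_)
  }
  tmp <- tempfile(fileext = ".aln")
  on.exit(unlink(tmp), add = TRUE)
  write_alignment(aln, tmp, format = "clustal")
  cons <- system2(alifold, c("--noPS", tmp), stdout = TRUE, stderr = FALSE)
  e_a <- as.numeric(sub(".*\\((\\s*-?[0-9.]+)\\).*", "\\1",
                        cons[grepl("\\(\\s*-?[0-9.]+\\)$", cons)][1]))
  singles <- vapply(degap(aln), function(s) {
    out <- system2(fold, "--noPS", input = s, stdout = TRUE, stderr = FALSE)
    as.numeric(sub(".*\\((\\s*-?[0-9.]+)\\).*", "\\1",
                   out[grepl("\\(\\s*-?[0-9.]+\\)$", out)][1]))
  }, numeric(1))
  ebar <- mean(singles)
  if (!is.finite(e_a) || !is.finite(ebar) || ebar == 0) return(NA_real_)
  e_a / ebar
}
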