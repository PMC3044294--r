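# Top-level pipeline: posteriors -> homology weights -> consistency
# transforms -> candidate sets -> structural skeleton -> greedy local
# insertions -> linearization -> discriminative refinement.

#' Structural multiple alignment of RNA sequences
#'
#' Non-progressive maximum-expected-accuracy structural alignment.  Pairwise
#' base-alignment posteriors (pair-HMM) and per-sequence base-pairing
#' posteriors (partition function) are sharpened by three consistency
#' transformations, then the alignment is built greedily as a DAG of
#' columns: first the most probable alignments of confident base-pairs (the
#' structural skeleton), then the most probable base alignments, and finally
#' a discriminative split-and-realign refinement pass.
#'
#' @param seqs named character vector of RNA sequences (A,C,G,U,N; T is
#'   normalized to U), or a FASTA path.
#' @param config pipeline configuration from [align_config()].
#' @param params pair-HMM parameters from [phmm_params()].
#' @param model pairing model from [pairing_model()].
#' @return an `rna_msa` with attributes `score` (total posterior score),
#'   `paired_columns` (number of skeleton column pairs) and `config`.
#' @export
#' @examples
#' seqs <- c(a = "GGGACAAACCC", b = "GGGCAAAGCCC")
#' rna_align(seqs, config = align_config(refine = FALSE))
rna_align <- function(seqs, config = align_config(),
                      params = phmm_params(), model = pairing_model()) {
  if (length(seqs) == 1 && is.null(names(seqs)) && file.exists(seqs))
    seqs <- read_fasta(seqs)
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  seqs[] <- vapply(seq_along(seqs), function(k)
    normalize_residues(seqs[k], names(seqs)[k]), character(1))
  if (length(seqs) == 1) {
    warning("single input sequence: emitted unchanged", call. = FALSE)
    out <- rna_msa(seqs)
    attr(out, "score") <- 0
    attr(out, "paired_columns") <- 0L
    attr(out, "config") <- config
    return(out)
  }
  ps <- probability_set(seqs, params, model, config$threshold)
  ps <- apply_consistency(ps, config$alpha, config$beta, config$rounds)
  cand <- build_candidates(ps, config$tb)
  g <- new_graph(seqs)
  if (config$skeleton) build_skeleton(g, ps, cand)
  insert_local_alignments(g, cand, strict_lr = config$strict_lr)
  npaired <- length(g$paired)
  aln <- linearize(g, seqs)
  # Confidently aligned bases — the skeleton's inserted base alignments —
  # are protected from being broken by refinement.
  if (config$refine && config$passes > 0)
    aln <- refine_alignment(aln, ps, passes = config$passes, k = config$k,
                            anchors = g$anchors)
  attr(aln, "score") <- msa_posterior_score(aln, ps)
  attr(aln, "paired_columns") <- npaired
  attr(aln, "config") <- config
  aln
}
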