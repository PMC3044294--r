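# Model parameter containers: pair-HMM, pairing model, pipeline config.

#' Pair hidden Markov model parameters
#'
#' Three-state (M, Ix, Iy) global-alignment pair-HMM.  The match state emits
#' residue pairs from a 4x4 table favouring identity; insert states emit
#' single residues from a background distribution.  `delta` is the
#' gap-open probability (M to Ix or Iy), `epsilon` the gap-extend
#' probability (Ix to Ix, Iy to Iy); cross-gap transitions (Ix to Iy) are
#' disallowed.  N residues emit the marginal over the four bases and the
#' model is fully overridable, including from a YAML file via
#' [phmm_params_from_file()].
#'
#' @param match_prob total probability mass on identical residue pairs.
#' @param delta gap-open probability, in (0, 0.5).
#' @param epsilon gap-extend probability, in (0, 1).
#' @param background insert-state emission distribution over A, C, G, U.
#' @return list with components `emit_match` (4x4), `emit_insert` (length 4),
#'   `trans` (3x3, rows/cols M, Ix, Iy), `init` (length 3).
#' @export
phmm_params <- function(match_prob = 0.6, delta = 0.02, epsilon = 0.7,
                        background = rep(0.25, 4)) {
  stopifnot(match_prob > 0, match_prob < 1,
            delta > 0, delta < 0.5, epsilon > 0, epsilon < 1,
            length(background) == 4, all(background > 0))
  background <- background / sum(background)
  emit_match <- matrix((1 - match_prob) / 12, 4, 4,
                       dimnames = list(RNA_ALPHABET[1:4], RNA_ALPHABET[1:4]))
  diag(emit_match) <- match_prob / 4
  trans <- rbind(M  = c(1 - 2 * delta, delta, delta),
                 Ix = c(1 - epsilon, epsilon, 0),
                 Iy = c(1 - epsilon, 0, epsilon))
  colnames(trans) <- rownames(trans)
  p <- list(emit_match = emit_match,
            emit_insert = stats::setNames(background, RNA_ALPHABET[1:4]),
            trans = trans,
            init = c(M = 1 - 2 * delta, Ix = delta, Iy = delta))
  validate_phmm_params(p)
  p
}

#' @keywords internal
validate_phmm_params <- function(p) {
  stopifnot(abs(sum(p$emit_match) - 1) < 1e-9,
            abs(sum(p$emit_insert) - 1) < 1e-9,
            all(abs(rowSums(p$trans) - 1) < 1e-9),
            abs(sum(p$init) - 1) < 1e-9,
            all(p$emit_match >= 0), all(p$trans >= 0), all(p$init >= 0))
  invisible(p)
}

#' Read pair-HMM parameters from a YAML config file
#'
#' The file may set any of `match_prob`, `delta`, `epsilon`, `background`;
#' unset keys use the [phmm_params()] defaults.
#'
#' @param path YAML file.
#' @return pair-HMM parameter list.
#' @export
phmm_params_from_file <- function(path) {
  cfg <- yaml::read_yaml(path)
  keep <- intersect(names(cfg), c("match_prob", "delta", "epsilon", "background"))
  do.call(phmm_params, cfg[keep])
}

#' Base-pairing model
#'
#' A Boltzmann-weighted Nussinov-style ensemble: each canonical pair type
#' contributes a positive multiplicative weight, unpaired positions weight 1,
#' non-canonical pairs (and anything involving N) weight 0, and every
#' directly stacked pair of pairs contributes an extra `stack` factor.  The
#' stacking term concentrates probability mass on contiguous helices, the
#' behaviour of thermodynamic ensembles, and is what lets real stems reach
#' high pairing probabilities.  Hairpin loops must enclose at least `h`
#' unpaired positions.  The defaults order pair stabilities GC > AU > GU.
#'
#' @param weights named positive weights for GC, CG, AU, UA, GU, UG.
#' @param stack multiplicative bonus per stacked pair (1 disables stacking).
#' @param h minimum hairpin loop length.
#' @return list with components `w` (5x5 matrix over A,C,G,U,N), `stack`
#'   and `h`.
#' @export
pairing_model <- function(weights = c(GC = 6, CG = 6, AU = 3, UA = 3,
                                      GU = 1.5, UG = 1.5),
                          stack = 8, h = 3L) {
  need <- c("GC", "CG", "AU", "UA", "GU", "UG")
  stopifnot(all(need %in% names(weights)), all(weights[need] > 0),
            stack > 0, h >= 0)
  w <- matrix(0, 5, 5, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  for (t in need) {
    a <- substr(t, 1, 1); b <- substr(t, 2, 2)
    w[a, b] <- weights[[t]]
  }
  list(w = w, stack = stack, h = as.integer(h))
}

#' Pipeline configuration
#'
#' Defaults follow the aligner's standard setting: consistency weights
#' `alpha = 0.4` (intra-sequence) and `beta = 0.1` (four-way), base-pair
#' candidate threshold `tb = 0.5`, sparsity threshold 0.01 (which keeps the
#' posterior matrices at a few nonzeros per row on typical families).
#'
#' @param alpha intra-sequence transform weight on the original pairing
#'   probabilities, in \[0, 1\].
#' @param beta four-way transform weight on the structural term, in \[0, 1\].
#' @param tb base-pair probability threshold for the structural skeleton.
#' @param threshold sparsity threshold for all probability matrices.
#' @param rounds number of consistency rounds (inter, intra, four-way each).
#' @param skeleton build the structural skeleton (Step 1)?
#' @param refine run discriminative refinement?
#' @param passes refinement passes.
#' @param k number of k-means clusters for refinement.
#' @param strict_lr also enforce left-right compatibility for Step-2
#'   insertions (stricter than required).
#' @param format default output format.
#' @return a validated list of class `rnamea_config`.
#' @export
align_config <- function(alpha = 0.4, beta = 0.1, tb = 0.5, threshold = 0.01,
                         rounds = 1L, skeleton = TRUE, refine = TRUE,
                         passes = 1L, k = 2L, strict_lr = FALSE,
                         format = c("fasta", "clustal", "stockholm")) {
  for (nm in c("alpha", "beta", "tb")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop(nm, " must be a single value in [0, 1]", call. = FALSE)
  }
  if (threshold < 0 || threshold >= 1)
    stop("threshold must be in [0, 1)", call. = FALSE)
  if (rounds < 0 || passes < 0 || k < 1)
    stop("rounds and passes must be >= 0 and k >= 1", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, tb = tb, threshold = threshold,
                 rounds = as.integer(rounds), skeleton = isTRUE(skeleton),
                 refine = isTRUE(refine), passes = as.integer(passes),
                 k = as.integer(k), strict_lr = isTRUE(strict_lr),
                 format = match.arg(format)),
            class = "rnamea_config")
}
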