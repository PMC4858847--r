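#' Exhaustive structure enumeration on a short sequence
#'
#' Ground truth independent of the grammar DP: every well-nested structure
#' with canonical pairs, hairpins of at least `min_hairpin_unpaired`
#' unpaired bases and pair spans of at most `W` residues is generated by
#' backtracking; each structure's energy is then obtained by geometric loop
#' decomposition (structures containing an internal/bulge loop above the
#' model's size cap fall outside the model's structure class and are
#' excluded). Exact `Z`, base-pairing probabilities and per-position
#' loop-type frequencies follow by direct summation.
#'
#' @inheritParams potential_outermost_pairs
#' @param max_structures Enumeration cap (guard against explosion).
#' @param return_structures Also return the pair lists and per-structure
#'   log weights.
#' @return An object of class `structure_ensemble`: `n_structures`, `logZ`,
#'   `bpp` (dense `n x n` matrix, upper triangle), `profile` (`n x 6`
#'   matrix: stem, bulge, exterior, hairpin, interior, multi), and
#'   optionally `structures` / `log_weights`.
#' @export
enumerate_structures <- function(seq, W, model = energy_model(),
                                 max_structures = 2e6,
                                 return_structures = FALSE) {
  seq <- as_rna_sequence(seq)
  if (seq$n > 25L)
    sf_input_error("enumeration is restricted to N <= 25 (got %d)", seq$n)
  res <- cpp_enumerate(seq$codes, as.integer(W), as_cpp_model(model),
                       as.integer(max_structures), return_structures)
  colnames(res$profile) <- c("stem", "bulge", "exterior", "hairpin",
                             "interior", "multi")
  res$seq <- seq
  res$W <- as.integer(W)
  class(res) <- "structure_ensemble"
  res
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("structure_ensemble: %d structures, logZ = %.6g (N = %d, W = %d)\n",
              x$n_structures, x$logZ, x$seq$n, x$W))
  invisible(x)
}

#' Log Boltzmann weight of one explicit structure
#'
#' Sums loop free energies of the given pair list by geometric
#' decomposition and returns `-dG / (R T)`; `-Inf` when the structure lies
#' outside the model's structure class.
#'
#' @param seq Sequence.
#' @param pairs Two-column matrix of 1-based paired positions.
#' @param model Energy model.
#' @return The log weight.
#' @export
structure_log_weight <- function(seq, pairs, model = energy_model()) {
  seq <- as_rna_sequence(seq)
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  cpp_structure_log_weight(seq$codes, pairs, as_cpp_model(model))
}
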