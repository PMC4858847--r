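#' Potential outermost pairs under the span constraint
#'
#' A position pair `(i, j)` (0-based gap coordinates) is a potential
#' outermost pair when residues `(i+1, j)` form a canonical pair and the
#' span satisfies `min_hairpin + 2 <= j - i <= W`.
#'
#' @param seq An [rna_sequence()] or character string.
#' @param W Maximal base-pair span.
#' @param model Energy model (only `min_hairpin_unpaired` is used).
#' @return A data frame with columns `i`, `j` (gap coordinates) and
#'   `res_i`, `res_j` (the 1-based paired residues `i+1`, `j`).
#' @export
potential_outermost_pairs <- function(seq, W, model = energy_model()) {
  seq <- as_rna_sequence(seq)
  stopifnot(W >= 1)
  ms <- model$min_hairpin_unpaired + 2L
  n <- seq$n
  out_i <- integer(0); out_j <- integer(0)
  for (d in seq_len(min(W, n))) {
    if (d < ms) next
    i <- 0:(n - d)
    can <- mapply(function(a, b) .pair_code_r(a, b) > 0L,
                  seq$codes[i + 1L], seq$codes[i + d])
    out_i <- c(out_i, i[can]); out_j <- c(out_j, (i + d)[can])
  }
  data.frame(i = out_i, j = out_j, res_i = out_i + 1L, res_j = out_j)
}

#' Banded inside tables of the six-state grammar
#'
#' Fills the inside variables `alpha_sigma(i, j)` (log domain) for all
#' subsequences of span `j - i <= W`: `Stem` (region enclosed by outermost
#' pair `(i+1, j)`), `StemEnd` (loop closed by the pair `(i, j+1)`), and the
#' three multiloop states.
#'
#' @inheritParams potential_outermost_pairs
#' @return An object of class `state_tables` holding banded log-value
#'   matrices, the sequence and the model reference.
#' @export
fold_inside <- function(seq, W, model = energy_model()) {
  seq <- as_rna_sequence(seq)
  if (all(seq$codes == 0L)) sf_input_error("sequence contains only N residues")
  bands <- cpp_inside(seq$codes, as.integer(W), as_cpp_model(model))
  structure(list(seq = seq, W = as.integer(W), model = model,
                 bands = bands,
                 seq_digest = seq_digest(seq),
                 model_digest = model$digest),
            class = "state_tables")
}

#' @export
print.state_tables <- function(x, ...) {
  cat(sprintf("state_tables: N = %d, W = %d, model %s\n",
              x$seq$n, x$W, x$model_digest))
  invisible(x)
}

#' Read one inside value from banded state tables
#'
#' @param tables A `state_tables` object.
#' @param state One of `"Stem"`, `"StemEnd"`, `"Multi"`, `"Multi1"`,
#'   `"Multi2"`.
#' @param i,j Gap coordinates, `0 <= i <= j <= N`, `j - i <= W`.
#' @return The log inside value (`-Inf` for zero ensemble weight).
#' @export
inside_value <- function(tables, state, i, j) {
  b <- tables$bands[[state]]
  if (is.null(b)) sf_input_error("unknown state '%s'", state)
  d <- j - i
  if (d < 0 || d >= ncol(b$values) || i < 0 || j > b$N) return(-Inf)
  b$values[i + 1L, d + 1L]
}

#' Exterior block weights u(p, q)
#'
#' `u(p, q)` is the weight of one exterior step: the unpaired transition
#' when `p + 1 = q`, the outermost-pair block
#' `t(Outer -> Outer.Stem) * exp(alpha_Stem(p, q))` when `(p, q)` is a
#' potential outermost pair, and 0 otherwise.
#'
#' @param tables A `state_tables` object from [fold_inside()].
#' @return A banded matrix of log u values: row `p + 1`, column `q - p + 1`
#'   (so column 2 is the unpaired step).
#' @export
u_weights <- function(tables) {
  n <- tables$seq$n
  W <- min(tables$W, n)
  ST <- tables$bands$Stem$values
  logu <- matrix(-Inf, n + 1L, W + 1L)
  logu[cbind(seq_len(n), 2L)] <- 0  # t(Outer -> Outer) = 1
  lw_ext <- .lw_ext_branch_vec(tables)
  keep <- ncol(ST)
  d_max <- min(W, keep - 1L)
  for (d in seq_len(d_max)) {
    col <- ST[seq_len(n + 1L - d), d + 1L]
    fin <- is.finite(col)
    if (!any(fin)) next
    p <- which(fin) - 1L
    logu[p + 1L, d + 1L] <- col[fin] + lw_ext[cbind(p + 1L, p + d)]
  }
  logu
}

# log exterior-branch transition weights for every residue pair (a, b):
# 0 unless the simplified terminal penalty is on and the pair is non-CG
.lw_ext_branch_vec <- function(tables) {
  n <- tables$seq$n
  model <- tables$model
  out <- matrix(0, n, n)
  if (identical(model$dangle_mode, "simplified")) {
    kT <- model$gas_constant * model$temperature
    codes <- tables$seq$codes
    for (a in seq_len(n)) {
      b <- seq_len(n)
      pts <- vapply(b, function(bb) .pair_code_r(codes[a], codes[bb]), 0L)
      pen <- pts %in% c(1L, 2L, 5L, 6L)
      out[a, pen] <- -model$terminal_au / kT
    }
  }
  out
}

#' Reference global fold (raw log-domain accumulation)
#'
#' Left-to-right and right-to-left accumulation of the exterior inside and
#' outside variables `alpha_Outer(j)` and `beta_Outer(j)` without the ratio
#' transformation. Intended for short sequences and for validating the
#' ratio database: `Z = alpha_Outer(N) = beta_Outer(0)`.
#'
#' @inheritParams potential_outermost_pairs
#' @return A list with `logZ`, `log_alpha_outer` (indices 0..N) and
#'   `log_beta_outer`.
#' @export
global_reference_fold <- function(seq, W, model = energy_model()) {
  seq <- as_rna_sequence(seq)
  res <- cpp_reference_fold(seq$codes, as.integer(W), as_cpp_model(model))
  list(logZ = res$logZ,
       log_alpha_outer = as.numeric(res$log_alpha_outer),
       log_beta_outer = as.numeric(res$log_beta_outer))
}

#' Local outside variables below one outermost pair
#'
#' Computes `beta_sigma(k, l; i, j)` for a fixed potential outermost pair
#' `(i, j)`: the outside recursion restricted to the enclosed window, with
#' the initial condition
#' `beta_Stem(i, j; i, j) = t(Outer, i, j -> Outer.Stem, i, j)`.
#'
#' @inheritParams potential_outermost_pairs
#' @param outermost Integer pair `c(i, j)` in gap coordinates; must be a
#'   potential outermost pair.
#' @return A list of banded log-value matrices per state, addressable with
#'   [inside_value()] semantics via the returned `bands`.
#' @export
outside_local <- function(seq, outermost, W, model = energy_model()) {
  seq <- as_rna_sequence(seq)
  i <- as.integer(outermost[1]); j <- as.integer(outermost[2])
  P <- potential_outermost_pairs(seq, W, model)
  if (!any(P$i == i & P$j == j))
    sf_input_error("(%d, %d) is not a potential outermost pair", i, j)
  bands <- cpp_outside_local(seq$codes, as.integer(W), as_cpp_model(model),
                             i, j)
  structure(list(seq = seq, W = as.integer(W), model = model, bands = bands,
                 outermost = c(i, j)),
            class = "local_outside")
}

#' @export
print.local_outside <- function(x, ...) {
  cat(sprintf("local outside tables below outermost pair (%d, %d)\n",
              x$outermost[1], x$outermost[2]))
  invisible(x)
}

#' Read one local outside value
#' @param x A `local_outside` object.
#' @inheritParams inside_value
#' @export
outside_value <- function(x, state, i, j) {
  b <- x$bands[[state]]
  if (is.null(b)) sf_input_error("unknown state '%s'", state)
  d <- j - i
  if (d < 0 || d >= ncol(b$values) || i < 0 || j > b$N) return(-Inf)
  b$values[i + 1L, d + 1L]
}
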