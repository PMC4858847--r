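all_kmers <- function(k) {
  g <- expand.grid(rep(list(c("A", "C", "G", "U")), k),
                   stringsAsFactors = FALSE)[, k:1, drop = FALSE]
  apply(g, 1L, paste, collapse = "")
}

#' k-mer composition design matrix for windowed stem probabilities
#'
#' One row per non-overlapping window of `L` residues: features are
#' `(1/L, #kmer_1/L, ..., #kmer_{4^k}/L)` (an intercept column scaled like
#' the counts, then the overlapping k-mer counts divided by `L`; a window of
#' `L` residues contains `L - k + 1` k-mers, so the count features of a row
#' sum to `(L - k + 1)/L`). Targets are the window means of the supplied
#' per-position series. Windows containing `N` residues are excluded.
#'
#' @param seq Sequence (an [rna_sequence()] or string).
#' @param pstem_series Per-position numeric series of the same length
#'   (typically stem probabilities).
#' @param L Window length (default 32).
#' @param k k-mer size (default 4).
#' @return An object of class `kmer_design`: `X` (n_windows x (4^k + 1)),
#'   `y`, `windows` (start/end), `L`, `k`.
#' @export
kmer_design <- function(seq, pstem_series, L = 32L, k = 4L) {
  seq <- as_rna_sequence(seq)
  if (length(pstem_series) != seq$n)
    sf_input_error("series length (%d) does not match sequence length (%d)",
                   length(pstem_series), seq$n)
  nw <- seq$n %/% L
  if (nw == 0L) sf_input_error("sequence shorter than one window")
  kmers <- all_kmers(k)
  codes <- seq$codes
  # base-4 index of every k-mer occurrence; windows with N are dropped
  starts <- (seq_len(nw) - 1L) * L + 1L
  keep <- logical(nw)
  X <- matrix(0, nw, 4L^k + 1L, dimnames = list(NULL, c("intercept", kmers)))
  y <- numeric(nw)
  pow <- 4L^((k - 1L):0L)
  for (w in seq_len(nw)) {
    idx <- starts[w]:(starts[w] + L - 1L)
    cw <- codes[idx]
    if (any(cw == 0L)) next
    keep[w] <- TRUE
    sub <- cw - 1L
    kidx <- 1L + as.integer(
      vapply(seq_len(L - k + 1L),
             function(t) sum(sub[t:(t + k - 1L)] * pow), 0))
    cnt <- tabulate(kidx, nbins = 4L^k)
    X[w, ] <- c(1, cnt) / L
    y[w] <- mean(pstem_series[idx])
  }
  structure(list(X = X[keep, , drop = FALSE], y = y[keep],
                 windows = data.frame(start = starts[keep],
                                      end = starts[keep] + L - 1L),
                 L = as.integer(L), k = as.integer(k)),
            class = "kmer_design")
}

#' @export
print.kmer_design <- function(x, ...) {
  cat(sprintf("kmer_design: %d windows of %d nt, %d features\n",
              nrow(x$X), x$L, ncol(x$X)))
  invisible(x)
}

#' Ridge regression of windowed stem probabilities on k-mer composition
#'
#' Minimises `(1/2) sum_n (y_n - w' x_n)^2 + (lambda/2) w' w` in closed
#' form via the normal equations `(X'X + lambda I) w = X'y`. With
#' `lambda = 0` and a rank-deficient design (the k-mer count features sum
#' to a multiple of the intercept feature, so the design always has a null
#' space) the minimum-norm solution is returned via the singular value
#' decomposition.
#'
#' @param design A [kmer_design()] (or any list with `X`, `y`).
#' @param lambda Ridge penalty (>= 0); default 1.
#' @return An object of class `ridge_model` with fields `w` (named weight
#'   vector) and `lambda`.
#' @export
fit_ridge <- function(design, lambda = 1) {
  X <- design$X; y <- design$y
  if (nrow(X) < 1L) sf_input_error("empty design")
  if (lambda < 0) sf_input_error("lambda must be >= 0")
  if (lambda > 0) {
    A <- crossprod(X)
    diag(A) <- diag(A) + lambda
    w <- drop(solve(A, crossprod(X, y)))
  } else {
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    w <- drop(sv$v[, pos, drop = FALSE] %*%
              ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
    names(w) <- colnames(X)
  }
  structure(list(w = w, lambda = lambda), class = "ridge_model")
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("ridge_model: %d weights, lambda = %g, |w| = %.4g\n",
              length(x$w), x$lambda, sqrt(sum(x$w^2))))
  invisible(x)
}

#' @export
predict.ridge_model <- function(object, design, ...) {
  drop(design$X %*% object$w)
}

#' Composition-corrected windowed stem probabilities
#'
#' `Dp_stem(n) = y_n - w' x_n`: the residual of the windowed stem
#' probability after subtracting the part predicted by k-mer composition --
#' the structure propensity beyond sequence-composition bias.
#'
#' @param design A [kmer_design()].
#' @param model A fitted [fit_ridge()] model.
#' @return Numeric vector of per-window residuals.
#' @export
residualize <- function(design, model) {
  design$y - predict(model, design)
}

#' Write / read a ridge model as labelled TSV
#' @param model A `ridge_model`.
#' @param path File path.
#' @export
write_ridge_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# spanfold ridge model",
               sprintf("# lambda=%s", format(model$lambda, digits = 17)),
               "feature\tweight"), con)
  writeLines(sprintf("%s\t%s", names(model$w),
                     format(model$w, digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' @rdname write_ridge_model
#' @export
read_ridge_model <- function(path) {
  if (!file.exists(path)) sf_input_error("model file not found: %s", path)
  hdr <- readLines(path, n = 2L)
  lambda <- as.numeric(sub("# lambda=", "", hdr[2], fixed = TRUE))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  w <- tab$weight
  names(w) <- tab$feature
  structure(list(w = w, lambda = lambda), class = "ridge_model")
}
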