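#' Build the ratio database of local fold changes
#'
#' Computes, by a direct-ratio recursion that never materialises any
#' sequence-length-scale quantity,
#' `Dalpha(h) = alpha_Outer(h+1) / alpha_Outer(h)` and
#' `Dbeta(h) = beta_Outer(h) / beta_Outer(h+1)` for `h = 0..N-1` (stored as
#' logs). These two vectors are the persistent "database" from which every
#' probability of the span-constrained ensemble can be reconstructed
#' locally.
#'
#' @inheritParams potential_outermost_pairs
#' @return An object of class `ratio_db` with fields `N`, `W`, `logda`,
#'   `logdb`, `seq_digest`, `model_digest`.
#' @export
build_ratios <- function(seq, W, model = energy_model()) {
  seq <- as_rna_sequence(seq)
  res <- cpp_build_ratios(seq$codes, as.integer(W), as_cpp_model(model))
  new_ratio_db(seq, W, model, as.numeric(res$logda), as.numeric(res$logdb))
}

new_ratio_db <- function(seq, W, model, logda, logdb) {
  structure(list(N = seq$n, W = as.integer(W),
                 logda = logda, logdb = logdb,
                 seq_digest = seq_digest(seq),
                 model_digest = model$digest),
            class = "ratio_db")
}

#' @export
print.ratio_db <- function(x, ...) {
  cat(sprintf("ratio_db: N = %d, W = %d\n  max |log Dalpha| = %.4g, logZ = %.6g\n",
              x$N, x$W, max(abs(x$logda)), sum(x$logda)))
  invisible(x)
}

#' Write / read a ratio database (TSV)
#'
#' Plain-text persistent form: a commented header carrying `N`, `W` and the
#' sequence/model digests, then one row per position `h = 0..N-1` with
#' `log Dalpha(h)` and `log Dbeta(h)` at full precision (round-trip exact).
#'
#' @param db A `ratio_db`.
#' @param path Output file.
#' @export
write_ratio_db <- function(db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# spanfold ratio database",
               sprintf("# N=%d W=%d seq_digest=%s model_digest=%s",
                       db$N, db$W, db$seq_digest, db$model_digest),
               "h\tlog_dalpha\tlog_dbeta"), con)
  writeLines(sprintf("%d\t%s\t%s", 0:(db$N - 1L),
                     format(db$logda, digits = 17, trim = TRUE),
                     format(db$logdb, digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' @rdname write_ratio_db
#' @param seq Optional sequence to verify the stored digest against.
#' @param model Optional model to verify the stored digest against.
#' @export
read_ratio_db <- function(path, seq = NULL, model = NULL) {
  if (!file.exists(path)) sf_input_error("ratio database not found: %s", path)
  hdr <- readLines(path, n = 2L)
  m <- regmatches(hdr[2], regexec(
    "# N=(\\d+) W=(\\d+) seq_digest=(\\w+) model_digest=(\\w+)", hdr[2]))[[1]]
  if (length(m) != 5L) sf_integrity_error("malformed ratio database header")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  db <- structure(list(N = as.integer(m[2]), W = as.integer(m[3]),
                       logda = tab$log_dalpha, logdb = tab$log_dbeta,
                       seq_digest = m[4], model_digest = m[5]),
                  class = "ratio_db")
  if (db$N != nrow(tab)) sf_integrity_error("ratio database row count mismatch")
  if (!is.null(seq) && seq_digest(as_rna_sequence(seq)) != db$seq_digest)
    sf_integrity_error("ratio database does not match the sequence")
  if (!is.null(model) && model$digest != db$model_digest)
    sf_integrity_error("ratio database does not match the energy model")
  db
}

check_db <- function(db, seq, model) {
  if (seq_digest(seq) != db$seq_digest)
    sf_integrity_error("ratio database does not match the sequence")
  if (model$digest != db$model_digest)
    sf_integrity_error("ratio database does not match the energy model")
  invisible(TRUE)
}

#' Locally reconstructed ratio r(i, j) = Z / (alpha_Outer(i) beta_Outer(j))
#'
#' Evaluates the partition-function ratio from the database and the exterior
#' block weights `u(p, q)` over the anchor set
#' `S(i) = {(p, q) in P : p <= i < q} + {(i, i+1)}`, touching only entries
#' within `W` of position `i`:
#' `r(i,j) = sum over S(i) of [alpha(p)/alpha(i)] u(p,q) [beta(q)/beta(j)]`.
#'
#' @param i,j Gap coordinates with `i <= j` and `j - i <= W`.
#' @param db A `ratio_db`.
#' @param tables Matching `state_tables` from [fold_inside()].
#' @return The log ratio `log r(i, j)` (always `>= 0` up to rounding).
#' @export
ratio_r <- function(i, j, db, tables) {
  if (j < i || j - i > db$W)
    sf_input_error("ratio_r requires i <= j and j - i <= W")
  check_db(db, tables$seq, tables$model)
  logu <- u_weights(tables)
  n <- db$N
  W <- db$W
  # log alpha(p)/alpha(i) = -sum_{h=p}^{i-1} log Dalpha(h)
  # log beta(q)/beta(j) = -sum_{h=j}^{q-1} log Dbeta(h)  (can be > 0 if q < j)
  terms <- numeric(0)
  if (i < n) {
    cb_j <- c(0, cumsum(db$logdb))  # cb_j[t+1] = sum_{h<t} logdb
    lbeta_rel <- function(q) -(cb_j[q + 1L] - cb_j[j + 1L])
    ca <- c(0, cumsum(db$logda))
    lalpha_rel <- function(p) -(ca[i + 1L] - ca[p + 1L])
    # degenerate unpaired step (i, i+1)
    terms <- c(terms, logu[i + 1L, 2L] + lbeta_rel(i + 1L))
    for (p in max(0, i - W + 1L):i) {
      qs <- max(i + 1L, p + 1L):min(n, p + W)
      for (q in qs) {
        lu <- logu[p + 1L, q - p + 1L]
        if (q == p + 1L) next  # only the anchor's own degenerate step counts
        if (is.finite(lu))
          terms <- c(terms, lalpha_rel(p) + lu + lbeta_rel(q))
      }
    }
  } else {
    return(0)  # r(N, N) = 1
  }
  logsumexp(terms)
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Probability-scale outside values beta_sigma(k, l) / Z
#'
#' Assembles the bounded quantity
#' `beta_sigma(k, l) / Z = sum over outermost pairs (i, j) enclosing (k, l)
#' of beta_sigma(k, l; i, j) / r(i, j)`, evaluated through the banded global
#' outside pass seeded with `t(Outer -> Outer.Stem) / r(i, j)`.
#'
#' @param seq Sequence.
#' @param db A matching `ratio_db`.
#' @param model Energy model.
#' @param state Grammar state name.
#' @param k,l Gap coordinates with `l - k <= W`.
#' @return `beta_sigma(k, l) / Z` on the linear scale.
#' @export
outside_over_z <- function(seq, db, model = energy_model(),
                           state = "Stem", k, l) {
  seq <- as_rna_sequence(seq)
  check_db(db, seq, model)
  if (l - k > db$W) sf_input_error("l - k must not exceed W")
  ff <- cpp_fold_features(seq$codes, db$W, as_cpp_model(model),
                          db$logda, db$logdb, TRUE)
  b <- ff$outside[[state]]
  if (is.null(b)) sf_input_error("unknown state '%s'", state)
  d <- l - k
  if (d < 0 || d >= ncol(b$values) || k < 0 || l > b$N) return(0)
  exp(b$values[k + 1L, d + 1L])
}

#' State-transition probabilities from the ratio database
#'
#' Probability of one grammar transition under the ensemble,
#' `beta_sigma(k,l) t(...) alpha_sigma'(k',l') / Z`. Supported kinds:
#' \describe{
#'   \item{`outer_unpaired`}{position `i` is an exterior unpaired step:
#'     `t(Outer->Outer) / r(i, i+1)`.}
#'   \item{`outer_stem`}{`(i, j)` is an outermost pair:
#'     `t(Outer->Outer.Stem) exp(alpha_Stem(i,j)) / r(i, j)`.}
#'   \item{`stem`}{occupancy of the Stem state at `(i, j)`, i.e. the
#'     probability that residues `(i+1, j)` are paired.}
#' }
#'
#' @param kind Transition kind (see Details).
#' @param i,j Gap coordinates of the transition.
#' @param db A `ratio_db`.
#' @param tables Matching `state_tables`.
#' @return A probability in `[0, 1]`.
#' @export
transition_prob <- function(kind = c("outer_unpaired", "outer_stem", "stem"),
                            i, j = NULL, db, tables) {
  kind <- match.arg(kind)
  seq <- tables$seq
  model <- tables$model
  check_db(db, seq, model)
  if (kind == "outer_unpaired") {
    return(exp(-ratio_r(i, i + 1L, db, tables)))
  }
  st <- inside_value(tables, "Stem", i, j)
  if (!is.finite(st)) return(0)
  lw_ext <- .lw_ext_branch_vec(tables)[i + 1L, j]
  if (kind == "outer_stem") {
    return(exp(lw_ext + st - ratio_r(i, j, db, tables)))
  }
  # stem occupancy via the global outside pass
  ff <- cpp_fold_features(seq$codes, db$W, as_cpp_model(model),
                          db$logda, db$logdb, TRUE)
  b <- ff$outside$Stem
  exp(b$values[i + 1L, j - i + 1L] + st)
}
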