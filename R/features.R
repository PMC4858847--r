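fold_features <- function(seq, W, model = energy_model(), db = NULL,
                          return_outside = FALSE) {
  seq <- as_rna_sequence(seq)
  if (is.null(db)) db <- build_ratios(seq, W, model)
  check_db(db, seq, model)
  if (db$W != W) sf_input_error("database was built with W = %d", db$W)
  cpp_fold_features(seq$codes, as.integer(W), as_cpp_model(model),
                    db$logda, db$logdb, return_outside)
}

#' Base-pairing probabilities under the span constraint
#'
#' Exact ensemble probabilities `p(i, j)` that residues `i` and `j`
#' (1-based, `j - i + 1 <= W`) are paired, computed from the ratio database
#' via the outside variables rebuilt on the probability scale
#' (`beta_sigma / Z`), so the computation is numerically safe at any
#' sequence length.
#'
#' @inheritParams potential_outermost_pairs
#' @param db Optional precomputed [build_ratios()] database.
#' @param min_prob Drop pairs with probability below this threshold.
#' @return Data frame with columns `i`, `j` (1-based paired residues) and
#'   `prob`.
#' @export
base_pair_probabilities <- function(seq, W, model = energy_model(),
                                    db = NULL, min_prob = 0) {
  ff <- fold_features(seq, W, model, db)
  out <- data.frame(i = ff$bpp_i, j = ff$bpp_j, prob = ff$bpp_p)
  out <- out[out$prob >= min_prob, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n") <- length(ff$pstem)
  out
}

#' Per-position stem probability and accessibility
#'
#' `p_stem(i) = sum_{j>i} p(i,j) + sum_{j<i} p(j,i)`: the probability that
#' position `i` lies within a stem. Accessibility is `1 - p_stem`.
#'
#' @param bpp A base-pair probability data frame from
#'   [base_pair_probabilities()].
#' @param n Sequence length (taken from the `n` attribute of `bpp` when
#'   present).
#' @return Numeric vector of length `n`.
#' @export
stem_probability <- function(bpp, n = attr(bpp, "n")) {
  if (is.null(n)) sf_input_error("sequence length n is required")
  p <- numeric(n)
  if (nrow(bpp)) {
    ti <- tapply(bpp$prob, bpp$i, sum)
    tj <- tapply(bpp$prob, bpp$j, sum)
    p[as.integer(names(ti))] <- p[as.integer(names(ti))] + ti
    p[as.integer(names(tj))] <- p[as.integer(names(tj))] + tj
  }
  p
}

#' @rdname stem_probability
#' @param pstem A stem-probability vector.
#' @export
accessibility <- function(pstem) 1 - pstem

#' Loop-type structural profile
#'
#' Per-position probabilities of the six structural contexts: paired
#' (`stem`), or unpaired within a bulge loop, the exterior loop, a hairpin
#' loop, an internal loop, or a multibranch loop. Unpaired bases of a
#' two-branch loop count as `bulge` when the loop has unpaired bases on one
#' side only, `interior` otherwise. The six components sum to 1 at every
#' position.
#'
#' @inheritParams base_pair_probabilities
#' @return Data frame with columns `pos`, `stem`, `bulge`, `exterior`,
#'   `hairpin`, `interior`, `multi`.
#' @export
structural_profile <- function(seq, W, model = energy_model(), db = NULL) {
  ff <- fold_features(seq, W, model, db)
  prof <- ff$profile
  data.frame(pos = seq_len(nrow(prof)), stem = prof[, 1], bulge = prof[, 2],
             exterior = prof[, 3], hairpin = prof[, 4],
             interior = prof[, 5], multi = prof[, 6])
}

#' Convenience one-shot fold
#'
#' Builds (or reuses) the ratio database and returns every per-position
#' feature at once.
#'
#' @inheritParams base_pair_probabilities
#' @return A list with `db`, `bpp`, `pstem`, `accessibility`, `profile`.
#' @export
fold_span <- function(seq, W = 200, model = energy_model(), db = NULL) {
  seq <- as_rna_sequence(seq)
  if (is.null(db)) db <- build_ratios(seq, W, model)
  ff <- fold_features(seq, W, model, db)
  bpp <- data.frame(i = ff$bpp_i, j = ff$bpp_j, prob = ff$bpp_p)
  attr(bpp, "n") <- seq$n
  prof <- ff$profile
  list(db = db, bpp = bpp,
       pstem = ff$pstem, accessibility = 1 - ff$pstem,
       profile = data.frame(pos = seq_len(nrow(prof)), stem = prof[, 1],
                            bulge = prof[, 2], exterior = prof[, 3],
                            hairpin = prof[, 4], interior = prof[, 5],
                            multi = prof[, 6]))
}

#' Gamma-centroid structure (gamma <= 1)
#'
#' For `gamma <= 1` the gain-maximising structure consists of every base
#' pair with probability strictly above `1 / (gamma + 1) >= 1/2`; such
#' pairs are automatically conflict-free (two incompatible pairs cannot
#' both exceed 1/2), so the result is well-nested without any assembly DP.
#'
#' @param bpp Base-pair probabilities (data frame `i`, `j`, `prob`).
#' @param gamma Centroid parameter in `(0, 1]`.
#' @param n Sequence length.
#' @return An object of class `rna_structure`: fields `pairs` (data frame),
#'   `n`, `gamma`, and `dot_bracket`.
#' @export
gamma_centroid <- function(bpp, gamma = 1, n = attr(bpp, "n")) {
  if (gamma <= 0 || gamma > 1)
    sf_input_error("gamma must lie in (0, 1]; gamma > 1 is unsupported")
  if (is.null(n)) sf_input_error("sequence length n is required")
  sel <- bpp[bpp$prob > 1 / (gamma + 1), c("i", "j"), drop = FALSE]
  sel <- sel[order(sel$i), , drop = FALSE]
  rownames(sel) <- NULL
  st <- structure(list(pairs = sel, n = n, gamma = gamma), class = "rna_structure")
  validate_structure(st)
  st$dot_bracket <- dot_bracket(st)
  st
}

validate_structure <- function(st) {
  p <- st$pairs
  if (nrow(p) == 0L) return(invisible(TRUE))
  if (any(p$i >= p$j) || any(p$i < 1L) || any(p$j > st$n))
    sf_input_error("invalid pair coordinates")
  pos <- c(p$i, p$j)
  if (anyDuplicated(pos)) sf_input_error("a position occurs in two pairs")
  for (a in seq_len(nrow(p))) for (b in seq_len(nrow(p))) {
    if (p$i[a] < p$i[b] && p$i[b] < p$j[a] && p$j[a] < p$j[b])
      sf_input_error("crossing pairs: structure is not well-nested")
  }
  invisible(TRUE)
}

#' Dot-bracket rendering of a structure
#' @param st An `rna_structure`.
#' @return A single dot-bracket string.
#' @export
dot_bracket <- function(st) {
  ch <- rep(".", st$n)
  ch[st$pairs$i] <- "("
  ch[st$pairs$j] <- ")"
  paste(ch, collapse = "")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("rna_structure: %d pairs over %d nt (gamma = %g)\n%s\n",
              nrow(x$pairs), x$n, x$gamma, dot_bracket(x)))
  invisible(x)
}

#' Windowed averages of a per-position series
#'
#' @param values Numeric per-position series.
#' @param L Window length.
#' @param mode `"nonoverlapping"` (floor(N/L) windows; windows that would
#'   straddle the sequence end are dropped) or `"sliding"` (N - L + 1
#'   windows).
#' @return Data frame with `start`, `end` (1-based inclusive) and `mean`.
#' @export
window_average <- function(values, L,
                           mode = c("nonoverlapping", "sliding")) {
  mode <- match.arg(mode)
  stopifnot(L >= 1)
  n <- length(values)
  if (L > n)
    return(data.frame(start = integer(0), end = integer(0),
                      mean = numeric(0)))
  if (mode == "nonoverlapping") {
    k <- n %/% L
    start <- (seq_len(k) - 1L) * L + 1L
  } else {
    start <- seq_len(n - L + 1L)
  }
  cs <- c(0, cumsum(values))
  data.frame(start = start, end = start + L - 1L,
             mean = (cs[start + L] - cs[start]) / L)
}

#' Stem-probability difference between mRNA and pre-mRNA
#'
#' Maps every mRNA position to its pre-mRNA position through the exon
#' table and computes `Dq_stem(i) = p_stem,mRNA(i) - p_stem,pre-mRNA(i)`,
#' plus the median and median absolute deviation (unscaled) of `Dq_stem`
#' within a window around each splice junction.
#'
#' @param pre_pstem Per-position stem probabilities of the pre-mRNA.
#' @param mrna_pstem Per-position stem probabilities of the mRNA
#'   (concatenated exons).
#' @param exons Data frame with 1-based inclusive `start`, `end` columns on
#'   the pre-mRNA, in transcript order, non-overlapping.
#' @param window Total window size around each junction (default 200 nt:
#'   100 on each side, clipped at transcript ends).
#' @param smooth_L If non-`NULL`, additionally returns `Dq_stem` averaged in
#'   sliding windows of this length, separately for the regions upstream and
#'   downstream of each junction (windows never straddle a junction).
#' @return A list with `delta` (data frame `mrna_pos`, `pre_pos`, `delta`),
#'   `junctions` (data frame `junction`, `mrna_pos`, `median`, `mad`), and
#'   optionally `smoothed`.
#' @export
splice_delta <- function(pre_pstem, mrna_pstem, exons, window = 200L,
                         smooth_L = NULL) {
  if (!all(c("start", "end") %in% names(exons)))
    sf_coord_error("exon table must have 'start' and 'end' columns")
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$start > exons$end) || any(exons$start < 1L) ||
      any(exons$end > length(pre_pstem)))
    sf_coord_error("exon coordinates outside the pre-mRNA")
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    sf_coord_error("exon coordinates overlap")
  pre_pos <- unlist(mapply(seq, exons$start, exons$end, SIMPLIFY = FALSE))
  if (length(pre_pos) != length(mrna_pstem))
    sf_coord_error("exon lengths do not sum to the mRNA length (%d vs %d)",
                   length(pre_pos), length(mrna_pstem))
  delta <- mrna_pstem - pre_pstem[pre_pos]
  lens <- exons$end - exons$start + 1L
  jxn <- cumsum(lens)[-nrow(exons)]  # last mRNA position of each upstream exon
  half <- window %/% 2L
  junctions <- do.call(rbind, lapply(seq_along(jxn), function(t) {
    sel <- max(1L, jxn[t] - half + 1L):min(length(delta), jxn[t] + half)
    data.frame(junction = t, mrna_pos = jxn[t],
               median = stats::median(delta[sel]),
               mad = stats::median(abs(delta[sel] -
                                       stats::median(delta[sel]))))
  }))
  out <- list(delta = data.frame(mrna_pos = seq_along(delta),
                                 pre_pos = pre_pos, delta = delta),
              junctions = junctions)
  if (!is.null(smooth_L)) {
    out$smoothed <- do.call(rbind, lapply(seq_along(jxn), function(t) {
      lo <- if (t == 1L) 1L else jxn[t - 1L] + 1L
      hi <- if (t == length(jxn)) length(delta) else jxn[t + 1L]
      up <- window_average(delta[lo:jxn[t]], smooth_L, "sliding")
      dn <- window_average(delta[(jxn[t] + 1L):hi], smooth_L, "sliding")
      up$start <- up$start + lo - 1L; up$end <- up$end + lo - 1L
      dn$start <- dn$start + jxn[t]; dn$end <- dn$end + jxn[t]
      rbind(
        if (nrow(up)) cbind(junction = t, side = "upstream", up) else NULL,
        if (nrow(dn)) cbind(junction = t, side = "downstream", dn) else NULL)
    }))
  }
  out
}
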