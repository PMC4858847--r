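# shared fixtures: models are cheap to build but used everywhere
turner <- energy_model()
zero_m <- energy_model_zero()

# engine-vs-enumeration comparison on one (sequence, W, model) case;
# returns the largest absolute discrepancy over logZ (as exp-scale via
# telescoping), all p(i,j), p_stem and the six profile components
oracle_gap <- function(seq, W, model) {
  seq <- spanfold:::as_rna_sequence(seq)
  n <- seq$n
  en <- enumerate_structures(seq, W, model)
  db <- build_ratios(seq, W, model)
  fs <- fold_span(seq, W, model, db)
  bm <- matrix(0, n, n)
  if (nrow(fs$bpp)) bm[cbind(fs$bpp$i, fs$bpp$j)] <- fs$bpp$prob
  pr <- as.matrix(fs$profile[, -1]); dimnames(pr) <- NULL
  op <- en$profile; dimnames(op) <- NULL
  ops <- rowSums(en$bpp) + colSums(en$bpp)
  max(abs(sum(db$logda) - en$logZ),
      abs(sum(db$logdb) - en$logZ),
      max(abs(bm - en$bpp)),
      max(abs(fs$pstem - ops)),
      max(abs(pr - op)))
}

# stem probabilities straight from an enumeration oracle
oracle_pstem <- function(en) rowSums(en$bpp) + colSums(en$bpp)
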