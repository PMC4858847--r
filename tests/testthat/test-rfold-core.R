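test_that("potential outermost pairs respect canonicity and span", {
  expect_equal(nrow(potential_outermost_pairs("AAAAAAAA", 8)), 0L)
  P <- potential_outermost_pairs("GAAAC", 5)
  expect_true(any(P$i == 0 & P$j == 5))
  expect_equal(nrow(potential_outermost_pairs("GAAAC", 4)), 0L)
  # every reported pair is canonical with span in [min_hp + 2, W]
  s <- random_rna(40, 0.6, seed = 2)
  P <- potential_outermost_pairs(s, 15)
  res <- strsplit(as.character(s), "")[[1]]
  expect_true(all(P$j - P$i >= 5 & P$j - P$i <= 15))
  expect_true(all(!is.na(mapply(pair_type, res[P$res_i], res[P$res_j]))))
})

test_that("inside Stem values match enumeration on toy cases", {
  tb <- fold_inside("GAAAC", 5, zero_m)
  expect_equal(exp(inside_value(tb, "Stem", 0, 5)), 1)  # single hairpin
  tb0 <- fold_inside("AAAA", 4, zero_m)
  for (i in 0:3) for (j in i:4)
    expect_identical(inside_value(tb0, "Stem", i, j), -Inf)
})

test_that("exterior block weights u(p,q) follow the case definition", {
  tb <- fold_inside("GAAAC", 5, zero_m)
  logu <- u_weights(tb)
  expect_equal(logu[1, 2], 0)                 # unpaired step weight 1
  expect_equal(exp(logu[1, 6]), 1)            # u(0,5) = exp(alpha_Stem(0,5))
  expect_identical(logu[1, 4], -Inf)          # (0,3) not in P
  # sum over exterior decompositions equals the structure census
  for (seed in 1:5) {
    s <- random_rna(15, 0.6, seed = seed)
    en <- enumerate_structures(s, 15, zero_m)
    rf <- global_reference_fold(s, 15, zero_m)
    expect_equal(exp(rf$logZ), en$n_structures, tolerance = 1e-9)
  }
})

test_that("left and right exterior accumulations agree: alpha(N) = beta(0)", {
  expect_equal(global_reference_fold("AAAAAAAAAA", 10, turner)$logZ, 0)
  expect_equal(exp(global_reference_fold("GAAAC", 5, zero_m)$logZ), 2)
  for (seed in 1:50) {
    s <- random_rna(30, 0.5, seed = 100 + seed)
    rf <- global_reference_fold(s, 12, turner)
    expect_equal(rf$log_alpha_outer[31], rf$log_beta_outer[1],
                 tolerance = 1e-9)
    expect_equal(rf$logZ, rf$log_alpha_outer[31])
  }
})

test_that("Z decomposes identically at every anchor position", {
  for (seed in 1:5) {
    s <- random_rna(24, 0.55, seed = seed)
    W <- 14
    tb <- fold_inside(s, W, turner)
    rf <- global_reference_fold(s, W, turner)
    logu <- u_weights(tb)
    la <- rf$log_alpha_outer; lb <- rf$log_beta_outer
    for (anchor in 0:(s$n - 1)) {
      terms <- la[anchor + 1] + logu[anchor + 1, 2] + lb[anchor + 2]
      for (p in max(0, anchor - W + 1):anchor) {
        for (q in max(anchor + 1, p + 2):min(s$n, p + W)) {
          lu <- logu[p + 1, q - p + 1]
          if (q > p + 1 && is.finite(lu))
            terms <- c(terms, la[p + 1] + lu + lb[q + 1])
        }
      }
      expect_equal(spanfold:::logsumexp(terms), rf$logZ, tolerance = 1e-9)
    }
  }
})

test_that("grammar is complete and unambiguous: Z equals the oracle's sum", {
  for (seed in 1:8) {
    n <- 10 + seed
    s <- random_rna(n, 0.6, seed = 200 + seed)
    for (W in c(5, 8, n)) {
      en <- enumerate_structures(s, W, turner)
      rf <- global_reference_fold(s, W, turner)
      expect_equal(rf$logZ, en$logZ, tolerance = 1e-9)
    }
  }
})

test_that("local outside tables obey the initial condition and duality", {
  # beta_Stem(i,j;i,j) is exactly the Outer->Outer.Stem transition weight
  ol <- outside_local("GAAAC", c(0, 5), 5, zero_m)
  expect_equal(outside_value(ol, "Stem", 0, 5), 0)
  expect_error(outside_local("GAAAC", c(0, 4), 5, zero_m),
               class = "sf_input_error")
  # single-derivation window: on the derivation path, outside * inside
  # recovers the full block weight
  tb <- fold_inside("GAAAC", 5, zero_m)
  expect_equal(outside_value(ol, "StemEnd", 1, 4) +
                 inside_value(tb, "StemEnd", 1, 4), 0)
  # unreachable states carry zero ensemble weight
  expect_identical(outside_value(ol, "Multi", 1, 4), -Inf)
  # general case: for every banded cell, sum over outermost pairs of
  # beta_Stem(k,l;i,j)/r(i,j) equals the global outside over Z
  s <- random_rna(14, 0.7, seed = 31)
  W <- 10
  db <- build_ratios(s, W, turner)
  tb <- fold_inside(s, W, turner)
  P <- potential_outermost_pairs(s, W, turner)
  acc <- matrix(0, s$n + 1, s$n + 1)
  for (r in seq_len(nrow(P))) {
    ol <- outside_local(s, c(P$i[r], P$j[r]), W, turner)
    rr <- ratio_r(P$i[r], P$j[r], db, tb)
    for (k in P$i[r]:(P$j[r] - 1)) for (l in (k + 1):P$j[r]) {
      bv <- outside_value(ol, "Stem", k, l)
      if (is.finite(bv)) acc[k + 1, l + 1] <- acc[k + 1, l + 1] + exp(bv - rr)
    }
  }
  for (r in seq_len(nrow(P))) {
    k <- P$i[r]; l <- P$j[r]
    expect_equal(acc[k + 1, l + 1],
                 outside_over_z(s, db, turner, "Stem", k, l),
                 tolerance = 1e-9)
  }
})
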