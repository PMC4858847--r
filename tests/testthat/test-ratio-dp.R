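test_that("fold changes match raw exterior accumulation ratios", {
  # pairless sequence: the unpaired transition is the only path
  db <- build_ratios("AAAAAAAAAA", 10, zero_m)
  expect_equal(db$logda, rep(0, 10))
  expect_equal(db$logdb, rep(0, 10))
  for (seed in 1:10) {
    s <- random_rna(30, 0.5, seed = 300 + seed)
    W <- 12
    db <- build_ratios(s, W, turner)
    rf <- global_reference_fold(s, W, turner)
    expect_equal(db$logda, diff(rf$log_alpha_outer), tolerance = 1e-10)
    expect_equal(db$logdb, -diff(rf$log_beta_outer), tolerance = 1e-10)
    # telescoping: the ratios jointly recover log Z from either side
    expect_equal(sum(db$logda), rf$logZ, tolerance = 1e-9)
    expect_equal(sum(db$logdb), rf$logZ, tolerance = 1e-9)
  }
})

test_that("r(i,j) is reconstructed locally from the database", {
  # unit weights, no pairs: Z = alpha = beta = 1 everywhere
  s0 <- rna_sequence("ACACACAC")
  db0 <- build_ratios(s0, 8, zero_m)
  tb0 <- fold_inside(s0, 8, zero_m)
  for (i in 0:6) for (j in i:min(8, i + 8))
    expect_equal(exp(ratio_r(i, j, db0, tb0)), 1, tolerance = 1e-12)
  # single-hairpin toy
  db <- build_ratios("GAAAC", 5, zero_m)
  tb <- fold_inside("GAAAC", 5, zero_m)
  expect_equal(exp(ratio_r(0, 5, db, tb)), 2, tolerance = 1e-12)
  expect_error(ratio_r(0, 20, db, tb), class = "sf_input_error")
  # random sequences: r matches Z / (alpha(i) beta(j)) from the raw fold
  for (seed in 1:5) {
    s <- random_rna(25, 0.55, seed = 400 + seed)
    W <- 11
    db <- build_ratios(s, W, turner)
    tb <- fold_inside(s, W, turner)
    rf <- global_reference_fold(s, W, turner)
    for (i in c(0, 7, 13, 20)) for (j in c(i, i + 4, i + W)) {
      if (j > s$n) next
      want <- rf$logZ - rf$log_alpha_outer[i + 1] - rf$log_beta_outer[j + 1]
      expect_equal(ratio_r(i, j, db, tb), want, tolerance = 1e-9)
    }
  }
})

test_that("outside over Z matches raw outside values and the oracle", {
  # single-derivation toy: beta_Stem(0,5)/Z = 1/2 under zero energies
  db <- build_ratios("GAAAC", 5, zero_m)
  expect_equal(outside_over_z("GAAAC", db, zero_m, "Stem", 0, 5), 0.5,
               tolerance = 1e-12)
  expect_equal(outside_over_z("GAAAC", db, zero_m, "Multi", 1, 4), 0)
  # beta_Stem(i,j)/Z * alpha_Stem(i,j) is the pair probability: check the
  # probability-scale outside against the enumeration oracle
  for (seed in 1:5) {
    s <- random_rna(16, 0.6, seed = 500 + seed)
    W <- 12
    en <- enumerate_structures(s, W, turner)
    db <- build_ratios(s, W, turner)
    tb <- fold_inside(s, W, turner)
    P <- potential_outermost_pairs(s, W, turner)
    for (r in seq_len(nrow(P))) {
      i <- P$i[r]; j <- P$j[r]
      boz <- outside_over_z(s, db, turner, "Stem", i, j)
      expect_equal(boz * exp(inside_value(tb, "Stem", i, j)),
                   en$bpp[i + 1, j], tolerance = 1e-9)
    }
  }
})

test_that("transition probabilities obey the law of total probability", {
  s <- random_rna(20, 0.6, seed = 21)
  W <- 12
  db <- build_ratios(s, W, turner)
  tb <- fold_inside(s, W, turner)
  P <- potential_outermost_pairs(s, W, turner)
  for (anchor in c(0, 5, 12, 19)) {
    tot <- transition_prob("outer_unpaired", anchor, db = db, tables = tb)
    sel <- P[P$i <= anchor & P$j > anchor, ]
    if (nrow(sel)) for (r in seq_len(nrow(sel)))
      tot <- tot + transition_prob("outer_stem", sel$i[r], sel$j[r],
                                   db = db, tables = tb)
    expect_equal(tot, 1, tolerance = 1e-9)
  }
  # zero-weight transitions have probability zero
  expect_equal(transition_prob("stem", 1, 3, db = db, tables = tb), 0)
})

test_that("transition probabilities equal oracle ensemble frequencies", {
  s <- random_rna(15, 0.65, seed = 77)
  W <- 15
  en <- enumerate_structures(s, W, turner, return_structures = TRUE)
  db <- build_ratios(s, W, turner)
  tb <- fold_inside(s, W, turner)
  w <- exp(en$log_weights - en$logZ)
  P <- potential_outermost_pairs(s, W, turner)
  for (r in seq_len(nrow(P))) {
    i <- P$i[r]; j <- P$j[r]
    # ensemble frequency of (i, j) being an outermost pair
    freq <- sum(vapply(seq_along(w), function(t) {
      pr <- en$structures[[t]]
      if (nrow(pr) == 0) return(0)
      hit <- pr[, 1] == i + 1 & pr[, 2] == j
      if (!any(hit)) return(0)
      enclosed <- any(pr[, 1] < i + 1 & pr[, 2] > j)
      if (enclosed) 0 else w[t]
    }, 0))
    expect_equal(transition_prob("outer_stem", i, j, db = db, tables = tb),
                 freq, tolerance = 1e-9)
  }
})

test_that("ratio magnitudes stay bounded on long sequences", {
  s <- random_rna(20000, 0.5, seed = 55)
  db <- build_ratios(s, 30, turner)
  expect_true(all(is.finite(db$logda)) && all(is.finite(db$logdb)))
  # the fold change reflects at most W positions of context
  expect_lt(max(abs(db$logda)), 30)
  expect_lt(max(abs(db$logdb)), 30)
})

test_that("the ratio database round-trips through its TSV form bit-exactly", {
  s <- random_rna(120, 0.5, seed = 9)
  db <- build_ratios(s, 25, turner)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ratio_db(db, path)
  back <- read_ratio_db(path, seq = s, model = turner)
  expect_identical(back$logda, db$logda)
  expect_identical(back$logdb, db$logdb)
  expect_error(read_ratio_db(path, seq = random_rna(120, 0.5, seed = 10),
                             model = turner),
               class = "sf_integrity_error")
})
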