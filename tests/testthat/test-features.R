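test_that("base-pair probabilities match enumeration on toy cases", {
  expect_equal(nrow(base_pair_probabilities("AAAAAA", 6, zero_m)), 0L)
  bpp <- base_pair_probabilities("GAAAC", 5, zero_m)
  expect_equal(bpp$i, 1L)
  expect_equal(bpp$j, 5L)
  expect_equal(bpp$prob, 0.5)
})

test_that("stem probability and accessibility are complementary", {
  bpp <- base_pair_probabilities("GAAAC", 5, zero_m)
  ps <- stem_probability(bpp)
  expect_equal(ps, c(0.5, 0, 0, 0, 0.5))
  expect_equal(accessibility(ps) + ps, rep(1, 5))
  expect_equal(stem_probability(base_pair_probabilities("AAAAAA", 6, zero_m)),
               rep(0, 6))
})

test_that("a designed perfect hairpin folds into its stem", {
  hp <- designed_hairpin(20, 4, seed = 33)
  fs <- fold_span(hp, length(hp), turner)
  want <- attr(hp, "pairs")
  expect_gt(min(fs$pstem[c(want[, 1], want[, 2])]), 0.9)
})

test_that("structural profiles classify loops and sum to one", {
  pr0 <- structural_profile("AAAAAAAA", 8, zero_m)
  expect_equal(pr0$exterior, rep(1, 8))
  expect_equal(pr0$stem + pr0$bulge + pr0$hairpin + pr0$interior + pr0$multi,
               rep(0, 8))
  pr <- structural_profile("GAAAC", 5, zero_m)
  expect_equal(pr$hairpin[2:4], rep(0.5, 3))
  expect_equal(pr$exterior[2:4], rep(0.5, 3))
  expect_equal(pr$stem[c(1, 5)], c(0.5, 0.5))
  for (seed in 1:10) {
    s <- random_rna(60, 0.55, seed = 700 + seed)
    pr <- structural_profile(s, 20, turner)
    expect_lt(max(abs(rowSums(pr[, -1]) - 1)), 1e-9)
    expect_true(all(pr[, -1] >= -1e-9 & pr[, -1] <= 1 + 1e-9))
  }
})

test_that("span saturation: W = N reproduces the unconstrained fold", {
  for (seed in 1:6) {
    n <- 10 + 2 * seed
    s <- random_rna(n, 0.6, seed = 800 + seed)
    en_free <- enumerate_structures(s, 2L * n, turner)  # no effective limit
    fs <- fold_span(s, n, turner)
    expect_equal(fs$pstem, oracle_pstem(en_free), tolerance = 1e-9)
    pr <- as.matrix(fs$profile[, -1]); dimnames(pr) <- NULL
    op <- en_free$profile; dimnames(op) <- NULL
    expect_lt(max(abs(pr - op)), 1e-9)
  }
})

test_that("mid-sequence locality: context influence decays with distance", {
  motif <- random_rna(120, 0.5, seed = 91)
  W <- 30
  big <- rna_sequence(paste0(as.character(random_rna(1500, 0.5, seed = 92)),
                             as.character(motif),
                             as.character(random_rna(1500, 0.5, seed = 93))))
  full <- fold_span(big, W, turner)
  gap_at <- function(mult) {
    pad <- mult * W
    padded <- rna_sequence(paste0(
      substr(big$residues, 1501 - pad, 1500),
      as.character(motif),
      substr(big$residues, 1621, 1620 + pad)))
    fp <- fold_span(padded, W, turner)
    max(abs(full$pstem[1501:1620] - fp$pstem[(pad + 1):(pad + 120)]))
  }
  d5 <- gap_at(5); d10 <- gap_at(10)
  expect_lt(d10, 1e-4)   # ten spans of identical context pin the ensemble
  expect_lt(d10, d5)     # and agreement improves with more context
  expect_lt(d5, 0.05)    # five spans already give approximate agreement
})

test_that("gamma-centroid keeps exactly the above-threshold pairs", {
  # all probabilities below 1/2: empty structure
  bpp <- base_pair_probabilities("GAAAC", 5, zero_m)
  st <- gamma_centroid(bpp, 1, n = 5)
  expect_equal(nrow(st$pairs), 0L)
  expect_equal(st$dot_bracket, ".....")
  # designed hairpin: the full helix comes back as a nested dot-bracket
  hp <- designed_hairpin(12, 4, seed = 35)
  fs <- fold_span(hp, length(hp), turner)
  ct <- gamma_centroid(fs$bpp, 1, n = length(hp))
  expect_equal(nrow(ct$pairs), 12L)
  expect_equal(ct$dot_bracket,
               paste0(strrep("(", 12), "....", strrep(")", 12)))
  # gamma = 1 is exactly thresholding at 1/2
  keep <- fs$bpp[fs$bpp$prob > 0.5, c("i", "j")]
  expect_equal(ct$pairs, keep[order(keep$i), ], ignore_attr = TRUE)
  # smaller gamma demands more credible pairs
  ct2 <- gamma_centroid(fs$bpp, 0.5, n = length(hp))
  expect_true(all(ct2$pairs$i %in% ct$pairs$i))
  expect_error(gamma_centroid(fs$bpp, 1.5, n = length(hp)),
               class = "sf_input_error")
})

test_that("windowed averages follow both modes", {
  expect_equal(window_average(rep(3, 100), 10)$mean, rep(3, 10))
  expect_equal(nrow(window_average(rnorm(64), 32)), 2L)
  sl <- window_average(1:10, 5, "sliding")  # N - L + 1 = 6 windows
  expect_equal(sl$mean, 3:8)
  expect_equal(sl$start, 1:6)
  expect_equal(nrow(window_average(1:5, 6)), 0L)
})

test_that("splicing comparison maps coordinates and summarises junctions", {
  # identical transcript (exons cover everything): differences vanish
  ps <- runif(50)
  same <- splice_delta(ps, ps, data.frame(start = c(1, 21), end = c(20, 50)))
  expect_equal(same$delta$delta, rep(0, 50))
  expect_equal(same$junctions$median, 0)
  # toy construct where the intron pairs with the exon end: removing the
  # intron frees the exon tail, so Dq_stem < 0 near the junction
  pre <- rna_sequence("AAAGGCCCGGGCCAAAUUU")
  exons <- data.frame(start = c(1, 15), end = c(8, 19))
  mrna <- rna_sequence(paste0(substr(pre$residues, 1, 8),
                              substr(pre$residues, 15, 19)))
  psp <- oracle_pstem(enumerate_structures(pre, pre$n, turner))
  psm <- oracle_pstem(enumerate_structures(mrna, mrna$n, turner))
  sd <- splice_delta(psp, psm, exons, window = 8)
  expect_lt(sd$junctions$median, 0)
  expect_lt(mean(sd$delta$delta[5:8]), 0)
  # median/MAD agree with direct arithmetic on the window
  w <- sd$delta$delta[5:12]
  expect_equal(sd$junctions$median, median(w))
  expect_equal(sd$junctions$mad, median(abs(w - median(w))))
  # smoothed windows never straddle the junction
  sm <- splice_delta(psp, psm, exons, window = 8, smooth_L = 3)$smoothed
  expect_true(all(sm$end[sm$side == "upstream"] <= 8))
  expect_true(all(sm$start[sm$side == "downstream"] >= 9))
  # coordinate validation
  expect_error(splice_delta(psp, psm, data.frame(start = 1, end = 30)),
               class = "sf_coord_error")
  expect_error(splice_delta(psp, psm[-1], exons), class = "sf_coord_error")
})
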