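test_that("pair typing covers exactly the six canonical pairs", {
  expect_equal(pair_type("G", "C"), "GC")
  expect_equal(pair_type("G", "U"), "GU")
  expect_equal(pair_type("a", "u"), "AU")
  expect_true(is.na(pair_type("A", "G")))
  expect_true(is.na(pair_type("N", "A")))
  expect_error(pair_type("X", "A"), class = "sf_input_error")
  got <- outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
               Vectorize(function(a, b) pair_type(a, b)))
  expect_equal(sum(!is.na(got)), 6L)
})

test_that("loop weights are Boltzmann factors with the documented gates", {
  # hairpins below the minimum number of unpaired bases are forbidden
  expect_equal(loop_weight(turner, "hairpin", length = 2), 0)
  expect_gt(loop_weight(turner, "hairpin", length = 3), 0)
  # all-zero parameter set: every admissible loop has weight exactly 1
  expect_equal(loop_weight(zero_m, "hairpin", length = 7), 1)
  expect_equal(loop_weight(zero_m, "stack", closing = "CG", inner = "GC"), 1)
  expect_equal(loop_weight(zero_m, "internal", length = 6), 1)
  # CG-on-CG stack from the bundled file: dG = -3.26 kcal/mol at 310.15 K
  kT <- turner$gas_constant * turner$temperature
  expect_equal(loop_weight(turner, "stack", closing = "CG", inner = "CG"),
               exp(3.26 / kT), tolerance = 1e-12)
  # internal/bulge loops above the cap fall out of the structure class
  expect_equal(loop_weight(turner, "bulge", length = 31), 0)
})

test_that("the bundled stack table satisfies thermodynamic symmetry", {
  rev_pair <- c(AU = "UA", UA = "AU", CG = "GC", GC = "CG",
                GU = "UG", UG = "GU")
  st <- turner$stack_energies
  for (p in rownames(st)) for (q in colnames(st))
    expect_equal(st[p, q], st[rev_pair[q], rev_pair[p]])
})

test_that("parameter files round-trip and digests detect changes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_energy_model(turner, path)
  back <- read_energy_model(path)
  expect_equal(back$stack_energies, turner$stack_energies)
  expect_equal(back$hairpin_by_length, turner$hairpin_by_length)
  expect_equal(back$digest, turner$digest)
  m2 <- turner
  m2$stack_energies["CG", "CG"] <- -3.0
  expect_false(spanfold:::model_digest(m2) == turner$digest)
})

test_that("structure weight equals the product of its loop weights", {
  # independent R-side loop decomposition against the C++ energy summation
  r_structure_weight <- function(seq, pairs, model) {
    res <- strsplit(as.character(seq), "")[[1]]
    n <- length(res)
    mate <- integer(n); mate[pairs[, 1]] <- pairs[, 2]; mate[pairs[, 2]] <- pairs[, 1]
    w <- 1
    for (r in seq_len(nrow(pairs))) {
      k <- pairs[r, 1]; l <- pairs[r, 2]
      ch <- NULL; m <- k + 1L; unp <- 0L
      while (m < l) {
        if (mate[m] > m) { ch <- rbind(ch, c(m, mate[m])); m <- mate[m] + 1L }
        else { unp <- unp + 1L; m <- m + 1L }
      }
      if (is.null(ch)) {
        w <- w * loop_weight(model, "hairpin", length = l - k - 1L)
      } else if (nrow(ch) == 1L) {
        l1 <- ch[1, 1] - k - 1L; l2 <- l - ch[1, 2] - 1L
        w <- w * if (l1 == 0L && l2 == 0L)
          loop_weight(model, "stack", closing = pair_type(res[k], res[l]),
                      inner = pair_type(res[ch[1, 1]], res[ch[1, 2]]))
        else if (l1 == 0L || l2 == 0L)
          loop_weight(model, "bulge", length = l1 + l2)
        else loop_weight(model, "internal", length = l1 + l2)
      } else {
        # affine multiloop: a + b * (branches incl. closing) + c * unpaired
        w <- w * loop_weight(model, "multi", branches = nrow(ch) + 1L,
                             unpaired = unp)
      }
    }
    w
  }
  s2 <- rna_sequence("GGGCAAAGCGCAAAGCGGCAAA")
  en <- enumerate_structures(s2, 22, turner, return_structures = TRUE)
  idx <- order(en$log_weights)[unique(round(seq(1, en$n_structures,
                                                length.out = 25)))]
  for (t in idx) {
    pr <- en$structures[[t]]
    if (nrow(pr) == 0) next
    expect_equal(log(r_structure_weight(s2, pr, turner)), en$log_weights[t],
                 tolerance = 1e-9)
  }
})

test_that("zero energies turn the partition function into a structure count", {
  for (seed in 1:5) {
    s <- random_rna(14, 0.6, seed = seed)
    en <- enumerate_structures(s, 14, zero_m)
    rf <- global_reference_fold(s, 14, zero_m)
    expect_equal(exp(rf$logZ), en$n_structures, tolerance = 1e-9)
  }
})
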