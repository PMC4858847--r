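SF_ALPHABET <- c("N", "A", "C", "G", "U")

#' Construct a validated RNA sequence
#'
#' Builds the 1-based residue string used throughout the package. Input is
#' uppercased and DNA-style `T` is read as `U`; the alphabet is restricted to
#' `A`, `C`, `G`, `U`, `N`.
#'
#' @param x A single character string, or a character vector of single
#'   residues.
#' @param name Sequence identifier.
#' @return An object of class `rna_sequence` with fields `name`, `residues`
#'   (a single string), `codes` (integer residue codes) and `n` (length).
#' @examples
#' rna_sequence("gaaac")
#' rna_sequence("ACGT")  # T silently read as U
#' @export
rna_sequence <- function(x, name = "seq") {
  if (is.character(x) && length(x) > 1L) x <- paste(x, collapse = "")
  if (!is.character(x) || length(x) != 1L || is.na(x))
    sf_input_error("sequence must be a character string")
  s <- chartr("T", "U", toupper(x))
  codes <- match(strsplit(s, "", fixed = TRUE)[[1L]], SF_ALPHABET) - 1L
  if (anyNA(codes))
    sf_input_error("invalid residue symbol in sequence '%s'", name)
  if (length(codes) < 1L) sf_input_error("empty sequence")
  structure(list(name = name, residues = s, codes = codes,
                 n = length(codes)),
            class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  shown <- if (x$n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("rna_sequence '%s' (%d nt)\n%s\n", x$name, x$n, shown))
  invisible(x)
}

#' @export
as.character.rna_sequence <- function(x, ...) x$residues

#' @export
length.rna_sequence <- function(x) x$n

as_rna_sequence <- function(x, name = "seq") {
  if (inherits(x, "rna_sequence")) x else rna_sequence(x, name)
}

seq_digest <- function(seq) cpp_digest(seq$residues)

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Random RNA sequence with a given GC fraction
#'
#' @param n Sequence length.
#' @param gc_fraction Expected fraction of G+C residues.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param name Sequence identifier.
#' @return An [rna_sequence()].
#' @export
random_rna <- function(n, gc_fraction = 0.5, seed = NULL, name = "random") {
  stopifnot(n >= 1, gc_fraction >= 0, gc_fraction <= 1)
  p <- c(A = (1 - gc_fraction) / 2, U = (1 - gc_fraction) / 2,
         C = gc_fraction / 2, G = gc_fraction / 2)
  res <- with_seed(seed,
    sample(names(p), n, replace = TRUE, prob = p))
  rna_sequence(paste(res, collapse = ""), name = name)
}

rna_complement <- function(res) chartr("ACGU", "UGCA", res)

#' Designed perfect hairpin
#'
#' A stem of `stem_len` Watson-Crick pairs closed over a loop of `loop_len`
#' unpaired bases; the 3' arm is the reverse complement of the 5' arm. Used
#' to exercise centroid recovery: the designed pairs are attached as the
#' `pairs` attribute (1-based residue pairs).
#'
#' @param stem_len Number of base pairs in the stem.
#' @param loop_len Number of unpaired loop bases (>= 3).
#' @param seed Optional seed for the random 5' arm.
#' @param gc_fraction GC content of the stem arm.
#' @return An [rna_sequence()] of length `2 * stem_len + loop_len` with a
#'   `pairs` attribute.
#' @export
designed_hairpin <- function(stem_len, loop_len = 4, seed = NULL,
                             gc_fraction = 0.6) {
  stopifnot(stem_len >= 1, loop_len >= 3)
  arm <- with_seed(seed, {
    paste(sample(c("A", "U", "C", "G"), stem_len, replace = TRUE,
                 prob = c((1 - gc_fraction) / 2, (1 - gc_fraction) / 2,
                          gc_fraction / 2, gc_fraction / 2)),
          collapse = "")
  })
  # loop of A/C only, so the loop cannot pair with itself
  loop <- paste(rep(c("A", "C"), length.out = loop_len), collapse = "")
  arm3 <- paste(rev(strsplit(rna_complement(arm), "")[[1L]]), collapse = "")
  s <- rna_sequence(paste0(arm, loop, arm3), name = "hairpin")
  n <- 2L * stem_len + loop_len
  attr(s, "pairs") <- cbind(i = seq_len(stem_len), j = n + 1L - seq_len(stem_len))
  s
}

#' Toy gene fixture: pre-mRNA, mRNA and exon coordinates
#'
#' Builds a small two-exon gene whose intron is designed to base-pair with
#' the end of the upstream exon, so that splicing (removing the intron)
#' changes the stem probability of exonic positions near the junction.
#'
#' @param seed Optional seed.
#' @param exon_len Length of each exon.
#' @param intron_len Minimum intron length (>= pairing arm + 10).
#' @return A list with elements `pre` (pre-mRNA [rna_sequence()]), `mrna`,
#'   and `exons` (data frame of 1-based inclusive `start`, `end` on the
#'   pre-mRNA).
#' @export
make_gene_fixture <- function(seed = NULL, exon_len = 40L, intron_len = 30L) {
  with_seed(seed, {
    arm <- 12L
    exon1 <- as.character(random_rna(exon_len, 0.55, name = "e1"))
    # intron opens with the reverse complement of the exon-1 tail, so in the
    # pre-mRNA the exon end is sequestered in a stem across the junction
    tail1 <- substr(exon1, exon_len - arm + 1L, exon_len)
    anti <- paste(rev(strsplit(rna_complement(tail1), "")[[1L]]), collapse = "")
    filler <- as.character(random_rna(max(intron_len - arm - 4L, 6L), 0.3,
                                      name = "fill"))
    intron <- paste0("GU", anti, filler, "AG")
    exon2 <- as.character(random_rna(exon_len, 0.55, name = "e2"))
    pre <- paste0(exon1, intron, exon2)
    exons <- data.frame(start = c(1L, exon_len + nchar(intron) + 1L),
                        end = c(exon_len, exon_len + nchar(intron) + exon_len))
    list(pre = rna_sequence(pre, name = "pre_mrna"),
         mrna = rna_sequence(paste0(exon1, exon2), name = "mrna"),
         exons = exons)
  })
}

#' Read RNA sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return A list of [rna_sequence()] objects.
#' @export
read_fasta_rna <- function(path) {
  if (!file.exists(path)) sf_input_error("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) sf_input_error("malformed FASTA: %s",
                                                     conditionMessage(e)))
  if (length(set) == 0L) sf_input_error("FASTA contains no sequences")
  lapply(seq_along(set), function(i) {
    rna_sequence(as.character(set[[i]]), name = names(set)[i])
  })
}

#' Write sequences to FASTA
#' @param seqs A list of [rna_sequence()] (or a single one).
#' @param path Output path.
#' @export
write_fasta_rna <- function(seqs, path) {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  lines <- unlist(lapply(seqs, function(s) c(paste0(">", s$name), s$residues)))
  writeLines(lines, path)
  invisible(path)
}
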