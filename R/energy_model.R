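SF_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")
SF_GAS_CONSTANT <- 0.0019872  # kcal/(mol K)

#' Canonical pair type of two residues
#'
#' @param a,b Single residues from `A`, `C`, `G`, `U`, `N`.
#' @return One of `"AU"`, `"UA"`, `"CG"`, `"GC"`, `"GU"`, `"UG"`, or
#'   `NA_character_` when the two residues do not form a canonical pair
#'   (any pairing involving `N` is non-canonical).
#' @examples
#' pair_type("G", "C")  # "GC"
#' pair_type("A", "G")  # NA
#' @export
pair_type <- function(a, b) {
  ok <- function(z) is.character(z) && length(z) == 1L && z %in% SF_ALPHABET
  a <- toupper(a); b <- toupper(b)
  if (!ok(a) || !ok(b)) sf_input_error("invalid residue symbol")
  code <- .pair_code_r(match(a, SF_ALPHABET) - 1L, match(b, SF_ALPHABET) - 1L)
  if (code == 0L) NA_character_ else SF_PAIRS[code]
}

.pair_code_r <- function(a, b) {
  key <- a * 8L + b
  codes <- c(`12` = 1L, `33` = 2L, `19` = 3L, `26` = 4L, `28` = 5L, `35` = 6L)
  v <- codes[as.character(key)]
  if (is.na(v)) 0L else unname(v)
}

#' Path of the bundled energy-parameter file
#' @return File path of the default nearest-neighbour parameter set.
#' @export
default_param_file <- function() {
  system.file("extdata", "params", "default_params.tsv", package = "spanfold",
              mustWork = TRUE)
}

#' Read a nearest-neighbour energy model from a parameter file
#'
#' The native parameter format is a TSV with a section label in the first
#' column: `STACK` rows give `outer-pair inner-pair dG`; `HAIRPIN`, `BULGE`
#' and `INTERNAL` rows give `length dG`; `MULTI` rows give the affine
#' multiloop coefficients (`closing`, `branch`, `unpaired`); `MISC` rows hold
#' `terminal_au`. All free energies are in kcal/mol at 37 degrees C.
#'
#' @param path Parameter file; defaults to the bundled set.
#' @param temperature Absolute temperature in Kelvin.
#' @param dangle_mode `"none"` (default) or `"simplified"`, which switches on
#'   the terminal non-CG pair penalty for exterior and multiloop branches.
#' @param min_hairpin_unpaired Minimum unpaired bases in a hairpin loop.
#' @param max_internal_loop Cap on the total size of internal/bulge loops.
#' @return An object of class `energy_model`.
#' @export
read_energy_model <- function(path = default_param_file(),
                              temperature = 310.15,
                              dangle_mode = c("none", "simplified"),
                              min_hairpin_unpaired = 3L,
                              max_internal_loop = 30L) {
  dangle_mode <- match.arg(dangle_mode)
  if (!file.exists(path)) sf_input_error("parameter file not found: %s", path)
  if (min_hairpin_unpaired < 3L)
    sf_input_error("min_hairpin_unpaired must be >= 3")
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("section", "key1", "key2", "value"),
                           fill = TRUE)
  pick <- function(sec) tab[tab$section == sec, , drop = FALSE]

  stack <- matrix(NA_real_, 6, 6, dimnames = list(SF_PAIRS, SF_PAIRS))
  st <- pick("STACK")
  for (r in seq_len(nrow(st))) {
    if (!(st$key1[r] %in% SF_PAIRS) || !(st$key2[r] %in% SF_PAIRS))
      sf_input_error("unknown pair type in STACK section")
    stack[st$key1[r], st$key2[r]] <- as.numeric(st$value[r])
  }
  if (anyNA(stack)) sf_input_error("incomplete STACK table")

  len_table <- function(sec, min_len) {
    p <- pick(sec)
    if (nrow(p) == 0L) sf_input_error("missing %s section", sec)
    len <- as.integer(p$key1)
    val <- as.numeric(p$key2)
    out <- rep(Inf, max(len) + 1L)
    out[len + 1L] <- val
    if (any(!is.finite(out[(min_len + 1L):length(out)])))
      sf_input_error("%s table has gaps", sec)
    out
  }
  hairpin <- len_table("HAIRPIN", min_hairpin_unpaired)
  bulge <- len_table("BULGE", 1L)
  internal <- len_table("INTERNAL", 2L)

  mk <- pick("MULTI")
  mget1 <- function(k) {
    v <- as.numeric(mk$key2[mk$key1 == k])
    if (length(v) != 1L) sf_input_error("MULTI section needs '%s'", k)
    v
  }
  multi <- c(closing = mget1("closing"), branch = mget1("branch"),
             unpaired = mget1("unpaired"))
  misc <- pick("MISC")
  term_au <- as.numeric(misc$key2[misc$key1 == "terminal_au"])
  if (length(term_au) != 1L) term_au <- 0

  model <- structure(list(
    temperature = temperature,
    gas_constant = SF_GAS_CONSTANT,
    stack_energies = stack,
    hairpin_by_length = hairpin,
    bulge_by_length = bulge,
    internal_by_length = internal,
    multiloop_affine = multi,
    terminal_au = term_au,
    dangle_mode = dangle_mode,
    min_hairpin_unpaired = as.integer(min_hairpin_unpaired),
    max_internal_loop = as.integer(max_internal_loop),
    source = path), class = "energy_model")
  model$digest <- model_digest(model)
  model
}

#' Default energy model (bundled parameters, 37 degrees C)
#' @inheritParams read_energy_model
#' @return An `energy_model`.
#' @export
energy_model <- function(temperature = 310.15,
                         dangle_mode = c("none", "simplified")) {
  read_energy_model(default_param_file(), temperature = temperature,
                    dangle_mode = match.arg(dangle_mode))
}

#' All-zero energy model
#'
#' Every admissible loop gets free energy 0, so every admissible structure
#' has Boltzmann weight 1 and the partition function counts structures.
#'
#' @inheritParams read_energy_model
#' @return An `energy_model`.
#' @export
energy_model_zero <- function(min_hairpin_unpaired = 3L,
                              max_internal_loop = 30L) {
  hairpin <- rep(0, 31); hairpin[seq_len(min_hairpin_unpaired)] <- Inf
  bulge <- c(Inf, rep(0, 30))
  internal <- c(Inf, Inf, rep(0, 29))
  model <- structure(list(
    temperature = 310.15,
    gas_constant = SF_GAS_CONSTANT,
    stack_energies = matrix(0, 6, 6, dimnames = list(SF_PAIRS, SF_PAIRS)),
    hairpin_by_length = hairpin,
    bulge_by_length = bulge,
    internal_by_length = internal,
    multiloop_affine = c(closing = 0, branch = 0, unpaired = 0),
    terminal_au = 0,
    dangle_mode = "none",
    min_hairpin_unpaired = as.integer(min_hairpin_unpaired),
    max_internal_loop = as.integer(max_internal_loop),
    source = "<zero>"), class = "energy_model")
  model$digest <- model_digest(model)
  model
}

#' Write an energy model in the native parameter format
#'
#' Round-trips through [read_energy_model()].
#'
#' @param model An `energy_model`.
#' @param path Output file.
#' @export
write_energy_model <- function(model, path) {
  ln <- character(0)
  for (po in SF_PAIRS) for (pi in SF_PAIRS)
    ln <- c(ln, sprintf("STACK\t%s\t%s\t%.6g", po, pi,
                        model$stack_energies[po, pi]))
  tab_lines <- function(sec, tab) {
    lens <- which(is.finite(tab)) - 1L
    sprintf("%s\t%d\t%.6g", sec, lens, tab[lens + 1L])
  }
  ln <- c(ln, tab_lines("HAIRPIN", model$hairpin_by_length),
          tab_lines("BULGE", model$bulge_by_length),
          tab_lines("INTERNAL", model$internal_by_length),
          sprintf("MULTI\tclosing\t%.6g", model$multiloop_affine[["closing"]]),
          sprintf("MULTI\tbranch\t%.6g", model$multiloop_affine[["branch"]]),
          sprintf("MULTI\tunpaired\t%.6g",
                  model$multiloop_affine[["unpaired"]]),
          sprintf("MISC\tterminal_au\t%.6g", model$terminal_au))
  writeLines(c("# spanfold energy parameters", ln), path)
  invisible(path)
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(paste0("energy_model: T = %.2f K, dangles = %s, ",
                     "min hairpin = %d, digest = %s\n"),
              x$temperature, x$dangle_mode, x$min_hairpin_unpaired, x$digest))
  invisible(x)
}

model_digest <- function(model) {
  payload <- paste(
    format(c(model$temperature, model$stack_energies,
             model$hairpin_by_length, model$bulge_by_length,
             model$internal_by_length, model$multiloop_affine,
             model$terminal_au, model$min_hairpin_unpaired,
             model$max_internal_loop), digits = 17),
    collapse = ",")
  cpp_digest(paste(payload, model$dangle_mode, sep = "|"))
}

# internal: the flat list handed to the C++ kernels
as_cpp_model <- function(model) {
  stopifnot(inherits(model, "energy_model"))
  list(kT = model$gas_constant * model$temperature,
       stack = unname(model$stack_energies),
       hairpin = model$hairpin_by_length,
       bulge = model$bulge_by_length,
       internal = model$internal_by_length,
       multi = unname(model$multiloop_affine),
       term_au = model$terminal_au,
       use_term_au = identical(model$dangle_mode, "simplified"),
       min_hp = model$min_hairpin_unpaired,
       max_iloop = model$max_internal_loop)
}

#' Boltzmann weight of a single loop
#'
#' Returns `exp(-dG / (R T))` for one loop under the model. Hairpins with
#' fewer than `min_hairpin_unpaired` unpaired bases, and internal/bulge
#' loops larger than the model cap, have weight 0.
#'
#' @param model An `energy_model`.
#' @param type One of `"hairpin"`, `"stack"`, `"bulge"`, `"internal"`,
#'   `"multi"`, `"exterior_branch"`, `"multi_branch"`, `"multi_unpaired"`.
#' @param length Loop length (hairpin) or total size `l1 + l2`
#'   (bulge/internal).
#' @param closing,inner Pair types (for `"stack"` and the branch penalties).
#' @param branches,unpaired Multiloop branch count (including the closing
#'   pair) and unpaired base count, for `type = "multi"`.
#' @return A single non-negative finite weight.
#' @export
loop_weight <- function(model, type, length = NULL, closing = NULL,
                        inner = NULL, branches = NULL, unpaired = NULL) {
  kT <- model$gas_constant * model$temperature
  w <- function(dg) if (is.finite(dg)) exp(-dg / kT) else 0
  lookup <- function(tab, len, min_len) {
    if (len < min_len) return(Inf)
    m <- length(tab) - 1L
    if (len <= m) tab[len + 1L]
    else tab[m + 1L] + 1.75 * kT * log(len / m)
  }
  term_pen <- function(pt) {
    if (identical(model$dangle_mode, "simplified") && !(pt %in% c("CG", "GC")))
      model$terminal_au else 0
  }
  switch(type,
    hairpin = w(lookup(model$hairpin_by_length, length,
                       model$min_hairpin_unpaired)),
    stack = w(model$stack_energies[closing, inner]),
    bulge = {
      if (length > model$max_internal_loop) 0
      else w(lookup(model$bulge_by_length, length, 1L))
    },
    internal = {
      if (length > model$max_internal_loop) 0
      else w(lookup(model$internal_by_length, length, 2L))
    },
    multi = w(model$multiloop_affine[["closing"]] +
              model$multiloop_affine[["branch"]] * branches +
              model$multiloop_affine[["unpaired"]] * unpaired),
    exterior_branch = w(term_pen(closing)),
    multi_branch = w(model$multiloop_affine[["branch"]] + term_pen(closing)),
    multi_unpaired = w(model$multiloop_affine[["unpaired"]]),
    sf_input_error("unknown loop type '%s'", type))
}
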