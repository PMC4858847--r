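#' Segment bounds for K-way division
#'
#' Equal tiles of `ceiling(N / K)` positions with the remainder in the last
#' tile; empty trailing tiles (possible when `K` is close to `N`) are
#' dropped.
#'
#' @param N Sequence length.
#' @param K Number of jobs.
#' @return Data frame with columns `job`, `s`, `e`: segment `(s, e]` in gap
#'   coordinates, tiling `0..N`.
#' @export
segment_bounds <- function(N, K) {
  if (K < 1L || K > N) sf_input_error("K must satisfy 1 <= K <= N")
  tile <- ceiling(N / K)
  s <- seq(0L, by = tile, length.out = K)
  e <- pmin(s + tile, N)
  keep <- s < N
  data.frame(job = seq_len(sum(keep)), s = s[keep], e = e[keep])
}

segment_file_name <- function(job, K, s, e, digest) {
  sprintf("segment_%03d_of_%03d_%d_%d_%s.tsv", job, K, s, e, digest)
}

#' Divide: compute and persist per-segment partial tables
#'
#' Each job is computed independently of all others from its segment plus at
#' most `W` residues of context on each side, and persisted as a TSV of the
#' partial inside ratios `d-alpha^h_k` (with `d-alpha^0_k = 1` by
#' definition) and the segment-local fold changes, plus the mirrored beta
#' partials. Re-running a single job (`jobs` argument) reproduces its file
#' byte-for-byte.
#'
#' @inheritParams potential_outermost_pairs
#' @param K Total number of jobs.
#' @param dir Output directory for segment files.
#' @param jobs Which job indices to (re)compute; default all.
#' @param low_disk If `TRUE`, persist only the last `W + 1` positions of the
#'   alpha partials (and the first `W + 1` of the beta partials), reducing
#'   disk from O(N W) to O(N + K W^2); [connect_low_disk()] then recomputes
#'   the full tables in memory during the merge.
#' @return Invisibly, the written file paths.
#' @export
divide <- function(seq, W, K, model = energy_model(), dir = ".",
                   jobs = NULL, low_disk = FALSE) {
  seq <- as_rna_sequence(seq)
  bounds <- segment_bounds(seq$n, K)
  if (is.null(jobs)) jobs <- bounds$job
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sd <- seq_digest(seq)
  paths <- character(0)
  for (job in jobs) {
    b <- bounds[bounds$job == job, ]
    if (nrow(b) != 1L) sf_input_error("no such job index: %d", job)
    tab <- cpp_segment_table(seq$codes, as.integer(W), as_cpp_model(model),
                             b$s, b$e)
    meta <- list(job = job, K = nrow(bounds), s = b$s, e = b$e, N = seq$n,
                 W = as.integer(W), H = tab$H, Hb = tab$Hb,
                 low_disk = as.integer(low_disk),
                 seq_digest = sd, model_digest = model$digest)
    path <- file.path(dir, segment_file_name(job, nrow(bounds), b$s, b$e, sd))
    write_segment_file(tab, meta, path, low_disk = low_disk)
    paths <- c(paths, path)
  }
  invisible(paths)
}

fmt17 <- function(x) {
  out <- format(x, digits = 17, trim = TRUE, scientific = TRUE)
  out[is.na(x)] <- "NA"
  out
}

write_segment_file <- function(tab, meta, path, low_disk = FALSE) {
  s <- meta$s; e <- meta$e; len <- e - s
  W <- meta$W
  ks <- s:e
  Ra <- c(NA_real_, tab$log_Ra)            # defined for k = s+1..e
  Rb <- c(tab$log_Rb, NA_real_)            # defined for k = s..e-1
  da <- cbind(matrix(NA_real_, nrow = max(tab$H, 0L), ncol = 1L), tab$da)
  db <- cbind(tab$db, matrix(NA_real_, nrow = max(tab$Hb, 0L), ncol = 1L))
  keep <- rep(TRUE, len + 1L)
  if (low_disk) keep <- (ks >= e - W) | (ks <= s + W)
  header <- c("# spanfold segment table",
              sprintf(paste0("# job=%d K=%d s=%d e=%d N=%d W=%d H=%d Hb=%d ",
                             "low_disk=%d seq_digest=%s model_digest=%s"),
                      meta$job, meta$K, s, e, meta$N, W, meta$H, meta$Hb,
                      as.integer(low_disk), meta$seq_digest,
                      meta$model_digest))
  cols <- c("k", "log_Ra", "log_Rb",
            if (meta$H > 0L) paste0("da_", seq_len(meta$H)),
            if (meta$Hb > 0L) paste0("db_", seq_len(meta$Hb)))
  body <- cbind(ks, Ra, Rb,
                if (meta$H > 0L) t(da) else NULL,
                if (meta$Hb > 0L) t(db) else NULL)[keep, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(cols, collapse = "\t"), con)
  writeLines(apply(body, 1L, function(r)
    paste(c(sprintf("%d", r[1]), fmt17(r[-1])), collapse = "\t")), con)
  invisible(path)
}

read_segment_file <- function(path) {
  if (!file.exists(path)) sf_integrity_error("missing segment file: %s", path)
  hdr <- readLines(path, n = 2L)
  m <- regmatches(hdr[2], regexec(
    paste0("# job=(\\d+) K=(\\d+) s=(\\d+) e=(\\d+) N=(\\d+) W=(\\d+) ",
           "H=(\\d+) Hb=(\\d+) low_disk=(\\d+) seq_digest=(\\w+) ",
           "model_digest=(\\w+)"), hdr[2]))[[1]]
  if (length(m) != 12L) sf_integrity_error("malformed segment header: %s", path)
  meta <- list(job = as.integer(m[2]), K = as.integer(m[3]),
               s = as.integer(m[4]), e = as.integer(m[5]),
               N = as.integer(m[6]), W = as.integer(m[7]),
               H = as.integer(m[8]), Hb = as.integer(m[9]),
               low_disk = as.integer(m[10]),
               seq_digest = m[11], model_digest = m[12])
  body <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", check.names = FALSE)
  list(meta = meta, body = body)
}

segment_tab_from_body <- function(meta, body) {
  s <- meta$s; e <- meta$e; len <- e - s
  stopifnot(nrow(body) == len + 1L, all(body$k == s:e))
  da <- if (meta$H > 0L)
    t(as.matrix(body[-1L, paste0("da_", seq_len(meta$H)), drop = FALSE]))
  else matrix(0, 0L, len)
  db <- if (meta$Hb > 0L)
    t(as.matrix(body[-(len + 1L), paste0("db_", seq_len(meta$Hb)),
                     drop = FALSE]))
  else matrix(0, 0L, len)
  dimnames(da) <- NULL; dimnames(db) <- NULL
  list(s = s, e = e, H = meta$H, Hb = meta$Hb,
       log_Ra = body$log_Ra[-1L], da = da,
       log_Rb = body$log_Rb[-(len + 1L)], db = db)
}

collect_segment_files <- function(x) {
  files <- if (length(x) == 1L && dir.exists(x))
    list.files(x, pattern = "^segment_.*\\.tsv$", full.names = TRUE)
  else x
  if (length(files) == 0L) sf_integrity_error("no segment files found")
  files
}

validate_segments <- function(parts, seq, W, model) {
  metas <- lapply(parts, `[[`, "meta")
  sd <- seq_digest(seq)
  for (mt in metas) {
    if (mt$seq_digest != sd)
      sf_integrity_error("segment file does not match the sequence")
    if (mt$model_digest != model$digest)
      sf_integrity_error("segment file does not match the energy model")
    if (mt$N != seq$n || mt$W != W)
      sf_integrity_error("segment file N/W mismatch")
  }
  ord <- order(vapply(metas, `[[`, 0L, "s"))
  parts <- parts[ord]
  ss <- vapply(parts, function(p) p$meta$s, 0L)
  ee <- vapply(parts, function(p) p$meta$e, 0L)
  if (ss[1] != 0L || ee[length(ee)] != seq$n ||
      (length(ss) > 1L && any(ss[-1L] != ee[-length(ee)])))
    sf_integrity_error("segment files do not tile the sequence")
  parts
}

#' Connect: merge segment tables into the exact ratio database
#'
#' Recovers `alpha_Outer(k) = sum_h alpha_Outer(s - h) alpha^h_k` across
#' segment boundaries, carried entirely in scale-free ratio form, producing
#' the same `Dalpha`/`Dbeta` as [build_ratios()] on the undivided sequence.
#'
#' @param x A directory containing segment files, or a character vector of
#'   file paths.
#' @inheritParams potential_outermost_pairs
#' @return A `ratio_db`.
#' @export
connect <- function(x, seq, W, model = energy_model()) {
  seq <- as_rna_sequence(seq)
  parts <- lapply(collect_segment_files(x), read_segment_file)
  parts <- validate_segments(parts, seq, as.integer(W), model)
  if (any(vapply(parts, function(p) p$meta$low_disk, 0L) == 1L))
    sf_integrity_error(
      "low-disk segment files: use connect_low_disk() to merge them")
  tabs <- lapply(parts, function(p) segment_tab_from_body(p$meta, p$body))
  logda <- cpp_connect_alpha(tabs, seq$n)
  logdb <- cpp_connect_beta(tabs, seq$n)
  new_ratio_db(seq, W, model, as.numeric(logda), as.numeric(logdb))
}

#' Low-disk Connect
#'
#' Merges segment jobs written with `divide(low_disk = TRUE)`. Each
#' segment's full partial table is recomputed in memory (the second DP
#' round; twice the construction time) with the identical routine Divide
#' uses, so the merged database is byte-identical to [connect()] on full
#' files. The persisted boundary rows are checked against the
#' recomputation as an integrity guard.
#'
#' @inheritParams connect
#' @return A `ratio_db`.
#' @export
connect_low_disk <- function(x, seq, W, model = energy_model()) {
  seq <- as_rna_sequence(seq)
  W <- as.integer(W)
  parts <- lapply(collect_segment_files(x), read_segment_file)
  parts <- validate_segments(parts, seq, W, model)
  cm <- as_cpp_model(model)
  tabs <- lapply(parts, function(p) {
    tab <- cpp_segment_table(seq$codes, W, cm, p$meta$s, p$meta$e)
    stored_k <- p$body$k
    full_Ra <- c(NA_real_, tab$log_Ra)
    idx <- match(stored_k, p$meta$s:p$meta$e)
    ok <- isTRUE(all.equal(p$body$log_Ra, full_Ra[idx], tolerance = 0,
                           check.attributes = FALSE))
    if (!ok)
      sf_integrity_error("stored boundary rows disagree with recomputation")
    tab
  })
  logda <- cpp_connect_alpha(tabs, seq$n)
  logdb <- cpp_connect_beta(tabs, seq$n)
  new_ratio_db(seq, W, model, as.numeric(logda), as.numeric(logdb))
}
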