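# Session TSV dialect: tab-separated, header row, UTF-8, columns
#   trial, red_side{L,R}, red_pos{1..6}, side_A{L,R}, side_B{L,R},
#   choice_A{own,other}, choice_B{own,other}, reward_A, reward_B,
#   t_rel_A_ms, t_acq_A_ms, t_rel_B_ms, t_acq_B_ms, visible{0,1}
# Missing timestamps are encoded as empty fields.

session_tsv_cols <- c("trial", "red_side", "red_pos", "side_A", "side_B",
                      "choice_A", "choice_B", "reward_A", "reward_B",
                      "t_rel_A_ms", "t_acq_A_ms", "t_rel_B_ms", "t_acq_B_ms",
                      "visible")

#' Read and write sessions in the session TSV dialect
#'
#' `write_session()` emits exactly the tab-separated dialect described in
#' the package (header row, missing timestamps as empty fields);
#' `read_session()` parses it (tolerating CRLF line endings), validates
#' all per-trial invariants via [validate_session()], and fails with the
#' offending row number on malformed input. A write-then-read round trip
#' reproduces the trial table exactly.
#'
#' @param session a `bos_session`.
#' @param path file path.
#' @param agents,species,condition metadata attached by `read_session()`
#'   (the TSV stores trials only).
#' @return `read_session()` returns a `bos_session`; `write_session()`
#'   returns `path` invisibly.
#' @name session_io
NULL

#' @rdname session_io
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "bos_session"))
  tr <- session$trials[, session_tsv_cols]
  lines <- c(paste(session_tsv_cols, collapse = "\t"),
             vapply(seq_len(nrow(tr)), function(i) {
               row <- vapply(session_tsv_cols, function(cl) {
                 v <- tr[[cl]][i]
                 if (is.na(v)) "" else format(v, scientific = FALSE)
               }, character(1))
               paste(row, collapse = "\t")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname session_io
#' @export
read_session <- function(path, agents = c("A", "B"), species = "unknown",
                         condition = "dyadic") {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("session file has no data rows: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, session_tsv_cols))
    stop("unexpected TSV header in ", path, "; expected columns: ",
         paste(session_tsv_cols, collapse = ", "))
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  parse_row <- function(f, rownum) {
    if (length(f) < length(session_tsv_cols))
      f <- c(f, rep("", length(session_tsv_cols) - length(f)))
    if (length(f) != length(session_tsv_cols))
      stop(sprintf("malformed row %d: %d fields (expected %d)",
                   rownum, length(f), length(session_tsv_cols)))
    f
  }
  mat <- t(vapply(seq_along(fields), function(i)
    parse_row(fields[[i]], i), character(length(session_tsv_cols))))
  colnames(mat) <- session_tsv_cols
  num <- function(col) {
    v <- mat[, col]
    out <- suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
    bad <- nzchar(v) & is.na(out)
    if (any(bad)) stop(sprintf("malformed row %d: non-numeric '%s' in %s",
                               which(bad)[1L], v[bad][1L], col))
    out
  }
  trials <- data.frame(
    trial = as.integer(num("trial")),
    red_side = mat[, "red_side"], red_pos = as.integer(num("red_pos")),
    side_A = mat[, "side_A"], side_B = mat[, "side_B"],
    choice_A = mat[, "choice_A"], choice_B = mat[, "choice_B"],
    reward_A = as.integer(num("reward_A")),
    reward_B = as.integer(num("reward_B")),
    t_rel_A_ms = num("t_rel_A_ms"), t_acq_A_ms = num("t_acq_A_ms"),
    t_rel_B_ms = num("t_rel_B_ms"), t_acq_B_ms = num("t_acq_B_ms"),
    visible = as.integer(num("visible")), stringsAsFactors = FALSE)
  bos_session(trials, agents = agents, species = species,
              condition = condition, meta = list(source = path))
}
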