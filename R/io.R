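# File dialects (all plain text):
#   frame ethogram: one label per line, headers `# frame_rate=<Hz>`,
#                   optional `# fly_id=<string>` (plus free-form `# key=value`)
#   bout ethogram:  CSV `action,duration_s,category` with the same headers
#   transition matrix: CSV with `action.category` state labels as row and
#                   column headers

read_header_meta <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", h))[[1L]]
    if (length(kv) == 3L) meta[[kv[2L]]] <- trimws(kv[3L])
  }
  meta
}

#' Read and write frame-ethogram files
#'
#' Plain-text dialect: `# frame_rate=<Hz>` and optional `# fly_id=<id>`
#' header lines followed by one behavior label per line. Round trips are
#' lossless; CRLF and LF files parse identically.
#'
#' @param path File path.
#' @param etho A [frame_ethogram()].
#' @param extra Named character vector of extra `# key=value` headers.
#' @return `read_frame_ethogram` returns a [frame_ethogram()].
#' @export
read_frame_ethogram <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  meta <- read_header_meta(lines)
  if (is.null(meta$frame_rate))
    stop(sprintf("%s: missing '# frame_rate=' header", path))
  body_idx <- which(!grepl("^#", lines) & nzchar(lines))
  labels <- trimws(lines[body_idx])
  bad <- which(!(labels %in% .ALPHABET))
  if (length(bad) > 0L)
    stop(sprintf("%s line %d: unknown label '%s'", path,
                 body_idx[bad[1L]], labels[bad[1L]]))
  frame_ethogram(labels, as.numeric(meta$frame_rate), fly_id = meta$fly_id)
}

#' @rdname read_frame_ethogram
#' @export
write_frame_ethogram <- function(etho, path, extra = NULL) {
  stopifnot(inherits(etho, "frame_ethogram"))
  hdr <- sprintf("# frame_rate=%.10g", etho$frame_rate)
  if (!is.null(etho$fly_id)) hdr <- c(hdr, sprintf("# fly_id=%s", etho$fly_id))
  if (!is.null(extra)) hdr <- c(hdr, sprintf("# %s=%s", names(extra), extra))
  writeLines(c(hdr, etho$labels), path)
  invisible(path)
}

#' Read and write bout-ethogram files
#'
#' CSV dialect with columns `action,duration_s,category` (category blank for
#' unbinned bouts) and the same `# key=value` header convention as frame
#' files.
#'
#' @param path File path.
#' @param etho A [bout_ethogram()].
#' @param extra Named character vector of extra `# key=value` headers.
#' @return `read_bout_ethogram` returns a [bout_ethogram()].
#' @export
read_bout_ethogram <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  meta <- read_header_meta(lines)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) < 1L || body[1L] != "action,duration_s,category")
    stop(sprintf("%s: expected 'action,duration_s,category' header row", path))
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE,
                        colClasses = c("character", "numeric", "integer"))
  fr <- if (is.null(meta$frame_rate)) NA_real_ else as.numeric(meta$frame_rate)
  bout_ethogram(df$action, df$duration_s, df$category,
                frame_rate = fr, fly_id = meta$fly_id)
}

#' @rdname read_bout_ethogram
#' @export
write_bout_ethogram <- function(etho, path, extra = NULL) {
  stopifnot(inherits(etho, "bout_ethogram"))
  hdr <- character(0)
  if (!is.na(etho$frame_rate))
    hdr <- sprintf("# frame_rate=%.10g", etho$frame_rate)
  if (!is.null(etho$fly_id)) hdr <- c(hdr, sprintf("# fly_id=%s", etho$fly_id))
  if (!is.null(extra)) hdr <- c(hdr, sprintf("# %s=%s", names(extra), extra))
  df <- etho$bouts
  body <- c("action,duration_s,category",
            sprintf("%s,%.10g,%s", df$action, df$duration,
                    ifelse(is.na(df$category), "", df$category)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and write transition matrices as labeled CSV
#'
#' State labels (`h.s`, `h.m`, ... or bare actions for one bin) head the rows
#' and columns.
#'
#' @param M A [transition_matrix()].
#' @param path File path.
#' @param actions,n_bins State space used to re-read a matrix (defaults to
#'   the canonical six actions; the bin count is inferred from the labels).
#' @return `read_transition_matrix` returns a [transition_matrix()].
#' @export
write_transition_matrix <- function(M, path) {
  stopifnot(inherits(M, "transition_matrix"))
  utils::write.csv(as.data.frame(M$probs), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_transition_matrix
#' @export
read_transition_matrix <- function(path, actions = grooming_actions(),
                                   n_bins = NULL) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  if (is.null(n_bins)) n_bins <- as.integer(nrow(df) / length(actions))
  space <- build_state_space(actions, n_bins)
  m <- as.matrix(df)
  if (!identical(rownames(m), space$states$label))
    m <- m[space$states$label, space$states$label, drop = FALSE]
  transition_matrix(m, space)
}

#' Write a model score as JSON
#'
#' @param score A `model_score` from [bic_score()].
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_model_score <- function(score, path) {
  jsonlite::write_json(list(loglik = score$log_likelihood, k = score$k,
                            n = score$n, bic = score$bic,
                            convention = score$convention),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
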