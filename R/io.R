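# File-format contracts: JSONL for corpus/tokens/mentions, TSV for
# pairs/assigned, CSV for lexicons/gold, JSON for model/report. All UTF-8;
# a UTF-8 BOM is tolerated on read and never written.

strip_bom <- function(x) {
  if (length(x) && startsWith(x[1], "﻿")) x[1] <- sub("^﻿", "", x[1])
  x
}

read_jsonl <- function(path, required_fields) {
  lines <- strip_bom(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop("malformed JSON in ", path, " line ", i, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    miss <- setdiff(required_fields, names(rec))
    if (length(miss)) {
      stop(path, " line ", i, ": missing field(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    out[[i]] <- rec
  }
  out
}

write_jsonl <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in records) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Read a message corpus from JSON lines
#'
#' One JSON object per line with fields `message_id`, `text`, `source` and
#' optionally `date`. Message ids must be unique; texts must be non-empty
#' after stripping whitespace (empty token sequences are still legal later:
#' the constraint is on the raw record).
#'
#' @param path Path to a `.jsonl` file.
#' @return Data.frame with columns message_id, text, source, date.
#' @export
read_corpus_jsonl <- function(path) {
  recs <- read_jsonl(path, c("message_id", "text", "source"))
  df <- data.frame(
    message_id = vapply(recs, function(r) as.character(r$message_id), character(1)),
    text = vapply(recs, function(r) as.character(r$text), character(1)),
    source = vapply(recs, function(r) as.character(r$source), character(1)),
    date = vapply(recs, function(r)
      if (is.null(r$date)) NA_character_ else as.character(r$date), character(1)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(df$message_id)) {
    stop(path, ": duplicate message_id ",
         df$message_id[duplicated(df$message_id)][1], call. = FALSE)
  }
  if (any(trimws(df$text) == "")) {
    stop(path, ": empty text for message ",
         df$message_id[trimws(df$text) == ""][1], call. = FALSE)
  }
  df
}

#' Write a message corpus as JSON lines
#' @param corpus Data.frame with message_id, text, source, date.
#' @param path Output path.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  write_jsonl(lapply(seq_len(nrow(corpus)), function(i) {
    r <- as.list(corpus[i, c("message_id", "text", "source", "date")])
    if (is.na(r$date)) r$date <- NULL
    r
  }), path)
}

#' Write per-message token sequences as JSON lines
#' @param token_seqs Named list of `token_seq` objects.
#' @param path Output path.
#' @export
write_tokens_jsonl <- function(token_seqs, path) {
  write_jsonl(lapply(names(token_seqs), function(id) {
    list(message_id = id, tokens = as.list(token_seqs[[id]]$tokens))
  }), path)
}

#' Read per-message token sequences from JSON lines
#' @param path Input path.
#' @return Named list of `token_seq` objects.
#' @export
read_tokens_jsonl <- function(path) {
  recs <- read_jsonl(path, c("message_id", "tokens"))
  out <- lapply(recs, function(r) {
    toks <- as.character(unlist(r$tokens))
    structure(list(tokens = toks, positions = seq_along(toks)),
              class = "token_seq")
  })
  names(out) <- vapply(recs, function(r) as.character(r$message_id), character(1))
  out
}

#' Write mentions as JSON lines
#' @param mentions Mention data.frame ([recognize_entities()]).
#' @param path Output path.
#' @export
write_mentions_jsonl <- function(mentions, path) {
  write_jsonl(lapply(seq_len(nrow(mentions)), function(i) {
    r <- as.list(mentions[i, ])
    r[vapply(r, function(v) length(v) == 1L && is.na(v), logical(1))] <- NULL
    r
  }), path)
}

read_tabular <- function(path, required, sep) {
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", fileEncoding = "UTF-8-BOM",
                          check.names = FALSE, comment.char = "")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

pairs_tsv_columns <- c("message_id", "drug_id", "drug_name", "llt_id",
                       "llt_label", "pt_id", "pt_label", "disorder_pos",
                       "drug_pos", "relative_position", "distance",
                       "message_length")

#' Write the pair table as TSV
#' @param pairs Pair data.frame ([corpus_pairs()]); an optional `cluster`
#'   column is written when present.
#' @param path Output path.
#' @export
write_pairs_tsv <- function(pairs, path) {
  cols <- c(pairs_tsv_columns, intersect("cluster", names(pairs)))
  utils::write.table(pairs[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a pair table from TSV
#' @param path Input path.
#' @return Pair data.frame with integer position/distance columns.
#' @export
read_pairs_tsv <- function(path) {
  df <- read_tabular(path, pairs_tsv_columns, sep = "\t")
  for (col in c("disorder_pos", "drug_pos", "distance", "message_length", "cluster")) {
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  }
  df
}

#' Read gold annotations from CSV
#'
#' Columns: `message_id, llt_id, start_pos, label` with label ADR or OTHER.
#' @param path Input path.
#' @return Data.frame with integer `start_pos`.
#' @export
read_gold_csv <- function(path) {
  df <- read_tabular(path, c("message_id", "llt_id", "start_pos", "label"),
                     sep = ",")
  df$start_pos <- as.integer(df$start_pos)
  bad <- !toupper(df$label) %in% c("ADR", "OTHER")
  if (any(bad)) {
    stop(path, ": invalid label '", df$label[bad][1], "' (expected ADR/OTHER)",
         call. = FALSE)
  }
  df$label <- toupper(df$label)
  df
}

#' Write gold annotations to CSV
#' @param gold Data.frame with message_id, llt_id, start_pos, label.
#' @param path Output path.
#' @export
write_gold_csv <- function(gold, path) {
  utils::write.csv(gold, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a fitted mixture model to JSON
#' @param fit An `adr_mixture_fit` or `adr_mixture`.
#' @param path Output path.
#' @export
write_model_json <- function(fit, path) {
  if (inherits(fit, "adr_mixture")) {
    model <- fit
    extra <- list()
  } else {
    model <- fit$model
    extra <- list(loglik = fit$loglik_trace[length(fit$loglik_trace)],
                  n_iter = fit$n_iter, converged = fit$converged)
  }
  obj <- c(list(K = model$K, weights = model$weights, means = model$means,
                sds = model$sds), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mixture model from JSON
#' @param path Input path.
#' @return An `adr_mixture`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  mixture_model(obj$weights, obj$means, obj$sds)
}

#' Write a filter report to JSON
#' @param report A `filter_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "string")
  invisible(path)
}
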