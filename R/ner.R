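empty_mentions <- function() {
  data.frame(message_id = character(0), kind = character(0),
             surface = character(0), canonical_id = character(0),
             label = character(0), pt_id = character(0),
             pt_label = character(0), start_pos = integer(0),
             span_len = integer(0), stringsAsFactors = FALSE)
}

# Greedy left-to-right longest-match dictionary matcher over non-consumed
# tokens. At each free position, spans of length max_term_length down to 1
# are tried; the first (longest) hit wins and its tokens are consumed.
match_spans <- function(tokens, index, consumed, kind, message_id) {
  n <- length(tokens)
  out <- list()
  if (n == 0L || index$max_term_length == 0L) {
    return(list(mentions = empty_mentions(), consumed = consumed))
  }
  keys <- index$keyfun(tokens)
  pos <- 1L
  while (pos <= n) {
    if (consumed[pos]) { pos <- pos + 1L; next }
    hit_len <- 0L
    hit <- NULL
    for (len in seq(min(index$max_term_length, n - pos + 1L), 1L)) {
      span <- pos:(pos + len - 1L)
      if (any(consumed[span])) next
      cand <- index_lookup(index, keys[span])
      if (nrow(cand)) {
        if (length(unique(cand[[index$id_col]])) > 1L) {
          warning("ambiguous ", kind, " match at position ", pos,
                  " in message ", message_id, ": candidates ",
                  paste(unique(cand[[index$id_col]]), collapse = ","),
                  "; keeping smallest id", call. = FALSE)
        }
        hit <- cand[1L, , drop = FALSE]  # entries pre-sorted by id
        hit_len <- len
        break
      }
    }
    if (hit_len > 0L) {
      span <- pos:(pos + hit_len - 1L)
      consumed[span] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        message_id = message_id, kind = kind,
        surface = paste(tokens[span], collapse = " "),
        canonical_id = hit[[index$id_col]],
        label = if (kind == "disorder") hit$llt_label else hit$drug_name,
        pt_id = if (kind == "disorder") hit$pt_id else NA_character_,
        pt_label = if (kind == "disorder") hit$pt_label else NA_character_,
        start_pos = pos, span_len = hit_len, stringsAsFactors = FALSE)
      pos <- pos + hit_len
    } else {
      pos <- pos + 1L
    }
  }
  mentions <- if (length(out)) do.call(rbind, out) else empty_mentions()
  list(mentions = mentions, consumed = consumed)
}

#' Recognize drug mentions in a token sequence
#'
#' Fuzzy dictionary matching: a token span matches a drug name when the
#' fuzzy keys of the stemmed tokens are equal, so common misspellings
#' (doubled consonants, dropped vowels after the first) still match. Greedy
#' left-to-right, longest span first; matched tokens are consumed.
#'
#' @param tokens A `token_seq` or character vector of tokens.
#' @param drug_index `match_index` built in `"fuzzy"` mode from a drug list.
#' @param message_id Message identifier recorded on each mention.
#' @return Data.frame of mentions (`kind == "drug"`).
#' @export
match_drugs <- function(tokens, drug_index, message_id = "msg") {
  if (inherits(tokens, "token_seq")) tokens <- tokens$tokens
  res <- match_spans(tokens, drug_index, logical(length(tokens)),
                     "drug", message_id)
  res$mentions
}

#' Recognize disorder mentions in a token sequence
#'
#' Exact dictionary matching after stemming of both the message tokens and
#' the lexicon terms. Positions already consumed by drug mentions are masked
#' out, so a drug name can never double as (part of) a disorder term. Greedy
#' left-to-right longest match: nested shorter terms are suppressed by the
#' containing longer term.
#'
#' @param tokens A `token_seq` or character vector of tokens.
#' @param disorder_index `match_index` built in `"exact-stemmed"` mode.
#' @param consumed Logical vector marking positions consumed by drug matches.
#' @param message_id Message identifier recorded on each mention.
#' @return Data.frame of mentions (`kind == "disorder"`).
#' @export
match_disorders <- function(tokens, disorder_index,
                            consumed = NULL, message_id = "msg") {
  if (inherits(tokens, "token_seq")) tokens <- tokens$tokens
  if (is.null(consumed)) consumed <- logical(length(tokens))
  stopifnot(length(consumed) == length(tokens))
  res <- match_spans(tokens, disorder_index, consumed, "disorder", message_id)
  res$mentions
}

#' Recognize all drug and disorder mentions in one message
#'
#' Drugs are matched first (fuzzy mode) and their tokens masked, then
#' disorders (exact-after-stemming mode) over the remaining tokens.
#'
#' @param tokens A `token_seq` or character vector of tokens.
#' @param drug_index,disorder_index Match indexes from [build_index()].
#' @param message_id Message identifier recorded on each mention.
#' @return Data.frame of mentions, drugs then disorders, in token order.
#' @export
recognize_entities <- function(tokens, drug_index, disorder_index,
                               message_id = "msg") {
  if (inherits(tokens, "token_seq")) tokens <- tokens$tokens
  drug_res <- match_spans(tokens, drug_index, logical(length(tokens)),
                          "drug", message_id)
  dis <- match_disorders(tokens, disorder_index, drug_res$consumed, message_id)
  rbind(drug_res$mentions, dis)
}
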