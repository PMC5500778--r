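#' Insert whitespace around every punctuation character
#'
#' Pads each punctuation character with a space on both sides so that
#' punctuation marks become standalone tokens after whitespace splitting.
#' Punctuation is defined as any character in the Unicode punctuation
#' categories (Pc, Pd, Ps, Pe, Pi, Pf, Po) plus a configurable set of ASCII
#' symbol characters that forum users employ as punctuation. Letters
#' (including accented letters) and digits are never touched.
#'
#' Apostrophes inside French elisions (e.g. "l'insuline") are separated like
#' any other punctuation mark; this is deliberate and fixed, because token
#' counts feed directly into word distances downstream.
#'
#' @param text Character vector of raw UTF-8 strings.
#' @param extra_symbols A single string of additional (non-category-P)
#'   characters to treat as punctuation. The default covers the ASCII symbol
#'   characters `$ + < = > ^ \` | ~` which fall in Unicode symbol categories.
#' @return Character vector with punctuation padded by spaces. Idempotent
#'   after the first application.
#' @examples
#' separate_punctuation("aspirin,then")   # "aspirin , then"
#' separate_punctuation("j'ai mal!!")     # "j ' ai mal ! !"
#' @export
separate_punctuation <- function(text, extra_symbols = "$+<=>^`|~") {
  stopifnot(is.character(text))
  class_extra <- gsub("([\\^\\]\\\\-])", "\\\\\\1", extra_symbols)
  pattern <- paste0("([\\p{P}", class_extra, "])")
  out <- gsub(pattern, " \\1 ", text, perl = TRUE)
  # collapse the space runs this padding creates, so repeated application
  # is a no-op (leading/trailing whitespace is normalize_text's job)
  gsub("  +", " ", out, perl = TRUE)
}

#' Lowercase text and collapse whitespace
#'
#' Unicode-aware lowercasing (accents preserved, never transliterated),
#' followed by collapsing every run of whitespace to a single space and
#' stripping leading/trailing whitespace. Idempotent.
#'
#' @param text Character vector.
#' @return Normalized character vector.
#' @examples
#' normalize_text("  Zolpidem   DOSE ")  # "zolpidem dose"
#' @export
normalize_text <- function(text) {
  stopifnot(is.character(text))
  out <- tolower(text)
  out <- gsub("\\s+", " ", out, perl = TRUE)
  trimws(out)
}

#' Tokenize normalized text into positioned words
#'
#' Splits on whitespace. A word is any maximal run of non-whitespace
#' characters, so punctuation marks separated by [separate_punctuation()]
#' count as words: distances downstream are expressed in these token units.
#' Stop words are never removed, since removing them would distort the
#' word-distance distribution.
#'
#' @param text A single normalized string (already passed through
#'   [separate_punctuation()] and [normalize_text()]).
#' @return A `token_seq`: list with `tokens` (character vector) and
#'   `positions` (1-based integer vector `1..n`). Empty text gives a
#'   zero-length sequence.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || text == "") {
    return(structure(list(tokens = character(0), positions = integer(0)),
                     class = "token_seq"))
  }
  tokens <- strsplit(text, " ", fixed = TRUE)[[1L]]
  tokens <- tokens[tokens != ""]
  structure(list(tokens = tokens, positions = seq_along(tokens)),
            class = "token_seq")
}

#' Full text preprocessing: punctuation separation, normalization, tokenization
#'
#' Convenience composition applied to each message before entity recognition.
#'
#' @param text Character vector of raw message texts.
#' @return A list of `token_seq` objects, one per input element.
#' @export
preprocess_text <- function(text) {
  lapply(normalize_text(separate_punctuation(text)), tokenize)
}

#' @export
print.token_seq <- function(x, ...) {
  cat(sprintf("<token_seq: %d tokens>\n", length(x$tokens)))
  if (length(x$tokens)) {
    show <- utils::head(x$tokens, 20L)
    cat(" ", paste(show, collapse = " "),
        if (length(x$tokens) > 20L) "..." else "", "\n")
  }
  invisible(x)
}
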