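#' Fold accented Latin characters to their base letters
#'
#' Deterministic character mapping (no locale or iconv dependence) covering
#' the accented letters found in French forum text. Used by [fuzzy_key()]
#' so that, e.g., an accented vowel counts as a vowel.
#'
#' @param x Character vector.
#' @return Character vector with accents removed.
#' @export
fold_accents <- function(x) {
  from <- "àâäáãåçèéêëìíîïñòóôöõùúûüýÿÀÂÄÉÈÊËÎÏÔÖÙÛÜÇ"
  to   <- "aaaaaaceeeeiiiinoooooouuuuyyAAAEEEEIIOOUUUC"
  x <- chartr(from, to, x)
  x <- gsub("œ", "oe", x, fixed = TRUE)
  gsub("æ", "ae", x, fixed = TRUE)
}

#' Fuzzy grouping key for misspelling conflation
#'
#' Canonical key that conflates commonly misspelled or closely spelled words:
#' accents are folded to base letters, every vowel after the first vowel
#' occurrence is removed, then runs of two or three identical consecutive
#' consonants are collapsed to one. Words differing only by a doubled
#' consonant or by vowels after the first share a key, e.g. "modeling" and
#' "modelling" both map to "modlng".
#'
#' The order of operations (vowels stripped first, then consonant runs
#' collapsed) is fixed for determinism. Vowels are `a e i o u y`.
#'
#' @param word Character vector of single normalized tokens.
#' @return Character vector of keys; empty tokens give empty keys.
#' @examples
#' fuzzy_key("modelling") == fuzzy_key("modeling")  # TRUE
#' fuzzy_key("headache")                            # "hedch"
#' @export
fuzzy_key <- function(word) {
  stopifnot(is.character(word))
  vapply(word, function(w) {
    if (is.na(w) || w == "") return("")
    w <- fold_accents(tolower(w))
    chars <- strsplit(w, "", fixed = TRUE)[[1L]]
    is_vowel <- chars %in% c("a", "e", "i", "o", "u", "y")
    first_v <- which(is_vowel)[1L]
    if (!is.na(first_v)) {
      drop <- is_vowel
      drop[first_v] <- FALSE
      chars <- chars[!drop]
    }
    w <- paste(chars, collapse = "")
    gsub("([^aeiouy])\\1{1,2}", "\\1", w, perl = TRUE)
  }, character(1), USE.NAMES = FALSE)
}

#' Light French stemmer (Porter family)
#'
#' Suffix stripper in the Porter/Savoy family for French: strips plural and
#' feminine inflection (`-x`/`-aux`, `-s`, `-r`, `-e`, `-e-acute`) and a
#' trailing doubled letter from words of six or more characters, iterated to
#' a fixed point so the stemmer is idempotent. Words shorter than six
#' characters pass through unchanged. This intentionally light normalization
#' conflates singular/plural and masculine/feminine surface variants
#' ("maladie"/"maladies", "insomnie"/"insomnies") without the aggressive
#' derivational stripping of a full stemmer.
#'
#' The stemmer is pluggable everywhere it is used ([build_index()],
#' [recognize_entities()]): any deterministic `function(character) character`
#' can be substituted.
#'
#' @param word Character vector of single normalized tokens.
#' @return Character vector of stems.
#' @export
french_light_stem <- function(word) {
  stopifnot(is.character(word))
  step <- function(w) {
    n <- nchar(w)
    if (is.na(w) || n < 6L) return(w)
    chars <- strsplit(w, "", fixed = TRUE)[[1L]]
    if (chars[n] == "x") {
      if (chars[n - 2L] == "a" && chars[n - 1L] == "u") chars[n - 1L] <- "l"
      return(paste(chars[-n], collapse = ""))
    }
    if (chars[n] == "s") { chars <- chars[-n]; n <- n - 1L }
    if (chars[n] == "r") { chars <- chars[-n]; n <- n - 1L }
    if (chars[n] == "e") { chars <- chars[-n]; n <- n - 1L }
    if (chars[n] == "é") { chars <- chars[-n]; n <- n - 1L }
    if (n >= 2L && chars[n] == chars[n - 1L]) { chars <- chars[-n]; n <- n - 1L }
    paste(chars, collapse = "")
  }
  vapply(word, function(w) {
    if (is.na(w)) return(NA_character_)
    for (i in 1:10) {
      w2 <- step(w)
      if (identical(w2, w)) break
      w <- w2
    }
    w
  }, character(1), USE.NAMES = FALSE)
}

norm_term <- function(x) normalize_text(separate_punctuation(x))

#' Load a disorder lexicon (MedDRA-style LLT/PT/SOC table)
#'
#' Reads a UTF-8 CSV with columns `surface_term, llt_id, llt_label, pt_id,
#' pt_label, soc_label`. Surface terms are normalized exactly as message text
#' is (punctuation separation + lowercasing), so multi-word terms match the
#' tokenization of the messages. Duplicate rows mapping the same surface term
#' to the same LLT are deduplicated; the same surface term mapping to two
#' different LLTs is a fatal ambiguity. The LLT-to-PT and PT-to-SOC linkage
#' must be functional (each LLT under exactly one PT, each PT under exactly
#' one SOC).
#'
#' @param path Path to the CSV file.
#' @return A data.frame of lexicon entries, sorted by `llt_id` then surface
#'   term, with normalized `surface_term`.
#' @export
load_disorder_lexicon <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8-BOM")
  required <- c("surface_term", "llt_id", "llt_label", "pt_id", "pt_label", "soc_label")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("disorder lexicon ", path, ": missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$surface_term <- norm_term(df$surface_term)
  if (any(df$surface_term == "")) {
    stop("disorder lexicon ", path, ": empty surface_term", call. = FALSE)
  }
  df <- unique(df[required])
  amb <- stats::aggregate(llt_id ~ surface_term, df,
                          function(z) length(unique(z)))
  bad <- amb$surface_term[amb$llt_id > 1L]
  if (length(bad)) {
    rows <- df[df$surface_term %in% bad, c("surface_term", "llt_id")]
    stop("disorder lexicon ", path, ": surface term(s) mapped to multiple LLTs: ",
         paste(sprintf("'%s' -> {%s}", unique(rows$surface_term),
                       vapply(unique(rows$surface_term), function(s)
                         paste(sort(rows$llt_id[rows$surface_term == s]),
                               collapse = ","), character(1))),
               collapse = "; "), call. = FALSE)
  }
  for (spec in list(c("llt_id", "pt_id"), c("pt_id", "soc_label"))) {
    chk <- stats::aggregate(stats::as.formula(paste(spec[2], "~", spec[1])),
                            df, function(z) length(unique(z)))
    if (any(chk[[2]] > 1L)) {
      stop("disorder lexicon ", path, ": ", spec[1], " '",
           paste(chk[[1]][chk[[2]] > 1L], collapse = "','"),
           "' linked to multiple ", spec[2], " values", call. = FALSE)
    }
  }
  df <- df[order(df$llt_id, df$surface_term), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Load a drug-name list
#'
#' Reads a UTF-8 CSV with columns `drug_name, drug_id`. Names are normalized
#' as message text is.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with normalized `drug_name`, sorted by `drug_id`.
#' @export
load_drug_list <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8-BOM")
  missing <- setdiff(c("drug_name", "drug_id"), names(df))
  if (length(missing)) {
    stop("drug list ", path, ": missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$drug_name <- norm_term(df$drug_name)
  if (any(df$drug_name == "")) stop("drug list ", path, ": empty drug_name", call. = FALSE)
  df <- unique(df[c("drug_name", "drug_id")])
  df <- df[order(df$drug_id, df$drug_name), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build a token-level match index over lexicon entries
#'
#' Keys each entry by the tuple of its per-token canonical forms: per-token
#' stems in `"exact-stemmed"` mode (used for disorder matching) or fuzzy keys
#' of stems in `"fuzzy"` mode (used for drug matching, where misspelling
#' tolerance matters most). Entries whose key collides are retained as
#' multi-candidate keys; the NER longest-match policy resolves them at match
#' time. Index contents are independent of input row order (entries are
#' sorted by id).
#'
#' @param entries Data.frame from [load_disorder_lexicon()] (column
#'   `surface_term`) or [load_drug_list()] (column `drug_name`).
#' @param mode `"exact-stemmed"` or `"fuzzy"`.
#' @param stemmer Per-token stemming function; default [french_light_stem()].
#' @return A `match_index` object.
#' @export
build_index <- function(entries, mode = c("exact-stemmed", "fuzzy"),
                        stemmer = french_light_stem) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(entries), is.function(stemmer))
  surface_col <- if ("surface_term" %in% names(entries)) "surface_term" else "drug_name"
  id_col <- if (surface_col == "surface_term") "llt_id" else "drug_id"
  if (nrow(entries)) {
    entries <- entries[order(entries[[id_col]], entries[[surface_col]]), , drop = FALSE]
  }
  map <- new.env(parent = emptyenv(), hash = TRUE)
  max_len <- 0L
  keyfun <- function(tok) {
    s <- stemmer(tok)
    if (mode == "fuzzy") fuzzy_key(s) else s
  }
  if (nrow(entries)) {
    for (i in seq_len(nrow(entries))) {
      toks <- strsplit(entries[[surface_col]][i], " ", fixed = TRUE)[[1L]]
      toks <- toks[toks != ""]
      key <- paste(keyfun(toks), collapse = " ")
      max_len <- max(max_len, length(toks))
      cur <- if (exists(key, envir = map, inherits = FALSE)) get(key, envir = map) else integer(0)
      assign(key, c(cur, i), envir = map)
    }
  }
  structure(list(map = map, entries = entries, max_term_length = max_len,
                 mode = mode, keyfun = keyfun,
                 surface_col = surface_col, id_col = id_col),
            class = "match_index")
}

#' Look up a key tuple in a match index
#'
#' @param index A `match_index`.
#' @param key_tokens Character vector of per-token keys (already passed
#'   through the index's key function).
#' @return Data.frame of candidate entries (zero rows on a miss), sorted by id.
#' @export
index_lookup <- function(index, key_tokens) {
  stopifnot(inherits(index, "match_index"))
  key <- paste(key_tokens, collapse = " ")
  if (!exists(key, envir = index$map, inherits = FALSE)) {
    return(index$entries[integer(0), , drop = FALSE])
  }
  index$entries[get(key, envir = index$map), , drop = FALSE]
}

#' @export
print.match_index <- function(x, ...) {
  cat(sprintf("<match_index: %d entries, mode=%s, max term length=%d tokens>\n",
              nrow(x$entries), x$mode, x$max_term_length))
  invisible(x)
}
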