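#' Signed word distance between a drug and a disorder mention
#'
#' Defined as `disorder_pos - drug_pos` on 1-based token positions: negative
#' when the disorder precedes the drug, positive when it follows. Adjacent
#' tokens have distance 1; equal positions are a contract violation (mentions
#' cannot coincide because drug tokens are masked before disorder matching).
#'
#' @param drug_pos,disorder_pos Integer vectors of 1-based token positions
#'   (first token of each mention span).
#' @return Integer vector of signed distances in words.
#' @export
word_distance <- function(drug_pos, disorder_pos) {
  stopifnot(all(drug_pos >= 1L), all(disorder_pos >= 1L))
  if (any(drug_pos == disorder_pos)) {
    stop("drug and disorder mention at identical position: distance undefined",
         call. = FALSE)
  }
  as.integer(disorder_pos) - as.integer(drug_pos)
}

empty_pairs <- function() {
  data.frame(message_id = character(0), drug_id = character(0),
             drug_name = character(0), llt_id = character(0),
             llt_label = character(0), pt_id = character(0),
             pt_label = character(0), disorder_pos = integer(0),
             drug_pos = integer(0), relative_position = character(0),
             distance = integer(0), message_length = integer(0),
             stringsAsFactors = FALSE)
}

#' Enumerate deduplicated (drug, disorder) pairs for one message
#'
#' For every disorder mention and every distinct drug name in the message,
#' the distance to each occurrence of that drug name is evaluated and only
#' the occurrence minimizing the absolute distance is kept. A tie between an
#' equal distance before and after the drug keeps the positive (disorder
#' after drug) candidate. Positions are the first token of each mention span.
#' Messages with drug mentions but no disorder yield zero pairs; messages
#' with no drug mention yield zero pairs and are the caller's to log.
#'
#' @param mentions Data.frame of mentions for a single message, as returned
#'   by [recognize_entities()].
#' @param message_length Total token count of the message.
#' @return Data.frame of pairs, one row per (disorder mention, distinct drug
#'   name), with signed `distance` and `relative_position` ("before" if the
#'   disorder precedes the drug, else "after").
#' @export
enumerate_pairs <- function(mentions, message_length) {
  stopifnot(is.data.frame(mentions), message_length >= 0)
  drugs <- mentions[mentions$kind == "drug", , drop = FALSE]
  disorders <- mentions[mentions$kind == "disorder", , drop = FALSE]
  if (nrow(drugs) == 0L || nrow(disorders) == 0L) return(empty_pairs())
  out <- vector("list", nrow(disorders))
  drug_ids <- sort(unique(drugs$canonical_id))
  k <- 0L
  for (i in seq_len(nrow(disorders))) {
    d <- disorders[i, ]
    for (g in drug_ids) {
      occ <- drugs[drugs$canonical_id == g, , drop = FALSE]
      dist <- word_distance(occ$start_pos, rep(d$start_pos, nrow(occ)))
      # min |distance|; tie between -k and +k keeps the positive candidate
      best <- order(abs(dist), -sign(dist))[1L]
      k <- k + 1L
      out[[k]] <- data.frame(
        message_id = d$message_id, drug_id = g,
        drug_name = occ$label[best], llt_id = d$canonical_id,
        llt_label = d$label, pt_id = d$pt_id, pt_label = d$pt_label,
        disorder_pos = d$start_pos, drug_pos = occ$start_pos[best],
        relative_position = if (dist[best] < 0L) "before" else "after",
        distance = dist[best], message_length = as.integer(message_length),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Build the pair table for a whole corpus
#'
#' Runs entity recognition and pair enumeration per message and stacks the
#' results. Messages containing drugs but no disorder (or no drug) are
#' reported in the `"drug_only"` / `"no_drug"` attributes for corpus
#' bookkeeping.
#'
#' @param token_seqs Named list of `token_seq` objects (names are message ids).
#' @param drug_index,disorder_index Match indexes from [build_index()].
#' @return Data.frame of pairs for the corpus, with attributes `drug_only`
#'   and `no_drug` listing the ids of messages yielding no pairs.
#' @export
corpus_pairs <- function(token_seqs, drug_index, disorder_index) {
  stopifnot(is.list(token_seqs), !is.null(names(token_seqs)))
  res <- vector("list", length(token_seqs))
  drug_only <- character(0)
  no_drug <- character(0)
  for (i in seq_along(token_seqs)) {
    id <- names(token_seqs)[i]
    toks <- token_seqs[[i]]
    m <- recognize_entities(toks, drug_index, disorder_index, message_id = id)
    has_drug <- any(m$kind == "drug")
    has_dis <- any(m$kind == "disorder")
    if (!has_drug) no_drug <- c(no_drug, id)
    if (has_drug && !has_dis) drug_only <- c(drug_only, id)
    res[[i]] <- enumerate_pairs(m, length(toks$tokens))
  }
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) out <- empty_pairs()
  rownames(out) <- NULL
  attr(out, "drug_only") <- drug_only
  attr(out, "no_drug") <- no_drug
  out
}
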