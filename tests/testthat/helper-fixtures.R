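fix_path <- function(f) system.file("extdata", f, package = "adrdist", mustWork = TRUE)

fixture_lexicon <- function() load_disorder_lexicon(fix_path("disorder_lexicon_synthetic.csv"))
fixture_drugs <- function() load_drug_list(fix_path("drugs_synthetic.csv"))
fixture_table1 <- function() read_contingency_csv(fix_path("table1_contingency.csv"))

# draw n points from a univariate Gaussian mixture with known memberships
rmix <- function(n, weights, means, sds) {
  comp <- sample(length(weights), n, replace = TRUE, prob = weights)
  list(x = stats::rnorm(n, means[comp], sds[comp]), comp = comp)
}

# Independent dictionary-matching oracle: enumerate every candidate span,
# then resolve overlaps by longer-span-first, then leftmost. Returns the
# accepted (start, len, row) triples.
oracle_dictionary_match <- function(tokens, index, consumed = NULL) {
  n <- length(tokens)
  if (is.null(consumed)) consumed <- logical(n)
  keys <- index$keyfun(tokens)
  cands <- list()
  for (len in seq_len(min(index$max_term_length, n))) {
    for (start in seq_len(n - len + 1L)) {
      span <- start:(start + len - 1L)
      hit <- index_lookup(index, keys[span])
      if (nrow(hit)) {
        cands[[length(cands) + 1L]] <- list(start = start, len = len,
                                            entry = hit[1L, , drop = FALSE])
      }
    }
  }
  if (!length(cands)) {
    return(data.frame(start = integer(0), len = integer(0)))
  }
  ord <- order(-vapply(cands, `[[`, integer(1), "len"),
               vapply(cands, `[[`, integer(1), "start"))
  taken <- consumed
  out <- list()
  for (c_ in cands[ord]) {
    span <- c_$start:(c_$start + c_$len - 1L)
    if (any(taken[span])) next
    taken[span] <- TRUE
    out[[length(out) + 1L]] <- data.frame(start = c_$start, len = c_$len,
                                          id = c_$entry[[index$id_col]])
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

# Exhaustive minimum-|distance| deduplication oracle for one message:
# for every disorder mention and drug name, scan all drug occurrences.
oracle_min_distance <- function(drug_positions, disorder_pos) {
  d <- disorder_pos - drug_positions
  best <- d[order(abs(d), -sign(d))][1L]
  best
}

# Direct-summation mixture log-likelihood (no log-sum-exp), for small data
oracle_loglik <- function(model, x) {
  sum(log(vapply(x, function(xi)
    sum(model$weights * stats::dnorm(xi, model$means, model$sds)), numeric(1))))
}

make_tokens <- function(words) {
  structure(list(tokens = words, positions = seq_along(words)),
            class = "token_seq")
}
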