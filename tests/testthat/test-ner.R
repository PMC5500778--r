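drug_idx <- build_index(fixture_drugs(), mode = "fuzzy")
dis_idx <- build_index(fixture_lexicon(), mode = "exact-stemmed")

test_that("drug matching finds exact and fuzzily misspelled names", {
  m <- match_drugs(make_tokens(c("i", "took", "zolpidem", "yesterday")), drug_idx)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start_pos, 3L)
  expect_equal(m$canonical_id, "D003")

  # misspelling matches because the fuzzy keys of the stems coincide
  stopifnot(identical(fuzzy_key(french_light_stem("zolpidme")),
                      fuzzy_key(french_light_stem("zolpidem"))))
  m2 <- match_drugs(make_tokens(c("du", "zolpidme", "hier")), drug_idx)
  expect_equal(m2$canonical_id, "D003")

  expect_equal(nrow(match_drugs(make_tokens(character(0)), drug_idx)), 0L)
})

test_that("multi-word drug names match as one span", {
  m <- match_drugs(make_tokens(c("sous", "insuline", "glargine", "depuis")),
                   drug_idx)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start_pos, 2L)
  expect_equal(m$span_len, 2L)
})

test_that("disorder matching is exact-after-stemming with longest match", {
  m <- match_disorders(make_tokens(c("it", "gave", "me", "a", "terrible",
                                     "céphalée")), dis_idx)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start_pos, 6L)
  expect_equal(m$span_len, 1L)

  # inflected surface still matches via stemming
  m2 <- match_disorders(make_tokens(c("des", "vertiges", "traités")), dis_idx)
  expect_equal(m2$canonical_id, "LLT0005")

  # longest match wins over an embedded shorter term
  nested <- rbind(fixture_lexicon(),
                  data.frame(surface_term = "mal", llt_id = "LLT9999",
                             llt_label = "mal", pt_id = "PT9999",
                             pt_label = "malaise", soc_label = "troubles généraux"))
  idx <- build_index(nested, mode = "exact-stemmed")
  m3 <- match_disorders(make_tokens(c("un", "mal", "de", "tête", "hier")), idx)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$canonical_id, "LLT0001")
  expect_equal(m3$span_len, 3L)
})

test_that("tokens consumed by drug matches are masked from disorder matching", {
  # "insuline glargine" consumed as a drug: the lexicon term planted inside
  # its span must not produce a disorder mention
  toks <- make_tokens(c("sous", "insuline", "glargine", "fatigue"))
  out <- recognize_entities(toks, drug_idx, dis_idx, "m")
  expect_equal(out$kind, c("drug", "disorder"))
  expect_equal(out$start_pos, c(2L, 4L))
  # disorder matching with the drug span pre-consumed yields nothing there
  consumed <- c(FALSE, TRUE, TRUE, FALSE)
  m <- match_disorders(make_tokens(c("la", "fatigue", "fatigue", "ici")),
                       dis_idx, consumed = consumed)
  expect_equal(m$start_pos, integer(0))
})

test_that("no two emitted mentions overlap", {
  set.seed(42)
  lex <- fixture_lexicon()
  vocab <- c("je", "suis", "fatigué", "depuis", "des", "jours", "et", "la")
  for (i in 1:20) {
    n <- sample(5:30, 1)
    toks <- sample(vocab, n, replace = TRUE)
    # plant random lexicon terms and a drug
    term <- sample(lex$surface_term, 1)
    tt <- strsplit(term, " ")[[1]]
    at <- sample(seq_len(n - length(tt) + 1), 1)
    toks[at:(at + length(tt) - 1)] <- tt
    m <- recognize_entities(make_tokens(toks), drug_idx, dis_idx, "m")
    if (nrow(m) > 1) {
      spans <- unlist(lapply(seq_len(nrow(m)), function(j)
        m$start_pos[j]:(m$start_pos[j] + m$span_len[j] - 1L)))
      expect_false(any(duplicated(spans)))
    }
  }
})

test_that("greedy matching equals the longer-first-leftmost span oracle", {
  set.seed(99)
  lex <- fixture_lexicon()
  vocab <- c("un", "gros", "souci", "depuis", "peu", "chez", "moi")
  for (i in 1:30) {
    n <- sample(8:30, 1)
    toks <- sample(vocab, n, replace = TRUE)
    for (t in sample(lex$surface_term, sample(1:3, 1))) {
      tt <- strsplit(t, " ")[[1]]
      if (length(tt) > n) next
      at <- sample(seq_len(n - length(tt) + 1), 1)
      toks[at:(at + length(tt) - 1)] <- tt
    }
    got <- match_disorders(make_tokens(toks), dis_idx)
    want <- oracle_dictionary_match(toks, dis_idx)
    expect_equal(got$start_pos, want$start)
    expect_equal(got$span_len, want$len)
    expect_equal(got$canonical_id, want$id)
  }
})

test_that("every fixture lexicon term recognizes its own surface form", {
  lex <- fixture_lexicon()
  for (i in seq_len(nrow(lex))) {
    toks <- c("hier", strsplit(lex$surface_term[i], " ")[[1]], "encore")
    m <- match_disorders(make_tokens(toks), dis_idx)
    expect_true(lex$llt_id[i] %in% m$canonical_id,
                label = paste("self-recognition of", lex$surface_term[i]))
  }
})
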