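test_that("fuzzy key conflates doubled consonants and post-first vowels", {
  expect_identical(fuzzy_key("modeling"), fuzzy_key("modelling"))
  expect_equal(fuzzy_key("headache"), "hedch")
  expect_equal(fuzzy_key("mr"), "mr")
  expect_equal(fuzzy_key(""), "")
  # accents fold before vowel detection: é is the kept first vowel
  expect_identical(fuzzy_key("céphalée"), fuzzy_key("cephalee"))
  # stability: applying the rules to a key leaves it unchanged
  for (w in c("modeling", "insomnie", "vertige", "zolpidem")) {
    expect_identical(fuzzy_key(fuzzy_key(w)), fuzzy_key(w))
  }
})

test_that("light French stemmer conflates inflection and is idempotent", {
  expect_identical(french_light_stem("maladies"), french_light_stem("maladie"))
  expect_identical(french_light_stem("insomnies"), french_light_stem("insomnie"))
  expect_equal(french_light_stem("a"), "a")
  expect_equal(french_light_stem("chevaux"), "cheval")
  words <- c("maladies", "insomnies", "douleurs", "crampes", "vertiges",
             "palpitations", "éruptions", "cutanées", "express")
  for (w in words) {
    s <- french_light_stem(w)
    expect_identical(french_light_stem(s), s)
  }
})

test_that("disorder lexicon loads with normalized multi-word terms and linkage", {
  lex <- fixture_lexicon()
  expect_true(all(c("surface_term", "llt_id", "pt_id", "soc_label") %in% names(lex)))
  # multi-word colloquial synonym: no punctuation, three tokens
  mal <- lex[lex$surface_term == "mal au crâne", ]
  expect_equal(nrow(mal), 1L)
  expect_length(strsplit(mal$surface_term, " ")[[1]], 3L)
  # synonym LLTs group under the same PT
  expect_equal(unique(lex$pt_id[lex$llt_id %in% c("LLT0001", "LLT0002", "LLT0003")]),
               "PT0001")
})

test_that("lexicon format errors are fatal and name the offender", {
  bad1 <- tempfile(fileext = ".csv")
  writeLines(c("surface_term,llt_id,llt_label,pt_id,pt_label",
               "x,L1,x,P1,x"), bad1)
  expect_error(load_disorder_lexicon(bad1), "soc_label")
  bad2 <- tempfile(fileext = ".csv")
  writeLines(c("surface_term,llt_id,llt_label,pt_id,pt_label,soc_label",
               "mal,L1,mal,P1,mal,soc",
               "mal,L2,mal2,P2,mal2,soc"), bad2)
  expect_error(load_disorder_lexicon(bad2), "multiple LLTs")
  bad3 <- tempfile(fileext = ".csv")
  writeLines(c("drug_name,wrong", "zolpidem,1"), bad3)
  expect_error(load_drug_list(bad3), "drug_id")
})

test_that("every loaded entry is reachable under its own key", {
  lex <- fixture_lexicon()
  drugs <- fixture_drugs()
  dis_idx <- build_index(lex, mode = "exact-stemmed")
  drug_idx <- build_index(drugs, mode = "fuzzy")
  for (i in seq_len(nrow(lex))) {
    toks <- strsplit(lex$surface_term[i], " ")[[1]]
    hit <- index_lookup(dis_idx, dis_idx$keyfun(toks))
    expect_true(lex$llt_id[i] %in% hit$llt_id)
  }
  for (i in seq_len(nrow(drugs))) {
    toks <- strsplit(drugs$drug_name[i], " ")[[1]]
    hit <- index_lookup(drug_idx, drug_idx$keyfun(toks))
    expect_true(drugs$drug_id[i] %in% hit$drug_id)
  }
})

test_that("index contents are independent of input row order", {
  lex <- fixture_lexicon()
  set.seed(7)
  shuffled <- lex[sample(nrow(lex)), ]
  i1 <- build_index(lex, mode = "exact-stemmed")
  i2 <- build_index(shuffled, mode = "exact-stemmed")
  keys <- sort(ls(i1$map))
  expect_identical(keys, sort(ls(i2$map)))
  for (k in keys) {
    expect_identical(index_lookup(i1, k)$llt_id, index_lookup(i2, k)$llt_id)
  }
  expect_equal(i1$max_term_length, i2$max_term_length)
})

test_that("empty entry set yields an index where every lookup misses", {
  idx <- build_index(fixture_drugs()[0, ], mode = "fuzzy")
  expect_equal(idx$max_term_length, 0L)
  expect_equal(nrow(index_lookup(idx, "zolpidem")), 0L)
})

test_that("fuzzy drug keys tolerate the misspellings they are built for", {
  # doubled consonant and dropped post-first vowel preserve the fuzzy key
  expect_identical(fuzzy_key(french_light_stem("zolpidemm")),
                   fuzzy_key(french_light_stem("zolpidem")))
  expect_identical(fuzzy_key("zolpidm"), fuzzy_key("zolpidem"))
})
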