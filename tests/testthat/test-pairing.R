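mention_row <- function(kind, id, pos, span = 1L, msg = "m1") {
  data.frame(message_id = msg, kind = kind, surface = id, canonical_id = id,
             label = id, pt_id = if (kind == "disorder") paste0("PT", id) else NA,
             pt_label = NA, start_pos = as.integer(pos),
             span_len = as.integer(span), stringsAsFactors = FALSE)
}

test_that("signed distance is the position difference, disorder minus drug", {
  expect_equal(word_distance(3L, 10L), 7L)
  expect_equal(word_distance(5L, 2L), -3L)
  expect_equal(word_distance(1L, 2L), 1L)
  # antisymmetry
  set.seed(3)
  a <- sample(1:500, 50); b <- sample(501:900, 50)
  expect_equal(word_distance(a, b), -word_distance(b, a))
  expect_error(word_distance(4L, 4L), "identical position")
})

test_that("pair enumeration keeps only the minimum-|distance| drug occurrence", {
  m <- rbind(mention_row("drug", "D1", 3), mention_row("drug", "D1", 40),
             mention_row("disorder", "L1", 10))
  p <- enumerate_pairs(m, 60)
  expect_equal(nrow(p), 1L)
  expect_equal(p$distance, 7L)
  expect_equal(p$drug_pos, 3L)
  expect_equal(p$relative_position, "after")
})

test_that("each disorder mention pairs once per distinct drug name", {
  m <- rbind(mention_row("drug", "D1", 3),
             mention_row("disorder", "L1", 10),
             mention_row("disorder", "L2", 2))
  p <- enumerate_pairs(m, 30)
  expect_equal(nrow(p), 2L)
  expect_setequal(p$distance, c(7L, -1L))
  expect_equal(p$relative_position[p$distance == -1L], "before")

  # two different drugs: the disorder pairs with both
  m2 <- rbind(mention_row("drug", "D1", 3), mention_row("drug", "D2", 20),
              mention_row("disorder", "L1", 10))
  p2 <- enumerate_pairs(m2, 30)
  expect_equal(nrow(p2), 2L)
  expect_setequal(p2$drug_id, c("D1", "D2"))
})

test_that("an absolute-distance tie keeps the disorder-after-drug pair", {
  m <- rbind(mention_row("drug", "D1", 8), mention_row("drug", "D1", 12),
             mention_row("disorder", "L1", 10))
  p <- enumerate_pairs(m, 30)
  expect_equal(p$distance, 2L)
  expect_equal(p$relative_position, "after")
})

test_that("messages lacking either entity kind yield zero pairs", {
  expect_equal(nrow(enumerate_pairs(mention_row("drug", "D1", 3), 10)), 0L)
  expect_equal(nrow(enumerate_pairs(mention_row("disorder", "L1", 3), 10)), 0L)
  expect_equal(nrow(enumerate_pairs(mention_row("drug", "D1", 1)[0, ], 10)), 0L)
})

test_that("deduplication agrees with the exhaustive oracle on random messages", {
  set.seed(11)
  for (i in 1:40) {
    L <- sample(10:50, 1)
    n_occ <- sample(1:4, 1)
    positions <- sample(L, n_occ + 1)
    drug_pos <- positions[-1]
    dis_pos <- positions[1]
    m <- do.call(rbind, c(lapply(drug_pos, function(p) mention_row("drug", "D1", p)),
                          list(mention_row("disorder", "L1", dis_pos))))
    p <- enumerate_pairs(m, L)
    expect_equal(nrow(p), 1L)
    expect_equal(p$distance, oracle_min_distance(drug_pos, dis_pos))
    # minimality: no occurrence is strictly closer
    expect_true(all(abs(p$distance) <= abs(dis_pos - drug_pos)))
    # bounds
    expect_lt(abs(p$distance), L)
    expect_equal(p$relative_position, if (p$distance < 0) "before" else "after")
  }
})

test_that("pair count equals disorder-mention x distinct-drug combinations", {
  set.seed(21)
  for (i in 1:20) {
    L <- 200L
    n_drugs <- sample(1:3, 1)
    n_occ <- sample(1:2, n_drugs, replace = TRUE)
    n_dis <- sample(1:5, 1)
    pos <- sample(L, sum(n_occ) + n_dis)
    rows <- list()
    k <- 0
    for (d in seq_len(n_drugs)) for (j in seq_len(n_occ[d])) {
      k <- k + 1
      rows[[length(rows) + 1]] <- mention_row("drug", paste0("D", d), pos[k])
    }
    for (s in seq_len(n_dis)) {
      k <- k + 1
      rows[[length(rows) + 1]] <- mention_row("disorder", paste0("L", s), pos[k])
    }
    p <- enumerate_pairs(do.call(rbind, rows), L)
    expect_equal(nrow(p), n_dis * n_drugs)
  }
})
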