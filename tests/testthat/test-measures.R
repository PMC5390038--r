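fake_inventory <- function(units, counts) {
  tibble::tibble(
    unit = units,
    length = lengths(strsplit(units, " ", fixed = TRUE)),
    n = as.integer(counts)
  )
}

test_that("count_word_units counts distinct containing types", {
  inv <- fake_inventory(c("a b", "a c", "a"), c(2L, 5L, 9L))
  expect_equal(count_word_units(inv, "a", min_length = 2L)$n_units, 2L)
  expect_equal(count_word_units(inv, "a", min_length = 1L)$n_units, 3L)
  expect_equal(count_word_units(inv, "zzz")$n_units, 0L)
  # a word repeated within one unit counts that unit once
  inv2 <- fake_inventory(c("no no no", "no way"), c(4L, 1L))
  expect_equal(count_word_units(inv2, "no")$n_units, 2L)
  # an inventory with no qualifying units
  expect_equal(count_word_units(fake_inventory("a", 3L), "a")$n_units, 0L)
})

test_that("unit-type counts are monotone in the inventory and min_length", {
  cp <- random_corpus(150L, vocab = 10L, max_len = 5L, seed = 17L)
  inv <- chunk_corpus(cp)
  words <- paste0("v", 1:10)
  n2 <- count_word_units(inv, words, min_length = 2L)$n_units
  n1 <- count_word_units(inv, words, min_length = 1L)$n_units
  expect_true(all(n1 >= n2))
  # adding a type containing v1 increases (never decreases) its count
  inv_plus <- dplyr::bind_rows(inv, fake_inventory("v1 zzz9", 1L))
  n2_plus <- count_word_units(inv_plus, words, min_length = 2L)$n_units
  expect_true(all(n2_plus >= n2))
  expect_equal(n2_plus[1L], n2[1L] + 1L)
})

test_that("word frequencies count raw tokens and conserve totals", {
  cp <- as_corpus(c("a b", "a"))
  expect_equal(count_word_freq(cp, c("a", "b", "c"))$freq, c(2L, 1L, 0L))
  cp2 <- random_corpus(50L, vocab = 8L, seed = 2L)
  vocab <- unique(unlist(cp2$tokens))
  expect_equal(sum(count_word_freq(cp2, vocab)$freq), corpus_tokens(cp2))
})

test_that("words absent from a corpus are in no unit of its inventory", {
  cp <- random_corpus(100L, vocab = 10L, max_len = 5L, seed = 23L)
  inv <- chunk_corpus(cp)
  absent <- c("q1", "q2")
  expect_equal(count_word_freq(cp, absent)$freq, c(0L, 0L))
  expect_equal(count_word_units(inv, absent, min_length = 1L)$n_units, c(0L, 0L))
})

test_that("inventory and corpus summaries report counts, median and IQR", {
  inv <- fake_inventory(c("a b", "c"), c(2L, 1L))
  s <- summarize_inventory(inv)
  expect_equal(s$n_unit_tokens, 3L)
  expect_equal(s$n_unit_types, 2L)
  expect_equal(s$median_length, 1.5)
  st <- summarize_inventory(inv, weight = "tokens")
  expect_equal(st$median_length, 2)

  cp <- as_corpus(c("a b", "a b c d", "a b c d", "a b c d e f"))
  sc <- summarize_corpus(cp)
  expect_equal(sc$median_utt_length, 4)
  expect_equal(sc$n_tokens, 16L)
  expect_equal(sc$n_types, 6L)
  one <- summarize_corpus(as_corpus("a b c"))
  expect_equal(one$iqr_utt_length, 0)
  expect_error(summarize_inventory(fake_inventory(character(), integer())),
               "empty")
})

test_that("target words require presence in all four sources", {
  cds <- as_corpus(c("dog runs", "cat naps"))
  ads <- as_corpus(c("dog sleeps", "cat sits", "fox hides"))
  aofp <- tibble::tibble(word = c("dog", "cat", "fox"), aofp = c(1.5, 2, 3))
  rt <- tibble::tibble(word = c("dog", "fox"), rt = c(500, 600))
  # cat lacks RT, fox is absent from CDS
  expect_identical(select_target_words(cds, ads, aofp, rt), "dog")
  rt2 <- tibble::tibble(word = "unicorn", rt = 500)
  expect_error(select_target_words(cds, ads, aofp, rt2), "target")
})

test_that("build_word_measures assembles all predictors and responses", {
  cds <- as_corpus(c("sit down now", "sit down"))
  ads <- as_corpus(c("sit there", "down there"))
  inv_cds <- chunk_corpus(cds)
  inv_ads <- chunk_corpus(ads)
  base_cds <- chunk_corpus(cds, "baseline", seed = 1L)
  base_ads <- chunk_corpus(ads, "baseline", seed = 2L)
  aofp <- tibble::tibble(word = c("sit", "down"), aofp = c(1.2, 1.4))
  rt <- tibble::tibble(word = c("sit", "down"), rt = c(520, 560))
  m <- build_word_measures(c("down", "sit"), cds, ads, inv_cds, inv_ads,
                           base_cds, base_ads, aofp, rt)
  expect_equal(nrow(m), 2L)
  expect_named(m, c("word", "freq_cds", "freq_ads", "n_mwus_cds",
                    "n_mwus_ads", "n_baseline_cds", "n_baseline_ads",
                    "aofp", "rt"))
  expect_equal(m$freq_cds[m$word == "sit"], 2L)
  expect_equal(m$rt[m$word == "down"], 560)
  # freq = 0 implies unit-type count = 0 for that corpus
  expect_true(all(m$n_mwus_cds[m$freq_cds == 0L] == 0L))
})
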