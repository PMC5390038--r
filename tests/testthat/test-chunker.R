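test_that("backward_tp is the pair count over the word count", {
  # after transitions "a b" and "c b": b seen twice, once after a
  expect_equal(backward_tp(1, 2), 0.5)
  expect_equal(backward_tp(1, 1), 1)
  expect_equal(backward_tp(0, 3), 0)
  expect_error(backward_tp(2, 1))
})

test_that("filler/collocation trace: repeated bigram is chunked on second sight", {
  # ten one-off filler transitions push the running mean BTP to H_10/10,
  # then "a b" three times: first fails (threshold mean + 1/1), second
  # passes (1 > mean + 1/2), third re-chunked via the chunkatory.
  lines <- c(paste(sprintf("x%d", 1:10), "z"), rep("a b", 3L))
  inv <- chunk_corpus(as_corpus(lines), mode = "cbl", keep_segments = TRUE)
  expect_equal(inv$n[inv$unit == "a b"], 2L)
  # the first "a b" utterance was split into two single-word units
  segs <- attr(inv, "segments")
  expect_identical(segs[[11L]], list("a", "b"))
  expect_identical(segs[[12L]], list(c("a", "b")))
  expect_identical(segs[[13L]], list(c("a", "b")))
  # running mean after all 13 transitions: (H_10 + 3 * 1) / 13
  h10 <- sum(1 / (1:10))
  expect_equal(attr(inv, "n_transitions"), 13L)
  expect_equal(attr(inv, "mean_btp"), (h10 + 3) / 13)
})

test_that("trivial utterances produce the expected units", {
  inv <- chunk_corpus(as_corpus("hi"))
  expect_identical(inv$unit, "hi")
  inv <- chunk_corpus(as_corpus("a b"))
  expect_setequal(inv$unit, c("a", "b"))
  # corpus of only length-1 utterances: only single-word types
  inv <- chunk_corpus(as_corpus(c("a", "b", "a", "c")))
  expect_true(all(inv$length == 1L))
  expect_error(chunk_corpus(as_corpus(character())), "empty")
})

test_that("a word's first-ever occurrence never attaches", {
  # with the noise correction the threshold at first exposure is >= 1,
  # and the chunkatory cannot contain a never-seen word
  n_multiword <- 0L
  for (s in 1:8) {
    cp <- random_corpus(100L, vocab = 8L, max_len = 5L, seed = s)
    inv <- chunk_corpus(cp, keep_segments = TRUE)
    segs <- attr(inv, "segments")
    seen <- character(0)
    violations <- 0L
    for (ui in seq_len(nrow(cp))) {
      for (unit in segs[[ui]]) {
        if (length(unit) >= 2L) {
          n_multiword <- n_multiword + 1L
          # every non-initial token of a unit attached to its predecessor:
          # it must have been seen before this occurrence
          violations <- violations + sum(!(unit[-1L] %in% seen))
        }
        seen <- union(seen, unit)
      }
    }
    expect_equal(violations, 0L)
  }
  # the property was exercised on real attachments
  expect_gt(n_multiword, 0L)
})

test_that("emitted units partition each utterance and conserve tokens", {
  cp <- random_corpus(200L, vocab = 10L, max_len = 6L, seed = 11L)
  for (inv in list(chunk_corpus(cp, "cbl", keep_segments = TRUE),
                   chunk_corpus(cp, "baseline", seed = 5L, keep_segments = TRUE))) {
    segs <- attr(inv, "segments")
    for (ui in seq_len(nrow(cp))) {
      expect_identical(unlist(segs[[ui]]), cp$tokens[[ui]])
    }
    expect_equal(sum(inv$length * inv$n), corpus_tokens(cp))
  }
})

test_that("chunker matches a naive re-simulation oracle", {
  for (s in 1:4) {
    cp <- random_corpus(120L, vocab = 8L, max_len = 5L, seed = 100L + s)
    expect_same_inventory(chunk_corpus(cp, "cbl"),
                          oracle_chunker(cp, "cbl"))
    expect_same_inventory(chunk_corpus(cp, "baseline", seed = s),
                          oracle_chunker(cp, "baseline", seed = s))
    expect_same_inventory(chunk_corpus(cp, "cbl", threshold_mode = "per_word"),
                          oracle_chunker(cp, "cbl", threshold_mode = "per_word"))
  }
  # a larger corpus once
  cp <- random_corpus(500L, vocab = 15L, max_len = 6L, seed = 99L)
  expect_same_inventory(chunk_corpus(cp, "cbl"), oracle_chunker(cp, "cbl"))
})

test_that("baseline extremes and reproducibility", {
  cp <- random_corpus(150L, vocab = 10L, max_len = 6L, seed = 3L)
  inv0 <- chunk_corpus(cp, "baseline", attach_prob = 0, seed = 1L)
  expect_true(all(inv0$length == 1L))
  inv1 <- chunk_corpus(cp, "baseline", attach_prob = 1, seed = 1L)
  # one unit per utterance: unit tokens = number of utterances
  expect_equal(sum(inv1$n), nrow(cp))
  expect_equal(sort(unique(vapply(strsplit(inv1$unit, " "), length, 1L))),
               sort(unique(lengths(cp$tokens))))
  a <- chunk_corpus(cp, "baseline", seed = 42L)
  b <- chunk_corpus(cp, "baseline", seed = 42L)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- chunk_corpus(cp, "baseline", seed = 43L)
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
  expect_equal(sum(c2$length * c2$n), corpus_tokens(cp))
  expect_error(chunk_corpus(cp, "baseline"), "seed")
})

test_that("memoryless fair coin yields about half two-word units", {
  # 1000 two-word utterances of distinct pairs; chunkatory off so every
  # decision is an independent fair coin
  words <- sprintf("p%04d", 1:2000)
  lines <- paste(words[seq(1, 2000, 2)], words[seq(2, 2000, 2)])
  cp <- as_corpus(lines)
  inv <- chunk_corpus(cp, "baseline", attach_prob = 0.5,
                      use_chunkatory = FALSE, seed = 9L)
  frac2 <- sum(inv$n[inv$length == 2L]) / nrow(cp)
  expect_gt(frac2, 0.5 - 3 * sqrt(0.25 / 1000))
  expect_lt(frac2, 0.5 + 3 * sqrt(0.25 / 1000))
})

test_that("cbl runs are deterministic", {
  cp <- random_corpus(200L, vocab = 12L, max_len = 6L, seed = 21L)
  expect_identical(as.data.frame(chunk_corpus(cp)),
                   as.data.frame(chunk_corpus(cp)))
})

test_that("chunking is order-sensitive but frequencies are not", {
  cfg <- small_config()
  cp <- generate_corpus(cfg, "cds", seed = 8L)$corpus
  perm <- withr::with_seed(1L, sample.int(nrow(cp)))
  cp2 <- cp[perm, ]
  inv_a <- chunk_corpus(cp)
  inv_b <- chunk_corpus(cp2)
  expect_false(identical(as.data.frame(inv_a), as.data.frame(inv_b)))
  words <- c("w0001", "w0050", "w0123")
  expect_identical(count_word_freq(cp, words), count_word_freq(cp2, words))
})
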