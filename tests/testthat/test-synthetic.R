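test_that("generator is deterministic and register-shaped", {
  cfg <- small_config()
  a <- generate_corpus(cfg, "cds", seed = 4L)
  b <- generate_corpus(cfg, "cds", seed = 4L)
  expect_identical(a$corpus$tokens, b$corpus$tokens)
  expect_identical(a$truth, b$truth)
  c2 <- generate_corpus(cfg, "cds", seed = 5L)
  expect_false(identical(a$corpus$tokens, c2$corpus$tokens))

  ads <- generate_corpus(cfg, "ads", seed = 4L)
  expect_lt(summarize_corpus(a$corpus)$median_utt_length,
            summarize_corpus(ads$corpus)$median_utt_length)
  # both registers share the same planted templates
  expect_identical(attr(a$truth, "templates"), attr(ads$truth, "templates"))
})

test_that("ground truth freq equals an independent recount of the corpus", {
  cfg <- small_config()
  g <- generate_corpus(cfg, "ads", seed = 12L)
  recount <- count_word_freq(g$corpus, g$truth$word)
  expect_equal(g$truth$true_freq, recount$freq)
  expect_equal(sum(g$truth$true_freq), corpus_tokens(g$corpus))
  # template membership counts match a direct scan of the template list
  tpls <- attr(g$truth, "templates")
  manual <- vapply(g$truth$word, function(w) {
    sum(vapply(tpls, function(t) w %in% t, logical(1L)))
  }, integer(1L))
  expect_equal(g$truth$n_templates, unname(manual))
})

test_that("config validation rejects impossible template vocabularies", {
  expect_error(synth_config(vocab_size = 100L, template_pool_ranks = c(50L, 200L)),
               "vocab_size")
  expect_error(synth_config(template_pool_size = 5L,
                            template_length_range = c(2L, 6L)),
               "pool size")
})

test_that("planted templates lengthen the discovered units", {
  cfg0 <- small_config(template_use_prob = 0)
  cfg5 <- small_config(template_use_prob = 0.5)
  inv0 <- chunk_corpus(generate_corpus(cfg0, "cds", seed = 30L)$corpus)
  inv5 <- chunk_corpus(generate_corpus(cfg5, "cds", seed = 30L)$corpus)
  mean_len <- function(inv) sum(inv$length * inv$n) / sum(inv$n)
  expect_gt(mean_len(inv5), mean_len(inv0))
  multiword_tokens <- function(inv) sum(inv$n[inv$length >= 2L])
  expect_gt(multiword_tokens(inv5), multiword_tokens(inv0))
})

test_that("transcripts encode the configured effect structure", {
  cfg_null <- small_config(beta_freq = 0, beta_mwu = 0)
  cfg_eff <- small_config(beta_mwu = 2)
  g <- generate_corpus(cfg_eff, "cds", seed = 44L)
  g0 <- generate_corpus(cfg_null, "cds", seed = 44L)

  run_chain <- function(cfg, truth, seed) {
    tr <- generate_transcripts(cfg, truth, seed)
    mlu <- estimate_mlu(tr, reps = 200L, seed = 77L)
    tab <- assign_aofp(tr, mlu)
    dplyr::inner_join(truth, tab, by = "word")
  }
  # strong template effect: words in more templates have earlier AoFP
  d_eff <- run_chain(cfg_eff, g$truth, 91L)
  tau_eff <- kendall_tau_b(d_eff$n_templates, d_eff$aofp)$tau
  expect_lt(tau_eff, -0.15)
  # null: the tau(n_templates, aofp) interval covers zero
  d_null <- run_chain(cfg_null, g0$truth, 91L)
  ci <- tau_ci(d_null, n_templates, aofp, reps = 500L, seed = 13L)
  expect_true(ci$lower <= 0 && 0 <= ci$upper)
  # determinism
  t1 <- generate_transcripts(cfg_eff, g$truth, 91L)
  t2 <- generate_transcripts(cfg_eff, g$truth, 91L)
  expect_identical(t1$tokens, t2$tokens)
})

test_that("reaction times encode frequency and template effects", {
  cfg <- small_config(noise_sd = 0, beta_mwu = 0)
  g <- generate_corpus(cfg, "ads", seed = 3L)
  rt <- generate_rt_table(cfg, g$truth, seed = 8L)
  # noiseless pure-frequency RT: perfectly discordant up to frequency ties
  expect_equal(kendall_tau_b(g$truth$true_freq, rt$rt)$tau, -1)

  cfg2 <- small_config()
  g2 <- generate_corpus(cfg2, "ads", seed = 3L)
  rt2 <- generate_rt_table(cfg2, g2$truth, seed = 8L)
  d <- dplyr::inner_join(g2$truth, rt2, by = "word")
  # template membership speeds recognition beyond frequency
  part <- partial_tau_b(d$n_templates, d$rt, d$true_freq)
  expect_lt(part$tau, 0)
  expect_identical(rt2, generate_rt_table(cfg2, g2$truth, seed = 8L))
})

test_that("generate_study wires registers, transcripts and RTs together", {
  cfg <- small_config()
  st <- generate_study(cfg, seed = 2L)
  expect_named(st, c("cds", "ads", "truth_cds", "truth_ads", "templates",
                     "transcripts", "rt"))
  expect_equal(attr(st$cds, "label"), "CDS")
  expect_equal(attr(st$ads, "label"), "ADS")
  # transcript words come from the CDS vocabulary
  expect_true(all(unique(unlist(st$transcripts$tokens)) %in% st$truth_cds$word))
  # RT covers the ADS vocabulary
  expect_setequal(st$rt$word, st$truth_ads$word)
  st2 <- generate_study(cfg, seed = 2L)
  expect_identical(st$cds$tokens, st2$cds$tokens)
  expect_identical(st$rt, st2$rt)
})
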