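#' Configuration for the synthetic study generator
#'
#' Defines the generating conditions for a fully synthetic analogue of the
#' study design: two utterance corpora (a child-directed-like register with
#' shorter utterances and an adult-directed-like register with longer
#' ones) sharing a set of planted multi-word templates among Zipf-sampled
#' filler words; a developmental transcript set whose word-introduction
#' order is driven by word frequency and template membership; and a
#' reaction-time table driven by the same effects.
#'
#' Effects are standardized: `beta_freq` and `beta_mwu` weight z-scores of
#' log token frequency and of the number of planted templates containing
#' the word, against Gaussian noise with standard deviation `noise_sd` on
#' the same scale. Positive betas mean facilitation: earlier age of first
#' production and faster reaction times.
#'
#' @param vocab_size Vocabulary size (filler words ranked by Zipf
#'   frequency).
#' @param n_templates Number of planted multi-word templates.
#' @param template_length_range Inclusive range of template lengths in
#'   tokens.
#' @param template_pool_size Number of distinct words templates are built
#'   from.
#' @param template_pool_ranks Zipf-rank window the template pool is drawn
#'   from (mid-to-low frequency, so template transitions stand out from
#'   filler transitions).
#' @param template_use_prob Probability that an utterance instantiates a
#'   template (padded with fillers) rather than being all fillers.
#' @param utt_len_cds,utt_len_ads Inclusive utterance-length ranges per
#'   register; the child-directed-like range is shorter.
#' @param n_utterances Utterances per register.
#' @param zipf_exponent Exponent of the filler frequency distribution.
#' @param beta_freq,beta_mwu Standardized effect sizes of log frequency and
#'   template membership on both responses.
#' @param noise_sd Response noise on the standardized scale.
#' @param n_transcripts Number of transcripts on the developmental axis.
#' @param mlu_range Mean-length-of-utterance range spanned by the
#'   transcripts.
#' @param transcript_utt_meanlog,transcript_utt_sdlog,transcript_utt_clamp
#'   Log-normal draw (and clamp) for per-transcript utterance counts,
#'   giving the skewed per-child data volumes typical of pooled transcript
#'   collections.
#' @param rt_baseline_ms,rt_effect_ms Reaction-time intercept and the
#'   millisecond value of one standardized effect unit.
#' @param master_seed Seed fixing the template identities (shared by both
#'   registers regardless of the per-corpus emission seed).
#' @return A `synth_config` list.
#' @export
synth_config <- function(vocab_size = 1200L,
                         n_templates = 60L,
                         template_length_range = c(2L, 3L),
                         template_pool_size = 100L,
                         template_pool_ranks = c(201L, 1000L),
                         template_use_prob = 0.4,
                         utt_len_cds = c(2L, 7L),
                         utt_len_ads = c(4L, 11L),
                         n_utterances = 4000L,
                         zipf_exponent = 1,
                         beta_freq = 1,
                         beta_mwu = 1,
                         noise_sd = 1,
                         n_transcripts = 60L,
                         mlu_range = c(1.3, 6),
                         transcript_utt_meanlog = log(80),
                         transcript_utt_sdlog = 0.6,
                         transcript_utt_clamp = c(20L, 500L),
                         rt_baseline_ms = 700,
                         rt_effect_ms = 40,
                         master_seed = 1L) {
  cfg <- list(
    vocab_size = as.integer(vocab_size),
    n_templates = as.integer(n_templates),
    template_length_range = as.integer(template_length_range),
    template_pool_size = as.integer(template_pool_size),
    template_pool_ranks = as.integer(template_pool_ranks),
    template_use_prob = template_use_prob,
    utt_len_cds = as.integer(utt_len_cds),
    utt_len_ads = as.integer(utt_len_ads),
    n_utterances = as.integer(n_utterances),
    zipf_exponent = zipf_exponent,
    beta_freq = beta_freq,
    beta_mwu = beta_mwu,
    noise_sd = noise_sd,
    n_transcripts = as.integer(n_transcripts),
    mlu_range = mlu_range,
    transcript_utt_meanlog = transcript_utt_meanlog,
    transcript_utt_sdlog = transcript_utt_sdlog,
    transcript_utt_clamp = as.integer(transcript_utt_clamp),
    rt_baseline_ms = rt_baseline_ms,
    rt_effect_ms = rt_effect_ms,
    master_seed = as.integer(master_seed)
  )
  stopifnot(cfg$template_use_prob >= 0, cfg$template_use_prob <= 1,
            cfg$noise_sd >= 0, cfg$vocab_size >= 2L,
            cfg$template_length_range[1L] >= 2L,
            cfg$mlu_range[1L] >= 1)
  if (cfg$template_pool_ranks[2L] > cfg$vocab_size ||
      cfg$template_pool_size > diff(cfg$template_pool_ranks) + 1L) {
    abort("template vocabulary exceeds the configured vocab_size / rank window")
  }
  if (cfg$template_length_range[2L] > cfg$template_pool_size) {
    abort("template length exceeds the template pool size")
  }
  structure(cfg, class = "synth_config")
}

synth_words <- function(config) sprintf("w%04d", seq_len(config$vocab_size))

zipf_probs <- function(config) {
  p <- seq_len(config$vocab_size)^(-config$zipf_exponent)
  p / sum(p)
}

zscale <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Planted multi-word templates of a configuration
#'
#' Templates are fixed by `config$master_seed` alone, so both registers of
#' one configuration share the same planted structure regardless of the
#' per-corpus emission seeds. Template words are drawn (with reuse across
#' templates, never within one) from a pool of mid-frequency words, giving
#' per-word template-membership counts with real variance.
#'
#' @param config A [synth_config()].
#' @return A list of character vectors (the templates), with the word pool
#'   in the `pool` attribute.
#' @export
synth_templates <- function(config) {
  words <- synth_words(config)
  withr::with_seed(config$master_seed, {
    rk <- config$template_pool_ranks
    pool <- sample(words[rk[1L]:rk[2L]], config$template_pool_size)
    templates <- list()
    seen <- character()
    while (length(templates) < config$n_templates) {
      len <- sample(config$template_length_range[1L]:config$template_length_range[2L], 1L)
      tpl <- sample(pool, len)
      key <- paste(tpl, collapse = " ")
      if (key %in% seen) next
      seen <- c(seen, key)
      templates[[length(templates) + 1L]] <- tpl
    }
    attr(templates, "pool") <- pool
    templates
  })
}

#' Generate a synthetic utterance corpus with planted templates
#'
#' Each utterance either instantiates one planted template (with
#' probability `template_use_prob`), padded to the drawn utterance length
#' with independent Zipf-sampled fillers at a random offset, or consists of
#' fillers only. Within-template transitions therefore have high backward
#' transitional probability while filler transitions are diffuse.
#' Deterministic given `seed`.
#'
#' @param config A [synth_config()].
#' @param register `"cds"` (shorter utterances) or `"ads"` (longer).
#' @param seed Integer seed for the emission.
#' @return A list with `corpus` (a corpus tibble labelled by register) and
#'   `truth` (tibble `word`, `true_freq` — the realized token count, exact
#'   by construction — and `n_templates`, the number of planted templates
#'   containing the word; the template list is attached as the `templates`
#'   attribute).
#' @export
generate_corpus <- function(config, register = c("cds", "ads"), seed) {
  register <- match.arg(register)
  templates <- synth_templates(config)
  words <- synth_words(config)
  probs <- zipf_probs(config)
  rng <- if (register == "cds") config$utt_len_cds else config$utt_len_ads
  n <- config$n_utterances
  token_list <- withr::with_seed(as.integer(seed), {
    L <- sample(rng[1L]:rng[2L], n, replace = TRUE)
    is_tpl <- runif(n) < config$template_use_prob
    tpl_idx <- sample.int(length(templates), n, replace = TRUE)
    # one shared filler stream, consumed in order
    fill <- words[sample.int(config$vocab_size, sum(L), replace = TRUE, prob = probs)]
    fpos <- 0L
    take_fill <- function(k) {
      if (k == 0L) return(character())
      out <- fill[(fpos + 1L):(fpos + k)]
      fpos <<- fpos + k
      out
    }
    lapply(seq_len(n), function(i) {
      if (!is_tpl[i]) return(take_fill(L[i]))
      tpl <- templates[[tpl_idx[i]]]
      npad <- max(L[i] - length(tpl), 0L)
      pre <- sample.int(npad + 1L, 1L) - 1L
      c(take_fill(pre), tpl, take_fill(npad - pre))
    })
  })
  corpus <- new_corpus(seq_along(token_list), token_list,
                       label = toupper(register))
  counts <- table(unlist(token_list))
  tpl_tab <- table(unlist(lapply(templates, unique)))
  realized <- names(counts)
  ntpl <- as.integer(tpl_tab[realized])
  ntpl[is.na(ntpl)] <- 0L
  truth <- tibble::tibble(
    word = realized,
    true_freq = as.integer(counts),
    n_templates = ntpl
  )
  attr(truth, "templates") <- templates
  list(corpus = corpus, truth = truth)
}

#' Generate a synthetic developmental transcript set
#'
#' Transcripts span a developmental axis of increasing target mean length
#' of utterance. Every word is assigned an introduction point on that axis
#' by ranking the latent score
#' `beta_freq * z(log freq) + beta_mwu * z(n_templates) + noise`:
#' high-scoring words enter at low-MLU (early) transcripts. A transcript's
#' utterances are sampled (frequency-weighted) from the words already
#' introduced, each newly introduced word is guaranteed one utterance in
#' its introduction transcript, and per-transcript utterance counts follow
#' a skewed log-normal, mimicking pooled corpus collections where some
#' children contribute far more speech than others.
#'
#' @param config A [synth_config()].
#' @param truth Ground-truth tibble from [generate_corpus()] (normally the
#'   child-directed register's).
#' @param seed Integer seed.
#' @return A transcript tibble (one row per child utterance) with columns
#'   `transcript_id`, `child_id`, `age_months`, `line`, `tokens`; the
#'   per-word introduction index is attached as attribute `intro`.
#' @export
generate_transcripts <- function(config, truth, seed) {
  words <- truth$word
  nw <- length(words)
  nt <- config$n_transcripts
  stopifnot(nw >= nt)
  withr::with_seed(as.integer(seed), {
    score <- config$beta_freq * zscale(log(truth$true_freq)) +
      config$beta_mwu * zscale(truth$n_templates) +
      rnorm(nw, 0, config$noise_sd)
    intro <- ceiling(rank(-score, ties.method = "first") * nt / nw)
    mlu_targets <- seq(config$mlu_range[1L], config$mlu_range[2L],
                       length.out = nt)
    rows <- lapply(seq_len(nt), function(j) {
      pool <- words[intro <= j]
      pw <- truth$true_freq[intro <= j]
      n_base <- round(rlnorm(1L, config$transcript_utt_meanlog,
                             config$transcript_utt_sdlog))
      n_base <- min(max(n_base, config$transcript_utt_clamp[1L]),
                    config$transcript_utt_clamp[2L])
      lens <- 1L + rpois(n_base, mlu_targets[j] - 1)
      stream <- sample(pool, sum(lens), replace = TRUE, prob = pw)
      base_toks <- split(stream, rep.int(seq_len(n_base), lens))
      new_words <- words[intro == j]
      new_toks <- lapply(new_words, function(w) {
        len <- 1L + rpois(1L, mlu_targets[j] - 1)
        others <- if (len > 1L) sample(pool, len - 1L, replace = TRUE, prob = pw)
                  else character()
        at <- sample.int(len, 1L)
        append(others, w, after = at - 1L)
      })
      toks <- c(unname(base_toks), new_toks)
      age <- max(1, round(10 + 60 * (j - 1) / max(nt - 1, 1) + rnorm(1L, 0, 4)))
      tibble::tibble(
        transcript_id = sprintf("t%03d", j),
        child_id = sprintf("c%03d", j),
        age_months = age,
        line = seq_along(toks),
        tokens = toks
      )
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "intro") <- setNames(intro, words)
    out
  })
}

#' Generate a synthetic reaction-time table
#'
#' Mean lexical-decision reaction times with the configured effect
#' structure:
#' `rt = rt_baseline_ms - rt_effect_ms * (beta_freq * z(log freq) +
#' beta_mwu * z(n_templates)) + Gaussian noise`, truncated positive.
#'
#' @param config A [synth_config()].
#' @param truth Ground-truth tibble from [generate_corpus()] (normally the
#'   adult-directed register's).
#' @param seed Integer seed.
#' @return A tibble `word`, `rt` (milliseconds).
#' @export
generate_rt_table <- function(config, truth, seed) {
  withr::with_seed(as.integer(seed), {
    eff <- config$beta_freq * zscale(log(truth$true_freq)) +
      config$beta_mwu * zscale(truth$n_templates)
    rt <- config$rt_baseline_ms - config$rt_effect_ms * eff +
      rnorm(nrow(truth), 0, config$rt_effect_ms * config$noise_sd)
    tibble::tibble(word = truth$word, rt = pmax(rt, 1))
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper producing every input of the analysis pipeline from
#' one configuration and master seed: both register corpora (shared planted
#' templates, independent emissions), the transcript set driven by the
#' child-directed ground truth, and the reaction-time table driven by the
#' adult-directed ground truth. Component seeds are derived
#' deterministically from `seed`.
#'
#' @param config A [synth_config()].
#' @param seed Integer master seed.
#' @return A list: `cds`, `ads` (corpus tibbles), `truth_cds`, `truth_ads`,
#'   `templates`, `transcripts`, `rt`.
#' @export
generate_study <- function(config = synth_config(), seed = 1L) {
  cds <- generate_corpus(config, "cds", derive_seed(seed, 1L))
  ads <- generate_corpus(config, "ads", derive_seed(seed, 2L))
  transcripts <- generate_transcripts(config, cds$truth, derive_seed(seed, 3L))
  rt <- generate_rt_table(config, ads$truth, derive_seed(seed, 4L))
  list(
    cds = cds$corpus, ads = ads$corpus,
    truth_cds = cds$truth, truth_ads = ads$truth,
    templates = attr(cds$truth, "templates"),
    transcripts = transcripts, rt = rt
  )
}
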