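# Independent oracles used across the suite. These deliberately use naive
# data structures (named vectors, linear scans, full pair matrices) so they
# share nothing with the package's incremental / compiled implementations.

# Brute-force Kendall pair enumeration over the full pair matrix.
oracle_tau_counts <- function(x, y) {
  dx <- sign(outer(x, x, `-`))
  dy <- sign(outer(y, y, `-`))
  up <- upper.tri(dx)
  prod <- dx[up] * dy[up]
  c(
    P = sum(prod == 1),
    Q = sum(prod == -1),
    X0 = sum(dx[up] == 0 & dy[up] != 0),
    Y0 = sum(dx[up] != 0 & dy[up] == 0),
    B = sum(dx[up] == 0 & dy[up] == 0)
  )
}

oracle_tau_b <- function(x, y) {
  ct <- oracle_tau_counts(x, y)
  denom <- (ct[["P"]] + ct[["Q"]] + ct[["X0"]]) * (ct[["P"]] + ct[["Q"]] + ct[["Y0"]])
  (ct[["P"]] - ct[["Q"]]) / sqrt(denom)
}

# Naive re-simulation of the chunker: named count vectors, every-transition
# recomputation of the running mean from a stored BTP log, and a linear scan
# of the stored units for the chunkatory override. Same decision semantics,
# none of the incremental bookkeeping.
oracle_chunker <- function(corpus, mode = c("cbl", "baseline"),
                           threshold_mode = c("global", "per_word"),
                           noise_correction = TRUE, attach_prob = 0.5,
                           use_chunkatory = TRUE, seed = NULL) {
  mode <- match.arg(mode)
  threshold_mode <- match.arg(threshold_mode)
  freq <- integer(0)
  left <- integer(0)
  btp_log <- numeric(0)
  stored_units <- list()
  stored_keys <- character(0)
  emitted <- character(0)

  bump <- function(v, k) {
    cur <- v[k]
    if (is.na(cur)) cur <- 0L
    v[k] <- cur + 1L
    v
  }
  pair_in_units <- function(prev, curr) {
    for (u in stored_units) {
      if (length(u) >= 2L) {
        for (j in 2:length(u)) {
          if (u[j - 1L] == prev && u[j] == curr) return(TRUE)
        }
      }
    }
    FALSE
  }
  per_word_mean <- function(curr) {
    keys <- names(left)
    parts <- strsplit(keys, "\r", fixed = TRUE)
    hit <- vapply(parts, function(p) p[2L] == curr, logical(1L))
    mean(unname(left[keys[hit]]) / freq[[curr]])
  }

  body <- function() {
    for (toks in corpus$tokens) {
      freq <<- bump(freq, toks[1L])
      open <- toks[1L]
      if (length(toks) >= 2L) {
        for (i in 2:length(toks)) {
          prev <- toks[i - 1L]
          curr <- toks[i]
          freq <<- bump(freq, curr)
          pk <- paste(prev, curr, sep = "\r")
          left <<- bump(left, pk)
          btp <- unname(left[pk]) / unname(freq[curr])
          if (use_chunkatory && pair_in_units(prev, curr)) {
            attach <- TRUE
          } else if (mode == "baseline") {
            attach <- if (attach_prob >= 1) {
              runif(1L)
              TRUE
            } else {
              runif(1L) < attach_prob
            }
          } else {
            thr <- if (threshold_mode == "per_word") per_word_mean(curr)
                   else if (length(btp_log) > 0L) mean(btp_log) else 0
            if (noise_correction) thr <- thr + 1 / unname(freq[curr])
            attach <- btp > thr
          }
          btp_log <<- c(btp_log, btp)
          if (attach) {
            open <- c(open, curr)
          } else {
            key <- paste(open, collapse = " ")
            emitted <<- c(emitted, key)
            if (!(key %in% stored_keys)) {
              stored_keys <<- c(stored_keys, key)
              stored_units[[length(stored_units) + 1L]] <<- open
            }
            open <- curr
          }
        }
      }
      key <- paste(open, collapse = " ")
      emitted <<- c(emitted, key)
      if (!(key %in% stored_keys)) {
        stored_keys <<- c(stored_keys, key)
        stored_units[[length(stored_units) + 1L]] <<- open
      }
    }
  }
  if (mode == "baseline") withr::with_seed(as.integer(seed), body()) else body()
  table(emitted)
}

# Compare an oracle emission table with a chunk_corpus() inventory.
expect_same_inventory <- function(inventory, oracle_tab) {
  got <- setNames(inventory$n, inventory$unit)
  want <- setNames(as.integer(oracle_tab), names(oracle_tab))
  got <- got[order(names(got))]
  want <- want[order(names(want))]
  expect_identical(got, want)
}

random_corpus <- function(n_utt, vocab = 20L, max_len = 6L, seed = 1L) {
  withr::with_seed(seed, {
    lines <- vapply(seq_len(n_utt), function(i) {
      paste(sample(paste0("v", seq_len(vocab)), sample.int(max_len, 1L),
                   replace = TRUE), collapse = " ")
    }, "")
    as_corpus(lines)
  })
}

# Small generator configuration for simulation-heavy tests.
small_config <- function(...) {
  synth_config(
    vocab_size = 300L, n_templates = 30L, template_pool_size = 60L,
    template_pool_ranks = c(101L, 300L), n_utterances = 1200L,
    n_transcripts = 30L, transcript_utt_meanlog = log(50),
    ...
  )
}
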