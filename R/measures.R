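#' Count the unit types containing each target word
#'
#' The #MWUs (or #baseline) predictor: for every target word, the number of
#' *distinct* unit types of length at least `min_length` whose token
#' sequence contains the word. A word repeated inside one unit still counts
#' that unit once; words absent from every unit get 0.
#'
#' @param inventory A unit inventory (see [chunk_corpus()]).
#' @param words Character vector of target words.
#' @param min_length Minimum unit length (tokens) for a unit to qualify;
#'   default 2 (single-word units are not multi-word units).
#' @return A tibble with columns `word` and `n_units`, in the order of
#'   `words`.
#' @export
count_word_units <- function(inventory, words, min_length = 2L) {
  stopifnot(is.data.frame(inventory), min_length >= 1L)
  keep <- inventory$length >= min_length
  tab <- if (any(keep)) {
    membership <- lapply(strsplit(inventory$unit[keep], " ", fixed = TRUE), unique)
    table(unlist(membership))
  } else table(character())
  n <- as.integer(tab[words])
  n[is.na(n)] <- 0L
  tibble::tibble(word = words, n_units = n)
}

#' Raw token frequency of each target word in a corpus
#'
#' @param corpus A corpus tibble.
#' @param words Character vector of target words.
#' @return A tibble with columns `word` and `freq` (0 for absent words).
#' @export
count_word_freq <- function(corpus, words) {
  tab <- table(unlist(corpus$tokens))
  f <- as.integer(tab[words])
  f[is.na(f)] <- 0L
  tibble::tibble(word = words, freq = f)
}

iqr_linear <- function(x) {
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  q[2L] - q[1L]
}

#' Summarize a unit inventory
#'
#' Token/type counts plus the median and interquartile range (Q3 - Q1,
#' linear-interpolation quantiles) of the unit-length distribution.
#'
#' @param inventory A unit inventory.
#' @param weight Length distribution over unit `"types"` (default: each type
#'   counted once) or `"tokens"` (weighted by emission count).
#' @return A one-row tibble: `n_unit_tokens`, `n_unit_types`,
#'   `median_length`, `iqr_length`.
#' @export
summarize_inventory <- function(inventory, weight = c("types", "tokens")) {
  weight <- match.arg(weight)
  if (nrow(inventory) == 0L) abort("cannot summarize an empty inventory")
  lens <- if (weight == "types") inventory$length else
    rep.int(inventory$length, inventory$n)
  tibble::tibble(
    n_unit_tokens = sum(inventory$n),
    n_unit_types = nrow(inventory),
    median_length = median(lens),
    iqr_length = iqr_linear(lens)
  )
}

#' Summarize an utterance corpus
#'
#' @param corpus A corpus tibble.
#' @return A one-row tibble: `n_tokens`, `n_types`, `median_utt_length`,
#'   `iqr_utt_length`.
#' @export
summarize_corpus <- function(corpus) {
  if (nrow(corpus) == 0L) abort("cannot summarize an empty corpus")
  lens <- lengths(corpus$tokens)
  tibble::tibble(
    n_tokens = sum(lens),
    n_types = length(unique(unlist(corpus$tokens))),
    median_utt_length = median(lens),
    iqr_utt_length = iqr_linear(lens)
  )
}

#' Select the target-word set for the correlational analyses
#'
#' Target words are the word forms occurring in both registers for which
#' both an age-of-first-production and a reaction-time estimate exist: the
#' intersection of the four availability sets. Raw word forms only — no
#' stemming, lemmatization or tagging.
#'
#' @param cds,ads Corpus tibbles for the two registers.
#' @param aofp A tibble with a `word` column (see [assign_aofp()]).
#' @param rt A tibble with a `word` column (see [read_rt_table()]).
#' @return A sorted character vector of target words; an empty intersection
#'   is an error (no analysis is possible).
#' @export
select_target_words <- function(cds, ads, aofp, rt) {
  targets <- Reduce(intersect, list(
    unique(unlist(cds$tokens)),
    unique(unlist(ads$tokens)),
    unique(aofp$word),
    unique(rt$word)
  ))
  if (length(targets) == 0L) {
    abort("no target words: the corpora, AoFP and RT vocabularies do not intersect")
  }
  sort(targets)
}

#' Assemble the per-word measure table
#'
#' One row per target word with every predictor and response used in the
#' correlational analyses: token frequency and number of containing unit
#' types per register for both the BTP chunker and the random baseline,
#' plus age of first production (MLU units) and reaction time (ms).
#'
#' @param targets Character vector of target words.
#' @param cds,ads Corpus tibbles.
#' @param inv_cds,inv_ads CBL inventories for the two registers.
#' @param base_cds,base_ads Baseline inventories for the two registers.
#' @param aofp AoFP tibble (`word`, `aofp`).
#' @param rt RT tibble (`word`, `rt`).
#' @param min_length Minimum unit length for the type counts; default 2.
#' @return A tibble with columns `word`, `freq_cds`, `freq_ads`,
#'   `n_mwus_cds`, `n_mwus_ads`, `n_baseline_cds`, `n_baseline_ads`,
#'   `aofp`, `rt`.
#' @export
build_word_measures <- function(targets, cds, ads, inv_cds, inv_ads,
                                base_cds, base_ads, aofp, rt,
                                min_length = 2L) {
  out <- tibble::tibble(
    word = targets,
    freq_cds = count_word_freq(cds, targets)$freq,
    freq_ads = count_word_freq(ads, targets)$freq,
    n_mwus_cds = count_word_units(inv_cds, targets, min_length)$n_units,
    n_mwus_ads = count_word_units(inv_ads, targets, min_length)$n_units,
    n_baseline_cds = count_word_units(base_cds, targets, min_length)$n_units,
    n_baseline_ads = count_word_units(base_ads, targets, min_length)$n_units
  )
  out <- dplyr::left_join(out, aofp[, c("word", "aofp")], by = "word")
  dplyr::left_join(out, rt[, c("word", "rt")], by = "word")
}
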