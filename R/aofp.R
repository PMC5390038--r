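#' Bootstrap mean length of utterance per transcript
#'
#' A transcript's developmental stage is indexed by its mean length of
#' utterance (MLU): the average child utterance length in tokens. Because
#' transcripts contain very different numbers of utterances, the plain
#' per-transcript average is estimated by statistical bootstrap: `reps`
#' resamples with replacement of the utterance-length sequence, each of size
#' equal to the transcript's number of utterances, and the MLU point
#' estimate is the mean of the resample means. With `reps = 0` the plain
#' sample mean is returned.
#'
#' Per-transcript seeds are derived deterministically from `seed` and the
#' transcript's position, so adding transcripts never perturbs earlier
#' estimates.
#'
#' @param transcripts Transcript tibble, one row per child utterance
#'   (columns `transcript_id`, `tokens`; see [read_transcripts()]).
#' @param reps Bootstrap resamples per transcript; default 1000.
#' @param seed Integer master seed (required when `reps > 0`).
#' @return A tibble with one row per transcript: `transcript_id`, `mlu`,
#'   `n_utterances`, `reps`.
#' @export
estimate_mlu <- function(transcripts, reps = 1000L, seed = NULL) {
  stopifnot(is.data.frame(transcripts),
            all(c("transcript_id", "tokens") %in% names(transcripts)))
  if (nrow(transcripts) == 0L) abort("transcript set is empty")
  if (reps > 0L && is.null(seed)) abort("bootstrap MLU requires a seed")
  ids <- unique(transcripts$transcript_id)
  lens_by <- split(lengths(transcripts$tokens),
                   factor(transcripts$transcript_id, levels = ids))
  mlu <- purrr::imap_dbl(lens_by, function(lens, id) {
    n <- length(lens)
    if (n == 0L) abort(paste0("transcript has no utterances: ", id))
    if (reps == 0L) return(mean(lens))
    idx <- match(id, ids)
    withr::with_seed(derive_seed(seed, idx), {
      draws <- matrix(sample(lens, n * reps, replace = TRUE), nrow = n)
      mean(colMeans(draws))
    })
  })
  tibble::tibble(
    transcript_id = ids,
    mlu = unname(mlu),
    n_utterances = unname(lengths(lens_by)),
    reps = as.integer(reps)
  )
}

#' Assign age of first production from MLU estimates
#'
#' A word's age of first production (AoFP) is the earliest developmental
#' stage at which any child in the transcript set produces it: the minimum
#' MLU over all transcripts whose child utterances contain the word. Only
#' child utterances are scanned. AoFP is therefore expressed in MLU units
#' (tokens per utterance), not months.
#'
#' @param transcripts Transcript tibble (one row per child utterance).
#' @param mlu MLU estimates as returned by [estimate_mlu()]; every
#'   transcript in `transcripts` must have one.
#' @return A tibble with one row per word type: `word`, `aofp` (the minimum
#'   MLU), and `transcript_id` of the contributing transcript (ties broken
#'   by transcript order).
#' @export
assign_aofp <- function(transcripts, mlu) {
  stopifnot(all(c("transcript_id", "mlu") %in% names(mlu)))
  missing_ids <- setdiff(unique(transcripts$transcript_id), mlu$transcript_id)
  if (length(missing_ids) > 0L) {
    abort(paste0("transcript without MLU estimate: ", missing_ids[1L]))
  }
  pairs <- tibble::tibble(
    transcript_id = rep.int(transcripts$transcript_id, lengths(transcripts$tokens)),
    word = unlist(transcripts$tokens)
  )
  pairs <- dplyr::distinct(pairs)
  pairs <- dplyr::left_join(pairs, mlu[, c("transcript_id", "mlu")],
                            by = "transcript_id")
  out <- pairs |>
    dplyr::group_by(.data$word) |>
    dplyr::summarise(
      aofp = min(.data$mlu),
      transcript_id = .data$transcript_id[which.min(.data$mlu)],
      .groups = "drop"
    )
  out[order(out$word), , drop = FALSE]
}
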