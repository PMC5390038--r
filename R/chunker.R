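#' Backward transitional probability from explicit counts
#'
#' The backward transitional probability (BTP) of a transition is
#' p(prev | curr) = count(prev immediately before curr) / count(curr).
#' Exposed mainly for didactic use and testing; [chunk_corpus()] maintains
#' these counts incrementally.
#'
#' @param pair_count Times `prev` occurred one position left of `curr`.
#' @param word_count Times `curr` has been encountered so far (must be >= 1:
#'   the chunker counts a word before scoring it).
#' @return A probability in \[0, 1\].
#' @export
backward_tp <- function(pair_count, word_count) {
  stopifnot(word_count >= 1, pair_count >= 0, pair_count <= word_count)
  pair_count / word_count
}

#' Segment a corpus into multi-word units
#'
#' Incremental chunker in the Chunk-Based Learner (CBL) family. Utterances
#' are processed in order, word by word. Each within-utterance transition
#' (prev, curr) is scored by its backward transitional probability (BTP),
#' p(prev | curr); `curr` joins the open unit when the BTP exceeds the
#' running mean BTP over all previously scored transitions plus (with the
#' noise correction on) the reciprocal of curr's frequency count. Units
#' already discovered act as a "chunkatory": a bigram that is an adjacent
#' pair inside any stored unit of length >= 2 is re-grouped on sight,
#' regardless of BTP. Unit boundaries (and utterance ends) close the open
#' unit, which is emitted into the inventory and stored in the chunkatory.
#'
#' The `baseline` mode is the random control: identical control flow, but
#' each non-chunkatory attachment decision is an independent coin toss with
#' probability `attach_prob`.
#'
#' Per transition the update order is: (1) increment the frequency count of
#' `curr` and the (prev, curr) pair count; (2) compute the BTP; (3) form the
#' threshold from the running mean over *prior* transitions plus 1/freq(curr)
#' if `noise_correction`; (4) apply the chunkatory override, else compare
#' (strict `>`; ties are boundaries); (5) add this BTP to the running mean
#' (always, overridden transitions included). A consequence of the noise
#' correction is that a word's first-ever occurrence can only attach via the
#' chunkatory, never via the BTP rule (its threshold is at least 1).
#'
#' @param corpus A corpus tibble (see [as_corpus()]). Must be nonempty.
#' @param mode `"cbl"` (deterministic BTP rule) or `"baseline"` (coin toss).
#' @param threshold_mode `"global"` (default): running mean over all
#'   transitions scored so far, excluding the current one. `"per_word"`:
#'   mean BTP over the distinct words seen one position left of `curr`,
#'   computed from current counts.
#' @param noise_correction Add 1/freq(curr) to the threshold? Default `TRUE`.
#' @param attach_prob Baseline coin-toss probability, default 0.5.
#' @param use_chunkatory Keep the chunkatory override stage? Default `TRUE`
#'   (also for the baseline; set `FALSE` for a memoryless baseline).
#' @param seed Integer seed, required for `mode = "baseline"`; ignored for
#'   `"cbl"`.
#' @param keep_segments Also return the per-utterance segmentation (list of
#'   character-vector units per utterance) as the `segments` attribute?
#'   Default `FALSE` (saves memory on large corpora).
#' @return A unit inventory: a tibble of class `mwu_inventory` with columns
#'   `unit` (tokens joined by single spaces), `length` (tokens) and `n`
#'   (emission count), sorted by `n` descending then `unit`. Attributes
#'   record the configuration, the corpus label and token count, the number
#'   of transitions scored and the final running mean BTP.
#' @examples
#' cp <- as_corpus(c("you sit down", "sit down now", "sit down"))
#' chunk_corpus(cp)
#' @export
chunk_corpus <- function(corpus,
                         mode = c("cbl", "baseline"),
                         threshold_mode = c("global", "per_word"),
                         noise_correction = TRUE,
                         attach_prob = 0.5,
                         use_chunkatory = TRUE,
                         seed = NULL,
                         keep_segments = FALSE) {
  mode <- match.arg(mode)
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(is.data.frame(corpus), "tokens" %in% names(corpus))
  if (nrow(corpus) == 0L) abort("cannot chunk an empty corpus")
  stopifnot(attach_prob >= 0, attach_prob <= 1)
  if (mode == "baseline" && is.null(seed)) {
    abort("mode = \"baseline\" requires a seed")
  }

  run <- function() {
    freq <- new.env(hash = TRUE, parent = emptyenv())
    left <- new.env(hash = TRUE, parent = emptyenv())
    pairset <- new.env(hash = TRUE, parent = emptyenv())
    inv <- new.env(hash = TRUE, parent = emptyenv())
    nonfirst <- new.env(hash = TRUE, parent = emptyenv())
    nleft <- new.env(hash = TRUE, parent = emptyenv())
    btp_sum <- 0
    btp_n <- 0L
    per_word <- threshold_mode == "per_word"
    baseline <- mode == "baseline"
    segs <- if (keep_segments) vector("list", nrow(corpus))

    close_unit <- function(unit_tokens) {
      key <- paste(unit_tokens, collapse = " ")
      cnt <- inv[[key]]
      if (is.null(cnt)) {
        inv[[key]] <- 1L
        k <- length(unit_tokens)
        if (k >= 2L) {
          for (j in 2:k) {
            pairset[[paste(unit_tokens[j - 1L], unit_tokens[j], sep = "\r")]] <- TRUE
          }
        }
      } else {
        inv[[key]] <- cnt + 1L
      }
    }

    token_list <- corpus$tokens
    for (ui in seq_along(token_list)) {
      toks <- token_list[[ui]]
      if (length(toks) == 0L) abort("empty utterance in corpus")
      w1 <- toks[1L]
      f <- freq[[w1]]
      freq[[w1]] <- if (is.null(f)) 1L else f + 1L
      open <- w1
      useg <- if (keep_segments) list()
      if (length(toks) >= 2L) {
        for (i in 2:length(toks)) {
          prev <- toks[i - 1L]
          curr <- toks[i]
          f <- freq[[curr]]
          fc <- if (is.null(f)) 1L else f + 1L
          freq[[curr]] <- fc
          pk <- paste(prev, curr, sep = "\r")
          lc0 <- left[[pk]]
          lc <- if (is.null(lc0)) 1L else lc0 + 1L
          left[[pk]] <- lc
          if (per_word) {
            if (is.null(lc0)) {
              nl <- nleft[[curr]]
              nleft[[curr]] <- if (is.null(nl)) 1L else nl + 1L
            }
            nf <- nonfirst[[curr]]
            nonfirst[[curr]] <- if (is.null(nf)) 1L else nf + 1L
          }
          btp <- lc / fc

          attach <- FALSE
          if (use_chunkatory && !is.null(pairset[[pk]])) {
            attach <- TRUE
          } else if (baseline) {
            r <- runif(1L)
            attach <- if (attach_prob >= 1) TRUE else r < attach_prob
          } else {
            thr <- if (per_word) {
              nonfirst[[curr]] / (nleft[[curr]] * fc)
            } else if (btp_n > 0L) btp_sum / btp_n else 0
            if (noise_correction) thr <- thr + 1 / fc
            attach <- btp > thr
          }
          btp_sum <- btp_sum + btp
          btp_n <- btp_n + 1L

          if (attach) {
            open <- c(open, curr)
          } else {
            close_unit(open)
            if (keep_segments) useg[[length(useg) + 1L]] <- open
            open <- curr
          }
        }
      }
      close_unit(open)
      if (keep_segments) {
        useg[[length(useg) + 1L]] <- open
        segs[[ui]] <- useg
      }
    }

    units <- ls(inv, sorted = FALSE)
    counts <- vapply(units, function(k) inv[[k]], integer(1L), USE.NAMES = FALSE)
    out <- tibble::tibble(
      unit = units,
      length = lengths(strsplit(units, " ", fixed = TRUE)),
      n = counts
    )
    out <- out[order(-out$n, out$unit), , drop = FALSE]
    attr(out, "label") <- attr(corpus, "label")
    attr(out, "mode") <- mode
    attr(out, "threshold_mode") <- threshold_mode
    attr(out, "noise_correction") <- noise_correction
    attr(out, "attach_prob") <- if (baseline) attach_prob else NA_real_
    attr(out, "use_chunkatory") <- use_chunkatory
    attr(out, "seed") <- if (baseline) as.integer(seed) else NA_integer_
    attr(out, "n_transitions") <- btp_n
    attr(out, "mean_btp") <- if (btp_n > 0L) btp_sum / btp_n else NA_real_
    attr(out, "n_corpus_tokens") <- sum(lengths(token_list))
    attr(out, "n_utterances") <- length(token_list)
    if (keep_segments) attr(out, "segments") <- segs
    class(out) <- c("mwu_inventory", class(out))
    out
  }

  if (mode == "baseline") withr::with_seed(as.integer(seed), run()) else run()
}

#' @export
print.mwu_inventory <- function(x, ...) {
  cat(sprintf(
    "<mwu_inventory> %s: %d unit types, %d unit tokens (%d corpus tokens, mode=%s)\n",
    attr(x, "label") %||% "unlabelled",
    nrow(x), sum(x$n), attr(x, "n_corpus_tokens"), attr(x, "mode")
  ))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot the unit-length distribution of an inventory
#'
#' @param object An `mwu_inventory`.
#' @param weight `"types"` (each unit type once) or `"tokens"`
#'   (emission-weighted).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.mwu_inventory <- function(object, weight = c("types", "tokens"), ...) {
  weight <- match.arg(weight)
  df <- tibble::tibble(
    length = object$length,
    w = if (weight == "types") 1L else object$n
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, weight = .data$w)) +
    ggplot2::geom_bar(fill = "grey30") +
    ggplot2::labs(
      x = "unit length (tokens)",
      y = paste("unit", weight),
      title = paste0("Unit length distribution (",
                     attr(object, "label") %||% "unlabelled", ", ",
                     attr(object, "mode"), ")")
    ) +
    ggplot2::theme_minimal()
}
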