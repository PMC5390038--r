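predictor_grid <- function() {
  tibble::tibble(
    predictor = c("freq_cds", "freq_ads", "n_mwus_cds", "n_mwus_ads",
                  "n_baseline_cds", "n_baseline_ads"),
    register = rep(c("cds", "ads"), 3L),
    control = c("n_mwus_cds", "n_mwus_ads", "freq_cds", "freq_ads",
                "freq_cds", "freq_ads")
  )
}

#' Run the full multi-word-unit correlational analysis
#'
#' End-to-end orchestration: runs the BTP chunker and the random baseline
#' on both register corpora; derives per-target-word predictors (#Freq,
#' #MWUs, #baseline per register); estimates age of first production from
#' the transcripts via bootstrap MLU; and computes full and partial
#' Kendall tau-b correlations of every predictor with both responses
#' (reaction time and age of first production), each with a percentile
#' bootstrap confidence interval. When `comparisons = TRUE` it also
#' computes the paired-bootstrap difference intervals for the three
#' comparison families: register contrasts (ADS vs CDS variants per
#' response, full and partial), chunker-vs-baseline contrasts on the
#' designated response pairing (ADS predictors with RT, CDS predictors
#' with AoFP), and cross-response contrasts (each ADS predictor/RT cell
#' against its CDS counterpart/AoFP cell). Differences compare coefficient
#' magnitudes (`|A| - |B|`), the natural direction when all correlations
#' are negative.
#'
#' The whole run is deterministic given `seed`: named sub-seeds for the
#' two baseline chunker runs, the MLU bootstrap and every correlation
#' bootstrap are derived from it.
#'
#' @param cds,ads Corpus tibbles for the two registers.
#' @param transcripts Transcript tibble (one row per child utterance).
#' @param rt RT tibble (`word`, `rt`).
#' @param targets Optional character vector of target words; defaults to
#'   the intersection rule of [select_target_words()].
#' @param min_length Minimum unit length for the type counts; default 2.
#' @param reps Bootstrap resamples for every correlation interval; default
#'   1000.
#' @param mlu_reps Bootstrap resamples per transcript MLU; default 1000.
#' @param seed Integer master seed (required).
#' @param comparisons Also compute the difference intervals? Default
#'   `TRUE`.
#' @param threshold_mode,noise_correction,attach_prob,use_chunkatory
#'   Passed to [chunk_corpus()].
#' @return An object of class `mwu_analysis`: a list with `measures` (the
#'   word-level table), `correlations` (one row per predictor x response x
#'   mode cell), `comparisons` (difference intervals, or `NULL`),
#'   `inventories` (the four unit inventories), `mlu`, `aofp`, `targets`,
#'   `seed`, `reps`. A cell whose coefficient is undefined (completely
#'   tied predictor) is reported as `NA` and the run continues.
#' @export
run_mwu_analysis <- function(cds, ads, transcripts, rt,
                             targets = NULL, min_length = 2L,
                             reps = 1000L, mlu_reps = 1000L, seed = NULL,
                             comparisons = TRUE,
                             threshold_mode = "global",
                             noise_correction = TRUE,
                             attach_prob = 0.5,
                             use_chunkatory = TRUE) {
  if (is.null(seed)) abort("run_mwu_analysis requires a seed")
  seed <- as.integer(seed)

  inv_cds <- chunk_corpus(cds, "cbl", threshold_mode = threshold_mode,
                          noise_correction = noise_correction)
  inv_ads <- chunk_corpus(ads, "cbl", threshold_mode = threshold_mode,
                          noise_correction = noise_correction)
  base_cds <- chunk_corpus(cds, "baseline", attach_prob = attach_prob,
                           use_chunkatory = use_chunkatory,
                           seed = derive_seed(seed, 11L))
  base_ads <- chunk_corpus(ads, "baseline", attach_prob = attach_prob,
                           use_chunkatory = use_chunkatory,
                           seed = derive_seed(seed, 12L))

  mlu <- estimate_mlu(transcripts, reps = mlu_reps,
                      seed = derive_seed(seed, 13L))
  aofp <- assign_aofp(transcripts, mlu)

  if (is.null(targets)) {
    targets <- select_target_words(cds, ads, aofp, rt)
  }
  measures <- build_word_measures(targets, cds, ads, inv_cds, inv_ads,
                                  base_cds, base_ads, aofp, rt, min_length)

  grid <- predictor_grid()
  cells <- tidyr::expand_grid(grid, response = c("rt", "aofp"),
                              mode = c("full", "partial"))
  correlations <- purrr::pmap_dfr(
    list(cells$predictor, cells$control, cells$response, cells$mode,
         seq_len(nrow(cells))),
    function(pred, ctl, resp, mode, i) {
      ctl_used <- if (mode == "partial") ctl else NA_character_
      row <- tryCatch({
        if (mode == "partial") {
          tau_ci(measures, !!rlang::sym(pred), !!rlang::sym(resp),
                 control = !!rlang::sym(ctl), reps = reps,
                 seed = derive_seed(seed, 100L + i))
        } else {
          tau_ci(measures, !!rlang::sym(pred), !!rlang::sym(resp),
                 reps = reps, seed = derive_seed(seed, 100L + i))
        }
      }, mwulex_degenerate = function(e) {
        warn(paste0("degenerate correlation cell: ", pred, " vs ", resp,
                    " (", mode, ")"))
        tibble::tibble(x = pred, y = resp, control = ctl_used,
                       tau = NA_real_, lower = NA_real_, upper = NA_real_,
                       level = 0.95, reps = as.integer(reps),
                       n = nrow(measures), n_redrawn = NA_integer_)
      })
      dplyr::bind_cols(
        tibble::tibble(predictor = pred, response = resp, mode = mode),
        row[, setdiff(names(row), c("x", "y"))]
      )
    }
  )

  comp <- NULL
  if (isTRUE(comparisons)) {
    comp <- run_comparisons(measures, reps = reps, seed = seed)
  }

  structure(
    list(
      measures = measures,
      correlations = correlations,
      comparisons = comp,
      inventories = list(cbl_cds = inv_cds, cbl_ads = inv_ads,
                         baseline_cds = base_cds, baseline_ads = base_ads),
      mlu = mlu,
      aofp = aofp,
      targets = targets,
      seed = seed,
      reps = as.integer(reps)
    ),
    class = "mwu_analysis"
  )
}

comparison_plan <- function() {
  spec <- function(x, y, control = NA_character_) {
    structure(list(x = x, y = y, control = control), class = "tau_spec")
  }
  add <- function(analysis, label, mode, a, b) {
    tibble::tibble(analysis = analysis, label = label, mode = mode,
                   spec_a = list(a), spec_b = list(b))
  }
  dplyr::bind_rows(
    # register contrasts: designated register vs the other, per response
    add("register", "rt: ads_freq vs cds_freq", "full",
        spec("freq_ads", "rt"), spec("freq_cds", "rt")),
    add("register", "rt: ads_mwus vs cds_mwus", "full",
        spec("n_mwus_ads", "rt"), spec("n_mwus_cds", "rt")),
    add("register", "aofp: cds_freq vs ads_freq", "full",
        spec("freq_cds", "aofp"), spec("freq_ads", "aofp")),
    add("register", "aofp: cds_mwus vs ads_mwus", "full",
        spec("n_mwus_cds", "aofp"), spec("n_mwus_ads", "aofp")),
    add("register", "rt: ads_freq vs cds_freq", "partial",
        spec("freq_ads", "rt", "n_mwus_ads"), spec("freq_cds", "rt", "n_mwus_cds")),
    add("register", "rt: ads_mwus vs cds_mwus", "partial",
        spec("n_mwus_ads", "rt", "freq_ads"), spec("n_mwus_cds", "rt", "freq_cds")),
    add("register", "aofp: cds_freq vs ads_freq", "partial",
        spec("freq_cds", "aofp", "n_mwus_cds"), spec("freq_ads", "aofp", "n_mwus_ads")),
    add("register", "aofp: cds_mwus vs ads_mwus", "partial",
        spec("n_mwus_cds", "aofp", "freq_cds"), spec("n_mwus_ads", "aofp", "freq_ads")),
    # chunker vs random baseline on the designated pairings
    add("baseline", "rt: ads_mwus vs ads_baseline", "full",
        spec("n_mwus_ads", "rt"), spec("n_baseline_ads", "rt")),
    add("baseline", "aofp: cds_mwus vs cds_baseline", "full",
        spec("n_mwus_cds", "aofp"), spec("n_baseline_cds", "aofp")),
    add("baseline", "rt: ads_mwus vs ads_baseline", "partial",
        spec("n_mwus_ads", "rt", "freq_ads"), spec("n_baseline_ads", "rt", "freq_ads")),
    add("baseline", "aofp: cds_mwus vs cds_baseline", "partial",
        spec("n_mwus_cds", "aofp", "freq_cds"), spec("n_baseline_cds", "aofp", "freq_cds")),
    # cross-response contrasts
    add("cross_response", "freq: ads/rt vs cds/aofp", "full",
        spec("freq_ads", "rt"), spec("freq_cds", "aofp")),
    add("cross_response", "mwus: ads/rt vs cds/aofp", "full",
        spec("n_mwus_ads", "rt"), spec("n_mwus_cds", "aofp")),
    add("cross_response", "freq: ads/rt vs cds/aofp", "partial",
        spec("freq_ads", "rt", "n_mwus_ads"), spec("freq_cds", "aofp", "n_mwus_cds")),
    add("cross_response", "mwus: ads/rt vs cds/aofp", "partial",
        spec("n_mwus_ads", "rt", "freq_ads"), spec("n_mwus_cds", "aofp", "freq_cds"))
  )
}

run_comparisons <- function(measures, reps, seed) {
  plan <- comparison_plan()
  purrr::pmap_dfr(
    list(plan$analysis, plan$label, plan$mode, plan$spec_a, plan$spec_b,
         seq_len(nrow(plan))),
    function(analysis, label, mode, a, b, i) {
      row <- tryCatch(
        tau_diff_ci(measures, a, b, absolute = TRUE, reps = reps,
                    seed = derive_seed(seed, 500L + i)),
        mwulex_degenerate = function(e) {
          tibble::tibble(a = NA_character_, b = NA_character_,
                         estimate = NA_real_, lower = NA_real_,
                         upper = NA_real_, excludes_zero = NA,
                         absolute = TRUE, level = 0.95,
                         reps = as.integer(reps), n = nrow(measures),
                         n_redrawn = NA_integer_)
        })
      dplyr::bind_cols(
        tibble::tibble(analysis = analysis, label = label, mode = mode), row
      )
    }
  )
}

#' @export
print.mwu_analysis <- function(x, ...) {
  cat("<mwu_analysis>\n")
  cat(sprintf("  targets: %d words; bootstrap reps: %d; seed: %d\n",
              length(x$targets), x$reps, x$seed))
  inv <- x$inventories
  cat(sprintf("  CBL unit types: CDS %d, ADS %d; baseline: CDS %d, ADS %d\n",
              nrow(inv$cbl_cds), nrow(inv$cbl_ads),
              nrow(inv$baseline_cds), nrow(inv$baseline_ads)))
  cat("  correlations:\n")
  print(x$correlations[, c("predictor", "response", "mode", "tau",
                           "lower", "upper")], n = 24)
  invisible(x)
}

#' @export
tidy.mwu_analysis <- function(x, ...) {
  x$correlations
}

#' @export
glance.mwu_analysis <- function(x, ...) {
  tibble::tibble(
    n_targets = length(x$targets),
    n_mwu_types_cds = nrow(x$inventories$cbl_cds),
    n_mwu_types_ads = nrow(x$inventories$cbl_ads),
    n_baseline_types_cds = nrow(x$inventories$baseline_cds),
    n_baseline_types_ads = nrow(x$inventories$baseline_ads),
    n_transcripts = nrow(x$mlu),
    reps = x$reps,
    seed = x$seed
  )
}

#' Plot the correlation cells of an analysis
#'
#' Bar rendering of every predictor x response x mode coefficient with its
#' bootstrap interval.
#'
#' @param object An `mwu_analysis`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.mwu_analysis <- function(object, ...) {
  df <- object$correlations
  df$predictor <- factor(df$predictor, levels = predictor_grid()$predictor)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predictor, y = .data$tau)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper), width = 0.25
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_grid(ggplot2::vars(.data$response),
                        ggplot2::vars(.data$mode)) +
    ggplot2::labs(x = NULL, y = "Kendall tau-b (95% bootstrap CI)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
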