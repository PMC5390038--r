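#' Tokenize a single utterance line
#'
#' Splits a line of transcribed speech into word tokens on runs of
#' whitespace. No punctuation stripping, stemming, lemmatization or tagging
#' is ever applied: tokens are raw word forms, optionally case-folded.
#'
#' @param line A length-one character string (UTF-8).
#' @param lowercase Case-fold the tokens? Default `TRUE`, so that e.g.
#'   "Good" and "good" count as one word type.
#' @return A character vector of tokens. A line containing only whitespace
#'   yields a zero-length vector; callers decide whether to skip or error.
#' @examples
#' tokenize_line("that's right")
#' tokenize_line("  oh   dear ")
#' @export
tokenize_line <- function(line, lowercase = TRUE) {
  stopifnot(is.character(line), length(line) == 1L)
  if (isTRUE(lowercase)) line <- tolower(line)
  toks <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
  toks[nzchar(toks)]
}

new_corpus <- function(lines_idx, token_list, label = NULL, n_skipped = 0L) {
  out <- tibble::tibble(line = as.integer(lines_idx), tokens = token_list)
  attr(out, "label") <- label
  attr(out, "n_skipped") <- as.integer(n_skipped)
  class(out) <- c("mwu_corpus", class(out))
  out
}

#' Build an utterance corpus from character lines
#'
#' A corpus is a tibble with one row per utterance: `line` (source line
#' number) and `tokens` (list-column of character vectors). Row order is the
#' incremental processing order, which the chunker is sensitive to.
#'
#' @param lines Character vector, one utterance per element.
#' @param lowercase Case-fold tokens? Default `TRUE`.
#' @param label Optional free-text register label (e.g. "CDS", "ADS").
#' @return A corpus tibble; blank lines are skipped and counted in the
#'   `n_skipped` attribute.
#' @examples
#' as_corpus(c("sit down", "good boy"), label = "CDS")
#' @export
as_corpus <- function(lines, lowercase = TRUE, label = NULL) {
  stopifnot(is.character(lines))
  toks <- lapply(lines, tokenize_line, lowercase = lowercase)
  keep <- lengths(toks) > 0L
  new_corpus(which(keep), toks[keep], label = label, n_skipped = sum(!keep))
}

#' Read an utterance corpus from a plain-text file
#'
#' Expects UTF-8 text, one utterance per line, tokens separated by
#' whitespace. Blank lines are skipped (their count is kept in the
#' `n_skipped` attribute); an empty file yields a zero-row corpus with a
#' warning.
#'
#' @param path Path to the corpus file.
#' @inheritParams as_corpus
#' @return A corpus tibble (see [as_corpus()]).
#' @export
read_corpus <- function(path, lowercase = TRUE, label = NULL) {
  if (!file.exists(path)) {
    abort(paste0("corpus file does not exist: ", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  out <- as_corpus(lines, lowercase = lowercase, label = label)
  if (nrow(out) == 0L) warn(paste0("corpus is empty: ", path))
  out
}

#' Write an utterance corpus to a plain-text file
#'
#' One utterance per line, tokens joined by single spaces. Reading the file
#' back with [read_corpus()] recovers the token sequences exactly.
#'
#' @param corpus A corpus tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(is.data.frame(corpus), "tokens" %in% names(corpus))
  writeLines(vapply(corpus$tokens, paste, "", collapse = " "), path, useBytes = TRUE)
  invisible(path)
}

#' Total token count of a corpus
#'
#' @param corpus A corpus tibble.
#' @return Integer: the sum of utterance lengths.
#' @export
corpus_tokens <- function(corpus) {
  sum(lengths(corpus$tokens))
}

#' Read a transcript set from a manifest
#'
#' A transcript set is stored as a directory of per-transcript utterance
#' files plus a tab-separated manifest with columns `file`, `child_id` and
#' `age_months` (age may be empty/NA; mean length of utterance does not need
#' it). Each transcript file holds the child's utterances, one per line.
#'
#' @param manifest Path to the manifest TSV.
#' @param dir Directory holding the transcript files; defaults to the
#'   manifest's directory.
#' @param lowercase Case-fold tokens? Default `TRUE`.
#' @return A tibble with one row per child utterance: `transcript_id`
#'   (file name without extension), `child_id`, `age_months`, `line`,
#'   `tokens`. Manifest order is preserved. Transcripts with no utterances
#'   are excluded with a warning.
#' @export
read_transcripts <- function(manifest, dir = dirname(manifest), lowercase = TRUE) {
  if (!file.exists(manifest)) {
    abort(paste0("manifest does not exist: ", manifest))
  }
  man <- utils::read.delim(manifest, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("file", "child_id", "age_months") %in% names(man))) {
    abort("manifest must have columns: file, child_id, age_months")
  }
  rows <- purrr::pmap(man, function(file, child_id, age_months, ...) {
    cp <- read_corpus(file.path(dir, file), lowercase = lowercase)
    if (nrow(cp) == 0L) {
      warn(paste0("transcript has no utterances, excluded: ", file))
      return(NULL)
    }
    age <- suppressWarnings(as.numeric(age_months))
    tibble::tibble(
      transcript_id = tools::file_path_sans_ext(basename(file)),
      child_id = child_id,
      age_months = age,
      line = cp$line,
      tokens = cp$tokens
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) abort("no usable transcripts in manifest")
  out
}

#' Write a transcript set to a directory with a manifest
#'
#' Inverse of [read_transcripts()]: one `.txt` file per transcript plus a
#' `manifest.tsv`.
#'
#' @param transcripts Transcript tibble (one row per utterance) as returned
#'   by [read_transcripts()] or [generate_transcripts()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_transcripts <- function(transcripts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  split_t <- split(transcripts, factor(transcripts$transcript_id,
                                       levels = unique(transcripts$transcript_id)))
  man <- purrr::map_dfr(split_t, function(tr) {
    file <- paste0(tr$transcript_id[1L], ".txt")
    writeLines(vapply(tr$tokens, paste, "", collapse = " "),
               file.path(dir, file), useBytes = TRUE)
    tibble::tibble(file = file,
                   child_id = tr$child_id[1L],
                   age_months = tr$age_months[1L])
  })
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(man, manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a word -> reaction time table
#'
#' Tab-separated file with a header row and two columns, `word` and `rt`
#' (mean lexical-decision reaction time in milliseconds).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `word` (character) and `rt` (positive
#'   numeric). Duplicate words, non-numeric or non-positive reaction times
#'   are errors.
#' @export
read_rt_table <- function(path) {
  if (!file.exists(path)) abort(paste0("RT table does not exist: ", path))
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("word", "rt") %in% names(tab))) {
    abort("RT table must have columns: word, rt")
  }
  rt <- suppressWarnings(as.numeric(tab$rt))
  bad <- which(is.na(rt))
  if (length(bad) > 0L) {
    abort(paste0("non-numeric RT at data line ", bad[1L],
                 " (word: ", tab$word[bad[1L]], ")"))
  }
  dup <- tab$word[duplicated(tab$word)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate word in RT table: ", dup[1L]))
  }
  if (any(rt <= 0)) {
    abort(paste0("RT must be positive (word: ", tab$word[which(rt <= 0)[1L]], ")"))
  }
  tibble::tibble(word = tab$word, rt = rt)
}
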