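#' @include pipeline.R
NULL

## ---------------------------------------------------------------------
## Plain-text serialisation: design tables, information tables, maps.
## ---------------------------------------------------------------------

#' Write / read a session design as TSV
#'
#' One row per trial with the factorial labels, cue glyphs, event times and
#' correctness flags; metadata (participant, session, block order, seed)
#' travels in `#`-prefixed header lines.
#'
#' @param design a [SessionDesign-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDesignTsv <- function(design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# participant=%s", design@participant),
    sprintf("# session=%d", design@session),
    sprintf("# block_order=%s", paste(design@blockOrder, collapse = ",")),
    sprintf("# seed=%d", design@seed)), con)
  utils::write.table(design@trials, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeDesignTsv
#' @export
readDesignTsv <- function(path) {
  hdr <- readLines(path, n = 4L)
  val <- function(key) sub(sprintf("^# %s=", key), "",
                           grep(sprintf("^# %s=", key), hdr, value = TRUE))
  trials <- utils::read.table(path, sep = "\t", header = TRUE,
                              comment.char = "#", stringsAsFactors = FALSE)
  new("SessionDesign", participant = val("participant"),
      session = as.integer(val("session")),
      blockOrder = as.integer(strsplit(val("block_order"), ",")[[1L]]),
      trials = trials, seed = as.integer(val("seed")))
}

#' Write an information result as tidy TSV
#'
#' Long format: `subject`, `session`, `variable`, `mode`, `train_time_ms`,
#' `test_time_ms`, `D`; the fold scheme travels in `#` header lines.
#'
#' @param info an [InformationResult-class].
#' @param path output file.
#' @param subject,session identifiers recorded with every row.
#' @return `path`, invisibly.
#' @export
writeInformationTsv <- function(info, path, subject = NA, session = NA) {
  v <- informationValues(info)
  tab <- if (is.matrix(v))
    data.frame(train_time_ms = rep(info@trainTimesMs, ncol(v)),
               test_time_ms = rep(info@testTimesMs, each = nrow(v)),
               D = as.vector(v))
  else
    data.frame(train_time_ms = info@testTimesMs,
               test_time_ms = info@testTimesMs, D = v)
  tab <- cbind(subject = subject, session = session,
               variable = info@variable, mode = info@mode, tab)
  con <- file(path, "w")
  on.exit(close(con))
  folds <- info@meta$folds
  if (!is.null(folds))
    writeLines(sprintf("# folds=%d reps=%d seed=%d", folds@nFolds,
                       folds@nReps, folds@seed), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a searchlight map as TSV
#'
#' One row per source location and window: position, hemisphere, window
#' label and D (NA where the searchlight was not estimable).
#'
#' @param result a [SearchlightResult-class].
#' @param space the matching [SourceSpace-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSearchlightTsv <- function(result, space, path) {
  nS <- nrow(result@D)
  tab <- data.frame(
    source_id = rep(seq_len(nS), ncol(result@D)),
    x = rep(space@positions[, 1L], ncol(result@D)),
    y = rep(space@positions[, 2L], ncol(result@D)),
    z = rep(space@positions[, 3L], ncol(result@D)),
    hemisphere = rep(result@hemisphere, ncol(result@D)),
    window = rep(colnames(result@D), each = nS),
    D = as.vector(result@D))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a group statistics table as TSV
#'
#' @param stats the `stats` table from [runExperiment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeStatsTsv <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
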