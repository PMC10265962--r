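#' @include preprocess.R
NULL

## ---------------------------------------------------------------------
## Condition-space contrasts for the decoded variables.
## ---------------------------------------------------------------------

#' Construct a contrast from explicit weights
#'
#' @param weights numeric vector or `conditions x q` matrix of zero-sum
#'   weights over the rows of `conditions`.
#' @param variable name of the decoded variable.
#' @param conditions condition table the weights are indexed by (defaults to
#'   the 16-condition task table).
#' @return a [Contrast-class].
#' @export
contrastFromWeights <- function(weights, variable = "custom",
                                conditions = conditionTable()) {
  if (!is.matrix(weights)) weights <- matrix(weights, ncol = 1L)
  new("Contrast", weights = weights, variable = variable,
      conditions = conditions)
}

#' Build a task contrast
#'
#' Zero-sum weighting over the 16 task conditions decoding `"content"`
#' (/u/ vs /\eqn{\schwa}/) or `"production"` (vocalized vs imagined),
#' optionally restricted to a cue-order context, a glyph assignment, or one
#' level of the other variable (the split analyses).  Restrictions zero the
#' weights of excluded conditions; because the design is balanced the
#' weights remain zero-sum.
#'
#' @param variable `"content"` or `"production"`.
#' @param orders cue orders to include (default both).
#' @param assignments glyph assignments to include (default both).
#' @param splitVariable optionally `"production"` (for content contrasts) or
#'   `"vowel"`/`"content"` (for production contrasts).
#' @param splitLevel the level of `splitVariable` to keep.
#' @return a [Contrast-class].
#' @examples
#' makeContrast("content", orders = "content_first")
#' @export
makeContrast <- function(variable = c("content", "production"),
                         orders = c("content_first", "production_first"),
                         assignments = 1:2,
                         splitVariable = NULL, splitLevel = NULL) {
  variable <- match.arg(variable)
  ct <- conditionTable()
  inc <- ct$order %in% orders & ct$assignment %in% assignments
  if (!is.null(splitVariable)) {
    stopIfNot(!is.null(splitLevel), "splitLevel required with splitVariable")
    col <- switch(splitVariable, production = "production",
                  vowel = , content = "vowel",
                  stop("unknown split variable", call. = FALSE))
    inc <- inc & ct[[col]] == splitLevel
  }
  stopIfNot(any(inc), "empty condition set for this contrast")
  sgn <- if (variable == "content") ifelse(ct$vowel == "u", 1, -1)
         else ifelse(ct$production == "vocalized", 1, -1)
  w <- ifelse(inc, sgn, 0)
  stopIfNot(abs(sum(w)) < 1e-8,
            "condition restriction leaves an unbalanced contrast")
  contrastFromWeights(w, variable, ct)
}

## Restrict a contrast's test side to one level of a split variable.
restrictContrast <- function(contrast, splitVariable, splitLevel) {
  ct <- contrast@conditions
  col <- switch(splitVariable, production = "production",
                vowel = , content = "vowel",
                stop("unknown split variable", call. = FALSE))
  stopIfNot(col %in% names(ct), "split variable not in condition table")
  keep <- ct[[col]] == splitLevel
  w <- contrast@weights * keep
  stopIfNot(any(w != 0), "empty split")
  stopIfNot(all(abs(colSums(w)) < 1e-8), "split leaves unbalanced contrast")
  methods::initialize(contrast, weights = w)
}
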