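#' @include methods-EpochArray.R
NULL

## ---------------------------------------------------------------------
## Rule-based vocalization task: rules, block orders, session designs.
## ---------------------------------------------------------------------

#' Canonical trial timeline (ms relative to cue-1 onset)
#'
#' Each visual cue lasts 100 ms and is followed by a 2-s delay; the go cue
#' for (overt or covert) vocalization follows the second delay, 4200 ms
#' after the first cue.  The response window extends 1500 ms past the go cue.
#'
#' @return named list of event times in ms: `cue1OnsetMs`, `cue1OffsetMs`,
#'   `cue2OnsetMs`, `cue2OffsetMs`, `goOnsetMs`, `trialEndMs`.
#' @export
taskTimeline <- function() {
  list(cue1OnsetMs = 0, cue1OffsetMs = 100,
       cue2OnsetMs = 2100, cue2OffsetMs = 2200,
       goOnsetMs = 4200, trialEndMs = 5700)
}

#' Enumerate the four block rules
#'
#' A rule fixes (i) the instruction order (content first or production
#' first) and (ii) the assignment of the two cue glyphs (forward or backward
#' slash) to their meanings at each cue position.  Two orders times two
#' glyph assignments give the four rules used as the four blocks of a
#' recording session.
#'
#' @return list of 4 rules; each a list with `id`, `order`
#'   (`"content_first"`/`"production_first"`), `assignment` (1 or 2) and
#'   `cueMap`, a per-position named character vector mapping glyph to
#'   meaning.
#' @examples
#' rules <- enumerateRules()
#' sapply(rules, `[[`, "order")
#' @export
enumerateRules <- function() {
  glyphs <- c("forward_slash", "backward_slash")
  contentMap <- function(a) {
    m <- if (a == 1L) c("u", "schwa") else c("schwa", "u")
    stats::setNames(m, glyphs)
  }
  productionMap <- function(a) {
    m <- if (a == 1L) c("vocalized", "imagined") else c("imagined", "vocalized")
    stats::setNames(m, glyphs)
  }
  out <- list()
  id <- 0L
  for (ord in c("content_first", "production_first")) {
    for (a in 1:2) {
      id <- id + 1L
      cm <- contentMap(a); pm <- productionMap(a)
      cueMap <- if (ord == "content_first") list(pos1 = cm, pos2 = pm)
                else list(pos1 = pm, pos2 = cm)
      out[[id]] <- list(id = id, order = ord, assignment = a, cueMap = cueMap)
    }
  }
  out
}

#' Enumerate all block orders
#'
#' All 24 permutations of the four rule blocks; one is assigned per
#' participant (uniformly, seeded) and reversed for their second session.
#'
#' @return list of 24 integer permutations of `1:4`.
#' @export
enumerateBlockOrders <- function() {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  perms(1:4)
}

#' The 16-condition table
#'
#' Every combination of cue order, glyph assignment, vowel and production
#' receives a fixed condition code.  The layout is lexicographic in
#' (order, assignment, vowel, production) so that codes 1-4 are the four
#' vowel-by-production cells (1: /u/ vocalized, 2: /u/ imagined,
#' 3: /\eqn{\schwa}/ vocalized, 4: /\eqn{\schwa}/ imagined) of the first
#' content-first rule, and `(code - 1) %% 4 + 1` always recovers the base
#' cell.
#'
#' @return `data.frame` with 16 rows: `condition_id`, `order`, `assignment`,
#'   `vowel`, `production`, `base_cell`.
#' @export
conditionTable <- function() {
  tab <- expand.grid(production = c("vocalized", "imagined"),
                     vowel = c("u", "schwa"),
                     assignment = 1:2,
                     order = c("content_first", "production_first"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- tab[, c("order", "assignment", "vowel", "production")]
  tab$base_cell <- (match(tab$vowel, c("u", "schwa")) - 1L) * 2L +
    match(tab$production, c("vocalized", "imagined"))
  tab$condition_id <- (match(tab$order,
                             c("content_first", "production_first")) - 1L) * 8L +
    (tab$assignment - 1L) * 4L + tab$base_cell
  tab <- tab[order(tab$condition_id), ]
  rownames(tab) <- NULL
  tab[, c("condition_id", "order", "assignment", "vowel", "production",
          "base_cell")]
}

#' Condition code of a trial
#'
#' Deterministic bijection from (vowel, production, cue order, glyph
#' assignment) to the codes 1-16 of [conditionTable()].
#'
#' @param vowel `"u"` or `"schwa"`.
#' @param production `"vocalized"` or `"imagined"`.
#' @param order `"content_first"` or `"production_first"`.
#' @param assignment glyph assignment, 1 or 2.
#' @return integer code(s) in 1-16.
#' @export
conditionCode <- function(vowel, production, order, assignment) {
  vi <- match(vowel, c("u", "schwa"))
  pi <- match(production, c("vocalized", "imagined"))
  oi <- match(order, c("content_first", "production_first"))
  stopIfNot(!anyNA(c(vi, pi, oi)) && all(assignment %in% 1:2),
            "invalid trial labels")
  as.integer((oi - 1L) * 8L + (assignment - 1L) * 4L + (vi - 1L) * 2L + pi)
}

## Glyph shown at a cue position for a given rule and trial labels.
glyphFor <- function(rule, position, vowel, production) {
  map <- rule$cueMap[[position]]
  meaning <- if (all(map %in% c("u", "schwa"))) vowel else production
  names(map)[match(meaning, map)]
}

#' Build one session of the task design
#'
#' Draws the participant's block order uniformly from the 24 permutations
#' (seeded by participant so both sessions agree), reverses it for session
#' 2, and fills each block with a seeded shuffle of the balanced multiset of
#' 20 trials per vowel-by-production cell.
#'
#' @param participant participant identifier (enters the seeding).
#' @param session 1 or 2.
#' @param seed master integer seed fixing all randomization.
#' @return a [SessionDesign-class] with a 320-row trial table: columns
#'   `participant`, `session`, `block`, `trial`, `rule`, `order`,
#'   `assignment`, `vowel`, `production`, `condition_id`, `cue1_glyph`,
#'   `cue2_glyph`, event times (ms), `production_correct`, `vowel_correct`,
#'   `vocal_onset_ms`.
#' @examples
#' d <- buildSessionDesign("P01", 1, seed = 42)
#' table(trialTable(d)$block)
#' @export
buildSessionDesign <- function(participant, session, seed) {
  stopIfNot(length(session) == 1L && session %in% 1:2,
            "session must be 1 or 2")
  seed <- as.integer(seed)
  rules <- enumerateRules()
  orders <- enumerateBlockOrders()
  pick <- withSeed(deriveSeed(seed, "block-order", participant),
                  sample.int(length(orders), 1L))
  blockOrder <- orders[[pick]]
  if (session == 2L) blockOrder <- rev(blockOrder)
  tl <- taskTimeline()
  cells <- expand.grid(vowel = c("u", "schwa"),
                       production = c("vocalized", "imagined"),
                       rep = 1:20, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  blocks <- lapply(1:4, function(b) {
    rule <- rules[[blockOrder[b]]]
    idx <- withSeed(deriveSeed(seed, "trials", participant, session, b),
                   sample.int(nrow(cells)))
    cc <- cells[idx, c("vowel", "production")]
    data.frame(
      participant = participant, session = session, block = b,
      rule = rule$id, order = rule$order, assignment = rule$assignment,
      vowel = cc$vowel, production = cc$production,
      condition_id = conditionCode(cc$vowel, cc$production, rule$order,
                                   rule$assignment),
      cue1_glyph = glyphFor(rule, "pos1", cc$vowel, cc$production),
      cue2_glyph = glyphFor(rule, "pos2", cc$vowel, cc$production),
      cue1_onset_ms = tl$cue1OnsetMs, cue1_offset_ms = tl$cue1OffsetMs,
      cue2_onset_ms = tl$cue2OnsetMs, cue2_offset_ms = tl$cue2OffsetMs,
      go_onset_ms = tl$goOnsetMs, trial_end_ms = tl$trialEndMs,
      production_correct = TRUE, vowel_correct = TRUE,
      vocal_onset_ms = NA_real_,
      stringsAsFactors = FALSE)
  })
  trials <- do.call(rbind, blocks)
  trials$trial <- seq_len(nrow(trials))
  rownames(trials) <- NULL
  new("SessionDesign", participant = as.character(participant),
      session = as.integer(session), blockOrder = as.integer(blockOrder),
      trials = trials, seed = seed)
}
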