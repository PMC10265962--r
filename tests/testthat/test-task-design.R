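test_that("the four block rules cover both orders and both assignments", {
  rules <- enumerateRules()
  expect_length(rules, 4L)
  expect_equal(sum(vapply(rules, `[[`, "", "order") == "content_first"), 2L)
  expect_equal(sum(vapply(rules, `[[`, "", "order") == "production_first"), 2L)
  ## no two rules identical
  sig <- vapply(rules, function(r)
    paste(r$order, r$assignment, paste(r$cueMap$pos1, collapse = ","),
          paste(r$cueMap$pos2, collapse = ",")), "")
  expect_equal(anyDuplicated(sig), 0L)
  ## within a rule, each glyph maps to exactly one meaning per position,
  ## and the two glyphs never share a meaning
  for (r in rules) for (pos in c("pos1", "pos2")) {
    expect_named(r$cueMap[[pos]], c("forward_slash", "backward_slash"))
    expect_equal(anyDuplicated(r$cueMap[[pos]]), 0L)
  }
})

test_that("block-order enumeration is the full symmetric group on 4 blocks", {
  orders <- enumerateBlockOrders()
  expect_length(orders, 24L)
  keys <- vapply(orders, paste, "", collapse = "")
  expect_equal(anyDuplicated(keys), 0L)
  expect_true("1234" %in% keys)
  ## each block appears in each position exactly 6 times
  posMat <- do.call(rbind, orders)
  for (pos in 1:4)
    expect_equal(as.vector(table(posMat[, pos])), rep(6L, 4L))
})

test_that("a session design is balanced, timed and reproducible", {
  d <- buildSessionDesign("P01", 1, seed = 42)
  tr <- trialTable(d)
  expect_equal(nrow(tr), 320L)
  expect_true(all(table(tr$block) == 80L))
  expect_true(all(table(tr$block, tr$vowel, tr$production) == 20L))
  expect_equal(length(unique(tr$condition_id)), 16L)
  ## event arithmetic: 100 ms cues, 2-s delays, go at 4200 ms
  expect_true(all(tr$cue1_offset_ms - tr$cue1_onset_ms == 100))
  expect_true(all(tr$cue2_onset_ms - tr$cue1_offset_ms == 2000))
  expect_true(all(tr$go_onset_ms - tr$cue2_offset_ms == 2000))
  expect_true(all(tr$go_onset_ms - tr$cue1_onset_ms == 4200))
  ## same seed -> identical design; session 2 reverses the block order
  expect_identical(trialTable(buildSessionDesign("P01", 1, seed = 42)), tr)
  d2 <- buildSessionDesign("P01", 2, seed = 42)
  expect_identical(d2@blockOrder, rev(d@blockOrder))
  expect_error(buildSessionDesign("P01", 3, seed = 1), "session")
})

test_that("condition codes are a bijection with base cells 1-4", {
  ct <- conditionTable()
  expect_equal(sort(ct$condition_id), 1:16)
  ## /u/ vocalized maps to base cell 1 under any rule
  codes <- conditionCode(rep("u", 4), rep("vocalized", 4),
                         rep(c("content_first", "production_first"), each = 2),
                         rep(1:2, 2))
  expect_true(all((codes - 1) %% 4 + 1 == 1L))
  ## the four base cells follow the canonical listing
  base <- conditionCode(c("u", "u", "schwa", "schwa"),
                        c("vocalized", "imagined", "vocalized", "imagined"),
                        rep("content_first", 4), rep(1L, 4))
  expect_equal(base, 1:4)
  ## trials differing only in cue assignment get different codes
  expect_false(conditionCode("u", "vocalized", "content_first", 1) ==
                 conditionCode("u", "vocalized", "content_first", 2))
  ## all 320 trials of a session span exactly 16 codes
  tr <- trialTable(buildSessionDesign("P07", 1, seed = 5))
  expect_equal(sort(unique(tr$condition_id)), 1:16)
})

test_that("different participants draw different block orders but a
           participant's sessions agree", {
  orders <- vapply(sprintf("P%02d", 1:20), function(p)
    paste(buildSessionDesign(p, 1, seed = 9)@blockOrder, collapse = ""), "")
  expect_gt(length(unique(orders)), 1L)
})

test_that("design tables round-trip through TSV", {
  d <- buildSessionDesign("P03", 2, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDesignTsv(d, path)
  d2 <- readDesignTsv(path)
  expect_identical(d2@blockOrder, d@blockOrder)
  expect_equal(d2@trials$condition_id, d@trials$condition_id)
  expect_equal(d2@participant, "P03")
})
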