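test_that("CHAT parsing handles speakers, annotations, and errors", {
  toy <- c("*CHI:\tI want the ball .", "*MOT:\tdo you ?")
  tr <- parse_chat(toy)
  expect_length(tr$utterances, 2)
  expect_equal(tr$utterances[[1]]$speaker, "CHI")
  expect_equal(tr$utterances[[1]]$tokens, c("I", "want", "the", "ball"))
  expect_equal(tr$utterances[[1]]$terminator, ".")
  expect_equal(tr$utterances[[2]]$speaker, "MOT")

  annotated <- c("@Begin", "@Participants:\tCHI Child, MOT Mother",
                 "*CHI:\tI [=! laughing] want &=coughs xxx the ball .",
                 "%com:\tchild points at the ball",
                 "*MOT:\t<you want> [/] you want it ?", "@End")
  tr2 <- parse_chat(annotated)
  expect_length(tr2$utterances, 2)
  expect_equal(tr2$utterances[[1]]$tokens, c("I", "want", "the", "ball"))
  expect_equal(tr2$utterances[[2]]$tokens,
               c("you", "want", "you", "want", "it"))

  expect_error(parse_chat(c("*CHI:\thi .", "*DOG:\twoof .")),
               "unknown speaker tier 'DOG' at line 2")
  expect_error(parse_chat("this is not a tier"), "line 1")
})

test_that("a file on disk parses the same as in-memory lines", {
  tr <- generate_transcript(0.7, seed = 5)
  f <- tempfile(fileext = ".cha")
  writeLines(tr$lines, f)
  expect_equal(parse_chat(f)$utterances, tr$utterances)
})

test_that("generated transcripts round-trip through the parser", {
  for (lv in c(0, 0.5, 1)) {
    tr <- generate_transcript(lv, seed = 11)
    reparsed <- parse_chat(tr$lines)
    expect_equal(reparsed$utterances, tr$utterances)
  }
  expect_identical(generate_transcript(0.5, seed = 3)$lines,
                   generate_transcript(0.5, seed = 3)$lines)
})

test_that("morpheme counting applies the documented rule table", {
  expect_equal(count_morphemes(c("dogs", "ran")), 3)
  expect_equal(count_morphemes("ball"), 1)
  expect_equal(count_morphemes(c("she's", "running")), 4)
  expect_equal(count_morphemes("don't"), 2)          # do + n't
  expect_equal(count_morphemes("we'll"), 2)
  expect_equal(count_morphemes("boxes"), 2)          # box + es
  expect_equal(count_morphemes("goes"), 2)
  expect_equal(count_morphemes("children"), 1)       # irregular plural
  expect_equal(count_morphemes("went"), 1)
  expect_equal(count_morphemes("played"), 2)
  expect_equal(count_morphemes("thing"), 1)          # -ing exception
  expect_equal(count_morphemes("red"), 1)            # -ed exception
  expect_equal(count_morphemes("yes"), 1)            # -s exception
  expect_equal(count_morphemes(c("I", "think", "that", "he", "left")), 5)
})

test_that("communication metrics match hand computation", {
  m <- compute_metrics(parse_chat("*CHI:\tI run ."))
  expect_equal(m$MLU, 2)
  expect_equal(m$TNW, 2L)
  expect_equal(m$WPS, 2)
  expect_equal(m$CPS, 1)

  two <- parse_chat(c("*CHI:\tI run .",                    # 2 morphemes
                      "*CHI:\tshe's running ."))           # 4 morphemes
  expect_equal(compute_metrics(two)$MLU, 3)

  sub <- compute_metrics(parse_chat("*CHI:\tI think that he left ."))
  expect_equal(sub$CPS, 2)

  expect_error(compute_metrics(parse_chat("*MOT:\thello ."), speaker = "CHI"),
               "no utterances")
})

test_that("fillers are excluded from counts by default", {
  m <- compute_metrics(parse_chat("*CHI:\tum I um run ."))
  expect_equal(m$TNW, 2L)
  expect_equal(m$MLU, 2)
  m2 <- compute_metrics(parse_chat("*CHI:\tum I um run ."),
                        exclude_fillers = FALSE)
  expect_equal(m2$TNW, 4L)
})

test_that("MLU is invariant to adding an utterance at the current mean", {
  base <- c("*CHI:\tI run .", "*CHI:\tshe's running .")     # MLU 3
  m1 <- compute_metrics(parse_chat(base))
  m2 <- compute_metrics(parse_chat(c(base, "*CHI:\tdogs ran .")))  # 3 morphemes
  expect_equal(m1$MLU, m2$MLU)
})

test_that("TNW is additive over transcript concatenation", {
  a <- c("*CHI:\tI want the ball .", "*CHI:\tno .")
  b <- c("*CHI:\tshe's running because we play .")
  expect_equal(compute_metrics(parse_chat(c(a, b)))$TNW,
               compute_metrics(parse_chat(a))$TNW +
                 compute_metrics(parse_chat(b))$TNW)
})

test_that("the generator floor and verbal-ability monotonicity hold", {
  m0 <- compute_metrics(generate_transcript(0, seed = 21))
  expect_gte(m0$MLU, 1)
  expect_lte(m0$MLU, 2)

  tnw0 <- sapply(1:50, function(s) compute_metrics(generate_transcript(0, seed = s))$TNW)
  tnw1 <- sapply(1:50, function(s) compute_metrics(generate_transcript(1, seed = s))$TNW)
  expect_gt(mean(tnw1), mean(tnw0))
})
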