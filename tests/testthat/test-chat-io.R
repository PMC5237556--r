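test_that("a file with no participant lines yields an empty transcript", {
  t <- read_chat(c("@Begin", "*INV:\thello there .", "@End"))
  expect_s3_class(t, "ld_transcript")
  expect_length(t$utterances, 0)
  expect_true(all(marker_counts(t) == 0))
})

test_that("repetition marker parses to tokens plus one event", {
  t <- read_chat("*PAR:\tthe boy [/] the boy is falling .")
  u <- t$utterances[[1]]
  expect_equal(u$tokens, c("the", "boy", "the", "boy", "is", "falling"))
  expect_equal(u$terminator, "period")
  expect_equal(nrow(u$events), 1L)
  expect_equal(u$events$kind, "repetition")
  expect_equal(u$events$position, 1L)
  expect_equal(u$events$width, 2L)
})

test_that("noncompletion and trailing off are captured", {
  t <- read_chat("*PAR:\tshe is goi(ng) +...")
  u <- t$utterances[[1]]
  expect_equal(u$tokens, c("she", "is", "going"))
  expect_equal(u$terminator, "trailing_off")
  expect_true(u$incomplete[3])
  expect_equal(sum(u$events$kind == "incomplete_word"), 1L)
})

test_that("revision, filler and replacement markers are counted", {
  t <- read_chat(c("*PAR:\t<the boy> [//] the girl is smiling .",
                   "*PAR:\t&-uh the &-uh mother .",
                   "*PAR:\tsommat [: water] is running ."))
  mk <- marker_counts(t)
  expect_equal(unname(mk["revision"]), 1L)
  expect_equal(unname(mk["filler"]), 2L)
  expect_equal(unname(mk["replacement"]), 1L)
  # replacement substitutes the target word into the token stream
  expect_equal(t$utterances[[3]]$tokens, c("water", "is", "running"))
})

test_that("header metadata is read from @ID", {
  t <- read_chat(chat_fixture_lines())
  expect_equal(t$group, "PrADG")
  expect_equal(t$age, 71)
  expect_length(t$utterances, 5)   # investigator tier skipped
})

test_that("token positions are contiguous 1..n after marker stripping", {
  t <- read_chat(chat_fixture_lines())
  for (u in t$utterances) {
    expect_length(u$incomplete, length(u$tokens))
    if (nrow(u$events))
      expect_true(all(u$events$position >= 1 &
                      u$events$position <= max(length(u$tokens), 1)))
  }
})

test_that("malformed bracket group warns with the line number", {
  expect_warning(read_chat("*PAR:\tthe boy [/ the boy ."),
                 "line 1")
})

test_that("pauses, events and unintelligible tokens are stripped silently", {
  t <- read_chat("*PAR:\tthe (.) boy &=laughs xxx runs .")
  expect_equal(t$utterances[[1]]$tokens, c("the", "boy", "runs"))
  expect_equal(sum(marker_counts(t)), 0)
})

test_that("sentence grouping follows continuation terminators", {
  t <- read_chat(c("*PAR:\tthe boy +,",
                   "*PAR:\tis falling .",
                   "*PAR:\tthe girl smiles ."))
  groups <- lingdx:::sentence_groups(t)
  expect_length(groups, 2)
  expect_equal(groups[[1]], 1:2)
  expect_equal(groups[[2]], 3L)
})

test_that("read_chat_dir maps groups from a manifest", {
  dir <- withr::local_tempdir()
  writeLines(c("*PAR:\tthe boy ."), file.path(dir, "a.cha"))
  writeLines(c("*PAR:\tthe girl is here ."), file.path(dir, "b.cha"))
  man <- data.frame(subject_id = c("a", "b"), group = c("PrADG", "HEG"),
                    age = c(70, 65), path = c("a.cha", "b.cha"))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  ts <- read_chat_dir(dir, manifest = file.path(dir, "manifest.csv"))
  expect_equal(vapply(ts, function(t) t$group, ""), c("PrADG", "HEG"))
  expect_equal(vapply(ts, function(t) t$age, 0), c(70, 65))
})
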