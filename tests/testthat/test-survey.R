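test_that("reading a long CSV builds the structured dataset", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,identity,behaviour",
               "P1,A,b1", "P1,A,b2", "P1,B,"), f)
  s <- read_survey(f)
  ids <- participant_identities(s)
  expect_equal(names(ids), "p1")
  expect_equal(ids$p1, c("a", "b"))
  expect_equal(sort(s$behaviour[s$identity == "a"]), c("b1", "b2"))
  expect_equal(s$behaviour[s$identity == "b"], "")
})

test_that("duplicate rows collapse and labels are normalized", {
  df <- data.frame(participant_id = c("P1", "p1 ", "P1"),
                   identity = c("A", "a", "  A "),
                   behaviour = c("B1", "b1", "b1"))
  s <- as_survey(df)
  expect_equal(nrow(s), 1L)
  expect_equal(s$identity, "a")
  expect_equal(s$behaviour, "b1")
})

test_that("format violations are rejected", {
  expect_error(as_survey(data.frame(participant_id = "p1", behaviour = "b")),
               "missing column")
  expect_warning(
    s <- as_survey(data.frame(participant_id = c("p1", "p1"),
                              identity = c("a", ""),
                              behaviour = c("", "b"))),
    "empty identity")
  expect_equal(nrow(s), 1L)
})

test_that("participants over the 10-identity cap are kept with a warning", {
  df <- data.frame(participant_id = "p1", identity = sprintf("i%02d", 1:11),
                   behaviour = "")
  expect_warning(s <- as_survey(df), "more than 10")
  expect_equal(length(participant_identities(s)$p1), 11L)
})

test_that("write_survey round-trips", {
  s <- toy_survey()
  f <- withr::local_tempfile(fileext = ".csv")
  write_survey(s, f)
  expect_equal(read_survey(f), s, ignore_attr = TRUE)
})

test_that("summary statistics follow the (mean, sd, mode, min, max) contract", {
  s <- as_survey(data.frame(participant_id = c("p1", "p1", "p2"),
                            identity = c("a", "b", "a"),
                            behaviour = ""))
  sm <- summary(s)
  expect_equal(sm$n_participants, 2L)
  expect_equal(sm$identities_per_participant[["mean"]], 1.5)
  expect_equal(sm$identities_per_participant[["min"]], 1)
  expect_equal(sm$identities_per_participant[["max"]], 2)
  # sample SD with n - 1
  expect_equal(sm$identities_per_participant[["sd"]], sd(c(2, 1)))
  # mode ties resolve to the smallest value
  expect_equal(sm$identities_per_participant[["mode"]], 1)

  # one participant, 3 identities with 2, 1, 0 behaviours
  s2 <- as_survey(data.frame(
    participant_id = "p1",
    identity = c("a", "a", "b", "c"),
    behaviour = c("x", "y", "z", "")
  ))
  sm2 <- summary(s2)
  expect_equal(sm2$behaviours_per_person[["mean"]], 3)
  # per-identity stats are over identities listing at least one behaviour
  expect_equal(sm2$behaviours_per_identity[["mean"]], 1.5)
  expect_equal(sm2$behaviours_per_identity[["min"]], 1)
})

test_that("occurrence counts use the sample definitions of each vocabulary", {
  s <- toy_survey()
  ic <- identity_counts(s)
  expect_equal(ic[["a"]], 2L)  # participants reporting the identity
  expect_equal(ic[["b"]], 2L)
  expect_equal(ic[["c"]], 1L)
  bc <- behaviour_counts(s)
  expect_equal(bc[["x"]], 2L)  # (participant, identity) entries listing it
  expect_equal(bc[["y"]], 1L)
})

test_that("the node-frequency filter is strict and monotone", {
  counts <- c(A = 5L, B = 3L, C = 4L)
  expect_setequal(filter_items(counts, 3), c("A", "C"))
  expect_equal(filter_items(integer(0), 3), character(0))
  expect_equal(filter_items(c(A = 4L), 0), "A")
  # raising the threshold never adds labels
  for (t in 0:6) {
    expect_true(all(filter_items(counts, t + 1) %in% filter_items(counts, t)))
  }
})
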