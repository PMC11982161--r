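test_that("interval CSV parses and invariants are enforced", {
  path <- write_fixture_csv(data.frame(
    onset = c(0, 1.6), offset = c(1.6, 3), label = c("sounding", "silent")))
  ann <- read_annotation(path)
  expect_s3_class(ann, "interval_annotation")
  expect_equal(nrow(ann$intervals), 2)
  expect_equal(ann$total_duration, 3)

  expect_error(
    interval_annotation(data.frame(onset = c(0, 1.5), offset = c(2, 3),
                                   label = c("s", "s"))),
    "overlap")
  expect_error(
    interval_annotation(data.frame(onset = 1, offset = 0.5, label = "s")),
    "offset")
  bad <- write_fixture_csv(data.frame(start = 0, end = 1, lab = "s"))
  expect_error(read_annotation(bad), "missing required columns")
})

test_that("TextGrid tier selection returns only the requested tier", {
  path <- fixture_textgrid()
  ann <- read_annotation(path, tier = "silences")
  expect_equal(nrow(ann$intervals), 3)
  expect_equal(ann$intervals$label, c("sounding", "silent", "sounding"))
  expect_equal(ann$intervals$onset, c(0, 1.6, 3))
  expect_equal(ann$total_duration, 4)
  # two interval tiers present: tier must be named
  expect_error(read_annotation(path), "specify")
  expect_error(read_annotation(path, tier = "nope"), "not found")
})

test_that("binarize follows the overlap rules and drops partial bins", {
  ann <- interval_annotation(data.frame(
    onset = c(0, 1.6), offset = c(1.6, 3), label = c("sounding", "silent")))
  expect_equal(binarize(ann)$values, c(1L, 1L, 0L))  # bin [1,2) has 0.6 s

  short <- interval_annotation(data.frame(
    onset = c(0, 0.4), offset = c(0.4, 2), label = c("sounding", "silent")))
  expect_equal(binarize(short, "majority")$values, c(0L, 0L))
  expect_equal(binarize(short, "any_speech")$values, c(1L, 0L))

  silence <- interval_annotation(data.frame(
    onset = 0, offset = 5, label = "silent"))
  expect_equal(binarize(silence)$values, rep(0L, 5))

  # exact half-second overlap ties to speech
  tie <- interval_annotation(data.frame(
    onset = c(0, 0.5), offset = c(0.5, 1), label = c("sounding", "silent")))
  expect_equal(binarize(tie)$values, 1L)

  # trailing partial bin dropped, not padded
  trail <- interval_annotation(data.frame(
    onset = 0, offset = 2.9, label = "sounding"))
  expect_length(binarize(trail)$values, 2)
  expect_error(
    binarize(interval_annotation(data.frame(onset = 0, offset = 0.8,
                                            label = "sounding"))),
    "no complete bin")
})

test_that("majority output never exceeds any_speech elementwise", {
  set.seed(11)
  for (rep in 1:20) {
    cuts <- sort(runif(8, 0, 10))
    bounds <- unique(c(0, cuts, 10))
    labs <- sample(c("sounding", "silent"), length(bounds) - 1, replace = TRUE)
    ann <- interval_annotation(data.frame(
      onset = head(bounds, -1), offset = bounds[-1], label = labs))
    maj <- binarize(ann, "majority")$values
    any_ <- binarize(ann, "any_speech")$values
    expect_true(all(maj <= any_))
    expect_lte(sum(maj), length(maj))
  }
})

test_that("binarize is idempotent through its own exported intervals", {
  set.seed(7)
  s <- speech_series(rbinom(40, 1, 0.6), "d1", "p1", "introduction")
  again <- binarize(as_intervals(s), dyad_id = "d1", task = "introduction")
  expect_equal(again$values, s$values)
})

test_that("speech series CSV round-trips exactly", {
  set.seed(3)
  s <- speech_series(rbinom(25, 1, 0.4), "d2", "p3", "argumentative")
  path <- tempfile(fileext = ".csv")
  write_speech_series(s, path)
  back <- read_speech_series(path, dyad_id = "d2", participant_id = "p3",
                             task = "argumentative")
  expect_equal(back$values, s$values)
  expect_equal(back$task, "argumentative")
})

test_that("align_dyad truncates to the shorter series and checks metadata", {
  a <- speech_series(rbinom(301, 1, 0.5), "d1", "p1", "introduction")
  b <- speech_series(rbinom(299, 1, 0.5), "d1", "p2", "introduction")
  d <- align_dyad(a, b)
  expect_equal(d$n, 299)
  expect_length(d$series_a$values, 299)

  same <- align_dyad(
    speech_series(rep(1, 300), "d1", "p1", "introduction"),
    speech_series(rep(0, 300), "d1", "p2", "introduction"))
  expect_equal(same$n, 300)

  expect_error(
    align_dyad(speech_series(1, "d1", "p1"), speech_series(1, "d2", "p2")),
    "different dyads")
  expect_error(
    align_dyad(speech_series(1, "d1", "p1", "introduction"),
               speech_series(1, "d1", "p2", "argumentative")),
    "different tasks")
  expect_error(
    align_dyad(speech_series(1, "d1", "p1"), speech_series(1, "d1", "p1")),
    "same participant")
})
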