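unit_grid <- matrix(c(1, 1, 1,  0, 0, 0,  0, 1, 0), nrow = 3)
# rows: [1,0,0], [1,0,1], [1,0,0]; one full vertical line, a lone cell

test_that("line extraction finds maximal runs of at least l_min", {
  expect_equal(extract_lines(unit_grid, "vertical"), 3L)
  expect_equal(extract_lines(unit_grid, "horizontal"), integer(0))
  ones <- matrix(TRUE, 2, 2)
  expect_equal(extract_lines(ones, "vertical"), c(2L, 2L))
  expect_equal(extract_lines(ones, "horizontal"), c(2L, 2L))
  expect_error(extract_lines(ones, "vertical", l_min = 1), "l_min")
})

test_that("directional laminarity and trapping time on worked grids", {
  d <- align_dyad(speech_series(c(1, 1, 0), "d", "p1"),
                  speech_series(c(0, 0, 0), "d", "p2"))
  st <- line_statistics(build_crp(d))
  expect_equal(st$lam_ver, 1)
  expect_equal(st$lam_hor, 1)
  expect_equal(st$tt_ver, 3)
  expect_equal(st$tt_hor, 2)
  expect_equal(st$n_ver_lines, 2)
  expect_equal(st$n_hor_lines, 3)

  # fabricate a crp around the unit grid to exercise the lone-cell case
  crp <- structure(list(matrix = unit_grid == 1, n = 3),
                   class = "cross_recurrence_plot")
  st2 <- line_statistics(crp)
  expect_equal(st2$lam_ver, 0.75)
  expect_equal(st2$lam_hor, 0)
  expect_equal(st2$tt_ver, 3)
  expect_equal(st2$tt_hor, 0)

  empty <- build_crp(align_dyad(speech_series(c(0, 0, 0), "d", "p1"),
                                speech_series(c(0, 0, 0), "d", "p2")))
  st3 <- line_statistics(empty)
  expect_equal(unlist(st3[c("lam_ver", "lam_hor", "tt_ver", "tt_hor")]),
               c(lam_ver = 0, lam_hor = 0, tt_ver = 0, tt_hor = 0))
})

test_that("absolute relative differences follow the quotient convention", {
  st <- list(lam_ver = 0.75, lam_hor = 0, tt_ver = 3, tt_hor = 2)
  class(st) <- "line_statistics"
  expect_equal(lam_ard(st), 1)
  expect_equal(tt_ard(st), 0.2)
  st$lam_ver <- st$lam_hor <- 0.9
  st$tt_ver <- st$tt_hor <- 4
  expect_equal(lam_ard(st), 0)
  expect_equal(tt_ard(st), 0)
  st$lam_ver <- st$lam_hor <- 0
  st$tt_ver <- st$tt_hor <- 0
  expect_identical(lam_ard(st), 0)
  expect_identical(tt_ard(st), 0)
})

test_that("run-length extraction equals exhaustive cell-walk enumeration", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(5:64, 1)
    m <- matrix(runif(n * n) < runif(1, 0.2, 0.8), n, n)
    l_min <- sample(2:3, 1)
    expect_equal(sort(extract_lines(m, "vertical", l_min)),
                 sort(naive_runs(m, TRUE, l_min)))
    expect_equal(sort(extract_lines(m, "horizontal", l_min)),
                 sort(naive_runs(m, FALSE, l_min)))
  }
})

test_that("transposing the plot swaps directions and fixes the ARDs", {
  set.seed(21)
  for (rep in 1:15) {
    n <- sample(5:40, 1)
    m <- matrix(runif(n * n) < 0.5, n, n)
    c1 <- structure(list(matrix = m, n = n), class = "cross_recurrence_plot")
    c2 <- structure(list(matrix = t(m), n = n),
                    class = "cross_recurrence_plot")
    s1 <- line_statistics(c1); s2 <- line_statistics(c2)
    expect_identical(s1$lam_ver, s2$lam_hor)
    expect_identical(s1$lam_hor, s2$lam_ver)
    expect_identical(s1$tt_ver, s2$tt_hor)
    expect_identical(s1$tt_hor, s2$tt_ver)
    expect_equal(lam_ard(s1), lam_ard(s2))
    expect_equal(tt_ard(s1), tt_ard(s2))
    expect_true(s1$lam_ver >= 0 && s1$lam_ver <= 1)
    expect_true(s1$tt_ver == 0 || (s1$tt_ver >= 2 && s1$tt_ver <= n))
  }
})

test_that("vertical runs in column i are runs of b equal to 1 - a_i", {
  set.seed(33)
  d <- random_dyad(48, 0.6, 0.5)
  crp <- build_crp(d)
  a <- d$series_a$values; b <- d$series_b$values
  for (i in sample(48, 8)) {
    col_runs <- rle(crp$matrix[, i])
    got <- col_runs$lengths[col_runs$values]
    br <- rle(b)
    want <- br$lengths[br$values == (1 - a[i])]
    expect_equal(sort(got), sort(want))
  }
})

test_that("dyad_measures bundles all measures consistently", {
  # identical constant series: the plot is empty and everything cascades to 0
  same <- align_dyad(speech_series(rep(0L, 30), "d", "p1", "introduction"),
                     speech_series(rep(0L, 30), "d", "p2", "introduction"))
  dm0 <- dyad_measures(same)
  expect_equal(dm0$rr_global, 0)
  expect_equal(dm0$rr_los, 0)
  expect_equal(dm0$q_dcrp, 0)
  expect_equal(dm0$lam_ard, 0)
  expect_equal(dm0$tt_ard, 0)

  # identical non-constant series still never complement simultaneously
  set.seed(8)
  v <- rbinom(30, 1, 0.5)
  eq <- align_dyad(speech_series(v, "d", "p1", "introduction"),
                   speech_series(v, "d", "p2", "introduction"))
  expect_equal(dyad_measures(eq)$rr_los, 0)

  # anti-phase construction: perfect lag-zero coordination
  dm1 <- dyad_measures(antiphase_dyad(300))
  expect_equal(dm1$rr_los, 1)

  # swapped partners: dyad-level measures invariant, directions exchanged
  set.seed(2)
  d <- random_dyad(60, 0.6, 0.4)
  swapped <- d
  swapped$series_a <- d$series_b; swapped$series_b <- d$series_a
  swapped$series_a$participant_id <- "x"; swapped$series_b$participant_id <- "y"
  m1 <- dyad_measures(d); m2 <- dyad_measures(swapped)
  for (col in c("rr_global", "rr_los", "q_dcrp", "lam_ard", "tt_ard")) {
    expect_equal(m1[[col]], m2[[col]], info = col)
  }
  expect_equal(m1$lam_ver, m2$lam_hor)
  expect_equal(m1$tt_ver, m2$tt_hor)
})
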