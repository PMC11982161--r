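test_that("complementary matching fills the plot as XOR of the states", {
  d <- align_dyad(speech_series(c(1, 0), "d", "p1"),
                  speech_series(c(0, 1), "d", "p2"))
  crp <- build_crp(d)
  expect_equal(unname(crp$matrix),
               matrix(c(TRUE, FALSE, FALSE, TRUE), 2))
  expect_equal(recurrence_rate_global(crp), 0.5)

  same <- build_crp(align_dyad(speech_series(c(0, 0, 0), "d", "p1"),
                               speech_series(c(0, 0, 0), "d", "p2")))
  expect_true(all(!same$matrix))
  opp <- build_crp(align_dyad(speech_series(c(1, 1), "d", "p1"),
                              speech_series(c(0, 0), "d", "p2")))
  expect_true(all(opp$matrix))
  expect_equal(recurrence_rate_global(opp), 1)
})

test_that("recurrence rates match the worked parity examples", {
  par4 <- build_crp(align_dyad(speech_series(c(1, 0, 1, 0), "d", "p1"),
                               speech_series(c(0, 1, 0, 1), "d", "p2")))
  expect_equal(recurrence_rate_global(par4), 0.5)
  expect_equal(recurrence_rate_los(par4), 1)

  crp <- build_crp(align_dyad(speech_series(c(1, 0, 0, 1), "d", "p1"),
                              speech_series(c(0, 0, 1, 1), "d", "p2")))
  expect_equal(recurrence_rate_los(crp), 0.5)
})

test_that("diagonal profile has 2L+1 per-lag normalized entries", {
  par4 <- build_crp(align_dyad(speech_series(c(1, 0, 1, 0), "d", "p1"),
                               speech_series(c(0, 1, 0, 1), "d", "p2")))
  pr <- diagonal_profile(par4, 1)
  expect_equal(unname(pr$rr_by_lag), c(0, 1, 0))

  allrec <- build_crp(align_dyad(speech_series(c(1, 1, 1), "d", "p1"),
                                 speech_series(c(0, 0, 0), "d", "p2")))
  expect_equal(unname(diagonal_profile(allrec, 2)$rr_by_lag), rep(1, 5))

  set.seed(1)
  pr7 <- diagonal_profile(build_crp(random_dyad(20)), 3)
  expect_length(pr7$rr_by_lag, 7)
  expect_error(diagonal_profile(par4, 4), "max_lag")
  expect_error(diagonal_profile(par4, 0), "max_lag")
})

test_that("profile quotient hits its definitional extremes", {
  balanced <- dcrp_profile(-2:2, c(0.2, 0.2, 0.5, 0.2, 0.2))
  expect_identical(q_dcrp(balanced), 0)
  onesided <- dcrp_profile(-2:2, c(0, 0, 0, 0.3, 0.3))
  expect_identical(q_dcrp(onesided), 1)
  mixed <- dcrp_profile(-1:1, c(0.1, 0, 0.3))
  expect_equal(q_dcrp(mixed), 0.5)
  empty <- dcrp_profile(-1:1, c(0, 0.4, 0))
  expect_identical(q_dcrp(empty), 0)
})

test_that("all four profile measures equal the double-loop recount", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(8:64, 1)
    L <- sample(1:(n - 1), 1)
    d <- random_dyad(n, runif(1, 0.2, 0.8), runif(1, 0.2, 0.8))
    crp <- build_crp(d)
    ref <- naive_measures(d$series_a$values, d$series_b$values, L)
    expect_identical(recurrence_rate_global(crp), ref$rr_global)
    expect_identical(recurrence_rate_los(crp), ref$rr_los)
    pr <- diagonal_profile(crp, L)
    expect_equal(unname(pr$rr_by_lag), ref$rr_by_lag)
    expect_equal(q_dcrp(pr), ref$q_dcrp)
  }
})

test_that("swapping partners preserves rates and mirrors the profile", {
  set.seed(5)
  for (rep in 1:10) {
    d <- random_dyad(40, 0.6, 0.4)
    swapped <- d
    swapped$series_a <- d$series_b
    swapped$series_b <- d$series_a
    swapped$series_a$participant_id <- "p2"
    swapped$series_b$participant_id <- "p1"
    c1 <- build_crp(d); c2 <- build_crp(swapped)
    expect_equal(recurrence_rate_global(c1), recurrence_rate_global(c2))
    expect_equal(recurrence_rate_los(c1), recurrence_rate_los(c2))
    p1 <- diagonal_profile(c1, 6); p2 <- diagonal_profile(c2, 6)
    expect_equal(unname(p1$rr_by_lag), rev(unname(p2$rr_by_lag)))
    expect_equal(q_dcrp(p1), q_dcrp(p2))
  }
})

test_that("lag-zero profile entry equals the line-of-synchrony rate", {
  set.seed(9)
  for (rep in 1:10) {
    crp <- build_crp(random_dyad(50, runif(1), runif(1)))
    pr <- diagonal_profile(crp, 10)
    expect_identical(pr$rr_by_lag[["0"]], recurrence_rate_los(crp))
    expect_true(all(pr$rr_by_lag >= 0 & pr$rr_by_lag <= 1))
    expect_gte(q_dcrp(pr), 0)
    expect_lte(q_dcrp(pr), 1)
  }
})

test_that("independent Bernoulli dyads hit the analytic chance level", {
  set.seed(101)
  p <- 0.65; q <- 0.45
  rr <- replicate(300, recurrence_rate_global(build_crp(random_dyad(120, p, q))))
  expected <- p * (1 - q) + q * (1 - p)
  se <- sd(rr) / sqrt(length(rr))
  expect_lt(abs(mean(rr) - expected), 3 * se)
})

test_that("plot and profile exports write well-formed CSV", {
  d <- antiphase_dyad(6)
  crp <- build_crp(d)
  f1 <- tempfile(fileext = ".csv")
  write_crp_csv(crp, f1)
  pts <- read.csv(f1)
  expect_equal(nrow(pts), sum(crp$matrix))
  expect_true(all(crp$matrix[cbind(pts$j, pts$i)]))
  f2 <- tempfile(fileext = ".csv")
  write_profile_csv(diagonal_profile(crp, 2), f2)
  prof <- read.csv(f2)
  expect_equal(prof$lag, -2:2)
})
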