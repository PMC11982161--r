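# Brute-force oracles and small fixture builders, independent of the
# package's vectorized implementations.

random_dyad <- function(n, p = 0.5, q = 0.5, dyad_id = "d1",
                        task = "introduction") {
  align_dyad(
    speech_series(rbinom(n, 1, p), dyad_id, paste0(dyad_id, "_a"), task),
    speech_series(rbinom(n, 1, q), dyad_id, paste0(dyad_id, "_b"), task)
  )
}

# cell-by-cell double-loop recount of all recurrence measures
naive_measures <- function(a, b, max_lag, l_min = 2) {
  n <- length(a)
  m <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) m[j, i] <- a[i] != b[j]
  }
  rr_global <- sum(m) / n^2
  rr_los <- sum(diag(m)) / n
  lags <- -max_lag:max_lag
  rr <- numeric(length(lags))
  for (li in seq_along(lags)) {
    k <- lags[li]
    cnt <- 0L; len <- 0L
    for (t in seq_len(n)) {
      if (t + k >= 1 && t + k <= n) {
        len <- len + 1L
        if (a[t] != b[t + k]) cnt <- cnt + 1L
      }
    }
    rr[li] <- cnt / len
  }
  rr_left <- mean(rr[lags < 0]); rr_right <- mean(rr[lags > 0])
  q <- if (rr_left + rr_right == 0) 0 else
    abs(rr_right - rr_left) / (rr_right + rr_left)
  ls <- naive_line_stats(m, l_min)
  list(rr_global = rr_global, rr_los = rr_los, rr_by_lag = rr,
       rr_left = rr_left, rr_right = rr_right, q_dcrp = q,
       lam_ver = ls$lam_ver, lam_hor = ls$lam_hor,
       tt_ver = ls$tt_ver, tt_hor = ls$tt_hor)
}

# exhaustive cell-walk enumeration of vertical/horizontal lines
naive_runs <- function(m, vertical = TRUE, l_min = 2) {
  nr <- nrow(m); nc <- ncol(m)
  runs <- integer(0)
  outer_n <- if (vertical) nc else nr
  inner_n <- if (vertical) nr else nc
  for (o in seq_len(outer_n)) {
    len <- 0L
    for (i in seq_len(inner_n)) {
      cell <- if (vertical) m[i, o] else m[o, i]
      if (cell) {
        len <- len + 1L
      } else {
        if (len >= l_min) runs <- c(runs, len)
        len <- 0L
      }
    }
    if (len >= l_min) runs <- c(runs, len)
  }
  runs
}

naive_line_stats <- function(m, l_min = 2) {
  total <- sum(m)
  ver <- naive_runs(m, TRUE, l_min)
  hor <- naive_runs(m, FALSE, l_min)
  list(
    lam_ver = if (total > 0) sum(ver) / total else 0,
    lam_hor = if (total > 0) sum(hor) / total else 0,
    tt_ver = if (length(ver) > 0) mean(ver) else 0,
    tt_hor = if (length(hor) > 0) mean(hor) else 0
  )
}

# alternating anti-phase dyad: a = 1,0,1,0,..., b = complement
antiphase_dyad <- function(n) {
  a <- rep_len(c(1L, 0L), n)
  align_dyad(
    speech_series(a, "d1", "p1", "introduction"),
    speech_series(1L - a, "d1", "p2", "introduction")
  )
}

write_fixture_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

fixture_textgrid <- function() {
  path <- tempfile(fileext = ".TextGrid")
  writeLines(c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    '',
    'xmin = 0',
    'xmax = 4',
    'tiers? <exists>',
    'size = 2',
    'item []:',
    '    item [1]:',
    '        class = "IntervalTier"',
    '        name = "silences"',
    '        xmin = 0',
    '        xmax = 4',
    '        intervals: size = 3',
    '        intervals [1]:',
    '            xmin = 0',
    '            xmax = 1.6',
    '            text = "sounding"',
    '        intervals [2]:',
    '            xmin = 1.6',
    '            xmax = 3',
    '            text = "silent"',
    '        intervals [3]:',
    '            xmin = 3',
    '            xmax = 4',
    '            text = "sounding"',
    '    item [2]:',
    '        class = "IntervalTier"',
    '        name = "words"',
    '        xmin = 0',
    '        xmax = 4',
    '        intervals: size = 1',
    '        intervals [1]:',
    '            xmin = 0',
    '            xmax = 4',
    '            text = "hello"'
  ), path)
  path
}
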