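# Categorical cross-recurrence under complementary (speaker/listener)
# matching, and diagonal-profile measures of leader-follower asymmetry.
#
# A cell (j, i) of the cross-recurrence plot is recurrent exactly when one
# partner speaks while the other is silent at the paired times: a_i XOR b_j.
# Rows index partner B (vertical axis), columns partner A (horizontal axis).
# No Theiler window is excluded; the line of synchrony is part of the plot.

#' Build a categorical cross-recurrence plot
#'
#' @param d a [align_dyad()] result (equal-length binary series).
#' @return An object of class `cross_recurrence_plot` with elements `matrix`
#'   (logical, rows = time of series B, columns = time of series A), `n`, the
#'   two series, and `matching_rule = "complementary"`.
#' @export
build_crp <- function(d) {
  stopifnot(inherits(d, "dyad_series"))
  a <- d$series_a$values
  b <- d$series_b$values
  m <- outer(b, a, FUN = "!=")
  structure(
    list(matrix = m, n = d$n, a = a, b = b,
         dyad_id = d$series_a$dyad_id, task = d$series_a$task,
         matching_rule = "complementary"),
    class = "cross_recurrence_plot"
  )
}

#' @export
print.cross_recurrence_plot <- function(x, ...) {
  cat(sprintf("<cross_recurrence_plot> %d x %d, RR = %.3f (%s matching)\n",
              x$n, x$n, mean(x$matrix), x$matching_rule))
  invisible(x)
}

#' Global recurrence rate of a cross-recurrence plot
#'
#' Proportion of recurrent cells over the whole n-by-n plot: coordination at
#' all lags. Because matching is the XOR of the binary states, this equals
#' `(n1_a * n0_b + n0_a * n1_b) / n^2`, where `n1`/`n0` count each partner's
#' speech/silence seconds.
#'
#' @param crp a [build_crp()] result.
#' @return Rate in `[0, 1]`.
#' @export
recurrence_rate_global <- function(crp) {
  stopifnot(inherits(crp, "cross_recurrence_plot"))
  mean(crp$matrix)
}

#' Recurrence rate on the line of synchrony
#'
#' Proportion of seconds at which the two partners are in complementary
#' states simultaneously (lag-zero coordination).
#'
#' @param crp a [build_crp()] result.
#' @return Rate in `[0, 1]`.
#' @export
recurrence_rate_los <- function(crp) {
  stopifnot(inherits(crp, "cross_recurrence_plot"))
  mean(crp$a != crp$b)
}

#' Diagonal cross-recurrence profile
#'
#' Recurrence rate on each diagonal at offset `k` from the line of synchrony,
#' for `k` in `[-max_lag, +max_lag]`. Lag `k` pairs `a[t]` with `b[t + k]`, so
#' a positive lag means partner B's matching behavior follows partner A by
#' `k` seconds. Each diagonal is normalized by its own length `n - |k|`.
#'
#' @param crp a [build_crp()] result.
#' @param max_lag profile half-window in seconds (default 30); must be
#'   `< n`.
#' @return An object of class `dcrp_profile`; see [dcrp_profile()].
#' @export
diagonal_profile <- function(crp, max_lag = 30) {
  stopifnot(inherits(crp, "cross_recurrence_plot"))
  max_lag <- as.integer(max_lag)
  n <- crp$n
  if (max_lag < 1 || max_lag >= n) {
    stop("max_lag must satisfy 1 <= max_lag < n (n = ", n, ")", call. = FALSE)
  }
  dcrp_profile(seq.int(-max_lag, max_lag),
               dcrp_rates(crp$a, crp$b, max_lag))
}

# per-lag recurrence rates straight from the two series (the plot itself is
# never needed for diagonal measures)
dcrp_rates <- function(a, b, max_lag) {
  n <- length(a)
  vapply(seq.int(-max_lag, max_lag), function(k) {
    if (k >= 0) mean(a[seq_len(n - k)] != b[seq_len(n - k) + k])
    else        mean(a[seq_len(n + k) - k] != b[seq_len(n + k)])
  }, numeric(1))
}

#' Construct a diagonal profile from lag/rate pairs
#'
#' Used both by [diagonal_profile()] and to build hand-specified profiles
#' (e.g. idealized fully one-sided profiles) for which only the left/right
#' balance matters.
#'
#' @param lags integer lags, a symmetric consecutive range `-L:L`.
#' @param rr recurrence rate per lag, each in `[0, 1]`.
#' @return An object of class `dcrp_profile` with `rr_by_lag`, the half-window
#'   means `rr_left` (lags < 0) and `rr_right` (lags > 0), and `max_lag`.
#' @export
dcrp_profile <- function(lags, rr) {
  lags <- as.integer(lags)
  L <- max(lags)
  if (!identical(lags, seq.int(-L, L)) || L < 1) {
    stop("lags must be the consecutive range -L:L with L >= 1", call. = FALSE)
  }
  if (length(rr) != length(lags) || any(rr < 0 | rr > 1)) {
    stop("rr must hold one rate in [0, 1] per lag", call. = FALSE)
  }
  structure(
    list(max_lag = L, lags = lags, rr_by_lag = stats::setNames(rr, lags),
         rr_left = mean(rr[lags < 0]), rr_right = mean(rr[lags > 0])),
    class = "dcrp_profile"
  )
}

#' @export
print.dcrp_profile <- function(x, ...) {
  cat(sprintf(
    "<dcrp_profile> lags -%d..%d, RR(0) = %.3f, RR_left = %.3f, RR_right = %.3f\n",
    x$max_lag, x$max_lag, x$rr_by_lag[["0"]], x$rr_left, x$rr_right))
  invisible(x)
}

#' Absolute quotient of the diagonal cross-recurrence profile
#'
#' `|RR_right - RR_left| / (RR_right + RR_left)`, the normalized imbalance of
#' recurrence mass on the two sides of the line of synchrony: 0 for a
#' completely balanced interaction (equal leading and following), 1 when one
#' partner leads throughout. Defined as 0 when both half-window means are 0.
#'
#' @param profile a [dcrp_profile()].
#' @return Quotient in `[0, 1]`.
#' @export
q_dcrp <- function(profile) {
  stopifnot(inherits(profile, "dcrp_profile"))
  denom <- profile$rr_right + profile$rr_left
  if (denom == 0) return(0)
  abs(profile$rr_right - profile$rr_left) / denom
}

#' Export the recurrent cells of a plot as sparse coordinates
#'
#' @param crp a [build_crp()] result.
#' @param path CSV output path; columns `i` (time of series A) and `j`
#'   (time of series B), 1-based.
#' @export
write_crp_csv <- function(crp, path) {
  stopifnot(inherits(crp, "cross_recurrence_plot"))
  idx <- which(crp$matrix, arr.ind = TRUE)
  utils::write.csv(data.frame(i = idx[, "col"], j = idx[, "row"]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Plot a cross-recurrence plot
#'
#' @param x a [build_crp()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot.cross_recurrence_plot <- function(x, ...) {
  graphics::image(seq_len(x$n), seq_len(x$n), t(x$matrix) * 1,
                  col = c("white", "steelblue4"),
                  xlab = "time series A (s)", ylab = "time series B (s)",
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Export a diagonal profile as CSV
#'
#' @param profile a [dcrp_profile()].
#' @param path CSV output path; columns `lag`, `rr`.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "dcrp_profile"))
  utils::write.csv(data.frame(lag = profile$lags,
                              rr = unname(profile$rr_by_lag)),
                   path, row.names = FALSE)
  invisible(path)
}
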