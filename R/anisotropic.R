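# Anisotropic line structure of the cross-recurrence plot.
#
# Runs of recurrent cells along a column (vertical lines) are episodes in
# which partner A's momentary state co-occurs with a sustained run in partner
# B; horizontal lines are the converse. Directional laminarity (share of
# recurrent points on such lines) and trapping time (their mean length)
# quantify how strongly, and for how long, one partner "traps" the other;
# their absolute relative differences are the dyad-level asymmetry indices.

#' Extract maximal run lengths along one direction of a recurrence plot
#'
#' @param matrix logical (or 0/1) rectangular matrix; rows index series B,
#'   columns series A.
#' @param direction `"vertical"` (runs within columns) or `"horizontal"`
#'   (runs within rows).
#' @param l_min minimum line length retained, an integer `>= 2` (default 2).
#'   Runs touching the plot border count with their visible length.
#' @return Integer vector of line lengths `>= l_min` (possibly empty).
#' @export
extract_lines <- function(matrix, direction = c("vertical", "horizontal"),
                          l_min = 2) {
  direction <- match.arg(direction)
  if (l_min < 2) stop("l_min must be >= 2", call. = FALSE)
  m <- matrix != 0
  if (direction == "horizontal") m <- t(m)
  lens <- unlist(lapply(seq_len(ncol(m)), function(i) {
    r <- rle(m[, i])
    r$lengths[r$values]
  }), use.names = FALSE)
  if (is.null(lens)) lens <- integer(0)
  as.integer(lens[lens >= l_min])
}

#' Directional line statistics of a cross-recurrence plot
#'
#' For each direction, laminarity is the fraction of recurrent points lying
#' on lines of length at least `l_min` in that direction, and trapping time
#' the mean length of those lines. Both are 0 on a plot with no recurrent
#' points (laminarity) or no qualifying lines (trapping time).
#'
#' @param crp a [build_crp()] result.
#' @param l_min minimum line length (default 2).
#' @return An object of class `line_statistics` with `lam_ver`, `lam_hor`,
#'   `tt_ver`, `tt_hor`, the line counts, and `min_line_length`.
#' @export
line_statistics <- function(crp, l_min = 2) {
  stopifnot(inherits(crp, "cross_recurrence_plot"))
  if (l_min < 2) stop("l_min must be >= 2", call. = FALSE)
  if (!is.null(crp$a) && !is.null(crp$b)) {
    return(line_statistics_xor(crp$a, crp$b, l_min))
  }
  total <- sum(crp$matrix)
  ver <- extract_lines(crp$matrix, "vertical", l_min)
  hor <- extract_lines(crp$matrix, "horizontal", l_min)
  new_line_statistics(sum(ver), length(ver), sum(hor), length(hor),
                      total, l_min)
}

new_line_statistics <- function(sum_ver, n_ver, sum_hor, n_hor, total,
                                l_min) {
  structure(
    list(
      lam_ver = if (total > 0) sum_ver / total else 0,
      lam_hor = if (total > 0) sum_hor / total else 0,
      tt_ver = if (n_ver > 0) sum_ver / n_ver else 0,
      tt_hor = if (n_hor > 0) sum_hor / n_hor else 0,
      n_ver_lines = n_ver, n_hor_lines = n_hor,
      min_line_length = as.integer(l_min), n_recurrent = total
    ),
    class = "line_statistics"
  )
}

# O(n) line statistics exploiting the complementary-matching structure:
# the vertical runs in column i are exactly the maximal runs of b equal to
# 1 - a_i, so every column with a_i = 1 contributes b's silence runs and
# every column with a_i = 0 contributes b's speech runs (and symmetrically
# for rows). Agrees exactly with the generic matrix scan.
line_statistics_xor <- function(a, b, l_min) {
  n <- length(a)
  runs_of <- function(x, val) {
    r <- rle(x)
    r$lengths[r$values == val & r$lengths >= l_min]
  }
  ca1 <- sum(a); ca0 <- n - ca1
  cb1 <- sum(b); cb0 <- n - cb1
  total <- ca1 * cb0 + ca0 * cb1
  b0 <- runs_of(b, 0L); b1 <- runs_of(b, 1L)
  a0 <- runs_of(a, 0L); a1 <- runs_of(a, 1L)
  sum_ver <- ca1 * sum(b0) + ca0 * sum(b1)
  n_ver <- ca1 * length(b0) + ca0 * length(b1)
  sum_hor <- cb1 * sum(a0) + cb0 * sum(a1)
  n_hor <- cb1 * length(a0) + cb0 * length(a1)
  new_line_statistics(sum_ver, n_ver, sum_hor, n_hor, total, l_min)
}

#' @export
print.line_statistics <- function(x, ...) {
  cat(sprintf(
    "<line_statistics> LAM ver/hor = %.3f/%.3f, TT ver/hor = %.2f/%.2f (l_min = %d)\n",
    x$lam_ver, x$lam_hor, x$tt_ver, x$tt_hor, x$min_line_length))
  invisible(x)
}

# |x - y| / (x + y), 0 by convention when both are 0.
abs_rel_diff <- function(x, y) {
  if (x + y == 0) 0 else abs(x - y) / (x + y)
}

#' Absolute relative difference of directional laminarity
#'
#' `|LAM_ver - LAM_hor| / (LAM_ver + LAM_hor)`: the magnitude of asymmetry in
#' nonverbal interactional dominance. Low values indicate a balanced
#' interaction in which neither partner consistently takes the lead.
#'
#' @param stats a [line_statistics()] result.
#' @return Value in `[0, 1]`; 0 when both laminarities are 0.
#' @export
lam_ard <- function(stats) {
  stopifnot(inherits(stats, "line_statistics"))
  abs_rel_diff(stats$lam_ver, stats$lam_hor)
}

#' Absolute relative difference of directional trapping time
#'
#' `|TT_ver - TT_hor| / (TT_ver + TT_hor)`: asymmetry in how long each
#' partner's behavior captures the other's.
#'
#' @param stats a [line_statistics()] result.
#' @return Value in `[0, 1]`; 0 when both trapping times are 0.
#' @export
tt_ard <- function(stats) {
  stopifnot(inherits(stats, "line_statistics"))
  abs_rel_diff(stats$tt_ver, stats$tt_hor)
}

#' All dyad-level coordination measures for one dyad-task
#'
#' Bundles the five response measures (RR_global, RR_LOS, Q_DCRP, LAM_ARD,
#' TT_ARD) with the directional raw values they derive from, as one row.
#'
#' @param d a [align_dyad()] result.
#' @param max_lag diagonal-profile half-window in seconds (default 30;
#'   clamped to `n - 1` for short series).
#' @param l_min minimum line length for the anisotropic measures (default 2).
#' @return A one-row `data.frame` (class `dyad_measures`) with columns
#'   `dyad_id`, `task`, `speech_time` (combined speaking seconds of both
#'   partners), `rr_global`, `rr_los`, `rr_left`, `rr_right`, `q_dcrp`,
#'   `lam_ver`, `lam_hor`, `tt_ver`, `tt_hor`, `lam_ard`, `tt_ard`.
#' @export
dyad_measures <- function(d, max_lag = 30, l_min = 2) {
  stopifnot(inherits(d, "dyad_series"))
  crp <- build_crp(d)
  prof <- diagonal_profile(crp, max_lag = min(max_lag, crp$n - 1))
  stats <- line_statistics(crp, l_min = l_min)
  out <- data.frame(
    dyad_id = d$series_a$dyad_id,
    task = d$series_a$task,
    speech_time = sum(d$series_a$values) + sum(d$series_b$values),
    rr_global = recurrence_rate_global(crp),
    rr_los = recurrence_rate_los(crp),
    rr_left = prof$rr_left,
    rr_right = prof$rr_right,
    q_dcrp = q_dcrp(prof),
    lam_ver = stats$lam_ver,
    lam_hor = stats$lam_hor,
    tt_ver = stats$tt_ver,
    tt_hor = stats$tt_hor,
    lam_ard = lam_ard(stats),
    tt_ard = tt_ard(stats),
    stringsAsFactors = FALSE
  )
  class(out) <- c("dyad_measures", class(out))
  out
}
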