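# Interval annotations of speech/silence and their 1 Hz binarization.
#
# The raw material of the pipeline is a per-participant voice-activity
# annotation: an ordered set of non-overlapping (onset, offset, label)
# intervals in seconds, as produced by Praat's silence annotation or any
# diarization step. These are binned at 1 Hz into binary speech(1)/silence(0)
# series before any recurrence analysis.

VALID_TASKS <- c("introduction", "self_disclosure", "argumentative")

#' Construct an interval annotation
#'
#' @param intervals data.frame with numeric columns `onset`, `offset` and a
#'   character column `label`, ordered by onset. Times are seconds.
#' @param total_duration total recording duration in seconds; defaults to the
#'   last offset.
#' @param source_id identifier of the recording/participant the annotation
#'   belongs to.
#' @param label_map named numeric vector mapping labels to 1 (speech) or
#'   0 (silence). Labels absent from the map are treated as silence, matching
#'   Praat's convention where unlabeled stretches are non-speech.
#' @return An object of class `interval_annotation`.
#' @export
interval_annotation <- function(intervals, total_duration = NULL,
                                source_id = NA_character_,
                                label_map = c(sounding = 1, silent = 0)) {
  stopifnot(is.data.frame(intervals),
            all(c("onset", "offset", "label") %in% names(intervals)))
  intervals <- intervals[, c("onset", "offset", "label")]
  intervals$onset <- as.numeric(intervals$onset)
  intervals$offset <- as.numeric(intervals$offset)
  intervals$label <- as.character(intervals$label)
  if (nrow(intervals) > 0) {
    if (any(diff(intervals$onset) <= 0)) {
      stop("interval onsets must be strictly increasing", call. = FALSE)
    }
    if (any(intervals$offset <= intervals$onset)) {
      bad <- which(intervals$offset <= intervals$onset)[1]
      stop(sprintf("interval %d has offset <= onset", bad), call. = FALSE)
    }
    overlap <- which(intervals$onset[-1] < intervals$offset[-nrow(intervals)])
    if (length(overlap) > 0) {
      i <- overlap[1]
      stop(sprintf(
        "overlapping intervals: [%g, %g] and [%g, %g]",
        intervals$onset[i], intervals$offset[i],
        intervals$onset[i + 1], intervals$offset[i + 1]
      ), call. = FALSE)
    }
  }
  if (is.null(total_duration)) {
    total_duration <- if (nrow(intervals) > 0) max(intervals$offset) else 0
  }
  if (nrow(intervals) > 0 && total_duration < max(intervals$offset)) {
    stop("total_duration is shorter than the last interval offset",
         call. = FALSE)
  }
  if (!all(label_map %in% c(0, 1))) {
    stop("label_map values must be 0 (silence) or 1 (speech)", call. = FALSE)
  }
  structure(
    list(intervals = intervals, total_duration = as.numeric(total_duration),
         source_id = source_id, label_map = label_map),
    class = "interval_annotation"
  )
}

#' Read a speech/silence interval annotation from disk
#'
#' Accepts either a Praat TextGrid (long text format, interval tiers) or a CSV
#' with onset/offset/label columns.
#'
#' @param path file path; `.TextGrid`/`.textgrid` files are parsed as Praat
#'   TextGrids, anything else as CSV.
#' @param tier for TextGrids, the name of the interval tier to read; required
#'   when the file has more than one tier.
#' @param columns for CSV, a named character vector giving the onset, offset
#'   and label column names.
#' @param label_map see [interval_annotation()].
#' @return An `interval_annotation`.
#' @export
read_annotation <- function(path, tier = NULL,
                            columns = c(onset = "onset", offset = "offset",
                                        label = "label"),
                            label_map = c(sounding = 1, silent = 0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.textgrid$", path, ignore.case = TRUE)) {
    read_textgrid_tier(path, tier = tier, label_map = label_map)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing_cols <- setdiff(unname(columns), names(df))
    if (length(missing_cols) > 0) {
      stop("CSV is missing required columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    intervals <- data.frame(
      onset = df[[columns[["onset"]]]],
      offset = df[[columns[["offset"]]]],
      label = df[[columns[["label"]]]],
      stringsAsFactors = FALSE
    )
    interval_annotation(intervals, source_id = basename(path),
                        label_map = label_map)
  }
}

# Parse one interval tier out of a Praat TextGrid in long text format.
# Quoted values may in principle contain escaped quotes (""), rare in
# silence annotations; we unescape them.
read_textgrid_tier <- function(path, tier = NULL,
                               label_map = c(sounding = 1, silent = 0)) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  grab <- function(pattern, x) {
    m <- regmatches(x, regexec(pattern, x))
    vapply(m, function(g) if (length(g) >= 2) g[2] else NA_character_, "")
  }
  tier_starts <- grep("^\\s*item\\s*\\[\\d+\\]", lines)
  if (length(tier_starts) == 0) {
    stop("no tiers found in TextGrid: ", path, call. = FALSE)
  }
  tier_ends <- c(tier_starts[-1] - 1L, length(lines))
  tiers <- lapply(seq_along(tier_starts), function(i) {
    lines[tier_starts[i]:tier_ends[i]]
  })
  tier_names <- vapply(tiers, function(tl) {
    nm <- grab('name\\s*=\\s*"(.*)"', tl)
    nm <- nm[!is.na(nm)]
    if (length(nm) > 0) nm[1] else NA_character_
  }, "")
  is_interval <- vapply(tiers, function(tl) {
    any(grepl('class\\s*=\\s*"IntervalTier"', tl))
  }, logical(1))
  if (is.null(tier)) {
    if (sum(is_interval) != 1) {
      stop("TextGrid has ", sum(is_interval), " interval tiers (",
           paste(tier_names[is_interval], collapse = ", "),
           "); specify `tier`", call. = FALSE)
    }
    idx <- which(is_interval)
  } else {
    idx <- which(tier_names == tier & is_interval)
    if (length(idx) != 1) {
      stop("interval tier not found in TextGrid: ", tier, call. = FALSE)
    }
  }
  tl <- tiers[[idx]]
  xmin <- as.numeric(grab("xmin\\s*=\\s*([0-9.eE+-]+)", tl))
  xmax <- as.numeric(grab("xmax\\s*=\\s*([0-9.eE+-]+)", tl))
  text <- grab('text\\s*=\\s*"(.*)"', tl)
  tier_xmax <- xmax[!is.na(xmax)][1]  # first xmax in the item is the tier's
  keep <- !is.na(text)
  onset <- xmin[!is.na(xmin)]
  offset <- xmax[!is.na(xmax)]
  # drop the tier-level xmin/xmax header pair, leaving per-interval values
  n_int <- sum(keep)
  onset <- utils::tail(onset, n_int)
  offset <- utils::tail(offset, n_int)
  text <- gsub('""', '"', text[keep])
  intervals <- data.frame(onset = onset, offset = offset, label = text,
                          stringsAsFactors = FALSE)
  interval_annotation(intervals, total_duration = tier_xmax,
                      source_id = basename(path), label_map = label_map)
}

#' Construct a 1 Hz binary speech series
#'
#' @param values integer vector of 0 (silence) / 1 (speech), one per second.
#' @param dyad_id,participant_id identifiers.
#' @param task conversation task, one of `"introduction"`,
#'   `"self_disclosure"`, `"argumentative"`, or `NA`.
#' @return An object of class `speech_series`.
#' @export
speech_series <- function(values, dyad_id = NA_character_,
                          participant_id = NA_character_,
                          task = NA_character_) {
  values <- as.integer(values)
  if (length(values) < 1) stop("speech series must have length >= 1",
                               call. = FALSE)
  if (!all(values %in% c(0L, 1L))) {
    stop("speech series values must all be 0 or 1", call. = FALSE)
  }
  if (!is.na(task) && !task %in% VALID_TASKS) {
    stop("task must be one of: ", paste(VALID_TASKS, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(values = values, dyad_id = dyad_id,
         participant_id = participant_id, task = task),
    class = "speech_series"
  )
}

#' @export
print.speech_series <- function(x, ...) {
  cat(sprintf(
    "<speech_series> %d s, %.1f%% speech (dyad %s, participant %s, task %s)\n",
    length(x$values), 100 * mean(x$values), x$dyad_id, x$participant_id,
    x$task))
  invisible(x)
}

#' @export
length.speech_series <- function(x) length(x$values)

#' Bin an interval annotation into a 1 Hz binary speech series
#'
#' Each 1-second bin `[t, t+1)` is labeled speech or silence from the overlap
#' of speech-labeled intervals with that bin. Under the default majority rule
#' a bin is speech when speech covers at least 0.5 s of it (ties count as
#' speech); under `any_speech` any positive overlap suffices. A trailing
#' partial bin (< 1 s) is dropped.
#'
#' @param ann an [interval_annotation()].
#' @param rule `"majority"` (default) or `"any_speech"`.
#' @param dyad_id,participant_id,task metadata for the resulting series.
#' @return A [speech_series()] of `floor(total_duration)` bins.
#' @export
binarize <- function(ann, rule = c("majority", "any_speech"),
                     dyad_id = NA_character_, participant_id = NULL,
                     task = NA_character_) {
  stopifnot(inherits(ann, "interval_annotation"))
  rule <- match.arg(rule)
  if (is.null(participant_id)) participant_id <- ann$source_id
  n_bins <- floor(ann$total_duration)
  if (n_bins < 1) {
    stop("annotation shorter than 1 s: no complete bin", call. = FALSE)
  }
  overlap <- numeric(n_bins)
  lm <- ann$label_map
  for (i in seq_len(nrow(ann$intervals))) {
    lab <- ann$intervals$label[i]
    code <- if (lab %in% names(lm)) lm[[lab]] else 0
    if (code != 1) next
    on <- ann$intervals$onset[i]
    off <- min(ann$intervals$offset[i], n_bins)
    if (off <= on) next
    first <- floor(on)
    last <- min(ceiling(off) - 1, n_bins - 1)
    for (b in first:last) {
      overlap[b + 1] <- overlap[b + 1] +
        max(0, min(off, b + 1) - max(on, b))
    }
  }
  values <- if (rule == "majority") as.integer(overlap >= 0.5)
            else as.integer(overlap > 0)
  speech_series(values, dyad_id = dyad_id, participant_id = participant_id,
                task = task)
}

#' Convert a speech series back to merged speech/silence intervals
#'
#' Consecutive equal bins are merged into single intervals labeled with the
#' Praat silence-annotation labels (`"sounding"`/`"silent"`). Binarizing the
#' result reproduces the series exactly.
#'
#' @param s a [speech_series()].
#' @return An [interval_annotation()].
#' @export
as_intervals <- function(s) {
  stopifnot(inherits(s, "speech_series"))
  r <- rle(s$values)
  offs <- cumsum(r$lengths)
  ons <- c(0, offs[-length(offs)])
  intervals <- data.frame(
    onset = ons, offset = offs,
    label = ifelse(r$values == 1, "sounding", "silent"),
    stringsAsFactors = FALSE
  )
  interval_annotation(intervals, total_duration = length(s$values),
                      source_id = s$participant_id)
}

#' Pair two speech series into an aligned dyad
#'
#' The two series must share dyad id and task (when set) and come from
#' distinct participants; both are truncated to the shorter length so the
#' cross-recurrence plot is square.
#'
#' @param a,b [speech_series()] objects for the two partners. `a` is placed on
#'   the horizontal axis of the cross-recurrence plot, `b` on the vertical.
#' @return An object of class `dyad_series`.
#' @export
align_dyad <- function(a, b) {
  stopifnot(inherits(a, "speech_series"), inherits(b, "speech_series"))
  if (!is.na(a$dyad_id) && !is.na(b$dyad_id) && a$dyad_id != b$dyad_id) {
    stop("series belong to different dyads: ", a$dyad_id, " vs ", b$dyad_id,
         call. = FALSE)
  }
  if (!is.na(a$task) && !is.na(b$task) && a$task != b$task) {
    stop("series belong to different tasks: ", a$task, " vs ", b$task,
         call. = FALSE)
  }
  if (!is.na(a$participant_id) && !is.na(b$participant_id) &&
      identical(a$participant_id, b$participant_id)) {
    stop("both series come from the same participant", call. = FALSE)
  }
  n <- min(length(a$values), length(b$values))
  if (n < 1) stop("aligned dyad has length 0", call. = FALSE)
  a$values <- a$values[seq_len(n)]
  b$values <- b$values[seq_len(n)]
  structure(list(series_a = a, series_b = b, n = n), class = "dyad_series")
}

#' @export
print.dyad_series <- function(x, ...) {
  cat(sprintf("<dyad_series> dyad %s, task %s, %d s\n",
              x$series_a$dyad_id, x$series_a$task, x$n))
  invisible(x)
}

#' Write / read a speech series as CSV
#'
#' Columns `second_index` (0-based bin index) and `value`.
#'
#' @param s a [speech_series()].
#' @param path output file path.
#' @export
write_speech_series <- function(s, path) {
  stopifnot(inherits(s, "speech_series"))
  utils::write.csv(
    data.frame(second_index = seq_along(s$values) - 1L, value = s$values),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_speech_series
#' @param dyad_id,participant_id,task metadata attached on read.
#' @export
read_speech_series <- function(path, dyad_id = NA_character_,
                               participant_id = NA_character_,
                               task = NA_character_) {
  df <- utils::read.csv(path)
  stopifnot(all(c("second_index", "value") %in% names(df)))
  df <- df[order(df$second_index), ]
  speech_series(df$value, dyad_id = dyad_id,
                participant_id = participant_id, task = task)
}
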