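#' Detect stage bouts in a hypnogram
#'
#' A bout of a stage is initiated by two consecutive epochs of that stage and
#' is terminated when two consecutive epochs fail to match it; a single
#' non-matching epoch (of any other stage) inside a bout does not terminate
#' it. An open bout at the end of the recording is closed at the last
#' matching epoch. Epoch indices are 0-based and bout intervals are closed
#' `[start, end]`.
#'
#' @param series an [epoch_series()].
#' @param state stage to detect bouts of (`"W"`, `"N"` or `"R"`, long forms
#'   accepted).
#' @return data.frame with one row per bout and columns `state`, `start`,
#'   `end` (0-based epoch indices, inclusive) and `duration` (seconds,
#'   `(end - start + 1) * epoch_length`). Bouts are disjoint and sorted.
#' @examples
#' es <- epoch_series(c("W", "N", "N", "W", "N", "N", "W", "W"))
#' detect_bouts(es, "N")  # one bout spanning epochs 1..5
#' @export
detect_bouts <- function(series, state) {
  stopifnot(inherits(series, "epoch_series"))
  state <- match_stage(state)
  s <- series$states
  n <- length(s)
  if (n == 0L) stop("empty epoch series", call. = FALSE)

  empty <- data.frame(state = character(), start = integer(),
                      end = integer(), duration = numeric())
  b <- s == state
  if (!any(b)) return(empty)

  r <- rle(b)
  len <- r$lengths
  run_end <- cumsum(len)
  run_start <- run_end - len + 1L

  # Group matching runs: a FALSE run of length 1 bridges neighbouring runs,
  # a FALSE run of length >= 2 terminates the group.
  grp <- integer(length(len))
  g <- 0L
  open <- FALSE
  for (i in seq_along(len)) {
    if (r$values[i]) {
      if (!open) {
        g <- g + 1L
        open <- TRUE
      }
      grp[i] <- g
    } else if (len[i] >= 2L) {
      open <- FALSE
    }
  }

  starts <- integer(0)
  ends <- integer(0)
  for (gi in seq_len(g)) {
    runs <- which(grp == gi)
    # A bout opens only at a run of >= 2 consecutive matching epochs;
    # leading single-epoch runs in the group stay outside the bout.
    opener <- runs[len[runs] >= 2L][1L]
    if (is.na(opener)) next
    starts <- c(starts, run_start[opener])
    ends <- c(ends, run_end[runs[length(runs)]])
  }
  if (!length(starts)) return(empty)

  data.frame(
    state = state,
    start = starts - 1L,
    end = ends - 1L,
    duration = (ends - starts + 1L) * series$epoch_length
  )
}

#' Detect brief arousals inside sleep bouts
#'
#' A brief arousal is a single WAKE epoch strictly inside a NREM or REM
#' bout. By the bout-termination rule such epochs are always isolated
#' (flanked by non-wake epochs).
#'
#' @param series an [epoch_series()].
#' @param bouts optional bout table from [detect_bouts()] run on the same
#'   series; if omitted, NREM and REM bouts are detected internally. Only
#'   sleep-state bouts are considered.
#' @return data.frame with columns `index` (0-based epoch index of the wake
#'   epoch), `bout_state`, `bout_start`, `bout_end`.
#' @export
detect_brief_arousals <- function(series, bouts = NULL) {
  stopifnot(inherits(series, "epoch_series"))
  if (is.null(bouts)) {
    bouts <- rbind(detect_bouts(series, "N"), detect_bouts(series, "R"))
  }
  n <- length(series$states)
  bouts <- bouts[bouts$state %in% c("N", "R"), , drop = FALSE]
  if (nrow(bouts) && (min(bouts$start) < 0 || max(bouts$end) > n - 1L)) {
    stop("bout indices out of range for this series", call. = FALSE)
  }
  out <- data.frame(index = integer(), bout_state = character(),
                    bout_start = integer(), bout_end = integer())
  for (i in seq_len(nrow(bouts))) {
    inner <- seq.int(bouts$start[i] + 1L, length.out = max(0L, bouts$end[i] - bouts$start[i] - 1L))
    wake <- inner[series$states[inner + 1L] == "W"]
    if (length(wake)) {
      out <- rbind(out, data.frame(index = wake, bout_state = bouts$state[i],
                                   bout_start = bouts$start[i], bout_end = bouts$end[i]))
    }
  }
  out
}

#' Stage time in ZT-labeled bins
#'
#' Splits a recording into consecutive bins of `bin_hours` (starting at the
#' recording's first epoch and labeled on the ZT axis) and reports percent
#' time in each stage per bin. A partial trailing bin is dropped with a
#' warning.
#'
#' @param series an [epoch_series()].
#' @param bin_hours bin width in hours (default 3).
#' @return data.frame with one row per whole bin: `bin`, `zt_start`,
#'   `zt_end`, `n_epochs`, `pct_wake`, `pct_nrem`, `pct_rem`,
#'   `pct_total_sleep`. Percentages sum to 100 per bin;
#'   `pct_total_sleep = pct_nrem + pct_rem`.
#' @export
stage_time_binned <- function(series, bin_hours = 3) {
  stopifnot(inherits(series, "epoch_series"))
  if (!is.numeric(bin_hours) || length(bin_hours) != 1L || bin_hours <= 0) {
    stop("bin_hours must be a positive number of hours", call. = FALSE)
  }
  epb <- bin_hours * 3600 / series$epoch_length
  if (abs(epb - round(epb)) > 1e-9) {
    stop("bin_hours must correspond to a whole number of epochs", call. = FALSE)
  }
  epb <- as.integer(round(epb))
  n <- length(series$states)
  nbin <- n %/% epb
  if (nbin == 0L) stop("recording shorter than one bin", call. = FALSE)
  if (n %% epb != 0L) {
    warning(sprintf("dropping partial trailing bin (%d of %d epochs)",
                    n %% epb, epb), call. = FALSE)
  }
  bin_of <- rep(seq_len(nbin), each = epb)
  st <- series$states[seq_len(nbin * epb)]
  cnt <- function(lbl) tapply(st == lbl, bin_of, sum)
  w <- cnt("W"); nn <- cnt("N"); rr <- cnt("R")
  zt0 <- (series$start_zt + (seq_len(nbin) - 1L) * bin_hours) %% 24
  data.frame(
    bin = seq_len(nbin),
    zt_start = zt0,
    zt_end = (zt0 + bin_hours) %% 24,
    n_epochs = epb,
    pct_wake = 100 * w / epb,
    pct_nrem = 100 * nn / epb,
    pct_rem = 100 * rr / epb,
    pct_total_sleep = 100 * (nn + rr) / epb,
    row.names = NULL
  )
}

#' Bout count and median duration
#'
#' @param bouts bout table from [detect_bouts()].
#' @param window optional `c(from, to)` epoch-index window (0-based,
#'   inclusive); a bout belongs to the window of its start epoch. Default:
#'   all bouts.
#' @return list with `n_bouts` and `median_bout_duration` (seconds; `NA` when
#'   there are no bouts). The median of an even count is the mean of the two
#'   middle durations.
#' @export
bout_statistics <- function(bouts, window = NULL) {
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] <= window[2])
    bouts <- bouts[bouts$start >= window[1] & bouts$start <= window[2], , drop = FALSE]
  }
  if (nrow(bouts) == 0L) {
    return(list(n_bouts = 0L, median_bout_duration = NA_real_))
  }
  list(n_bouts = nrow(bouts),
       median_bout_duration = stats::median(bouts$duration))
}

#' Recovery-sleep summary over 24 h
#'
#' Computes the standard post-disruption recovery metric set over a 24-h
#' recording: percent total sleep, NREM and REM (of the full window), bout
#' counts and median bout durations per sleep state, and the brief-arousal
#' count.
#'
#' @param series an [epoch_series()] spanning 24 h (to within one epoch).
#' @return one-row data.frame with columns `pct_total_sleep`, `pct_nrem`,
#'   `pct_rem`, `pct_wake`, `n_nrem_bouts`, `median_nrem_bout_duration`,
#'   `n_rem_bouts`, `median_rem_bout_duration`, `n_brief_arousals`.
#' @export
recovery_summary <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  span <- span_hours(series)
  tol <- series$epoch_length / 3600
  if (abs(span - 24) > tol + 1e-9) {
    stop(sprintf("series spans %.3f h; recovery_summary needs 24 h (+/- one epoch)",
                 span), call. = FALSE)
  }
  n <- length(series$states)
  st <- series$states
  nb <- detect_bouts(series, "N")
  rb <- detect_bouts(series, "R")
  ns <- bout_statistics(nb)
  rs <- bout_statistics(rb)
  ar <- detect_brief_arousals(series, rbind(nb, rb))
  data.frame(
    pct_total_sleep = 100 * sum(st != "W") / n,
    pct_nrem = 100 * sum(st == "N") / n,
    pct_rem = 100 * sum(st == "R") / n,
    pct_wake = 100 * sum(st == "W") / n,
    n_nrem_bouts = ns$n_bouts,
    median_nrem_bout_duration = ns$median_bout_duration,
    n_rem_bouts = rs$n_bouts,
    median_rem_bout_duration = rs$median_bout_duration,
    n_brief_arousals = nrow(ar)
  )
}

#' Object location memory index
#'
#' `100 * t_moved / (t_moved + t_unmoved)`: percent of object-exploration
#' time spent on the moved object. 50 denotes chance; values significantly
#' above 50 indicate retained spatial memory.
#'
#' @param t_moved seconds exploring the moved object (>= 0).
#' @param t_unmoved seconds exploring the unmoved object (>= 0).
#' @return percent in `[0, 100]`.
#' @examples
#' location_index(45, 15)  # 75
#' @export
location_index <- function(t_moved, t_unmoved) {
  if (any(t_moved < 0) || any(t_unmoved < 0)) {
    stop("exploration times must be non-negative", call. = FALSE)
  }
  total <- t_moved + t_unmoved
  if (any(total == 0)) {
    stop("no object exploration (t_moved + t_unmoved = 0)", call. = FALSE)
  }
  100 * t_moved / total
}
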