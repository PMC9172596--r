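#' @keywords internal
"_PACKAGE"

# Canonical single-letter stage tokens; aliases accepted on input.
STAGES <- c("W", "N", "R")
STAGE_ALIASES <- c(
  W = "W", WAKE = "W", wake = "W",
  N = "N", NREM = "N", nrem = "N",
  R = "R", REM = "R", rem = "R"
)

match_stage <- function(state) {
  if (length(state) != 1L || is.na(state) || !state %in% names(STAGE_ALIASES)) {
    stop("unknown sleep stage label: ", deparse(state),
         " (expected one of W/WAKE, N/NREM, R/REM)", call. = FALSE)
  }
  unname(STAGE_ALIASES[state])
}

normalize_stages <- function(states) {
  states <- as.character(states)
  bad <- which(!states %in% names(STAGE_ALIASES))
  if (length(bad)) {
    stop("unknown stage token(s) ", paste(unique(states[bad]), collapse = ", "),
         " at position(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  unname(STAGE_ALIASES[states])
}

#' Scored sleep-stage epoch series
#'
#' Container for a hypnogram: an ordered sequence of scored sleep stages
#' (`W` wake, `N` NREM, `R` REM) at fixed epoch length, anchored to
#' Zeitgeber time (ZT; hours since light onset, ZT0 = lights on).
#'
#' @param states character vector of stage labels; `W`/`N`/`R` (the long
#'   forms `WAKE`/`NREM`/`REM` are accepted and normalized).
#' @param epoch_length epoch duration in seconds (default 10).
#' @param start_zt Zeitgeber time of the first epoch, hours in `[0, 24)`.
#' @param subject_id subject label.
#' @param factors optional named list of experimental factor levels
#'   (e.g. `diet`, `sleep_disruption`, `social_defeat`).
#' @return an object of class `epoch_series`.
#' @examples
#' es <- epoch_series(c("W", "N", "N", "R", "W"), start_zt = 6)
#' epoch_zt(es)
#' @export
epoch_series <- function(states, epoch_length = 10, start_zt = 0,
                         subject_id = "subject", factors = list()) {
  if (length(states) == 0L) stop("empty epoch series", call. = FALSE)
  states <- normalize_stages(states)
  if (!is.numeric(epoch_length) || length(epoch_length) != 1L || epoch_length <= 0) {
    stop("epoch_length must be a positive number of seconds", call. = FALSE)
  }
  if (!is.numeric(start_zt) || start_zt < 0 || start_zt >= 24) {
    stop("start_zt must lie in [0, 24)", call. = FALSE)
  }
  structure(
    list(states = states, epoch_length = epoch_length, start_zt = start_zt,
         subject_id = as.character(subject_id), factors = factors),
    class = "epoch_series"
  )
}

#' Zeitgeber time of each epoch
#'
#' @param series an [epoch_series()].
#' @return numeric vector of ZT hours in `[0, 24)`, one per epoch
#'   (epoch `k` (0-based) sits at `(start_zt + k * epoch_length/3600) mod 24`).
#' @export
epoch_zt <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  k <- seq_along(series$states) - 1L
  (series$start_zt + k * series$epoch_length / 3600) %% 24
}

#' @export
print.epoch_series <- function(x, ...) {
  hrs <- length(x$states) * x$epoch_length / 3600
  cat(sprintf("<epoch_series> %s: %d epochs x %gs (%.2f h), start ZT %.2f\n",
              x$subject_id, length(x$states), x$epoch_length, hrs, x$start_zt))
  tab <- table(factor(x$states, levels = STAGES))
  cat(sprintf("  W %.1f%%  N %.1f%%  R %.1f%%\n",
              100 * tab["W"] / length(x$states),
              100 * tab["N"] / length(x$states),
              100 * tab["R"] / length(x$states)))
  if (length(x$factors)) {
    cat("  factors:", paste(names(x$factors), unlist(x$factors),
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

span_hours <- function(series) {
  length(series$states) * series$epoch_length / 3600
}
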