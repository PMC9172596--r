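# Independent brute-force references for bout and brief-arousal detection:
# a literal epoch-by-epoch state machine transcribing the scoring rules,
# deliberately different from the package's run-length implementation.

oracle_bouts <- function(s, state) {
  n <- length(s)
  res <- list()
  open <- FALSE
  start <- NA_integer_
  last <- NA_integer_
  i <- 1L
  while (i <= n) {
    if (!open) {
      if (i < n && s[i] == state && s[i + 1L] == state) {
        open <- TRUE
        start <- i
        last <- i + 1L
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    } else {
      if (s[i] == state) {
        last <- i
        i <- i + 1L
      } else if (i < n && s[i + 1L] != state) {
        res[[length(res) + 1L]] <- c(start, last)
        open <- FALSE
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (open) res[[length(res) + 1L]] <- c(start, last)
  if (!length(res)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, res)
  data.frame(start = m[, 1] - 1L, end = m[, 2] - 1L)  # 0-based
}

oracle_arousals <- function(s) {
  idx <- integer(0)
  for (st in c("N", "R")) {
    b <- oracle_bouts(s, st)
    for (r in seq_len(nrow(b))) {
      inner <- seq.int(b$start[r] + 1L, length.out = max(0L, b$end[r] - b$start[r] - 1L))
      idx <- c(idx, inner[s[inner + 1L] == "W"])
    }
  }
  sort(idx)
}

expect_bouts_match_oracle <- function(s) {
  es <- epoch_series(s)
  for (st in c("W", "N", "R")) {
    got <- detect_bouts(es, st)
    want <- oracle_bouts(s, st)
    expect_identical(cbind(got$start, got$end), cbind(want$start, want$end))
  }
  expect_identical(sort(detect_brief_arousals(es)$index), oracle_arousals(s))
}

# small fixture: rooted 4-leaf star tree with unit branches
star_tree <- function(labels = c("A", "B", "C", "D")) {
  ape::read.tree(text = paste0("(", paste0(labels, ":1", collapse = ","), "):0;"))
}
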