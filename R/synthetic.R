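#' Synthetic study design
#'
#' Full-factorial 2 x 2 x 2 rodent study layout: diet (control/prebiotic) x
#' sleep disruption (undisturbed/disrupted) x social defeat (none/defeat),
#' `n_per_group` subjects per cell, four fecal-sampling timepoints (T1-T4),
#' 12:12 light:dark cycle, 10-s scored epochs, and a 5-day sleep-disruption
#' protocol active 20 h/day (ZT6-ZT2).
#'
#' @param n_per_group subjects per factor cell (default 10).
#' @param epoch_length epoch duration in seconds (default 10).
#' @param n_disruption_days length of the disruption protocol (default 5).
#' @return list of class `study_design` with a `subjects` data.frame
#'   (`subject_id`, `diet`, `sleep_disruption`, `social_defeat`).
#' @export
study_design <- function(n_per_group = 10, epoch_length = 10,
                         n_disruption_days = 5) {
  stopifnot(n_per_group >= 1, epoch_length > 0, n_disruption_days >= 1)
  grid <- expand.grid(
    diet = c("control", "prebiotic"),
    sleep_disruption = c("undisturbed", "disrupted"),
    social_defeat = c("none", "defeat"),
    stringsAsFactors = FALSE
  )
  subjects <- grid[rep(seq_len(nrow(grid)), each = n_per_group), ]
  subjects$subject_id <- sprintf("S%03d", seq_len(nrow(subjects)))
  rownames(subjects) <- NULL
  structure(list(
    subjects = subjects[, c("subject_id", "diet", "sleep_disruption", "social_defeat")],
    n_per_group = n_per_group,
    timepoints = c("T1", "T2", "T3", "T4"),
    epoch_length = epoch_length,
    n_disruption_days = n_disruption_days,
    disruption_window = c(on = 6, off = 2)  # ZT6 -> ZT2 next day (20 h)
  ), class = "study_design")
}

#' Hypnogram generation model
#'
#' First-order Markov chain over W/N/R at epoch resolution with
#' light/dark-specific transition matrices (one per ZT hour). REM is entered
#' only from NREM. Sleep disruption is modeled as forced wake during active
#' windows with a per-day escape probability (non-decreasing across days,
#' reflecting the protocol's declining efficacy); recovery sleep multiplies
#' wake-to-NREM entry by a rebound gain.
#'
#' @param light,dark 3x3 row-stochastic transition matrices (rows/cols in
#'   order W, N, R) for the light and dark phases.
#' @param escape_prob per-day probability that a disruption-window epoch
#'   follows the free-running chain instead of being forced to wake;
#'   non-decreasing, in `[0, 1]`.
#' @param rebound_gain default multiplicative gain on W->N during recovery.
#' @return list of class `hypnogram_model` with 24 per-ZT-hour matrices.
#' @export
hypnogram_model <- function(light = NULL, dark = NULL,
                            escape_prob = c(0.010, 0.020, 0.032, 0.046, 0.060),
                            rebound_gain = 1.8) {
  if (is.null(light)) {
    light <- rbind(c(0.90, 0.10, 0.00),
                   c(0.05, 0.93, 0.02),
                   c(0.08, 0.02, 0.90))
  }
  if (is.null(dark)) {
    dark <- rbind(c(0.970, 0.030, 0.000),
                  c(0.100, 0.885, 0.015),
                  c(0.100, 0.020, 0.880))
  }
  check_tm <- function(m, what) {
    if (!is.matrix(m) || any(dim(m) != 3) || any(m < 0) ||
        any(abs(rowSums(m) - 1) > 1e-8)) {
      stop(what, " transition matrix must be 3x3 row-stochastic", call. = FALSE)
    }
    if (m[1, 3] != 0) {
      stop(what, ": direct WAKE->REM transitions are disallowed", call. = FALSE)
    }
    dimnames(m) <- list(STAGES, STAGES)
    m
  }
  light <- check_tm(light, "light")
  dark <- check_tm(dark, "dark")
  if (any(escape_prob < 0) || any(escape_prob > 1) ||
      is.unsorted(escape_prob)) {
    stop("escape_prob must be non-decreasing probabilities", call. = FALSE)
  }
  hourly <- c(replicate(12, light, simplify = FALSE),
              replicate(12, dark, simplify = FALSE))
  structure(list(hourly = hourly, light = light, dark = dark,
                 escape_prob = escape_prob, rebound_gain = rebound_gain),
            class = "hypnogram_model")
}

# Stationary distribution of a transition matrix (left eigenvector).
stationary_distribution <- function(m) {
  e <- eigen(t(m))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# boost W->N by `gain`, shrinking W->W; cap so the row stays stochastic
apply_rebound <- function(m, gain) {
  if (gain == 1) return(m)
  wn <- min(0.95, m[1, 2] * gain)
  m[1, 1] <- m[1, 1] + m[1, 2] - wn
  m[1, 2] <- wn
  m
}

#' Simulate a hypnogram
#'
#' @param model a [hypnogram_model()].
#' @param hours recording span in hours (default 24).
#' @param start_zt Zeitgeber time of the first epoch.
#' @param epoch_length epoch duration in seconds.
#' @param disrupted simulate the sleep-disruption protocol: epochs whose ZT
#'   falls in the active window (ZT6-ZT2) are forced to wake unless an
#'   escape event (day-indexed probability) lets the chain run.
#' @param start_day protocol day of the first epoch (indexes
#'   `escape_prob`; days advance every 24 h of simulated time).
#' @param rebound_gain multiplicative gain on W->N entry (recovery sleep);
#'   default 1 (no rebound).
#' @param subject_id,factors passed to [epoch_series()].
#' @param seed optional integer seed.
#' @return an [epoch_series()].
#' @export
gen_hypnogram <- function(model, hours = 24, start_zt = 0, epoch_length = 10,
                          disrupted = FALSE, start_day = 1, rebound_gain = 1,
                          subject_id = "sim", factors = list(), seed = NULL) {
  stopifnot(inherits(model, "hypnogram_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(hours * 3600 / epoch_length))
  if (n < 1L) stop("recording span too short", call. = FALSE)
  zt <- (start_zt + (seq_len(n) - 1L) * epoch_length / 3600) %% 24
  hour <- pmin(23L, as.integer(zt)) + 1L
  day <- start_day + (seq_len(n) - 1L) %/% as.integer(86400 / epoch_length)
  esc <- model$escape_prob
  day <- pmin(day, length(esc))
  in_window <- disrupted & (zt >= 6 | zt < 2)

  # cumulative transition rows per ZT hour (with rebound applied)
  cum <- lapply(model$hourly, function(m) {
    t(apply(apply_rebound(m, rebound_gain), 1, cumsum))
  })
  u <- stats::runif(n)
  force_wake <- in_window & (stats::runif(n) >= esc[day])

  s <- integer(n)
  cur <- 1L  # start awake
  for (k in seq_len(n)) {
    if (force_wake[k]) {
      cur <- 1L
    } else {
      cur <- findInterval(u[k], cum[[hour[k]]][cur, ], left.open = TRUE) + 1L
    }
    s[k] <- cur
  }
  epoch_series(STAGES[s], epoch_length = epoch_length, start_zt = start_zt,
               subject_id = subject_id, factors = factors)
}

#' Synthesize per-epoch EEG signals with target band composition
#'
#' Each epoch's signal is band-limited Gaussian noise spectrally shaped so
#' the expected relative power per band matches the state's target vector
#' (frequency-domain shaping; content outside the band set is zero).
#'
#' @param series an [epoch_series()].
#' @param targets 3 x n_bands matrix of relative-power targets, rows named
#'   `W`, `N`, `R`, each row summing to 1. Defaults mimic wake
#'   (mixed/beta-rich), NREM (delta-dominant) and REM (theta-dominant) EEG.
#' @param sampling_rate sampling rate in Hz (default 100).
#' @param bands a [band_set()].
#' @param amplitude RMS scale of each epoch's signal; 0 produces flat
#'   signals (useful to exercise degenerate-input handling downstream).
#' @param guard_hz guard margin kept empty inside each band edge so that
#'   Welch-window leakage stays within the band (default 0.5 Hz, half the
#'   analysis resolution of a 2-s segment).
#' @param seed optional integer seed.
#' @return matrix (epochs x samples) with attributes `sampling_rate` and
#'   `bands`.
#' @export
gen_eeg_epochs <- function(series, targets = NULL, sampling_rate = 100,
                           bands = band_set(), amplitude = 1, guard_hz = 0.5,
                           seed = NULL) {
  stopifnot(inherits(series, "epoch_series"))
  if (is.null(targets)) {
    targets <- rbind(
      W = c(0.25, 0.30, 0.15, 0.10, 0.20),
      N = c(0.60, 0.15, 0.10, 0.10, 0.05),
      R = c(0.20, 0.45, 0.15, 0.10, 0.10)
    )
    colnames(targets) <- bands$name
  }
  targets <- as.matrix(targets)
  if (any(abs(rowSums(targets) - 1) > 1e-6)) {
    stop("each state's relative-power targets must sum to 1", call. = FALSE)
  }
  if (!all(STAGES %in% rownames(targets))) {
    stop("targets must have rows named W, N, R", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ns <- as.integer(round(series$epoch_length * sampling_rate))
  freq <- seq(0, ns %/% 2) * sampling_rate / ns
  band_of <- rep(NA_integer_, length(freq))
  for (i in seq_len(nrow(bands))) {
    lo <- bands$low[i] + guard_hz
    hi <- bands$high[i] - guard_hz
    if (hi <= lo) {  # band narrower than both guards: use its center
      lo <- (bands$low[i] + bands$high[i]) / 2 - 0.01
      hi <- lo + 0.02
    }
    band_of[freq >= lo & freq < hi] <- i
  }
  nb <- tabulate(band_of, nrow(bands))
  gains <- lapply(STAGES, function(st) {
    g2 <- numeric(length(freq))
    for (i in seq_len(nrow(bands))) {
      g2[which(band_of == i)] <- targets[st, i] / nb[i]
    }
    sqrt(g2)
  })
  names(gains) <- STAGES

  out <- matrix(0, length(series$states), ns)
  if (amplitude > 0) {
    for (k in seq_along(series$states)) {
      g <- gains[[series$states[k]]]
      X <- stats::fft(stats::rnorm(ns))
      # full-length gain: bins 1..nh+1 then the mirrored interior bins
      nh <- ns %/% 2
      full <- c(g, g[nh:2])
      x <- Re(stats::fft(X * full, inverse = TRUE)) / ns
      sdx <- stats::sd(x)
      if (sdx > 0) x <- x * amplitude / sdx
      out[k, ] <- x
    }
  }
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "bands") <- bands
  out
}

#' Microbiome generation model
#'
#' Log-normal relative abundances with a planted diet-driven bloom of one
#' feature, multinomial sequencing counts, and a random rooted bifurcating
#' phylogeny with exponential branch lengths.
#'
#' @param n_features number of features (default 50).
#' @param log_mean_sd SD of per-feature baseline log-abundance means.
#' @param sample_sd per-sample log-abundance noise SD.
#' @param bloom_feature index of the feature that blooms under the
#'   prebiotic diet.
#' @param bloom_fold named fold factors applied to the bloom feature's
#'   expected relative abundance at each post-baseline timepoint (defaults
#'   6.5 at T2, 7 at T3, 5 at T4).
#' @param bloom_subject_sd SD of each subject's persistent log-scale bloom
#'   deviation (couples microbiome to recovery sleep in [gen_study()]).
#' @param depth_meanlog,depth_sdlog log-normal sequencing-depth parameters.
#' @param low_depth_fraction fraction of samples whose depth is shrunk
#'   below the default rarefaction depth (exercises sample dropping).
#' @return list of class `microbiome_model`.
#' @export
microbiome_model <- function(n_features = 50, log_mean_sd = 1.5,
                             sample_sd = 0.6, bloom_feature = 1,
                             bloom_fold = c(T1 = 1, T2 = 6.5, T3 = 7, T4 = 5),
                             bloom_subject_sd = 0.6,
                             depth_meanlog = log(12000), depth_sdlog = 0.12,
                             low_depth_fraction = 0.05) {
  if (n_features < 10) stop("need at least 10 features", call. = FALSE)
  if (any(bloom_fold <= 0)) stop("fold factors must be positive", call. = FALSE)
  if (low_depth_fraction < 0 || low_depth_fraction >= 1) {
    stop("low_depth_fraction must lie in [0, 1)", call. = FALSE)
  }
  structure(as.list(environment()), class = "microbiome_model")
}

#' Generate a synthetic microbiome dataset
#'
#' One sample per subject and timepoint. Prebiotic-diet samples at
#' post-baseline timepoints have the bloom feature's expected relative
#' abundance multiplied by the timepoint's fold factor (plus the subject's
#' persistent deviation) before renormalization; counts are multinomial at
#' a log-normal depth.
#'
#' @param design a [study_design()].
#' @param model a [microbiome_model()].
#' @param seed optional integer seed.
#' @return list with `table` (a [feature_table()] whose metadata carries
#'   `subject_id`, `timepoint` and the design factors), `tree` (`phylo`)
#'   and `bloom_deviation` (named per-subject log-scale deviations).
#' @export
gen_microbiome <- function(design, model = microbiome_model(), seed = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(model, "microbiome_model"))
  if (!is.null(seed)) set.seed(seed)
  nf <- model$n_features
  fid <- sprintf("F%03d", seq_len(nf))
  mu <- stats::rnorm(nf, 0, model$log_mean_sd)
  mu[model$bloom_feature] <- 0  # keep the bloom taxon at a typical baseline
  subj <- design$subjects
  dev <- stats::rnorm(nrow(subj), 0, model$bloom_subject_sd)
  names(dev) <- subj$subject_id

  tps <- design$timepoints
  ids <- as.vector(outer(subj$subject_id, tps, paste, sep = "_"))
  counts <- matrix(0L, nf, length(ids), dimnames = list(fid, ids))
  meta <- data.frame(
    subject_id = rep(subj$subject_id, times = length(tps)),
    timepoint = rep(tps, each = nrow(subj)),
    diet = rep(subj$diet, times = length(tps)),
    sleep_disruption = rep(subj$sleep_disruption, times = length(tps)),
    social_defeat = rep(subj$social_defeat, times = length(tps)),
    row.names = ids
  )
  for (k in seq_along(ids)) {
    l <- mu + stats::rnorm(nf, 0, model$sample_sd)
    tp <- meta$timepoint[k]
    if (meta$diet[k] == "prebiotic" && tp %in% names(model$bloom_fold) &&
        model$bloom_fold[tp] != 1) {
      l[model$bloom_feature] <- l[model$bloom_feature] +
        log(model$bloom_fold[[tp]]) + dev[meta$subject_id[k]]
    }
    p <- exp(l - max(l))
    p <- p / sum(p)
    depth <- round(stats::rlnorm(1, model$depth_meanlog, model$depth_sdlog))
    if (stats::runif(1) < model$low_depth_fraction) {
      depth <- round(depth * 0.4)
    }
    counts[, k] <- stats::rmultinom(1, depth, p)
  }
  tree <- ape::rtree(nf, tip.label = sample(fid))
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 10)
  tax <- paste0("Bacteria;phylum", (seq_len(nf) - 1) %% 5 + 1,
                ";;order", (seq_len(nf) - 1) %% 8 + 1, ";;genus",
                seq_len(nf), ";species", seq_len(nf))
  list(table = feature_table(counts, taxonomy = tax, metadata = meta),
       tree = tree, bloom_deviation = dev)
}

#' Generate taxa-linked metabolite intensities
#'
#' Each acid's log-intensity is a baseline plus the sum of linked taxa's
#' clr values scaled by the link strengths, plus Gaussian noise; internal
#' standards are drawn near a constant. Raw intensities carry the
#' internal-standard scaling so that [normalize_bile_acids()] undoes it.
#'
#' @param table a [feature_table()] (samples define the rows of the
#'   output).
#' @param linkage data.frame with columns `taxon`, `acid` (1-based index or
#'   acid name), `strength` (signed); `NULL` for no planted links.
#' @param n_acids number of acids (default 20).
#' @param noise_sd log-intensity noise SD (default 0.5).
#' @param seed optional integer seed.
#' @return list with `intensities` (samples x acids) and
#'   `internal_standard` (per sample).
#' @export
gen_metabolites <- function(table, linkage = NULL, n_acids = 20,
                            noise_sd = 0.5, seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.null(seed)) set.seed(seed)
  samples <- colnames(table$counts)
  acids <- sprintf("BA%02d", seq_len(n_acids))
  clr <- clr_transform(table)
  base <- stats::rnorm(n_acids, 10, 1)
  li <- matrix(stats::rnorm(length(samples) * n_acids, 0, noise_sd),
               length(samples), n_acids,
               dimnames = list(samples, acids))
  li <- sweep(li, 2, base, "+")
  if (!is.null(linkage)) {
    bad <- setdiff(linkage$taxon, rownames(table$counts))
    if (length(bad)) {
      stop("unknown taxon in linkage: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (r in seq_len(nrow(linkage))) {
      ai <- if (is.numeric(linkage$acid[r])) linkage$acid[r] else
        match(linkage$acid[r], acids)
      li[, ai] <- li[, ai] + linkage$strength[r] * clr[linkage$taxon[r], samples]
    }
  }
  is0 <- pmax(1, stats::rnorm(length(samples), 1e6, 5e4))
  names(is0) <- samples
  intensities <- sweep(exp(li), 1, is0 / mean(is0), "*")
  list(intensities = intensities, internal_standard = is0)
}

#' Generate and write a full synthetic study bundle
#'
#' Simulates the complete protocol — baseline sleep, the disruption days,
#' 24 h of recovery sleep, microbiome samples at T1-T4, a phylogeny, and
#' T4 metabolite intensities — and writes every artifact with a JSON
#' manifest. Each subject's recovery rebound gain is the diet's base gain
#' plus `coupling` times the subject's bloom deviation (prebiotic group
#' only), planting the microbiome-to-recovery-sleep association.
#'
#' @param design a [study_design()].
#' @param hyp_model a [hypnogram_model()].
#' @param mic_model a [microbiome_model()].
#' @param dir output directory (created if needed).
#' @param phases subset of `c("baseline", "disruption", "recovery")` to
#'   simulate (default all).
#' @param rebound_gain named base recovery gains per diet.
#' @param coupling gain units per unit bloom deviation (prebiotic group).
#' @param linkage metabolite linkage passed to [gen_metabolites()];
#'   defaults to two links from the bloom feature.
#' @param seed integer seed (required: the bundle is fully reproducible).
#' @return (invisibly) list with `epochs` (per phase, lists of
#'   [epoch_series()]), `microbiome`, `metabolites`, `recovery_gain` and
#'   `manifest_path`.
#' @export
gen_study <- function(design = study_design(), hyp_model = hypnogram_model(),
                      mic_model = microbiome_model(), dir = NULL,
                      phases = c("baseline", "disruption", "recovery"),
                      rebound_gain = c(control = 1.8, prebiotic = 2.4),
                      coupling = 1.0, linkage = NULL, seed = 1) {
  stopifnot(inherits(design, "study_design"))
  phases <- match.arg(phases, several.ok = TRUE)
  set.seed(seed)
  mic <- gen_microbiome(design, mic_model, seed = NULL)
  subj <- design$subjects
  fid <- rownames(mic$table$counts)
  bloom_id <- fid[mic_model$bloom_feature]
  if (is.null(linkage)) {
    linkage <- data.frame(taxon = bloom_id, acid = c(1, 2),
                          strength = c(1.2, -0.8))
  }
  t4 <- rownames(mic$table$metadata)[mic$table$metadata$timepoint == "T4"]
  t4_table <- feature_table(mic$table$counts[, t4, drop = FALSE],
                            taxonomy = mic$table$taxonomy,
                            metadata = mic$table$metadata[t4, , drop = FALSE])
  met <- gen_metabolites(t4_table, linkage = linkage, seed = NULL)

  gain <- rebound_gain[subj$diet] +
    ifelse(subj$diet == "prebiotic", coupling * mic$bloom_deviation[subj$subject_id], 0)
  gain <- pmax(1, gain)
  names(gain) <- subj$subject_id

  epochs <- list()
  for (ph in phases) {
    epochs[[ph]] <- lapply(seq_len(nrow(subj)), function(i) {
      fac <- as.list(subj[i, c("diet", "sleep_disruption", "social_defeat")])
      switch(ph,
        baseline = gen_hypnogram(hyp_model, hours = 24, start_zt = 0,
                                 epoch_length = design$epoch_length,
                                 subject_id = subj$subject_id[i], factors = fac),
        disruption = gen_hypnogram(hyp_model,
                                   hours = 24 * design$n_disruption_days,
                                   start_zt = 6,
                                   epoch_length = design$epoch_length,
                                   disrupted = subj$sleep_disruption[i] == "disrupted",
                                   subject_id = subj$subject_id[i], factors = fac),
        recovery = gen_hypnogram(hyp_model, hours = 24, start_zt = 7,
                                 epoch_length = design$epoch_length,
                                 rebound_gain = if (subj$sleep_disruption[i] == "disrupted")
                                   gain[i] else 1,
                                 subject_id = subj$subject_id[i], factors = fac))
    })
    names(epochs[[ph]]) <- subj$subject_id
  }

  manifest_path <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character(0)
    kinds <- character(0)
    for (ph in names(epochs)) {
      f <- file.path(dir, paste0("epochs_", ph, ".csv"))
      write_epochs(epochs[[ph]], f)
      files <- c(files, f); kinds <- c(kinds, "epochs")
    }
    for (tp in design$timepoints) {
      sel <- rownames(mic$table$metadata)[mic$table$metadata$timepoint == tp]
      f <- file.path(dir, paste0("counts_", tp, ".tsv"))
      write_count_table(feature_table(mic$table$counts[, sel, drop = FALSE],
                                      taxonomy = mic$table$taxonomy), f)
      files <- c(files, f); kinds <- c(kinds, "table")
      f <- file.path(dir, paste0("metadata_", tp, ".tsv"))
      write_metadata(mic$table$metadata[sel, , drop = FALSE], f)
      files <- c(files, f); kinds <- c(kinds, "metadata")
    }
    f <- file.path(dir, "tree.nwk")
    ape::write.tree(mic$tree, f)
    files <- c(files, f); kinds <- c(kinds, "tree")
    f <- file.path(dir, "metabolites.tsv")
    write_metabolites(met$intensities, met$internal_standard, f)
    files <- c(files, f); kinds <- c(kinds, "metabolites")
    manifest_path <- file.path(dir, "manifest.json")
    write_manifest(files, kinds, manifest_path)
  }

  invisible(list(design = design, epochs = epochs, microbiome = mic,
                 metabolites = met, recovery_gain = gain,
                 manifest_path = manifest_path))
}
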