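#' Read scored epochs from CSV
#'
#' Expects columns `subject_id, epoch_index, zt, state` (state tokens
#' `W`/`N`/`R`), long format with one or more subjects. Extra columns named
#' after design factors (`diet`, `sleep_disruption`, `social_defeat`) are
#' carried into each series' `factors`.
#'
#' @param path CSV file.
#' @param epoch_length epoch duration in seconds (default 10).
#' @return named list of [epoch_series()], one per subject.
#' @export
read_epochs <- function(path, epoch_length = 10) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  need <- c("subject_id", "epoch_index", "zt", "state")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$state %in% names(STAGE_ALIASES))
  if (length(bad)) {
    stop(sprintf("unknown state token '%s' at line %d of %s",
                 df$state[bad[1]], bad[1] + 1L, path), call. = FALSE)
  }
  fac_cols <- intersect(c("diet", "sleep_disruption", "social_defeat"),
                        colnames(df))
  out <- lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$epoch_index), ]
    if (!identical(as.integer(d$epoch_index),
                   seq.int(0L, length.out = nrow(d)))) {
      stop("non-contiguous epoch indices for subject ", d$subject_id[1],
           call. = FALSE)
    }
    epoch_series(d$state, epoch_length = epoch_length, start_zt = d$zt[1],
                 subject_id = d$subject_id[1],
                 factors = if (length(fac_cols)) as.list(d[1, fac_cols, drop = FALSE])
                           else list())
  })
  out[unique(df$subject_id)]
}

#' Write scored epochs to CSV
#'
#' @param series an [epoch_series()] or a list of them.
#' @param path output CSV file.
#' @return the path, invisibly.
#' @export
write_epochs <- function(series, path) {
  if (inherits(series, "epoch_series")) series <- list(series)
  rows <- lapply(series, function(es) {
    d <- data.frame(subject_id = es$subject_id,
                    epoch_index = seq_along(es$states) - 1L,
                    zt = round(epoch_zt(es), 6),
                    state = es$states)
    for (f in names(es$factors)) d[[f]] <- es$factors[[f]]
    d
  })
  data.table::fwrite(data.table::rbindlist(rows, fill = TRUE), path)
  invisible(path)
}

#' Read a taxon-by-sample count table from TSV
#'
#' Features as rows with `feature_id` and `taxonomy` columns followed by
#' one column per sample.
#'
#' @param path TSV file.
#' @param metadata_path optional metadata TSV (first column = sample id).
#' @return a [feature_table()].
#' @export
read_count_table <- function(path, metadata_path = NULL) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("feature_id", "taxonomy")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  counts <- as.matrix(df[, setdiff(colnames(df), need), drop = FALSE])
  rownames(counts) <- df$feature_id
  if (any(counts < 0)) stop("negative counts in ", path, call. = FALSE)
  meta <- if (is.null(metadata_path)) NULL else read_metadata(metadata_path)
  feature_table(counts, taxonomy = df$taxonomy, metadata = meta)
}

#' Write a count table to TSV
#' @param table a [feature_table()].
#' @param path output TSV file.
#' @return the path, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(feature_id = rownames(table$counts),
                   taxonomy = if (is.null(table$taxonomy)) "" else
                     unname(table$taxonomy),
                   table$counts, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read sample metadata from TSV (first column = sample id)
#' @param path TSV file.
#' @return data.frame with sample ids as rownames.
#' @export
read_metadata <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  rownames(df) <- df[[1]]
  df[, -1, drop = FALSE]
}

#' Write sample metadata to TSV
#' @param metadata data.frame with sample ids as rownames.
#' @param path output TSV file.
#' @return the path, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  df <- data.frame(sample_id = rownames(metadata), metadata,
                   check.names = FALSE, row.names = NULL)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a rooted Newick tree
#'
#' @param path Newick file.
#' @param features optional feature ids that must all map to leaves.
#' @return an `ape::phylo` tree (validated: rooted, branch lengths >= 0).
#' @export
read_tree <- function(path, features = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file ", path, call. = FALSE)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree must carry non-negative branch lengths", call. = FALSE)
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (!is.null(features)) {
    miss <- setdiff(features, tree$tip.label)
    if (length(miss)) {
      stop("feature(s) missing from tree: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  tree
}

#' Read a square distance matrix from TSV
#'
#' @param path TSV with a header row and a leading id column.
#' @return validated symmetric matrix (zero diagonal, non-negative).
#' @export
read_distances <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (!identical(colnames(m), ids)) {
    stop("distance matrix row/column ids disagree in ", path, call. = FALSE)
  }
  if (any(m < 0)) stop("negative distances in ", path, call. = FALSE)
  if (any(abs(diag(m)) > 1e-12)) stop("nonzero diagonal in ", path, call. = FALSE)
  asym <- which(abs(m - t(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(asym)) {
    stop(sprintf("asymmetric distances, e.g. d(%s,%s) != d(%s,%s)",
                 ids[asym[1, 1]], ids[asym[1, 2]],
                 ids[asym[1, 2]], ids[asym[1, 1]]), call. = FALSE)
  }
  m
}

#' Write a distance matrix to TSV
#' @param dm symmetric matrix with sample ids.
#' @param path output TSV file.
#' @return the path, invisibly.
#' @export
write_distances <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm), dm, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read metabolite intensities from TSV
#'
#' Expects `sample_id`, `internal_standard`, then one column per acid.
#'
#' @param path TSV file.
#' @return list with `intensities` (samples x acids) and
#'   `internal_standard`.
#' @export
read_metabolites <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("sample_id", "internal_standard")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(colnames(df), need), drop = FALSE])
  rownames(m) <- df$sample_id
  if (any(m < 0)) stop("negative intensities in ", path, call. = FALSE)
  is0 <- df$internal_standard
  names(is0) <- df$sample_id
  list(intensities = m, internal_standard = is0)
}

#' Write metabolite intensities to TSV
#' @param intensities samples x acids matrix.
#' @param internal_standard per-sample internal-standard values.
#' @param path output TSV file.
#' @return the path, invisibly.
#' @export
write_metabolites <- function(intensities, internal_standard, path) {
  df <- data.frame(sample_id = rownames(intensities),
                   internal_standard = unname(internal_standard[rownames(intensities)]),
                   intensities, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Write a JSON manifest for a set of files
#'
#' Records each file's path (relative to the manifest), kind, row count and
#' MD5 checksum.
#'
#' @param files file paths.
#' @param kinds one kind per file (`epochs`, `table`, `metadata`, `tree`,
#'   `distances`, `metabolites`, `network`, `summary`).
#' @param path manifest output path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(files, kinds, path) {
  stopifnot(length(files) == length(kinds))
  n_rows <- vapply(files, function(f) {
    length(readLines(f, warn = FALSE))
  }, integer(1))
  entries <- data.frame(
    file = basename(files),
    kind = kinds,
    n_rows = unname(n_rows),
    md5 = unname(tools::md5sum(files))
  )
  jsonlite::write_json(entries, path, pretty = TRUE)
  invisible(path)
}

#' Verify a manifest
#'
#' Checks that every listed file exists next to the manifest and that its
#' checksum and row count match.
#'
#' @param path manifest JSON path.
#' @return the manifest data.frame, invisibly; errors on any mismatch.
#' @export
verify_manifest <- function(path) {
  entries <- jsonlite::fromJSON(path)
  dir <- dirname(path)
  for (i in seq_len(nrow(entries))) {
    f <- file.path(dir, entries$file[i])
    if (!file.exists(f)) stop("manifest file missing: ", f, call. = FALSE)
    if (unname(tools::md5sum(f)) != entries$md5[i]) {
      stop("checksum mismatch for ", f, call. = FALSE)
    }
    if (length(readLines(f, warn = FALSE)) != entries$n_rows[i]) {
      stop("row-count mismatch for ", f, call. = FALSE)
    }
  }
  invisible(entries)
}
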