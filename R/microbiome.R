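#' Taxon-by-sample count table
#'
#' @param counts features x samples matrix of non-negative integers with
#'   rownames (feature ids) and colnames (sample ids).
#' @param taxonomy optional character vector of semicolon-delimited rank
#'   labels, one per feature.
#' @param metadata optional data.frame of sample metadata, rownames = sample
#'   ids; must cover every sample.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(counts, taxonomy = NULL, metadata = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("F%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("S%03d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids", call. = FALSE)
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-9)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    stopifnot(length(taxonomy) == nrow(counts))
    taxonomy <- as.character(taxonomy)
    names(taxonomy) <- rownames(counts)
  }
  if (!is.null(metadata)) {
    missing <- setdiff(colnames(counts), rownames(metadata))
    if (length(missing)) {
      stop("metadata missing for sample(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    metadata <- metadata[colnames(counts), , drop = FALSE]
  }
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples, depth %d-%d reads\n",
              nrow(x$counts), ncol(x$counts),
              min(colSums(x$counts)), max(colSums(x$counts))))
  if (!is.null(x$metadata)) {
    cat("  metadata:", paste(colnames(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Rarefy a count table to even depth
#'
#' Samples whose total is below `depth` are removed (with a warning naming
#' them); remaining samples are subsampled uniformly without replacement to
#' exactly `depth` reads.
#'
#' @param table a [feature_table()].
#' @param depth target reads per sample (default 9000).
#' @param seed optional integer seed for reproducible subsampling.
#' @return a rarefied [feature_table()].
#' @export
rarefy <- function(table, depth = 9000, seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  totals <- colSums(table$counts)
  drop <- totals < depth
  if (all(drop)) stop("all samples fall below the rarefaction depth", call. = FALSE)
  if (any(drop)) {
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(colnames(table$counts)[drop], collapse = ", "), call. = FALSE)
  }
  keep <- table$counts[, !drop, drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  # counts are validated integers; silence vegan's smallest-count heuristic
  rar <- t(suppressWarnings(vegan::rrarefy(t(keep), depth)))
  meta <- if (is.null(table$metadata)) NULL else
    table$metadata[colnames(keep), , drop = FALSE]
  feature_table(rar, taxonomy = table$taxonomy, metadata = meta)
}

#' Alpha diversity
#'
#' @param table a [feature_table()].
#' @param metric `"observed"` (feature richness), `"pielou"` (evenness
#'   `J = H'/ln S`, Shannon `H'` in nats; `NA` when `S <= 1`) or
#'   `"faith_pd"` (total branch length of the minimal rooted subtree
#'   connecting the observed features, root path included).
#' @param tree rooted `phylo` with branch lengths; required for
#'   `"faith_pd"`, whose observed features must all map to leaves.
#' @return named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(table, metric = c("observed", "pielou", "faith_pd"),
                            tree = NULL) {
  stopifnot(inherits(table, "feature_table"))
  metric <- match.arg(metric)
  x <- table$counts
  if (metric == "observed") return(colSums(x > 0))
  if (metric == "pielou") {
    return(apply(x, 2, function(v) {
      p <- v[v > 0] / sum(v)
      s <- length(p)
      if (s <= 1L) return(NA_real_)
      -sum(p * log(p)) / log(s)
    }))
  }
  # faith_pd
  if (is.null(tree)) stop("faith_pd requires a phylogenetic tree", call. = FALSE)
  em <- edge_tip_matrix(tree)
  obs_feats <- rownames(x)[rowSums(x) > 0]
  unmapped <- setdiff(obs_feats, tree$tip.label)
  if (length(unmapped)) {
    stop("feature(s) not on the tree: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  apply(x, 2, function(v) {
    tips <- tree$tip.label %in% rownames(x)[v > 0]
    if (!any(tips)) return(0)
    sum(tree$edge.length[as.vector(tips %*% em) > 0])
  })
}

# tips x edges incidence: em[t, e] TRUE iff tip t descends from edge e's child.
edge_tip_matrix <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  nt <- length(tree$tip.label)
  ne <- nrow(tree$edge)
  em <- matrix(FALSE, nt, ne)
  # accumulate tip sets child-before-parent
  sets <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- i
  ord <- ape::postorder(tree)
  for (e in ord) {
    ch <- tree$edge[e, 2L]
    em[sets[[ch]], e] <- TRUE
    pa <- tree$edge[e, 1L]
    sets[[pa]] <- c(sets[[pa]], sets[[ch]])
  }
  em
}

#' UniFrac distance between two samples
#'
#' Unweighted UniFrac is the fraction of branch length unique to one
#' sample's observed descendants over the branch length spanned by either;
#' weighted UniFrac is `sum_b len(b) * |p_a(b) - p_b(b)|` with `p` the
#' proportion of a sample's reads descending through branch `b`
#' (unnormalized by default; `normalized = TRUE` divides by
#' `sum_b len(b) * (p_a(b) + p_b(b))`).
#'
#' @param table a [feature_table()].
#' @param tree rooted `phylo` covering the observed features.
#' @param a,b sample ids or column indices.
#' @param weighted logical; abundance-weighted variant.
#' @param normalized logical; normalize the weighted variant to `[0, 1]`.
#' @return a single distance.
#' @export
unifrac <- function(table, tree, a, b, weighted = FALSE, normalized = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  em <- edge_tip_matrix(tree)
  unifrac_pair(table, tree, em, a, b, weighted, normalized)
}

unifrac_pair <- function(table, tree, em, a, b, weighted, normalized) {
  x <- table$counts
  va <- x[, a]; vb <- x[, b]
  if (sum(va) == 0 || sum(vb) == 0) {
    stop("UniFrac undefined for an empty (all-zero) sample", call. = FALSE)
  }
  obs <- rownames(x)
  unmapped <- setdiff(obs[va > 0 | vb > 0], tree$tip.label)
  if (length(unmapped)) {
    stop("feature(s) not on the tree: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  tip_of <- match(tree$tip.label, obs)
  ta <- ifelse(is.na(tip_of), 0, va[tip_of])
  tb <- ifelse(is.na(tip_of), 0, vb[tip_of])
  len <- tree$edge.length
  if (!weighted) {
    ina <- as.vector((ta > 0) %*% em) > 0
    inb <- as.vector((tb > 0) %*% em) > 0
    union_len <- sum(len[ina | inb])
    if (union_len == 0) return(0)
    return(sum(len[xor(ina, inb)]) / union_len)
  }
  pa <- as.vector((ta / sum(ta)) %*% em)
  pb <- as.vector((tb / sum(tb)) %*% em)
  d <- sum(len * abs(pa - pb))
  if (normalized) {
    denom <- sum(len * (pa + pb))
    if (denom == 0) return(0)
    d <- d / denom
  }
  d
}

#' All-pairs UniFrac distance matrix
#'
#' @inheritParams unifrac
#' @return symmetric matrix of distances with zero diagonal.
#' @export
unifrac_matrix <- function(table, tree, weighted = FALSE, normalized = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  em <- edge_tip_matrix(tree)
  ids <- colnames(table$counts)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- unifrac_pair(table, tree, em, i, j,
                                         weighted, normalized)
    }
  }
  d
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate ANOVA: total sum of squared distances
#' `SS_T = sum_{i<j} d_ij^2 / n`, within-group `SS_W` summed per group
#' (each divided by its group size), pseudo-F
#' `((SS_T - SS_W)/(g-1)) / (SS_W/(n-g))`, and a permutation p-value
#' `(1 + #{F_perm >= F_obs}) / (1 + n_permutations)` from free permutation
#' of sample labels.
#'
#' @param dm symmetric distance matrix with sample ids.
#' @param grouping factor/character of group labels, one per sample (or
#'   named, matched to `dm`'s ids).
#' @param n_permutations number of label permutations (>= 99; default 999).
#' @param seed optional integer seed.
#' @return list with `pseudo_F`, `p`, `df` and the permutation count.
#' @export
permanova <- function(dm, grouping, n_permutations = 999, seed = NULL) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)) || any(diag(dm) != 0)) {
    stop("dm must be symmetric with a zero diagonal", call. = FALSE)
  }
  if (!is.null(names(grouping)) && !is.null(rownames(dm))) {
    grouping <- grouping[rownames(dm)]
  }
  g <- as.factor(grouping)
  if (length(g) != n) stop("one group label per sample required", call. = FALSE)
  sizes <- table(g)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("singleton group(s): ", paste(names(sizes)[sizes < 2], collapse = ", "),
         call. = FALSE)
  }
  if (n_permutations < 99) stop("n_permutations must be >= 99", call. = FALSE)

  d2 <- dm^2
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ng <- nlevels(g)
  f_stat <- function(gv) {
    ss_w <- 0
    for (lv in levels(gv)) {
      idx <- which(gv == lv)
      ss_w <- ss_w + sum(d2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
    }
    ((ss_t - ss_w) / (ng - 1)) / (ss_w / (n - ng))
  }
  f_obs <- f_stat(g)
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (p in seq_len(n_permutations)) {
    if (f_stat(g[sample.int(n)]) >= f_obs - 1e-12) count <- count + 1L
  }
  list(pseudo_F = f_obs, p = (1 + count) / (1 + n_permutations),
       df = c(ng - 1L, n - ng), n_permutations = n_permutations)
}

#' Centered log-ratio transform
#'
#' Per sample, `clr_i = ln(x_i / g(x))` with `g` the geometric mean of the
#' pseudocounted vector. By default the pseudocount is added only to zero
#' counts; `all = TRUE` adds it to every count.
#'
#' @param x non-negative counts: a vector (one sample) or a features x
#'   samples matrix / [feature_table()].
#' @param pseudocount value added to zeros (default 0.5); must be positive
#'   when zeros are present.
#' @param all add the pseudocount to every count, not only zeros.
#' @return clr values in the shape of the input; each sample's clr values
#'   sum to zero.
#' @export
clr_transform <- function(x, pseudocount = 0.5, all = FALSE) {
  if (inherits(x, "feature_table")) x <- x$counts
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), ncol = 1) else apply(x, 2, as.numeric)
  if (vec) rownames(m) <- names(x) else dimnames(m) <- dimnames(x)
  if (any(m < 0)) stop("negative counts", call. = FALSE)
  if (all) {
    if (pseudocount <= 0) stop("pseudocount must be positive", call. = FALSE)
    m <- m + pseudocount
  } else if (any(m == 0)) {
    if (pseudocount <= 0) {
      stop("zeros present: a positive pseudocount is required", call. = FALSE)
    }
    m[m == 0] <- pseudocount
  }
  lm <- log(m)
  out <- sweep(lm, 2, colMeans(lm))
  if (vec) drop(out) else out
}

#' ANCOM differential abundance
#'
#' Analysis of composition of microbiomes: for each feature `i`, `W_i`
#' counts the features `j != i` for which a rank test on the additive
#' log-ratio `ln((x_i + c)/(x_j + c))` differs between groups at level
#' `alpha` (Mann-Whitney for two groups, Kruskal-Wallis for more); a
#' feature is flagged when `W_i >= w_fraction * (m - 1)`.
#'
#' @param table a [feature_table()] or counts matrix (features x samples).
#' @param grouping group labels, one per sample.
#' @param alpha per-ratio significance level (default 0.05).
#' @param w_fraction flagging threshold as a fraction of `m - 1`
#'   (default 0.7).
#' @param pseudocount additive constant `c` (default 1).
#' @return data.frame with `feature`, `W`, `flagged`; the numeric threshold
#'   is attached as attribute `"threshold"`.
#' @export
ancom <- function(table, grouping, alpha = 0.05, w_fraction = 0.7,
                  pseudocount = 1) {
  x <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  m <- nrow(x)
  if (m < 2L) stop("ANCOM needs at least two features", call. = FALSE)
  g <- as.factor(grouping)
  if (length(g) != ncol(x)) stop("one group label per sample required", call. = FALSE)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  two <- nlevels(g) == 2L
  lx <- log(x + pseudocount)
  sig <- matrix(FALSE, m, m)
  idx1 <- which(g == levels(g)[1L])
  idx2 <- which(g == levels(g)[2L])
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      y <- lx[i, ] - lx[j, ]
      p <- if (two) {
        suppressWarnings(stats::wilcox.test(y[idx1], y[idx2], exact = FALSE)$p.value)
      } else {
        suppressWarnings(stats::kruskal.test(y, g)$p.value)
      }
      if (!is.na(p) && p < alpha) sig[i, j] <- sig[j, i] <- TRUE
    }
  }
  W <- rowSums(sig)
  thr <- w_fraction * (m - 1L)
  res <- data.frame(feature = rownames(x) %||% as.character(seq_len(m)),
                    W = as.integer(W), flagged = W >= thr)
  attr(res, "threshold") <- thr
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collapse features by taxonomy rank
#'
#' Sums counts over features sharing the label at the requested rank.
#' Features with no assignment at that rank are grouped under an explicit
#' `"unknown <nearest assigned parent>"` label.
#'
#' @param table a [feature_table()] with taxonomy (semicolon-delimited
#'   ranks, optionally with `g__`-style prefixes).
#' @param level rank position (1 = highest) or one of
#'   `"kingdom","phylum","class","order","family","genus","species"`.
#' @return a collapsed [feature_table()].
#' @export
collapse_taxonomy <- function(table, level = "genus") {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$taxonomy)) stop("table has no taxonomy labels", call. = FALSE)
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
  lv <- if (is.character(level)) match(match.arg(level, ranks), ranks) else as.integer(level)
  parts <- strsplit(table$taxonomy, ";", fixed = TRUE)
  clean <- function(s) sub("^\\s*[a-z]__", "", trimws(s))
  lab <- vapply(parts, function(p) {
    p <- clean(p)
    if (length(p) >= lv && nzchar(p[lv])) return(p[lv])
    parent <- rev(p[seq_len(min(lv - 1L, length(p)))])
    parent <- parent[nzchar(parent)]
    paste("unknown", if (length(parent)) parent[1L] else "root")
  }, character(1))
  agg <- rowsum(table$counts, lab)
  feature_table(agg, taxonomy = rownames(agg), metadata = table$metadata)
}
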