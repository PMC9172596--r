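#' Spearman rank correlation
#'
#' `rho` is the Pearson correlation of mid-ranks (ties receive average
#' ranks). The p-value uses the exact permutation distribution for
#' `n < 10` (all `n!` permutations, two-sided on `|rho|`) and the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` for `n >= 10`.
#'
#' @param x,y numeric vectors of equal length `n >= 4`.
#' @return list with `rho`, `p` and `n`. A constant input yields `rho = NA`
#'   with a warning.
#' @examples
#' spearman_cor(1:5, c(3, 1, 2, 5, 4))  # rho = 0.7
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n < 10L) {
    perms <- all_permutations(n)
    # rho is affine in sum(rx * ry[perm]); compare |rho| over all permutations
    s <- as.vector(matrix(ry[perms], nrow(perms)) %*% rx)
    rho_perm <- (s - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

# n! x n matrix of all permutations of 1..n (n <= 9)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_permutations(n - 1L)
  r <- nrow(p)
  out <- matrix(0L, r * n, n)
  for (k in seq_len(n)) {
    q <- p
    q[q >= k] <- q[q >= k] + 1L
    out[((k - 1L) * r + 1L):(k * r), ] <- cbind(k, q)
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: on the sorted p-values,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, mapped back to input order.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, `q >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Taxa-target Spearman correlation network
#'
#' Tests every (taxon, target) pair with [spearman_cor()], adjusts the full
#' family of pairs with Benjamini-Hochberg, and keeps edges with
#' `q < q_threshold`. Taxa-taxa and target-target pairs are not tested.
#'
#' @param clr_taxa samples x taxa matrix of clr-transformed abundances
#'   (rownames = sample ids).
#' @param targets samples x variables matrix of phenotypes or normalized
#'   metabolite intensities (rownames = sample ids, same samples).
#' @param q_threshold FDR threshold (default 0.05).
#' @param node_classes optional named character vector mapping node ids to
#'   classes (e.g. `bacterium`, `secondary BA`, `phenotype`).
#' @return object of class `correlation_network`: list with `edges`
#'   (`source`, `target`, `rho`, `p`, `q`, `sign`), `nodes` and `tests`
#'   (all pairs tested).
#' @export
build_network <- function(clr_taxa, targets, q_threshold = 0.05,
                          node_classes = NULL) {
  clr_taxa <- as.matrix(clr_taxa)
  targets <- as.matrix(targets)
  if (!is.null(rownames(clr_taxa)) && !is.null(rownames(targets))) {
    bad <- c(setdiff(rownames(clr_taxa), rownames(targets)),
             setdiff(rownames(targets), rownames(clr_taxa)))
    if (length(bad)) {
      stop("sample mismatch between matrices: ", paste(unique(bad), collapse = ", "),
           call. = FALSE)
    }
    targets <- targets[rownames(clr_taxa), , drop = FALSE]
  } else if (nrow(clr_taxa) != nrow(targets)) {
    stop("matrices must cover the same samples", call. = FALSE)
  }
  tn <- colnames(clr_taxa) %||% sprintf("taxon%02d", seq_len(ncol(clr_taxa)))
  vn <- colnames(targets) %||% sprintf("target%02d", seq_len(ncol(targets)))
  tests <- expand.grid(source = tn, target = vn, stringsAsFactors = FALSE)
  tests$rho <- NA_real_
  tests$p <- NA_real_
  for (k in seq_len(nrow(tests))) {
    r <- suppressWarnings(
      spearman_cor(clr_taxa[, tests$source[k]], targets[, tests$target[k]]))
    tests$rho[k] <- r$rho
    tests$p[k] <- r$p
  }
  ok <- !is.na(tests$p)
  tests$q <- NA_real_
  tests$q[ok] <- bh_adjust(tests$p[ok])
  edges <- tests[ok & tests$q < q_threshold, , drop = FALSE]
  edges$sign <- ifelse(edges$rho >= 0, "+", "-")
  rownames(edges) <- NULL
  ids <- unique(c(edges$source, edges$target))
  nodes <- data.frame(
    id = ids,
    class = if (is.null(node_classes)) rep(NA_character_, length(ids)) else
      unname(node_classes[ids])
  )
  structure(list(edges = edges, nodes = nodes, tests = tests,
                 q_threshold = q_threshold),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("<correlation_network> %d edge(s) at q < %g from %d tested pair(s)\n",
              nrow(x$edges), x$q_threshold, nrow(x$tests)))
  if (nrow(x$edges)) print(x$edges[, c("source", "target", "rho", "q", "sign")])
  invisible(x)
}

#' Aligned rank transform two-way ANOVA
#'
#' Nonparametric factorial ANOVA: for each effect (A, B, A:B) the response
#' is aligned by removing the cell-mean estimates of every other effect,
#' the aligned values are mid-ranked, a full two-way ANOVA is fitted to the
#' ranks, and only the target effect's F and p are retained.
#'
#' @param response numeric response.
#' @param a,b factors (two levels each in the standard design; any number
#'   of levels is accepted). Every cell must hold >= 2 observations.
#' @return object of class `art_anova`: data.frame with one row per effect
#'   (`effect`, `df1`, `df2`, `F`, `p`).
#' @export
art_anova <- function(response, a, b) {
  a <- droplevels(as.factor(a))
  b <- droplevels(as.factor(b))
  y <- as.numeric(response)
  stopifnot(length(y) == length(a), length(y) == length(b))
  cell_n <- table(a, b)
  if (any(cell_n == 0)) stop("empty design cell", call. = FALSE)
  if (any(cell_n < 2)) stop("every cell needs >= 2 observations", call. = FALSE)
  unbalanced <- length(unique(as.vector(cell_n))) > 1L
  if (unbalanced) {
    message("unbalanced design: alignment uses unweighted cell means")
  }

  cm <- tapply(y, list(a, b), mean)                 # cell means
  am <- rowMeans(cm)                                # A marginal (unweighted)
  bm <- colMeans(cm)
  gm <- mean(cm)
  ai <- as.integer(a)
  bi <- as.integer(b)
  eff_a <- am[ai] - gm
  eff_b <- bm[bi] - gm
  eff_ab <- cm[cbind(ai, bi)] - am[ai] - bm[bi] + gm
  resid <- y - cm[cbind(ai, bi)]

  one_effect <- function(aligned, label) {
    r <- rank(aligned)
    fit <- stats::aov(r ~ a * b)
    tab <- summary(fit)[[1]]
    rn <- trimws(rownames(tab))
    row <- match(label, rn)
    data.frame(effect = label, df1 = tab[row, "Df"],
               df2 = tab[nrow(tab), "Df"], F = tab[row, "F value"],
               p = tab[row, "Pr(>F)"])
  }
  out <- rbind(
    one_effect(resid + eff_a, "a"),
    one_effect(resid + eff_b, "b"),
    one_effect(resid + eff_ab, "a:b")
  )
  out$effect <- c("A", "B", "A:B")
  rownames(out) <- NULL
  class(out) <- c("art_anova", "data.frame")
  attr(out, "aligned") <- list(A = resid + eff_a, B = resid + eff_b,
                               `A:B` = resid + eff_ab)
  out
}

#' @export
print.art_anova <- function(x, ...) {
  cat("Aligned rank transform ANOVA\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Normalize bile-acid intensities
#'
#' Two-step normalization: each sample's intensities are divided by its
#' internal-standard value, then by the sample's total bile-acid ion count,
#' so every row sums to 1.
#'
#' @param intensities samples x acids matrix of non-negative intensities.
#' @param internal_standard positive internal-standard value per sample.
#' @return normalized matrix; rows sum to 1.
#' @export
normalize_bile_acids <- function(intensities, internal_standard) {
  m <- as.matrix(intensities)
  if (any(m < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (length(internal_standard) != nrow(m)) {
    stop("one internal-standard value per sample required", call. = FALSE)
  }
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  bad <- which(internal_standard <= 0)
  if (length(bad)) {
    stop("non-positive internal standard for sample(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  m <- sweep(m, 1, internal_standard, "/")
  tot <- rowSums(m)
  bad <- which(tot == 0)
  if (length(bad)) {
    stop("zero total intensity for sample(s): ", paste(ids[bad], collapse = ", "),
         call. = FALSE)
  }
  sweep(m, 1, tot, "/")
}

#' Per-variable fold change with rank-sum test
#'
#' For each variable, compares two groups and reports a fold change —
#' relative difference `(mean_t - mean_c)/mean_c` (default) or ratio
#' `mean_t / mean_c` — alongside a Wilcoxon rank-sum p-value and its
#' Benjamini-Hochberg q across variables.
#'
#' @param values samples x variables matrix (or vector).
#' @param groups two-level grouping, one label per sample.
#' @param control the label of the control/reference group.
#' @param definition `"relative"` or `"ratio"`.
#' @return data.frame with `variable`, `fold_change`, `p`, `q`.
#' @export
group_fold_change <- function(values, groups, control,
                              definition = c("relative", "ratio")) {
  definition <- match.arg(definition)
  m <- as.matrix(values)
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups required", call. = FALSE)
  if (missing(control)) control <- levels(g)[1L]
  if (!control %in% levels(g)) stop("unknown control label", call. = FALSE)
  treat <- setdiff(levels(g), control)
  vn <- colnames(m) %||% sprintf("var%02d", seq_len(ncol(m)))
  fc <- p <- numeric(ncol(m))
  for (k in seq_len(ncol(m))) {
    mc <- mean(m[g == control, k])
    mt <- mean(m[g == treat, k])
    fc[k] <- if (mc == 0) NA_real_ else if (definition == "relative")
      (mt - mc) / mc else mt / mc
    p[k] <- suppressWarnings(
      stats::wilcox.test(m[g == treat, k], m[g == control, k], exact = FALSE)$p.value)
  }
  p[!is.finite(p)] <- NA_real_  # fully tied comparisons have no rank test
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  data.frame(variable = vn, fold_change = fc, p = p, q = q)
}
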