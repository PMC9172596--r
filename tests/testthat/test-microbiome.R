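test_that("rarefaction drops shallow samples and subsamples the rest exactly", {
  set.seed(4)
  cnt <- matrix(rpois(5 * 4, 40), 5, 4,
                dimnames = list(paste0("F", 1:5), paste0("s", 1:4)))
  cnt[, 4] <- c(2, 1, 0, 0, 0)  # shallow sample
  ft <- feature_table(cnt)
  expect_warning(r <- rarefy(ft, depth = 100, seed = 1), "s4")
  expect_equal(colnames(r$counts), c("s1", "s2", "s3"))
  expect_true(all(colSums(r$counts) == 100))
  expect_true(all(r$counts <= cnt[, 1:3]))
  # no feature absent before rarefaction appears after
  expect_true(all(r$counts[cnt[, 1:3] == 0] == 0))

  # total exactly at depth: unchanged
  one <- feature_table(matrix(c(60, 40), 2, 1))
  expect_equal(unname(rarefy(one, 100)$counts), unname(one$counts))

  expect_error(rarefy(ft, depth = 1e6), "below the rarefaction depth")

  # deterministic under a fixed seed
  r1 <- suppressWarnings(rarefy(ft, 100, seed = 7))
  r2 <- suppressWarnings(rarefy(ft, 100, seed = 7))
  expect_identical(r1$counts, r2$counts)
})

test_that("alpha diversity matches closed forms and picante", {
  cnt <- matrix(c(5, 5, 5, 5,
                  10, 0, 0, 0,
                  8, 4, 2, 1), 4, 3,
                dimnames = list(c("A", "B", "C", "D"), paste0("s", 1:3)))
  ft <- feature_table(cnt)
  expect_equal(unname(alpha_diversity(ft, "observed")), c(4, 1, 4))
  J <- alpha_diversity(ft, "pielou")
  expect_equal(unname(J[1]), 1)          # equal abundances: maximal evenness
  expect_true(is.na(J[2]))               # single feature: ln S = 0
  p <- cnt[, 3] / sum(cnt[, 3])
  expect_equal(unname(J[3]), -sum(p * log(p)) / log(4))

  # star tree with unit branches: PD = number of observed leaves
  st <- star_tree()
  expect_equal(unname(alpha_diversity(ft, "faith_pd", st)), c(4, 1, 4))

  # random tree: agree with picante (include.root convention)
  set.seed(5)
  tr <- ape::rtree(6, tip.label = paste0("F", 1:6))
  tr$edge.length <- rexp(nrow(tr$edge), 5)
  cm <- matrix(rpois(6 * 4, 6), 6, 4, dimnames = list(paste0("F", 1:6), paste0("t", 1:4)))
  ft2 <- feature_table(cm)
  got <- alpha_diversity(ft2, "faith_pd", tr)
  want <- picante::pd(t(cm), tr, include.root = TRUE)$PD
  expect_equal(unname(got), want, tolerance = 1e-12)

  # PD is monotone in added leaves
  v <- c(3, 0, 0, 0, 0, 0)
  pds <- sapply(1:6, function(k) {
    vv <- v; vv[seq_len(k)] <- 3
    alpha_diversity(feature_table(matrix(vv, ncol = 1,
      dimnames = list(paste0("F", 1:6), "s"))), "faith_pd", tr)
  })
  expect_true(all(diff(pds) >= 0))

  extra <- feature_table(rbind(cm, X1 = 2))
  expect_error(alpha_diversity(extra, "faith_pd", tr), "X1")
})

test_that("UniFrac matches hand computation, axioms, and phyloseq", {
  st <- star_tree()
  cnt <- matrix(c(5, 0, 0, 0,
                  0, 3, 0, 0,
                  5, 0, 0, 0), 4, 3,
                dimnames = list(c("A", "B", "C", "D"), c("a", "b", "c")))
  ft <- feature_table(cnt)
  # disjoint single-leaf samples on a star tree: unique/union = 2/2
  expect_equal(unifrac(ft, st, "a", "b"), 1)
  expect_equal(unifrac(ft, st, "a", "c"), 0)
  expect_equal(unifrac(ft, st, "a", "b", weighted = TRUE), 2)  # |1-0|+|0-1|
  expect_equal(unifrac(ft, st, "a", "b", weighted = TRUE, normalized = TRUE), 1)

  # hand-computed 3-leaf case: ((A:1,B:1):1,C:2);
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  cm <- matrix(c(4, 0, 0,
                 0, 4, 0,
                 2, 0, 2), 3, 3, dimnames = list(c("A", "B", "C"), c("x", "y", "z")))
  ft2 <- feature_table(cm)
  # x={A}, y={B}: unique = 1+1, union = 1+1+1 (shared internal branch)
  expect_equal(unifrac(ft2, tr, "x", "y"), 2 / 3, tolerance = 1e-12)
  # x={A}, z={A,C}: unique = C's branch 2; union = 1+1+2
  expect_equal(unifrac(ft2, tr, "x", "z"), 2 / 4, tolerance = 1e-12)
  # weighted x vs z: A branch |1-.5|=.5, AB branch |1-.5|=.5, C branch 2*.5
  expect_equal(unifrac(ft2, tr, "x", "z", weighted = TRUE),
               1 * 0.5 + 1 * 0.5 + 2 * 0.5, tolerance = 1e-12)

  # axioms on random tables
  set.seed(6)
  for (i in 1:20) {
    k <- sample(4:7, 1)
    rt <- ape::rtree(k, tip.label = paste0("F", 1:k))
    rt$edge.length <- rexp(nrow(rt$edge), 5)
    cm <- matrix(rpois(k * 3, 4), k, 3, dimnames = list(paste0("F", 1:k), c("a", "b", "c")))
    cm[, colSums(cm) == 0] <- 1
    ftr <- feature_table(cm)
    for (w in c(FALSE, TRUE)) {
      d <- unifrac_matrix(ftr, rt, weighted = w)
      expect_equal(d, t(d))
      expect_true(all(diag(d) == 0))
      expect_true(all(d >= 0))
      if (!w) expect_true(all(d <= 1 + 1e-12))
    }
  }

  # agreement with phyloseq on a random table
  set.seed(8)
  tr5 <- ape::rtree(5, tip.label = paste0("F", 1:5))
  tr5$edge.length <- rexp(nrow(tr5$edge), 5)
  cm5 <- matrix(rpois(20, 8) + 1, 5, 4,
                dimnames = list(paste0("F", 1:5), paste0("s", 1:4)))
  ft5 <- feature_table(cm5)
  ps <- phyloseq::phyloseq(phyloseq::otu_table(cm5, taxa_are_rows = TRUE),
                           phyloseq::phy_tree(tr5))
  du <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  dw <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = FALSE))
  expect_equal(unifrac_matrix(ft5, tr5), du[paste0("s", 1:4), paste0("s", 1:4)],
               tolerance = 1e-10)
  expect_equal(unifrac_matrix(ft5, tr5, weighted = TRUE),
               dw[paste0("s", 1:4), paste0("s", 1:4)], tolerance = 1e-10)

  # nested communities: distance falls as shared taxa increase
  k <- 8
  lad <- ape::rtree(k, tip.label = paste0("F", 1:k))
  lad$edge.length <- rep(1, nrow(lad$edge))
  ref <- rep(1, k)
  dists <- sapply(1:(k - 1), function(m) {
    v <- c(rep(1, m), rep(0, k - m))
    cm <- cbind(ref = ref, sub = v)
    rownames(cm) <- paste0("F", 1:k)
    unifrac(feature_table(cm), lad, "ref", "sub")
  })
  expect_true(all(diff(dists) <= 1e-12))

  empty <- feature_table(cbind(a = c(1, 1, 1), b = c(0, 0, 0)))
  st3 <- star_tree(c("1", "2", "3"))
  expect_error(unifrac(feature_table(cbind(a = c(1, 1, 1), b = c(0, 0, 0))),
                       st3, 1, 2), "empty")
})

test_that("PERMANOVA matches vegan and detects separated clouds", {
  set.seed(10)
  x <- matrix(rnorm(24 * 3), 24, 3)
  rownames(x) <- paste0("s", 1:24)
  d <- as.matrix(dist(x))
  g <- rep(c("A", "B"), each = 12)
  pm <- permanova(d, g, 999, seed = 1)
  ad <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(pm$pseudo_F, ad$F[1], tolerance = 1e-10)

  # two well-separated clouds: minimal attainable p
  x2 <- rbind(matrix(rnorm(36), 12, 3), matrix(rnorm(36, mean = 30), 12, 3))
  d2 <- as.matrix(dist(x2))
  rownames(d2) <- colnames(d2) <- paste0("s", 1:24)
  expect_equal(permanova(d2, g, 999, seed = 2)$p, 1 / 1000)

  # F is invariant to permuting sample order together with labels
  perm <- sample(24)
  pm2 <- permanova(d[perm, perm], g[perm], 99, seed = 3)
  expect_equal(pm2$pseudo_F, pm$pseudo_F, tolerance = 1e-10)

  expect_error(permanova(d, rep(c("A", "B", "C"), c(12, 11, 1)), 999), "singleton")
  expect_error(permanova(d, g, 50), ">= 99")
})

test_that("clr transform centres each sample and inverts to relative abundances", {
  expect_equal(unname(clr_transform(c(5, 5, 5, 5))), rep(0, 4))
  expect_equal(unname(clr_transform(c(8, 2), pseudocount = 0)),
               c(log(2), -log(2)))
  expect_error(clr_transform(c(-1, 2)), "negative")
  expect_error(clr_transform(c(0, 2), pseudocount = 0), "pseudocount")

  set.seed(11)
  m <- matrix(rpois(50, 10), 10, 5)
  cl <- clr_transform(m, pseudocount = 0.5)
  expect_equal(unname(colSums(cl)), rep(0, 5), tolerance = 1e-10)

  # softmax inverse recovers the pseudocounted composition exactly
  v <- c(0, 3, 7, 12)
  cl1 <- clr_transform(v, pseudocount = 0.5)
  vp <- ifelse(v == 0, 0.5, v)
  expect_equal(exp(cl1) / sum(exp(cl1)), vp / sum(vp), tolerance = 1e-12)

  # pseudocount-everywhere option
  cl2 <- clr_transform(v, pseudocount = 0.5, all = TRUE)
  expect_equal(exp(cl2) / sum(exp(cl2)), (v + 0.5) / sum(v + 0.5),
               tolerance = 1e-12)
})

test_that("ANCOM flags a planted bloom and nothing on exchangeable groups", {
  # identical group compositions: zero flags
  set.seed(12)
  half <- matrix(rpois(20 * 10, 50), 20, 10)
  cnt <- cbind(half, half)
  g <- rep(c("a", "b"), each = 10)
  res <- ancom(cnt, g)
  expect_equal(sum(res$flagged), 0)

  # constant table: all W = 0, no error
  res <- ancom(matrix(5, 10, 8), rep(c("a", "b"), each = 4))
  expect_true(all(res$W == 0))
  expect_equal(sum(res$flagged), 0)

  # planted multiplicative shift on one feature
  set.seed(13)
  cnt <- matrix(rpois(30 * 24, 100), 30, 24)
  g <- rep(c("a", "b"), each = 12)
  cnt[7, g == "b"] <- rpois(12, 650)
  res <- ancom(cnt, g)
  expect_true(res$flagged[7])
  expect_equal(which.max(res$W), 7L)
  expect_true(all(res$W <= 29))
  expect_equal(attr(res, "threshold"), 0.7 * 29)

  expect_error(ancom(matrix(1, 1, 4), c("a", "a", "b", "b")), "two features")
})

test_that("taxonomy collapse sums counts and labels unassigned ranks", {
  cnt <- matrix(1:8, 4, 2, dimnames = list(paste0("F", 1:4), c("s1", "s2")))
  tax <- c("Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Porphyromonadaceae;Parabacteroides;distasonis",
           "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Porphyromonadaceae;Parabacteroides;distasonis",
           "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;;;",
           "Bacteria;Firmicutes;Clostridia;Clostridiales;Ruminococcaceae;Ruminococcus;")
  ft <- feature_table(cnt, taxonomy = tax)
  gen <- collapse_taxonomy(ft, "genus")
  expect_setequal(rownames(gen$counts),
                  c("Parabacteroides", "unknown Bacteroidales", "Ruminococcus"))
  expect_equal(gen$counts["Parabacteroides", "s1"], 1L + 2L)
  expect_equal(sum(gen$counts), sum(cnt))
})
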