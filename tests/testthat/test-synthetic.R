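test_that("hypnogram generator is seeded, circadian and respects forced wake", {
  m <- hypnogram_model()
  h1 <- gen_hypnogram(m, hours = 6, seed = 30)
  h2 <- gen_hypnogram(m, hours = 6, seed = 30)
  expect_identical(h1$states, h2$states)

  # light-phase sleep exceeds dark-phase sleep (rodent pattern)
  h <- gen_hypnogram(m, hours = 72, seed = 31)
  zt <- epoch_zt(h)
  expect_gt(mean(h$states[zt < 12] != "W"), mean(h$states[zt >= 12] != "W"))

  # stationary composition per lighting phase within +/- 3%
  pi_l <- sleepbiome:::stationary_distribution(m$light)
  pi_d <- sleepbiome:::stationary_distribution(m$dark)
  h <- gen_hypnogram(m, hours = 120, seed = 32)
  zt <- epoch_zt(h)
  emp_l <- table(factor(h$states[zt < 12], levels = c("W", "N", "R")))
  emp_l <- as.numeric(emp_l / sum(emp_l))
  emp_d <- table(factor(h$states[zt >= 12], levels = c("W", "N", "R")))
  emp_d <- as.numeric(emp_d / sum(emp_d))
  expect_true(all(abs(emp_l - pi_l) < 0.03))
  expect_true(all(abs(emp_d - pi_d) < 0.03))

  # escape probability 0: no sleep at all inside disruption windows
  m0 <- hypnogram_model(escape_prob = rep(0, 5))
  h0 <- gen_hypnogram(m0, hours = 120, start_zt = 6, disrupted = TRUE, seed = 33)
  win <- epoch_zt(h0) >= 6 | epoch_zt(h0) < 2
  expect_true(all(h0$states[win] == "W"))

  # day-1 disruption suppresses REM more than NREM (relative to baseline)
  hb <- gen_hypnogram(m, hours = 24, start_zt = 6, seed = 34)
  hd <- gen_hypnogram(m, hours = 24, start_zt = 6, disrupted = TRUE, seed = 34)
  base_n <- mean(hb$states == "N"); base_r <- mean(hb$states == "R")
  dis_n <- mean(hd$states == "N"); dis_r <- mean(hd$states == "R")
  expect_lt(dis_r / base_r, dis_n / base_n)

  expect_error(hypnogram_model(light = diag(3) * 2), "row-stochastic")
  expect_error(hypnogram_model(escape_prob = c(0.5, 0.1)), "non-decreasing")
})

test_that("microbiome generator plants the bloom and exercises rarefaction", {
  des <- study_design(n_per_group = 5)  # 20 per diet arm
  # subject deviations off: isolates the planted population-level fold
  gm <- gen_microbiome(des, microbiome_model(bloom_subject_sd = 0), seed = 40)
  meta <- gm$table$metadata
  rel <- sweep(gm$table$counts, 2, colSums(gm$table$counts), "/")
  t2 <- meta$timepoint == "T2"
  ratio <- mean(rel[1, t2 & meta$diet == "prebiotic"]) /
    mean(rel[1, t2 & meta$diet == "control"])
  expect_gt(ratio, 4)
  expect_lt(ratio, 9)

  # no bloom at baseline T1
  t1 <- meta$timepoint == "T1"
  r1 <- mean(rel[1, t1 & meta$diet == "prebiotic"]) /
    mean(rel[1, t1 & meta$diet == "control"])
  expect_lt(abs(log(r1)), log(2.5))

  # tree covers all features; bloom factor 1 gives exchangeable diets
  expect_setequal(gm$tree$tip.label, rownames(gm$table$counts))
  null_model <- microbiome_model(bloom_fold = c(T1 = 1, T2 = 1, T3 = 1, T4 = 1))
  gm0 <- gen_microbiome(study_design(n_per_group = 3), null_model, seed = 41)
  m0 <- gm0$table$metadata
  sel <- m0$timepoint == "T2"
  res <- ancom(gm0$table$counts[, sel], m0$diet[sel])
  expect_equal(sum(res$flagged), 0)

  # all depths >= 9000: rarefy drops nothing
  deep <- microbiome_model(low_depth_fraction = 0, depth_meanlog = log(15000),
                           depth_sdlog = 0.05)
  gmd <- gen_microbiome(study_design(n_per_group = 2), deep, seed = 42)
  expect_silent(r <- rarefy(gmd$table, 9000, seed = 1))
  expect_equal(ncol(r$counts), ncol(gmd$table$counts))

  # determinism
  gm2 <- gen_microbiome(des, microbiome_model(bloom_subject_sd = 0), seed = 40)
  expect_identical(gm$table$counts, gm2$table$counts)
})

test_that("metabolite generator plants signed taxon links", {
  des <- study_design(n_per_group = 5)
  gm <- gen_microbiome(des, seed = 43)
  t4 <- rownames(gm$table$metadata)[gm$table$metadata$timepoint == "T4"]
  ft <- feature_table(gm$table$counts[, t4], metadata = gm$table$metadata[t4, ])

  link <- data.frame(taxon = "F010", acid = 4, strength = 1.5)
  met <- gen_metabolites(ft, link, noise_sd = 0.3, seed = 44)
  expect_equal(dim(met$intensities), c(40, 20))
  clr <- t(clr_transform(ft))
  norm <- normalize_bile_acids(met$intensities, met$internal_standard)
  net <- build_network(clr[, "F010", drop = FALSE], norm)
  hit <- net$edges[net$edges$target == "BA04", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$sign, "+")

  # strength 0 everywhere: no planted structure
  met0 <- gen_metabolites(ft, NULL, seed = 45)
  net0 <- build_network(t(clr_transform(ft))[, 1:4],
                        normalize_bile_acids(met0$intensities, met0$internal_standard))
  expect_lte(nrow(net0$edges), 4)  # at most a stray false discovery

  met1 <- gen_metabolites(ft, link, noise_sd = 0.3, seed = 46)
  met2 <- gen_metabolites(ft, link, noise_sd = 0.3, seed = 46)
  expect_identical(met1$intensities, met2$intensities)

  expect_error(gen_metabolites(ft, data.frame(taxon = "nope", acid = 1,
                                              strength = 1)), "nope")
})

test_that("gen_study writes a verifiable bundle that round-trips", {
  dir <- file.path(tempdir(), "bundle-test")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  des <- study_design(n_per_group = 2)
  st <- gen_study(design = des, dir = dir, phases = "recovery", seed = 50)

  expect_equal(nrow(des$subjects), 16)
  man <- verify_manifest(st$manifest_path)
  expect_true(all(file.exists(file.path(dir, man$file))))

  eps <- read_epochs(file.path(dir, "epochs_recovery.csv"))
  expect_equal(length(eps), 16)
  expect_identical(eps[["S001"]]$states, st$epochs$recovery[["S001"]]$states)

  ft <- read_count_table(file.path(dir, "counts_T2.tsv"),
                         file.path(dir, "metadata_T2.tsv"))
  expect_equal(unname(ft$counts),
               unname(st$microbiome$table$counts[, colnames(ft$counts)]))
  tr <- read_tree(file.path(dir, "tree.nwk"), features = rownames(ft$counts))
  expect_equal(length(tr$tip.label), nrow(ft$counts))

  met <- read_metabolites(file.path(dir, "metabolites.tsv"))
  expect_equal(dim(met$intensities), dim(st$metabolites$intensities))
  expect_equal(unname(met$intensities),
               unname(st$metabolites$intensities[rownames(met$intensities), ]),
               tolerance = 1e-6)
})
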