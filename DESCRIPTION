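Package: sleepbiome
Title: Sleep Architecture, Gut Microbiome and Metabolite Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for rodent sleep-disruption studies that pair
    polysomnographic sleep scoring with 16S microbiome profiling and fecal
    bile-acid metabolomics. Turns scored 10-second sleep epochs into bout,
    brief-arousal and stage-time metrics; computes EEG band powers and NREM
    delta-power timecourses; implements rarefaction, alpha diversity (observed
    features, Pielou's evenness, Faith's phylogenetic diversity), weighted and
    unweighted UniFrac, PERMANOVA, ANCOM differential abundance and the
    centered log-ratio transform; builds Spearman/Benjamini-Hochberg
    correlation networks between taxa, metabolites and sleep phenotypes; runs
    aligned rank transform factorial ANOVA; and generates study-shaped
    synthetic data (hypnograms, EEG epochs, count tables, phylogenies,
    metabolite tables) with planted effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    vegan,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    picante,
    phyloseq
Config/testthat/edition: 3
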