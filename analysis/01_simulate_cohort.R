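#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 131 subjects in four latent clusters
# (26/17/52/36), mixed 450K/EPIC platforms (28/103), planted hypo- and
# hypermethylated blocks separating the case-dominant clusters, a global
# severity gradient, detection failures, missingness, and cluster-dependent
# clinical phenotypes. Writes the plain-text fixture consumed by the later
# steps, plus the ground truth used to evaluate them.

library(methylotyper)

cfg <- simulation_config(seed = 20260901L)
bundle <- simulate_cohort(cfg)
paths <- write_fixture(bundle, "results/cohort")

cat("cohort:", ncol(bundle$beta), "subjects x", nrow(bundle$beta), "CpGs\n")
cat("cases:", sum(bundle$samples$case), " non-cases:",
    sum(1 - bundle$samples$case), "\n")
cat("platforms:", paste(names(table(bundle$samples$platform)),
                        table(bundle$samples$platform), collapse = ", "), "\n")
cat("planted blocks:", nrow(bundle$truth$dmr_intervals),
    "(", sum(bundle$truth$dmr_intervals$severe_vs_mild), "severe-vs-mild )\n")
cat("files:\n"); for (p in paths) cat(" ", p, "\n")
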