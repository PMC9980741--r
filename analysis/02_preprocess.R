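#!/usr/bin/env Rscript
# Probe and sample quality control on the simulated cohort: restrict to the
# 450K/EPIC probe intersection, drop probes failing detection (p > 0.01 in
# more than 5% of samples), drop samples with more than 5% failing probes,
# then remove SNP-overlapping and cross-reactive probes. Writes the filter
# report and the filtered beta matrix.

library(methylotyper)

fx <- read_fixture("results/cohort")
ann <- fx$annotation

shared <- intersect_platforms(ann)
beta <- fx$beta[rownames(fx$beta) %in% shared, ]
detp <- fx$detp[rownames(beta), ]
cat("platform intersection:", nrow(beta), "of", nrow(fx$beta), "probes\n")

fd <- filter_detection(beta, detp)
cat("detection filter removed", length(fd$removed_probes), "probes and",
    length(fd$removed_samples), "samples\n")

bf <- filter_flagged(fd$beta, ann)
cat("flag filter removed", nrow(fd$beta) - nrow(bf), "probes; retained",
    nrow(bf), "CpGs x", ncol(bf), "subjects\n")

report <- rbind(
  data.frame(probe_id = setdiff(rownames(fx$beta), rownames(beta)),
             reason = "platform"),
  data.frame(probe_id = fd$removed_probes, reason = "detection"),
  data.frame(probe_id = setdiff(rownames(fd$beta), rownames(bf)),
             reason = "snp_or_crossreactive"))
write.table(report, "results/probe_filter_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
methylotyper:::write_numeric_tsv(bf, "results/beta_filtered.tsv")
cat("wrote results/probe_filter_report.tsv and results/beta_filtered.tsv\n")
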