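#!/usr/bin/env Rscript
# Differentially methylated regions between severe and mild cases:
# per-CpG regression of the (un-batch-corrected) M-value on the subgroup
# with array type as covariate, max-gap candidate segmentation (cutoff 1.0,
# at least 2 CpGs), bootstrap null (B = 1000) and fwerArea scoring. Writes
# the annotated DMR table and a BED export (0-based half-open).

library(methylotyper)

qn <- methylotyper:::read_numeric_tsv("results/beta_normalized.tsv")
samples <- read.csv("results/cohort/samples.csv", stringsAsFactors = FALSE)
asg <- read.delim("results/cluster_assignment.tsv", stringsAsFactors = FALSE)
ann <- read.delim("results/cohort/annotation.tsv", stringsAsFactors = FALSE)

cases <- asg$sample_id[!is.na(asg$subgroup) & asg$subgroup != ""]
outcome <- as.integer(asg$subgroup[match(cases, asg$sample_id)] == "severe")
m <- beta_to_m(qn[, cases])
arr <- as.integer(samples$platform[match(cases, samples$sample_id)] == "450K")

res <- find_dmrs(m, outcome, covariates = cbind(arraytype = arr),
                 annotation = ann, config = dmr_config(B = 1000L, seed = 42L))
d <- res$dmrs
cat("candidate regions:", nrow(d), "\n")
cat("significant (fwerArea <= 0.05):", sum(d$significant),
    "(", sum(d$significant & d$direction == "hypo"), "hypo /",
    sum(d$significant & d$direction == "hyper"), "hyper )\n")

cols <- c("chrom", "start", "end", "L", "region", "value", "area",
          "fwerArea", "p_valueArea", "direction", "gene", "island", "probes",
          "significant")
write.table(d[order(d$fwerArea, -d$area), cols], "results/dmrs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

sig <- d[d$significant, ]
bed <- data.frame(chrom = sig$chrom, start = sig$start - 1L, end = sig$end,
                  name = ifelse(sig$gene == "", ".", sig$gene),
                  score = pmin(1000L, as.integer(sig$area * 10)),
                  strand = ".")
write.table(bed, "results/dmrs_significant.bed", sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
cat("wrote results/dmrs.tsv and results/dmrs_significant.bed\n")
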