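#!/usr/bin/env Rscript
# Clinical phenotype association: apply the focus-score and tear-break-up
# special rules, then test every phenotype against the four patient clusters
# (chi-square / Kruskal-Wallis) and against the severe/mild case subgroups
# (chi-square with Yates / Wilcoxon rank-sum). Writes both association
# tables.

library(methylotyper)

samples <- read.csv("results/cohort/samples.csv", stringsAsFactors = FALSE)
asg <- read.delim("results/cluster_assignment.tsv", stringsAsFactors = FALSE)

spec <- default_phenotype_spec()
types <- vapply(spec, `[[`, "", "type")
rules <- vapply(spec, function(s)
  if (is.null(s$rule)) NA_character_ else s$rule, "")

pheno_cols <- intersect(names(spec), names(samples))
pt <- phenotype_table(samples[, c("sample_id", pheno_cols)],
                      types[pheno_cols], rules[pheno_cols])
pt <- apply_special_rules(pt)

clusters <- setNames(asg$cluster, asg$sample_id)
tab_cluster <- association_table(pt, clusters)
cat("== phenotypes by cluster ==\n")
print(tab_cluster[, c("variable", "test", "p", "significant")], digits = 3)

sub <- setNames(asg$subgroup, asg$sample_id)
sub <- sub[!is.na(sub) & sub != ""]
tab_sub <- association_table(pt, sub)
cat("== phenotypes by severe/mild subgroup ==\n")
print(tab_sub[, c("variable", "test", "p", "significant")], digits = 3)

write.table(tab_cluster, "results/assoc_by_cluster.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tab_sub, "results/assoc_by_subgroup.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote assoc_by_cluster.tsv and assoc_by_subgroup.tsv\n")
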