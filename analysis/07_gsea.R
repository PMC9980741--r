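#!/usr/bin/env Rscript
# Gene-set over-representation of DMR genes: restrict to promoter/gene-body
# regions, split by direction, hypergeometric test against the
# retained-probe gene universe, Benjamini-Hochberg FDR. Writes one ranked
# table per direction.

library(methylotyper)

d <- read.delim("results/dmrs.tsv", stringsAsFactors = FALSE)
d$gene[is.na(d$gene)] <- ""
ann <- read.delim("results/cohort/annotation.tsv", stringsAsFactors = FALSE)
sets <- read_gmt("results/cohort/gene_sets.gmt")
coll <- list(sets = sets, universe = gene_universe(ann))
cat("universe:", length(coll$universe), "genes;", length(sets), "gene sets\n")

for (dir in c("hypo", "hyper")) {
  g <- run_gsea(d, coll, dir)
  cat("==", dir, "query:", g$n[1], "genes; top sets ==\n")
  print(head(g[, c("set", "K", "k", "p", "adj_p")], 5), digits = 3)
  write.table(g, sprintf("results/gsea_%s.tsv", dir), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
cat("wrote results/gsea_hypo.tsv and results/gsea_hyper.tsv\n")
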