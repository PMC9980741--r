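#!/usr/bin/env Rscript
# Train the variational autoencoder on the adjusted beta matrix, cluster the
# posterior-mean embeddings with Ward linkage, cut at k = 4, renumber
# clusters by case proportion, and define the severe/mild case subgroups.
# Also runs the baseline clustering (mean absolute beta difference) and
# reports its agreement with the embedding-based clusters. Writes the
# embedding, loss history, assignments, dendrogram (Newick) and the PCA
# coordinates of the embedding.

library(methylotyper)

adj <- methylotyper:::read_numeric_tsv("results/beta_adjusted.tsv")
samples <- read.csv("results/cohort/samples.csv", stringsAsFactors = FALSE)
truth <- read.delim("results/cohort/truth_subjects.tsv", stringsAsFactors = FALSE)
case <- setNames(samples$case, samples$sample_id)

complete <- mean_impute(adj)$beta
trained <- train_vae(complete, vae_config(hidden_sizes = c(128L, 32L), seed = 1L))
emb <- trained$embedding

tree <- ward_linkage(emb$mu)
assignment <- cut_tree(tree, k = 4, case_status = case)
sub <- define_subgroups(assignment, case)

cat("cluster sizes:", table(assignment$cluster), "\n")
cat("case proportion by cluster:", round(sub$case_proportion, 3), "\n")
cat("severe cases:", sum(sub$subgroup == "severe"),
    " mild cases:", sum(sub$subgroup == "mild"), "\n")
ari <- mclust::adjustedRandIndex(assignment$cluster,
                                 setNames(truth$cluster, truth$sample_id)[names(assignment$cluster)])
cat("ARI vs planted clusters:", round(ari, 3), "\n")

baseline <- cut_tree(ward_linkage(baseline_distance(adj)), 4,
                     case_status = case, provenance = "baseline")
cmp <- compare_clusterings(assignment, baseline)
cat("baseline vs embedding agreement:", round(cmp$agreement, 1), "% (ARI",
    round(cmp$ari, 3), ")\n")

pe <- pca_embedding(emb$mu)
out <- data.frame(sample_id = names(assignment$cluster),
                  cluster = assignment$cluster,
                  subgroup = sub$subgroup[names(assignment$cluster)],
                  baseline_cluster = baseline$cluster[names(assignment$cluster)],
                  pc1 = pe$scores[, 1], pc2 = pe$scores[, 2])
write.table(out, "results/cluster_assignment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
emb_df <- data.frame(sample_id = rownames(emb$mu), emb$mu)
write.table(emb_df, "results/embedding.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(emb$history, "results/vae_loss_history.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
ape::write.tree(ape::as.phylo(tree), "results/dendrogram.nwk")
cat("wrote cluster_assignment.tsv, embedding.tsv, vae_loss_history.tsv,",
    "dendrogram.nwk\n")
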