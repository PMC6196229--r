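#!/usr/bin/env Rscript
# Distance-based phylogeny of the family: identity distances from the hit
# table, neighbor-joining tree, rooting on the most divergent member.
# Reads earlier results/, writes results/phylogeny/.

library(syntrace)

out <- "results/phylogeny"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ind <- "results/simulated"
net <- build_network(ingest_hits(file.path(ind, "hits.tsv")))
members <- read.delim("results/family/members.tsv")$gene_id

dm <- distances_from_hits(net, members)
tr <- nj_tree(dm)
rooted <- root_by_most_divergent(tr, dm)
ape::write.tree(rooted, file.path(out, "family_nj.nwk"))

cat("NJ tree over", length(members), "family members\n")
cat("Outgroup (most divergent member):", attr(rooted, "outgroup"), "\n")
cat("Mean pairwise distance:", round(mean(dm[upper.tri(dm)]), 3), "\n")
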