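#!/usr/bin/env Rscript
# Partition the family into synteny sub-lineages, tabulate per-species copy
# numbers, and rank duplication-timing scenarios against the WGD-marked
# species tree by implied-loss parsimony.
# Reads earlier results/, writes results/lineage/.

library(syntrace)

out <- "results/lineage"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ind <- "results/simulated"
gs <- load_genome_set(file.path(ind, "proteins.faa"),
                      file.path(ind, "gene_table.tsv"),
                      file.path(ind, "manifest.tsv"))
members <- read.delim("results/family/members.tsv")$gene_id
et <- read.delim("results/neighborhood/synteny_edges.tsv")
st <- species_tree(file.path(ind, "species_tree.nwk"), wgd = c("cagl", "naca"))

lg <- partition_sublineages(et, members)
print(lg)
write.table(lg$nodes, file.path(out, "sublineages.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_lineage_dot(lg, file.path(out, "lineage.dot"))

td <- detect_tandem(gs, members)
cat("Tandem pairs:", nrow(td), "\n")

pm <- presence_matrix(lg, gs)
write_presence_tsv(pm, file.path(out, "presence_matrix.tsv"))
print(pm)

for (sl in colnames(pm)) {
  carriers <- rownames(pm)[pm[, sl] > 0]
  mrca <- if (length(carriers) == 1) match(carriers, st$phy$tip.label)
          else ape::getMRCA(st$phy, carriers)
  if (!st$wgd_node %in% syntrace:::ancestor_chain(st$phy, mrca)) {
    cat("\n", sl, ": carriers are not confined to the post-WGD clade;",
        "duplication timing relative to the WGD is not at issue\n")
    next
  }
  cat("\nScenario ranking for", sl, "(", length(carriers), "carrier species ):\n")
  sc <- rank_scenarios(pm, st, sl)
  for (s in sc) print(s)
  write_scenarios_json(sc, file.path(out, paste0("scenarios_", sl, ".json")))
}
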