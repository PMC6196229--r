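#!/usr/bin/env Rscript
# Delimit the focal family by seeded traversal of the similarity network:
# sweep the e-value grid from the S. cerevisiae-like seed gene, pick the
# plateau threshold, traverse, and flag suspect members.
# Reads results/simulated/, writes results/family/.

library(syntrace)

ind <- "results/simulated"
out <- "results/family"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

gs <- load_genome_set(file.path(ind, "proteins.faa"),
                      file.path(ind, "gene_table.tsv"),
                      file.path(ind, "manifest.tsv"))
hits <- ingest_hits(file.path(ind, "hits.tsv"))
net <- build_network(hits, nodes = gs$loci$gene_id)
truth <- read.delim(file.path(ind, "truth.tsv"))

seed_gene <- truth$gene_id[truth$family & truth$genome_id == "sace" &
                           truth$origin == "ancestral"][1]
cat("Seed gene:", seed_gene, "\n")

curve <- sweep_family(net, seed_gene, seq(-200, -20, by = 2))
write_sweep_tsv(curve, file.path(out, "sweep.tsv"))
thr <- select_threshold(curve)
cat("Plateau threshold: E", thr$exponent, " (family size ",
    curve$counts[match(thr$exponent, curve$grid)], ")\n", sep = "")

members <- traverse(net, seed_gene, thr$evalue)
fam <- merge_families(list(list(seed = seed_gene, threshold = thr$evalue,
                                members = members)))
fam <- flag_suspects(fam, gs, net)
cat("Family:", length(fam$members), "members,", length(fam$flags), "flagged\n")
cat("Recovered all planted family genes:",
    setequal(members, truth$gene_id[truth$family]), "\n")

write.table(data.frame(gene_id = fam$members),
            file.path(out, "members.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
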