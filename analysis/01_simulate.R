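#!/usr/bin/env Rscript
# Simulate the reference genome set: 14 yeast-like species on a WGD-marked
# species tree, three 50-gene contigs per genome, with a planted family
# history (ohnolog loss at the WGD, dispersed duplication on the
# Saccharomyces stem, loss of the original copy on the Naumovozyma stem).
# Writes the genome set, true hit table, species tree, event log and truth
# table under results/simulated/.

library(syntrace)

out <- "results/simulated"
st <- fixture_species_tree()
cfg <- sim_config(
  species_tree = st,
  protect_lineages = "g025",
  planted_events = list(
    list(branch = "postWGD", type = "loss", lineage = "g025", origin = "wgd"),
    list(branch = "Saccharomyces", type = "duplication_dispersed",
         lineage = "g025", origin = "ancestral",
         target_contig = "c2", insert_at = 20L),
    list(branch = "Naumovozyma", type = "loss", lineage = "g025",
         origin = "ancestral")),
  rng_seed = 20260927)
sim <- simulate_genomes(cfg)
paths <- write_sim(sim, out)

cat("Simulated", length(unique(sim$truth$genome_id)), "genomes,",
    nrow(sim$truth), "genes,", nrow(sim$hits), "true pairwise hits\n")
cat("Family lineage:", sim$family_lineages, "with",
    sum(sim$truth$family), "surviving copies;",
    "planted duplicate instance:", sim$planted_instances, "\n")
cat("Events logged:", length(sim$event_log), "\n")
cat("Files written under", out, "\n")
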