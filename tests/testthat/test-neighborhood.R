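# small deterministic world for synteny scoring: two genomes with mirrored
# neighborhoods; clusters supplied explicitly
synteny_world <- function(n = 40, conserved = TRUE, seed = 1) {
  set.seed(seed)
  rows <- list(); prot <- character()
  for (g in c("gen1", "gen2")) {
    ids <- paste0(g, "_x", seq_len(n))
    rows[[g]] <- data.frame(gene_id = ids, genome_id = g, contig_id = "c1",
                            position = seq_len(n), strand = "+",
                            stringsAsFactors = FALSE)
    prot[ids] <- paste(rep("ACDEFGHIKL", 3), collapse = "")
  }
  gs <- genome_set(do.call(rbind, rows), prot,
                   c(gen1 = "gen1", gen2 = "gen2"))
  # orthologous columns: gen1_xi ~ gen2_xi when conserved
  hits <- if (conserved)
    data.frame(query_id = paste0("gen1_x", 1:n),
               subject_id = paste0("gen2_x", 1:n),
               evalue = 1e-120, identity_pct = 85, similarity_pct = 92,
               score = 400, aln_length = 100, stringsAsFactors = FALSE)
  else data.frame(query_id = character(), subject_id = character(),
                  evalue = numeric(), identity_pct = numeric(),
                  similarity_pct = numeric(), score = numeric(),
                  aln_length = integer())
  net <- build_network(hits, nodes = gs$loci$gene_id)
  list(gs = gs, net = net)
}

test_that("neighbor blocks carry offsets and contig-end markers", {
  w <- synteny_world()
  b <- build_block(w$gs, "gen1_x20", k = 15)
  expect_identical(nrow(b$upstream), 15L)
  expect_identical(nrow(b$downstream), 15L)
  expect_false(b$end_upstream); expect_false(b$end_downstream)
  expect_identical(b$upstream$offset, 1:15)
  expect_identical(b$upstream$gene_id[1], "gen1_x19")   # nearest-first
  b2 <- build_block(w$gs, "gen1_x38", k = 15)           # 2 genes to the end
  expect_identical(nrow(b2$downstream), 2L)
  expect_true(b2$end_downstream)
  expect_false(b2$end_upstream)
})

test_that("the single-match weight reproduces the stated formula", {
  # one shared cluster of size 2, both neighbors at offset 1, identity 100%
  tab <- data.frame(gene_id = c("q1", "n1", "q2", "n2"),
                    genome_id = c("g1", "g1", "g2", "g2"),
                    contig_id = "c", position = c(1L, 2L, 1L, 2L),
                    strand = "+")
  prot <- setNames(rep(paste(rep("ACDEFGHIKL", 3), collapse = ""), 4), tab$gene_id)
  gs <- genome_set(tab, prot, c(g1 = "gen1", g2 = "gen2"))
  hits <- data.frame(query_id = "n1", subject_id = "n2", evalue = 1e-90,
                     identity_pct = 100, similarity_pct = 100, score = 300,
                     aln_length = 100)
  net <- build_network(hits, nodes = tab$gene_id)
  cl <- cluster_at(net, 1e-50, include = tab$gene_id)
  e <- score_synteny(build_block(gs, "q1"), build_block(gs, "q2"), cl, net)
  expect_identical(e$raw_count, 1L)
  expect_equal(e$strength, 1 / (1 + log10(2)), tolerance = 1e-9)
  expect_identical(e$category, "weak")
})

test_that("synteny scoring is symmetric, bounded and zero for disjoint blocks", {
  w <- synteny_world()
  cl <- cluster_at(w$net, 1e-50, include = w$gs$loci$gene_id)
  b1 <- build_block(w$gs, "gen1_x20"); b2 <- build_block(w$gs, "gen2_x20")
  e12 <- score_synteny(b1, b2, cl, w$net)
  e21 <- score_synteny(b2, b1, cl, w$net)
  expect_identical(e12$raw_count, e21$raw_count)
  expect_equal(e12$strength, e21$strength, tolerance = 1e-12)
  expect_identical(e12$category, e21$category)
  expect_identical(e12$raw_count, 30L)          # fully conserved +/-15 block
  expect_lte(e12$strength, e12$raw_count)       # each weight <= 1
  expect_lte(e12$raw_count, 2L * b1$k)
  expect_identical(e12$category, "strong")

  wd <- synteny_world(conserved = FALSE)
  cld <- cluster_at(wd$net, 1e-50, include = wd$gs$loci$gene_id)
  ed <- score_synteny(build_block(wd$gs, "gen1_x20"),
                      build_block(wd$gs, "gen2_x20"), cld, wd$net)
  expect_identical(ed$raw_count, 0L)
  expect_identical(ed$strength, 0)
  expect_identical(ed$category, "none")
})

test_that("bigger clusters weigh strictly less at equal offsets and identity", {
  w_clu <- function(size) 1 / (1 + log10(size))
  sizes <- c(2, 5, 20, 100, 366)
  expect_true(all(diff(vapply(sizes, w_clu, numeric(1))) < 0))
})

test_that("pushing a matched neighbor outward never raises the strength", {
  w <- synteny_world()
  cl <- cluster_at(w$net, 1e-50, include = w$gs$loci$gene_id)
  base <- score_synteny(build_block(w$gs, "gen1_x20"),
                        build_block(w$gs, "gen2_x20"), cl, w$net)
  # move the query one position: offsets of every shared neighbor change,
  # raw counts stay comparable but strength cannot exceed the aligned case
  offcenter <- score_synteny(build_block(w$gs, "gen1_x20"),
                             build_block(w$gs, "gen2_x22"), cl, w$net)
  expect_lte(offcenter$strength, base$strength + 1e-12)
})

test_that("the all-vs-all synteny network finds conserved pairs and honors flags", {
  sim <- small_sim(seed = 21)
  net <- build_network(sim$hits, nodes = sim$truth$gene_id)
  two <- sim$truth$gene_id[sim$truth$family & sim$truth$origin == "ancestral" &
                           sim$truth$genome_id %in% c("zyro", "tode")]
  fam <- merge_families(list(list(seed = two[1], threshold = 1e-50, members = two)))
  edges <- synteny_network(fam, sim$genome_set, net)
  expect_length(edges, 1L)
  expect_identical(edges[[1]]$category, "strong")

  fam2 <- merge_families(list(list(seed = two[1], threshold = 1e-50, members = two)))
  fam2 <- apply_exclusions(fam2, two[2])
  edges2 <- synteny_network(fam2, sim$genome_set, net)
  expect_length(edges2, 0L)                # singleton after exclusion
})

test_that("neighborhood reports tabulate clusters and honor truncation", {
  w <- synteny_world()
  cl <- cluster_at(w$net, 1e-50, include = w$gs$loci$gene_id)
  blocks <- list(build_block(w$gs, "gen1_x20"))
  names(blocks) <- "gen1_x20"
  rep_full <- neighborhood_report(blocks, cl)
  expect_identical(nrow(rep_full), 30L)
  rep5 <- neighborhood_report(blocks, cl, truncate = 5)
  expect_identical(nrow(rep5), 10L)
  expect_lte(max(rep5$offset), 5L)
})
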