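edge_row <- function(a, b, raw = 6, strength = 2, category = "strong") {
  data.frame(gene_a = a, gene_b = b, raw_count = raw, strength = strength,
             category = category, evidence_level = "E-50",
             stringsAsFactors = FALSE)
}

test_that("sub-lineages are components over weak-or-stronger edges", {
  members <- c("a1", "a2", "a3", "b1", "b2", "solo")
  edges <- rbind(edge_row("a1", "a2"), edge_row("a2", "a3"),
                 edge_row("b1", "b2", raw = 2, category = "weak"),
                 edge_row("a1", "b1", raw = 0, strength = 0, category = "none"))
  lg <- partition_sublineages(edges, members)
  grp <- setNames(lg$nodes$sublineage_id, lg$nodes$gene_id)
  expect_identical(unname(grp["a1"]), unname(grp["a3"]))
  expect_identical(unname(grp["b1"]), unname(grp["b2"]))
  expect_false(grp[["a1"]] == grp[["b1"]])
  expect_true(lg$nodes$singleton[lg$nodes$gene_id == "solo"])
  expect_identical(length(unique(lg$nodes$sublineage_id)), 3L)
  # no edges at all: everything is a singleton
  lg0 <- partition_sublineages(edges[0, ], members)
  expect_true(all(lg0$nodes$singleton))
  expect_error(partition_sublineages(edge_row("a1", "zz"), members), "non-member")
})

test_that("tandem pairs are same-contig members within the rank gap", {
  tab <- data.frame(gene_id = c("t1", "t2", "far", "other"),
                    genome_id = "g", contig_id = c("c1", "c1", "c1", "c2"),
                    position = c(7L, 8L, 18L, 1L), strand = "+")
  # positions must be consecutive per contig: pad the contig
  pad <- data.frame(gene_id = sprintf("p%d", 1:18), genome_id = "g",
                    contig_id = "c1", position = 1:18, strand = "+")
  pad <- pad[!pad$position %in% c(7, 8, 18), ]
  tab <- rbind(tab, pad)
  prot <- setNames(rep("MKTAYIAKQRMKTAYIAKQR", nrow(tab)), tab$gene_id)
  gs <- genome_set(tab, prot, c(g = "gggg"))
  td <- detect_tandem(gs, c("t1", "t2", "far", "other"), max_gap = 3)
  expect_identical(nrow(td), 1L)
  expect_setequal(c(td$gene_a, td$gene_b), c("t1", "t2"))
})

test_that("planted tandem duplications are recovered from the event log", {
  sim <- small_sim(seed = 31, planted_events = list(
    list(branch = "sace", type = "duplication_tandem", lineage = "g025",
         origin = "ancestral")))
  stopifnot(length(sim$planted_instances) == 1)
  pair <- sim$truth$gene_id[sim$truth$genome_id == "sace" &
                            sim$truth$lineage == "g025"]
  td <- detect_tandem(sim$genome_set, pair, max_gap = 3)
  expect_identical(nrow(td), 1L)
  expect_setequal(c(td$gene_a, td$gene_b), pair)
})

test_that("presence matrices tally copies per species and sub-lineage", {
  sim <- small_sim(seed = 33)
  members <- sim$truth$gene_id[sim$truth$family]
  # partition by ground-truth group, then tally with an independent table()
  et <- do.call(rbind, lapply(split(members, sim$truth$group[sim$truth$family]),
    function(g) if (length(g) >= 2) {
      prs <- t(combn(sort(g), 2)); edge_row(prs[, 1], prs[, 2])
    } else NULL))
  lg <- partition_sublineages(et, members)
  pm <- presence_matrix(lg, sim$genome_set)
  expect_identical(sort(rownames(pm)), sort(unname(sim$genome_set$species)))
  for (sl in unique(lg$nodes$sublineage_id)) {
    genes <- lg$nodes$gene_id[lg$nodes$sublineage_id == sl]
    oracle <- table(sim$truth$genome_id[match(genes, sim$truth$gene_id)])
    for (sp in rownames(pm)) {
      expect_identical(pm[sp, sl],
                       if (sp %in% names(oracle)) as.integer(oracle[[sp]]) else 0L)
    }
  }
  # round-trip through TSV
  f <- withr::local_tempfile()
  write_presence_tsv(pm, f)
  expect_identical(read_presence_tsv(f), pm)
})

test_that("scenario evaluation counts species and Dollo losses correctly", {
  fx <- paper_pattern_fixture()
  # every descendant carries the copy: no losses
  s0 <- evaluate_scenario(fx$presence, fx$species_tree, "snq2", "postWGD")
  expect_identical(s0$implied_species_losses, 0L)
  expect_identical(s0$implied_dollo_losses, 0L)
  expect_identical(s0$event_total, 1L)
  # the WGD-duplication hypothesis for the Saccharomyces-only sub-lineage
  s1 <- evaluate_scenario(fx$presence, fx$species_tree, "pdr18", "postWGD")
  expect_identical(s1$implied_species_losses, 5L)
  expect_identical(s1$implied_dollo_losses, 3L)
  expect_identical(s1$event_total, 4L)
  expect_lte(s1$implied_dollo_losses, s1$implied_species_losses)
  # degenerate: no carrier below the branch
  pm0 <- fx$presence; pm0[, "pdr18"] <- 0L
  expect_error(evaluate_scenario(pm0, fx$species_tree, "pdr18", "postWGD"),
               "degenerate")
})

test_that("Dollo counts equal exhaustive minimization on random patterns", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(5:12, 1)
    phy <- ape::rtree(n, tip.label = sprintf("s%02d", 1:n))
    st <- species_tree(phy)
    internal <- setdiff((n + 1):max(phy$edge), n + 1L)
    dup_node <- if (length(internal) && runif(1) < 0.8) sample(internal, 1) else n + 1L
    if (dup_node == n + 1L) next   # duplication at the root is not a branch
    desc <- syntrace:::tip_descendants(phy, dup_node)
    if (length(desc) < 2) next
    present <- sample(desc, sample(seq_len(length(desc)), 1))
    pm <- matrix(0L, n, 1, dimnames = list(phy$tip.label, "sl"))
    pm[present, 1] <- 1L
    sc <- evaluate_scenario(pm, st, "sl", dup_node)
    expect_identical(sc$implied_dollo_losses,
                     brute_force_dollo(phy, dup_node, present))
    expect_identical(sc$implied_species_losses, length(setdiff(desc, present)))
  }
})

test_that("moving the duplication rootward never decreases species losses", {
  fx <- paper_pattern_fixture()
  path <- c("Saccharomyces", "NakSac", "KNS", "postWGD")
  losses <- vapply(path, function(b)
    evaluate_scenario(fx$presence, fx$species_tree, "pdr18", b)$implied_species_losses,
    integer(1))
  expect_true(all(diff(losses) >= 0))
})

test_that("scenario ranking prefers the most parsimonious recent branch", {
  fx <- paper_pattern_fixture()
  sc <- rank_scenarios(fx$presence, fx$species_tree, "pdr18")
  expect_identical(sc[[1]]$branch_label, "Saccharomyces")
  expect_identical(sc[[1]]$event_total, 1L)
  expect_gt(sc[[length(sc)]]$event_total, sc[[1]]$event_total)
  # a sub-lineage carried by all post-WGD species ranks the WGD branch first
  sc2 <- rank_scenarios(fx$presence, fx$species_tree, "snq2")
  expect_identical(sc2[[1]]$branch_label, "postWGD")
  expect_error(rank_scenarios(fx$presence, species_tree(fx$species_tree$phy), "snq2"),
               "WGD")
})

test_that("unexpectedly similar cross-genus pairs raise a lateral-transfer flag", {
  tab <- data.frame(gene_id = c("cagl_1", "kana_1", "saca_1", "sacb_1"),
                    genome_id = c("cagl", "kana", "saca", "sacb"),
                    contig_id = "c", position = 1L, strand = "+")
  prot <- setNames(rep("MKTAYIAKQRMKTAYIAKQR", 4), tab$gene_id)
  gs <- genome_set(tab, prot,
                   c(cagl = "cagl", kana = "kana", saca = "saca", sacb = "sacb"))
  hits <- data.frame(
    query_id = c("saca_1", "cagl_1", "saca_1"),
    subject_id = c("sacb_1", "kana_1", "cagl_1"),
    evalue = 1e-100, identity_pct = c(60, 74.5, 30),
    similarity_pct = c(70, 85.9, 40), score = 200, aln_length = 100)
  net <- build_network(hits)
  expect_warning(out <- flag_cross_genus_similarity(net, gs, tab$gene_id),
                 "cross-genus")
  expect_identical(nrow(out), 1L)
  expect_setequal(c(out$gene_a, out$gene_b), c("cagl_1", "kana_1"))
})
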