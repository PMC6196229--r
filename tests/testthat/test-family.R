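chain_net <- function() {
  hits <- data.frame(query_id = c("a", "b"), subject_id = c("b", "c"),
                     evalue = c(1e-150, 1e-100), identity_pct = 90,
                     similarity_pct = 95, score = 100, aln_length = 100)
  build_network(hits, nodes = c("a", "b", "c", "iso"))
}

test_that("traversal returns the seed's component at the threshold", {
  net <- chain_net()
  expect_identical(traverse(net, "iso", 1e-10), "iso")
  expect_identical(traverse(net, "a", 1e-142), c("a", "b"))
  expect_identical(traverse(net, "a", 1e-50), c("a", "b", "c"))
  expect_error(traverse(net, "nope", 1e-10), "unknown seed")
})

test_that("traversal agrees with an independent DFS oracle and is monotone", {
  for (seed in 1:10) {
    rn <- random_network(n = 200, p = 0.015, seed = seed)
    set.seed(seed + 1000)
    seeds <- sample(rn$ids, 3)
    thrs <- 10^runif(3, -150, -20)
    for (s in seeds) for (t in thrs) {
      expect_identical(traverse(rn$net, s, t),
                       dfs_component(rn$hits, rn$ids, s, t))
    }
    # monotone in threshold and seed-containing
    t1 <- 1e-100; t2 <- 1e-40
    for (s in seeds) {
      m1 <- traverse(rn$net, s, t1); m2 <- traverse(rn$net, s, t2)
      expect_true(all(m1 %in% m2))
      expect_true(s %in% m1)
    }
    # all seeds in one component retrieve the identical set
    comp <- traverse(rn$net, seeds[1], t2)
    for (s in intersect(seeds, comp))
      expect_identical(traverse(rn$net, s, t2), comp)
  }
})

test_that("the sweep records non-decreasing family sizes", {
  net <- chain_net()
  sw <- sweep_family(net, "iso", seq(-200, -20, 2))
  expect_true(all(sw$counts == 1))
  # two 3-cliques joined by a single 1e-60 edge: the family size jumps at E-60
  cl <- expand.grid(a = c("p1", "p2", "p3"), b = c("p1", "p2", "p3"))
  cl <- cl[cl$a != cl$b, ]
  cl2 <- expand.grid(a = c("q1", "q2", "q3"), b = c("q1", "q2", "q3"))
  cl2 <- cl2[cl2$a != cl2$b, ]
  hits <- data.frame(query_id = c(as.character(cl$a), as.character(cl2$a), "p1"),
                     subject_id = c(as.character(cl$b), as.character(cl2$b), "q1"),
                     evalue = c(rep(1e-120, nrow(cl) + nrow(cl2)), 1e-60),
                     identity_pct = 90, similarity_pct = 95, score = 100,
                     aln_length = 100)
  net2 <- build_network(hits)
  sw2 <- sweep_family(net2, "p1", seq(-100, -40, 2))
  expect_true(all(diff(sw2$counts) >= 0))
  expect_identical(unique(sw2$counts[sw2$grid < -60]), 3L)
  expect_identical(unique(sw2$counts[sw2$grid >= -60]), 6L)
  expect_error(sweep_family(net2, "p1", numeric()), "empty")
})

test_that("the plateau rule picks the most stringent stable threshold", {
  curve <- structure(list(seed_id = "s", grid = seq(-140, -80, 10),
                          counts = c(1L, 1L, 5L, 5L, 5L, 5L, 80L)),
                     class = "sweep_curve")
  expect_identical(select_threshold(curve, stability_steps = 3)$exponent, -120)
  incr <- structure(list(seed_id = "s", grid = seq(-60, -10, 10),
                         counts = c(1L, 2L, 4L, 8L, 16L, 32L)),
                    class = "sweep_curve")
  expect_error(select_threshold(incr, stability_steps = 3), "no plateau")
  const <- structure(list(seed_id = "s", grid = seq(-60, -10, 10),
                          counts = rep(7L, 6)), class = "sweep_curve")
  expect_identical(select_threshold(const, stability_steps = 3)$exponent, -60)
  # a long seed-only run at ultra-stringent thresholds is not a plateau
  lead1 <- structure(list(seed_id = "s", grid = seq(-200, -100, 10),
                          counts = c(rep(1L, 7), rep(16L, 4))),
                     class = "sweep_curve")
  expect_identical(select_threshold(lead1, stability_steps = 3)$exponent, -130)
  # appending more-permissive points past the chosen run leaves it unchanged
  appended <- curve
  appended$grid <- c(curve$grid, -70, -60)
  appended$counts <- c(curve$counts, 120L, 250L)
  expect_identical(select_threshold(appended, stability_steps = 3)$exponent, -120)
})

test_that("families merge by union with per-seed thresholds and overlap warnings", {
  fam <- merge_families(list(
    list(seed = "s1", threshold = 1e-142, members = c("s1", "a", "b")),
    list(seed = "s2", threshold = 1e-104, members = c("s2", "c"))))
  expect_identical(fam$members, c("a", "b", "c", "s1", "s2"))
  expect_identical(unname(fam$thresholds["s2"]), 1e-104)
  expect_warning(
    merge_families(list(list(seed = "s1", threshold = 1e-10, members = c("a", "b")),
                        list(seed = "s2", threshold = 1e-10, members = c("b", "c")))),
    "overlap")
})

test_that("fragments and sequence outliers get flagged but stay listed", {
  n <- 8
  ids <- sprintf("m%d", 1:n)
  base <- paste(rep("ACDEFGHIKL", 10), collapse = "")
  prot <- setNames(rep(base, n), ids)
  prot["m8"] <- substr(base, 1, 30)             # 30% of the median length
  tab <- data.frame(gene_id = ids, genome_id = "g", contig_id = "c",
                    position = 1:n, strand = "+")
  gs <- genome_set(tab, prot, c(g = "gggg"))
  prs <- t(combn(ids, 2))
  hits <- data.frame(query_id = prs[, 1], subject_id = prs[, 2],
                     evalue = 1e-100, identity_pct = 98, similarity_pct = 99,
                     score = 300, aln_length = 100, stringsAsFactors = FALSE)
  hits$identity_pct[hits$query_id == "m7" | hits$subject_id == "m7"] <- 45
  net <- build_network(hits)
  fam <- merge_families(list(list(seed = "m1", threshold = 1e-50, members = ids)))
  fam <- flag_suspects(fam, gs, net, len_frac = 0.5)
  expect_true("fragment" %in% fam$flags[["m8"]])
  expect_true("long_branch" %in% fam$flags[["m7"]])
  expect_true(all(ids %in% fam$members))
  expect_setequal(unflagged_members(fam), setdiff(ids, "m8"))

  # identical members: nothing to flag
  prot2 <- setNames(rep(base, 4), sprintf("u%d", 1:4))
  tab2 <- data.frame(gene_id = names(prot2), genome_id = "g", contig_id = "c",
                     position = 1:4, strand = "+")
  gs2 <- genome_set(tab2, prot2, c(g = "gggg"))
  prs2 <- t(combn(names(prot2), 2))
  hits2 <- data.frame(query_id = prs2[, 1], subject_id = prs2[, 2],
                      evalue = 1e-180, identity_pct = 100, similarity_pct = 100,
                      score = 500, aln_length = 100)
  fam2 <- merge_families(list(list(seed = "u1", threshold = 1e-50,
                                   members = names(prot2))))
  fam2 <- flag_suspects(fam2, gs2, build_network(hits2))
  expect_identical(length(fam2$flags), 0L)
})

test_that("manual exclusions are flags, not removals", {
  fam <- merge_families(list(list(seed = "a", threshold = 1e-50,
                                  members = c("a", "b", "hxt1"))))
  fam <- apply_exclusions(fam, c("hxt1", "not_a_member"))
  expect_identical(fam$flags[["hxt1"]], "manual_exclude")
  expect_true("hxt1" %in% fam$members)
  expect_setequal(unflagged_members(fam), c("a", "b"))
})
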