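# Shared fixtures and independent oracles, all built in code.

# deterministic toy genome set: 2 genomes, proteins long enough to pass
# validation, ordinal gene order
toy_genome_set <- function(genes_per_contig = 10, genomes = c("aaaa", "bbbb")) {
  rows <- list(); prot <- character()
  set.seed(42)
  for (g in genomes) for (ctg in c("chr1", "chr2")) {
    ids <- paste(g, ctg, seq_len(genes_per_contig), sep = "_")
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = ids, genome_id = g, contig_id = ctg,
      position = seq_len(genes_per_contig),
      strand = rep(c("+", "-"), length.out = genes_per_contig),
      stringsAsFactors = FALSE)
    prot[ids] <- vapply(seq_len(genes_per_contig), function(i)
      paste(sample(c("A","C","D","E","F","G","H","I","K","L"), 30, TRUE), collapse = ""),
      character(1))
  }
  genome_set(do.call(rbind, rows), prot, setNames(substr(genomes, 1, 4), genomes))
}

# random similarity network as (hits, igraph): n nodes, edge prob p,
# exponents uniform on [lo, hi]
random_network <- function(n = 200, p = 0.02, seed = 1, lo = -180, hi = -10) {
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  ev <- 10^runif(nrow(pairs), lo, hi)
  hits <- data.frame(query_id = ids[pairs[, 1]], subject_id = ids[pairs[, 2]],
                     evalue = ev, identity_pct = runif(nrow(pairs), 20, 100),
                     similarity_pct = 100, score = -log10(ev),
                     aln_length = 100L, stringsAsFactors = FALSE)
  hits$similarity_pct <- pmin(100, hits$identity_pct + 5)
  list(ids = ids, hits = hits, net = build_network(hits, nodes = ids))
}

# independent reachability oracle: iterative DFS over an adjacency list
# built directly from the hit table (never touches igraph)
dfs_component <- function(hits, ids, seed_id, threshold) {
  adj <- setNames(vector("list", length(ids)), ids)
  keep <- hits$evalue <= threshold
  for (r in which(keep)) {
    a <- hits$query_id[r]; b <- hits$subject_id[r]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- setNames(logical(length(ids)), ids)
  stack <- seed_id
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (seen[[v]]) next
    seen[[v]] <- TRUE
    stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
  }
  sort(names(seen)[seen])
}

# exhaustive Dollo oracle: smallest set of loss branches (each wiping the
# subtree below it) that makes exactly the absent species absent
brute_force_dollo <- function(phy, dup_node, present) {
  tips_below <- function(node) {
    ntip <- length(phy$tip.label)
    if (node <= ntip) return(phy$tip.label[node])
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  all_tips <- tips_below(dup_node)
  absent <- setdiff(all_tips, present)
  if (!length(absent)) return(0L)
  # candidate loss edges: those whose subtree contains no present species
  sub_nodes <- integer()
  collect <- function(node) {
    sub_nodes <<- c(sub_nodes, node)
    ntip <- length(phy$tip.label)
    if (node > ntip) for (k in phy$edge[phy$edge[, 1] == node, 2]) collect(k)
  }
  for (k in phy$edge[phy$edge[, 1] == dup_node, 2]) collect(k)
  usable <- sub_nodes[vapply(sub_nodes, function(n)
    !any(tips_below(n) %in% present), logical(1))]
  for (s in seq_along(usable)) {
    combos <- combn(usable, s)
    for (cc in seq_len(ncol(combos))) {
      wiped <- unique(unlist(lapply(combos[, cc], tips_below)))
      if (setequal(wiped, absent)) return(s)
    }
  }
  stop("oracle failed to find a loss set")
}

# random tree with strictly positive branch lengths and its (additive)
# path-length matrix
random_additive_case <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.5, 3))
  dm <- ape::cophenetic.phylo(tr)
  dm <- dm[order(rownames(dm)), order(colnames(dm))]
  list(tree = tr, dm = dm)
}

default_planted_events <- function(fam = "g025") {
  list(
    list(branch = "postWGD", type = "loss", lineage = fam, origin = "wgd"),
    list(branch = "Saccharomyces", type = "duplication_dispersed",
         lineage = fam, origin = "ancestral", target_contig = "c2",
         insert_at = 20L),
    list(branch = "Naumovozyma", type = "loss", lineage = fam,
         origin = "ancestral"))
}

small_sim <- function(seed = 7, ...) {
  args <- list(rng_seed = seed, ...)
  if (!"planted_events" %in% names(args))
    args$planted_events <- default_planted_events()
  if (!"protect_lineages" %in% names(args))
    args$protect_lineages <- "g025"
  simulate_genomes(do.call(sim_config, args))
}
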