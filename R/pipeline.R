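#' Pipeline run configuration
#'
#' Collects the file paths, seeds and thresholds for an end-to-end run.
#' Defaults follow the printed analysis parameters: neighbor clustering at
#' E-50 with an E-40 corroboration fallback, 15 neighbors per side, and a
#' sweep grid of e-value exponents from -200 to -20 in steps of 2.
#'
#' @param genome_fasta,gene_table,manifest genome-set input files
#'   ([load_genome_set()])
#' @param hits tabular hit file ([ingest_hits()])
#' @param seeds character vector of seed gene ids for family traversal
#' @param species_tree_path optional Newick species tree
#' @param wgd optional WGD branch selector ([resolve_branch()])
#' @param grid sweep grid of e-value exponents (stringent to permissive)
#' @param stability_steps,tol_frac plateau rule parameters
#'   ([select_threshold()])
#' @param threshold optional fixed e-value per seed (named vector), skipping
#'   the sweep
#' @param cluster_t,fallback_t,k,strong_min,max_gap neighborhood/lineage
#'   parameters
#' @param exclude gene ids to flag `manual_exclude`
#' @param outdir output directory
#' @param rng_seed seed for any stochastic step
#' @return list of class `run_config`
#' @export
run_config <- function(genome_fasta, gene_table, manifest, hits, seeds,
                       species_tree_path = NULL, wgd = NULL,
                       grid = seq(-200, -20, by = 2),
                       stability_steps = 5, tol_frac = 0.01,
                       threshold = NULL,
                       cluster_t = 1e-50, fallback_t = 1e-40, k = 15,
                       strong_min = 5, max_gap = 3,
                       exclude = character(), outdir = tempfile("run"),
                       rng_seed = 1) {
  cfg <- structure(as.list(environment()), class = "run_config")
  for (f in c(genome_fasta, gene_table, manifest, hits, species_tree_path))
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  cfg
}

#' Run the full pipeline
#'
#' Executes family delimitation (sweep, plateau threshold, traversal,
#' merge, suspect flagging) then neighborhood synteny scoring then lineage
#' partitioning, copy-count tabulation and — when a WGD-marked species tree
#' is configured — duplication-timing scenario ranking for every
#' sub-lineage whose carriers descend from the WGD branch. Writes each
#' stage's tables plus `summary.json` under `cfg$outdir`; reruns with the
#' same configuration produce byte-identical summaries.
#'
#' @param cfg a [run_config()]
#' @return invisibly, the summary list
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$rng_seed)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  gs <- load_genome_set(cfg$genome_fasta, cfg$gene_table, cfg$manifest)
  hits <- ingest_hits(cfg$hits)
  net <- build_network(hits, nodes = gs$loci$gene_id)

  summary <- list(parameters = list(
    cluster_t = cfg$cluster_t, fallback_t = cfg$fallback_t, k = cfg$k,
    strong_min = cfg$strong_min, grid = range(cfg$grid),
    stability_steps = cfg$stability_steps, tol_frac = cfg$tol_frac,
    rng_seed = cfg$rng_seed))
  message("defaults in effect: cluster_t=", cfg$cluster_t,
          " fallback_t=", cfg$fallback_t, " k=", cfg$k)

  results <- list()
  sweeps <- list()
  for (sd in cfg$seeds) {
    if (!is.null(cfg$threshold) && sd %in% names(cfg$threshold)) {
      thr <- cfg$threshold[[sd]]
    } else {
      curve <- sweep_family(net, sd, cfg$grid)
      sweeps[[sd]] <- curve
      write_sweep_tsv(curve, file.path(cfg$outdir, paste0("sweep_", sd, ".tsv")))
      thr <- select_threshold(curve, cfg$stability_steps, cfg$tol_frac)$evalue
    }
    results[[sd]] <- list(seed = sd, threshold = thr,
                          members = traverse(net, sd, thr))
  }
  fam <- merge_families(unname(results))
  fam <- flag_suspects(fam, gs, net)
  fam <- apply_exclusions(fam, cfg$exclude)
  flag_vec <- unlist(fam$flags, use.names = FALSE)
  summary$family <- list(
    seeds = as.list(setNames(lapply(results, function(r)
      list(threshold = r$threshold, members = length(r$members))), names(results))),
    total_members = length(fam$members),
    flagged = if (length(flag_vec)) as.list(table(flag_vec)) else list())
  write.table(data.frame(gene_id = fam$members,
                         flags = vapply(fam$members, function(g)
                           paste(fam$flags[[g]] %||% "", collapse = ";"), character(1))),
              file.path(cfg$outdir, "family_members.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  members <- unflagged_members(fam)
  if (length(members) < 1)
    stop("pipeline halted at neighborhood stage: family is empty after traversal/flagging")
  edges <- synteny_network(fam, gs, net, cluster_t = cfg$cluster_t,
                           fallback_t = cfg$fallback_t, k = cfg$k,
                           weights_cfg = synteny_weights(cfg$strong_min))
  et <- synteny_edge_table(edges)
  write.table(et, file.path(cfg$outdir, "synteny_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  lg <- partition_sublineages(et, members)
  tand <- detect_tandem(gs, members, cfg$max_gap)
  write.table(lg$nodes, file.path(cfg$outdir, "lineage.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pm <- presence_matrix(lg, gs)
  write_presence_tsv(pm, file.path(cfg$outdir, "presence_matrix.tsv"))
  summary$lineage <- list(
    sublineage_sizes = as.list(table(lg$nodes$sublineage_id)),
    singletons = sum(lg$nodes$singleton),
    tandem_pairs = nrow(tand))

  if (!is.null(cfg$species_tree_path)) {
    st <- species_tree(cfg$species_tree_path, wgd = cfg$wgd)
    scen <- list()
    if (!is.null(st$wgd_node)) {
      for (sl in colnames(pm)) {
        carriers <- rownames(pm)[pm[, sl] > 0]
        if (!length(carriers)) next
        mrca <- if (length(carriers) == 1) match(carriers, st$phy$tip.label)
                else ape::getMRCA(st$phy, carriers)
        if (!st$wgd_node %in% ancestor_chain(st$phy, mrca)) next
        scen[[sl]] <- lapply(rank_scenarios(pm, st, sl), function(s)
          list(branch = s$branch_label,
               implied_species_losses = s$implied_species_losses,
               implied_dollo_losses = s$implied_dollo_losses,
               event_total = s$event_total))
      }
    }
    summary$scenarios <- scen
    jsonlite::write_json(scen, file.path(cfg$outdir, "scenarios.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}

#' Export the lineage graph as Graphviz DOT
#'
#' Edge pen width grows monotonically with synteny strength, the standard
#' way lineage figures encode synteny evidence.
#'
#' @param lg a [partition_sublineages()] result
#' @param path output DOT file
#' @param fragments gene ids to annotate with an "F" label
#' @export
write_lineage_dot <- function(lg, path, fragments = character()) {
  esc <- function(x) gsub('"', "'", x)
  lines <- c("graph lineage {", "  node [shape=box];")
  for (i in seq_len(nrow(lg$nodes))) {
    g <- lg$nodes$gene_id[i]
    lab <- if (g %in% fragments) paste0(g, " (F)") else g
    lines <- c(lines, sprintf('  "%s" [label="%s", group="%s"];',
                              esc(g), esc(lab), lg$nodes$sublineage_id[i]))
  }
  if (nrow(lg$edges)) {
    w <- 1 + 4 * lg$edges$strength / max(lg$edges$strength)
    for (i in seq_len(nrow(lg$edges)))
      lines <- c(lines, sprintf('  "%s" -- "%s" [penwidth=%.2f];',
                                esc(lg$edges$gene_a[i]), esc(lg$edges$gene_b[i]), w[i]))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

#' One planted-history recovery trial
#'
#' Simulates the reference evolutionary history on the fixture species
#' tree — the focal family is single-copy, its WGD ohnolog is lost on the
#' WGD branch, a dispersed duplication creating a second sub-lineage is
#' planted on the Saccharomyces stem, and the original copy is lost on the
#' deeper Naumovozyma stem — then runs the analysis pipeline (network from
#' the true hit table, seeded traversal, synteny scoring, sub-lineage
#' partition, scenario ranking) and reports whether the true duplication
#' branch ranks first and whether the synteny partition matches the
#' ground-truth neighborhood-origin groups (adjusted Rand index).
#'
#' @param seed RNG seed for the replicate
#' @param cfg_overrides named list merged over the default [sim_config()]
#'   arguments
#' @return list with `top_branch_correct`, `ari`, `n_members`,
#'   `n_sublineages`, `top_branch`
#' @export
planted_history_trial <- function(seed, cfg_overrides = list()) {
  st <- fixture_species_tree()
  gpc <- cfg_overrides$genes_per_contig %||% formals(sim_config)$genes_per_contig
  fam <- sprintf("g%03d", max(1L, gpc %/% 2L))   # the mid-contig family seed
  args <- modifyList(list(
    species_tree = st,
    protect_lineages = fam,
    planted_events = list(
      list(branch = "postWGD", type = "loss", lineage = fam, origin = "wgd"),
      list(branch = "Saccharomyces", type = "duplication_dispersed",
           lineage = fam, origin = "ancestral",
           target_contig = "c2", insert_at = 20L),
      list(branch = "Naumovozyma", type = "loss", lineage = fam,
           origin = "ancestral")),
    rng_seed = seed), cfg_overrides)
  cfg <- do.call(sim_config, args)
  sim <- simulate_genomes(cfg)
  fam_lin <- sim$family_lineages[1]
  net <- build_network(sim$hits, nodes = sim$truth$gene_id)

  seed_gene <- sim$truth$gene_id[sim$truth$family & sim$truth$genome_id == "sace" &
                                 sim$truth$origin == "ancestral"][1]
  if (is.na(seed_gene))
    seed_gene <- sim$truth$gene_id[sim$truth$family][1]
  members <- traverse(net, seed_gene, 1e-50)
  fam <- merge_families(list(list(seed = seed_gene, threshold = 1e-50,
                                  members = members)))
  edges <- synteny_network(fam, sim$genome_set, net)
  lg <- partition_sublineages(synteny_edge_table(edges), unflagged_members(fam))

  truth_groups <- sim$truth$group[match(lg$nodes$gene_id, sim$truth$gene_id)]
  ari <- mclust::adjustedRandIndex(lg$nodes$sublineage_id, truth_groups)

  planted_group <- sim$planted_instances[1]
  planted_genes <- sim$truth$gene_id[sim$truth$group == planted_group]
  sl <- unique(lg$nodes$sublineage_id[lg$nodes$gene_id %in% planted_genes])
  top_ok <- FALSE; top_branch <- NA_character_
  if (length(sl) == 1) {
    pm <- presence_matrix(lg, sim$genome_set)
    sc <- tryCatch(rank_scenarios(pm, st, sl), error = function(e) NULL)
    if (!is.null(sc)) {
      top_branch <- sc[[1]]$branch_label
      top_ok <- sc[[1]]$duplication_branch == resolve_branch(st, "Saccharomyces")
    }
  }
  list(top_branch_correct = top_ok, ari = ari, n_members = length(members),
       n_sublineages = length(unique(lg$nodes$sublineage_id)),
       top_branch = top_branch)
}
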