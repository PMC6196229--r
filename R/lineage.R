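#' Species tree with an optional WGD mark
#'
#' Wraps a rooted `ape::phylo` with species codes at the tips and optionally
#' flags one branch as the whole-genome-duplication (WGD) event. A branch is
#' identified by the node it subtends (its child node), named either by an
#' internal node label, by a tip label, or by a set of >= 2 tip labels whose
#' MRCA subtends the branch.
#'
#' @param phy rooted `phylo` or a Newick string/path readable by
#'   `ape::read.tree`
#' @param wgd branch selector for the WGD event (see above), or NULL
#' @return object of class `species_tree`: `phy`, `wgd_node`
#' @export
species_tree <- function(phy, wgd = NULL) {
  if (is.character(phy)) {
    phy <- if (file.exists(phy[1])) ape::read.tree(phy) else ape::read.tree(text = phy)
  }
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  if (anyDuplicated(phy$tip.label)) stop("species codes must be unique")
  st <- structure(list(phy = phy, wgd_node = NULL), class = "species_tree")
  if (!is.null(wgd)) {
    st$wgd_node <- resolve_branch(st, wgd)
    if (st$wgd_node == root_node(phy)) stop("WGD mark must be a branch, not the root")
  }
  st
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species_tree:", length(x$phy$tip.label), "species",
      if (!is.null(x$wgd_node)) paste0("; WGD branch above {",
        paste(tip_descendants(x$phy, x$wgd_node), collapse = ","), "}") else "; no WGD mark",
      "\n")
  invisible(x)
}

root_node <- function(phy) length(phy$tip.label) + 1L

#' Resolve a branch selector to its child node id
#' @param st a [species_tree()]
#' @param spec integer node id, a node/tip label, or >= 2 tip labels (MRCA)
#' @return integer node id of the node the branch subtends
#' @export
resolve_branch <- function(st, spec) {
  phy <- st$phy
  if (is.numeric(spec) && length(spec) == 1) {
    node <- as.integer(spec)
  } else if (is.character(spec) && length(spec) == 1) {
    node <- match(spec, phy$tip.label)
    if (is.na(node) && !is.null(phy$node.label)) {
      hit <- match(spec, phy$node.label)
      if (!is.na(hit)) node <- length(phy$tip.label) + hit
    }
    if (is.na(node)) stop("no tip or node labelled '", spec, "'")
  } else if (is.character(spec)) {
    missing <- setdiff(spec, phy$tip.label)
    if (length(missing)) stop("unknown species: ", paste(missing, collapse = ", "))
    node <- ape::getMRCA(phy, spec)
  } else stop("cannot interpret branch selector")
  if (node < 1 || node > max(phy$edge)) stop("node id out of range: ", node)
  node
}

tip_descendants <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  todo <- node
  tips <- integer()
  while (length(todo)) {
    n <- todo[[1]]; todo <- todo[-1]
    kids <- phy$edge[phy$edge[, 1] == n, 2]
    tips <- c(tips, kids[kids <= ntip])
    todo <- c(todo, kids[kids > ntip])
  }
  sort(phy$tip.label[tips])
}

ancestor_chain <- function(phy, node) {
  # node ids from `node` up to (and including) the root
  out <- node
  repeat {
    parent <- phy$edge[phy$edge[, 2] == node, 1]
    if (!length(parent)) break
    out <- c(out, parent)
    node <- parent
  }
  out
}

branch_label <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  if (!is.null(phy$node.label)) {
    lab <- phy$node.label[node - ntip]
    if (!is.na(lab) && nzchar(lab)) return(lab)
  }
  paste0("mrca(", paste(range(tip_descendants(phy, node)), collapse = ","), ")")
}

#' Partition family genes into synteny sub-lineages
#'
#' Sub-lineages are the connected components of the graph whose edges are
#' synteny edges of category `weak` or `strong`; genes with no such edge are
#' singletons. A sub-lineage is interpreted as the descendants of one
#' ancestral chromosomal locus.
#'
#' @param edges list of `synteny_edge` objects or a [synteny_edge_table()]
#'   data.frame
#' @param members character vector of family genes to partition (edges must
#'   reference members only)
#' @return object of class `lineage_graph`: `nodes` data.frame
#'   (`gene_id`, `sublineage_id`, `singleton`), `edges` data.frame
#' @export
partition_sublineages <- function(edges, members) {
  et <- if (is.data.frame(edges)) edges[edges$category != "none", , drop = FALSE]
        else synteny_edge_table(edges)
  stray <- setdiff(c(et$gene_a, et$gene_b), members)
  if (length(stray)) stop("edges reference non-members: ",
                          paste(head(stray, 5), collapse = ", "))
  g <- igraph::graph_from_data_frame(et[, c("gene_a", "gene_b"), drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = sort(unique(members))))
  comp <- igraph::components(g)
  mem <- comp$membership
  first <- tapply(names(mem), mem, min)
  relabel <- setNames(paste0("SL", seq_along(sort(first))), names(sort(first)))
  sub_id <- unname(relabel[as.character(mem)])
  nodes <- data.frame(gene_id = names(mem), sublineage_id = sub_id,
                      stringsAsFactors = FALSE)
  sizes <- table(nodes$sublineage_id)
  nodes$singleton <- sizes[nodes$sublineage_id] == 1
  nodes <- nodes[order(nodes$sublineage_id, nodes$gene_id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = et), class = "lineage_graph")
}

#' @export
print.lineage_graph <- function(x, ...) {
  cat("lineage_graph:", nrow(x$nodes), "genes in",
      length(unique(x$nodes$sublineage_id)), "sub-lineage(s) (",
      sum(x$nodes$singleton), "singleton(s) )\n")
  invisible(x)
}

#' Detect tandemly duplicated family members
#'
#' Pairs of members on the same contig whose ordinal positions differ by at
#' most `max_gap` are reported as tandem pairs.
#'
#' @param gs a [genome_set()]
#' @param members character vector of family genes
#' @param max_gap maximum rank gap (default 3)
#' @return data.frame `gene_a, gene_b, gap`
#' @export
detect_tandem <- function(gs, members, max_gap = 3) {
  loc <- gs$loci[gs$index[members], , drop = FALSE]
  out <- data.frame(gene_a = character(), gene_b = character(), gap = integer(),
                    stringsAsFactors = FALSE)
  key <- paste(loc$genome_id, loc$contig_id, sep = "\r")
  for (k in unique(key)) {
    sub <- loc[key == k, , drop = FALSE]
    if (nrow(sub) < 2) next
    sub <- sub[order(sub$position), , drop = FALSE]
    pr <- combn(seq_len(nrow(sub)), 2)
    for (p in seq_len(ncol(pr))) {
      gap <- abs(sub$position[pr[2, p]] - sub$position[pr[1, p]])
      if (gap <= max_gap)
        out[nrow(out) + 1L, ] <- list(sub$gene_id[pr[1, p]], sub$gene_id[pr[2, p]], gap)
    }
  }
  out
}

#' Per-species copy counts of each sub-lineage
#'
#' Rows are species codes, columns sub-lineages, entries copy counts.
#' Multiple strains of one species are collapsed by the maximum count (the
#' presence/absence arguments downstream are species-level); a message notes
#' when collapsing happened. Species present in the genome set but carrying
#' no family gene appear as all-zero rows.
#'
#' @param lg a [partition_sublineages()] result
#' @param gs a [genome_set()]
#' @return integer matrix (class `presence_matrix` via attribute only;
#'   plain matrix)
#' @export
presence_matrix <- function(lg, gs) {
  all_species <- sort(unique(unname(gs$species)))
  subs <- sort(unique(lg$nodes$sublineage_id))
  pm <- matrix(0L, length(all_species), length(subs),
               dimnames = list(all_species, subs))
  if (!nrow(lg$nodes)) return(pm)
  genome <- gs$loci$genome_id[gs$index[lg$nodes$gene_id]]
  sp <- unname(gs$species[genome])
  per_strain <- table(paste(genome, lg$nodes$sublineage_id, sep = "\r"))
  strain_of <- sub("\r.*", "", names(per_strain))
  sub_of <- sub(".*\r", "", names(per_strain))
  collapsed <- FALSE
  for (i in seq_along(per_strain)) {
    spc <- unname(gs$species[strain_of[i]])
    prev <- pm[spc, sub_of[i]]
    if (prev > 0) collapsed <- TRUE
    pm[spc, sub_of[i]] <- max(prev, as.integer(per_strain[i]))
  }
  if (collapsed)
    message("presence_matrix: multiple strains per species collapsed by maximum count")
  pm
}

#' Write / read a presence matrix as TSV
#' @param pm matrix from [presence_matrix()]
#' @param path TSV path
#' @export
write_presence_tsv <- function(pm, path) {
  df <- data.frame(species_code = rownames(pm), pm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_tsv
#' @export
read_presence_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$species_code
  storage.mode(m) <- "integer"
  m
}

dollo_losses <- function(phy, dup_node, present_species) {
  # minimal number of loss branches explaining all absences under dup_node,
  # assuming presence at dup_node and no regain (Dollo): one loss per
  # maximal all-absent subtree
  ntip <- length(phy$tip.label)
  n_losses <- 0L
  count <- function(node) {
    tips <- tip_descendants(phy, node)
    if (!any(tips %in% present_species)) return(TRUE)  # all-absent subtree
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    for (k in kids) if (count(k)) n_losses <<- n_losses + 1L
    FALSE
  }
  if (count(dup_node)) stop("degenerate scenario: no descendant carries the sub-lineage")
  n_losses
}

#' Evaluate a duplication-timing scenario
#'
#' Under the hypothesis that the sub-lineage's copy arose on
#' `duplication_branch`, counts the extant descendant species lacking the
#' copy (`implied_species_losses`) and the minimal number of loss branches
#' explaining those absences under Dollo parsimony
#' (`implied_dollo_losses`; presence at the duplication node, no regain).
#' `event_total = 1 (duplication) + implied_dollo_losses` is the scenario's
#' parsimony cost.
#'
#' @param pm presence matrix ([presence_matrix()])
#' @param st a [species_tree()]
#' @param sublineage column name of `pm`
#' @param duplication_branch branch selector ([resolve_branch()])
#' @return object of class `event_scenario`
#' @export
evaluate_scenario <- function(pm, st, sublineage, duplication_branch) {
  if (!sublineage %in% colnames(pm)) stop("unknown sub-lineage: ", sublineage)
  node <- resolve_branch(st, duplication_branch)
  desc <- tip_descendants(st$phy, node)
  counts <- setNames(rep(0L, length(desc)), desc)
  known <- intersect(desc, rownames(pm))
  counts[known] <- pm[known, sublineage]
  present <- names(counts)[counts > 0]
  if (!length(present)) stop("degenerate scenario: no descendant carries the sub-lineage")
  absent <- names(counts)[counts == 0]
  dollo <- dollo_losses(st$phy, node, present)
  structure(list(duplication_branch = node,
                 branch_label = branch_label(st$phy, node),
                 sublineage = sublineage,
                 implied_species_losses = length(absent),
                 implied_dollo_losses = dollo,
                 event_total = 1L + dollo),
            class = "event_scenario")
}

#' @export
print.event_scenario <- function(x, ...) {
  cat("scenario: duplication on branch '", x$branch_label, "' for ",
      x$sublineage, " -> ", x$implied_species_losses, " species loss(es), ",
      x$implied_dollo_losses, " Dollo loss event(s), total cost ",
      x$event_total, "\n", sep = "")
  invisible(x)
}

#' Rank duplication-timing scenarios
#'
#' Evaluates every branch on the path from the WGD branch down to the stem
#' of the most recent common ancestor of the species carrying the
#' sub-lineage (inclusive of both ends) and sorts scenarios by ascending
#' parsimony cost (`event_total`), ties broken toward more recent branches.
#'
#' @param pm presence matrix
#' @param st a [species_tree()] with a WGD mark
#' @param sublineage column of `pm`
#' @return list of `event_scenario`, best first
#' @export
rank_scenarios <- function(pm, st, sublineage) {
  if (is.null(st$wgd_node)) stop("species tree carries no WGD mark")
  if (!sublineage %in% colnames(pm)) stop("unknown sub-lineage: ", sublineage)
  carriers <- rownames(pm)[pm[, sublineage] > 0]
  if (!length(carriers)) stop("sub-lineage absent from every species")
  mrca <- if (length(carriers) == 1) match(carriers, st$phy$tip.label)
          else ape::getMRCA(st$phy, carriers)
  chain <- ancestor_chain(st$phy, mrca)
  if (st$wgd_node %in% chain) {
    cand <- chain[seq_len(match(st$wgd_node, chain))] # mrca .. wgd, inclusive
  } else if (mrca %in% ancestor_chain(st$phy, st$wgd_node)) {
    # carriers reach beyond the WGD clade: the only branch at issue relative
    # to the WGD is the WGD branch itself
    cand <- st$wgd_node
  } else {
    stop("carriers of ", sublineage, " do not all descend from the WGD branch")
  }
  depth <- ape::node.depth.edgelength(st$phy)         # distance from root
  scen <- lapply(cand, function(n) evaluate_scenario(pm, st, sublineage, n))
  cost <- vapply(scen, `[[`, integer(1), "event_total")
  recency <- depth[cand]
  scen[order(cost, -recency)]
}

#' Write ranked scenarios as a JSON report
#' @param scenarios list from [rank_scenarios()]
#' @param path output JSON
#' @export
write_scenarios_json <- function(scenarios, path) {
  out <- lapply(scenarios, function(s)
    list(branch = s$branch_label, sublineage = s$sublineage,
         implied_species_losses = s$implied_species_losses,
         implied_dollo_losses = s$implied_dollo_losses,
         event_total = s$event_total))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Flag unexpectedly similar cross-genus pairs
#'
#' Within a family, reports member pairs from different genera whose
#' identity exceeds the given quantile of within-genus identities — the
#' signature that prompts a lateral-transfer hypothesis. No transfer
#' inference is performed; this is a warning surface only.
#'
#' @param net similarity network
#' @param gs a [genome_set()]
#' @param members family genes
#' @param genus_of function mapping species code to genus (default: first
#'   two letters of the code)
#' @param quantile_cut quantile of within-genus identities (default 0.95)
#' @return data.frame of flagged pairs `gene_a, gene_b, identity_pct`
#' @export
flag_cross_genus_similarity <- function(net, gs, members,
                                        genus_of = function(sp) substr(sp, 1, 2),
                                        quantile_cut = 0.95) {
  sub <- igraph::induced_subgraph(net, intersect(members, igraph::V(net)$name))
  el <- igraph::as_data_frame(sub, what = "edges")
  if (!nrow(el)) return(data.frame(gene_a = character(), gene_b = character(),
                                   identity_pct = numeric()))
  ga <- genus_of(species_of(gs, el$from))
  gb <- genus_of(species_of(gs, el$to))
  within <- el$identity_pct[ga == gb]
  if (!length(within)) return(data.frame(gene_a = character(), gene_b = character(),
                                         identity_pct = numeric()))
  cut <- stats::quantile(within, quantile_cut, names = FALSE)
  hit <- ga != gb & el$identity_pct > cut
  out <- data.frame(gene_a = el$from[hit], gene_b = el$to[hit],
                    identity_pct = el$identity_pct[hit], stringsAsFactors = FALSE)
  if (nrow(out))
    warning(nrow(out), " cross-genus pair(s) with unexpectedly high identity")
  out
}
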