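#' Neighbor block around a family gene
#'
#' Wraps [neighbors_on_contig()] with 1-based offsets (nearest-first) and
#' contig-end flags: `end_upstream`/`end_downstream` are set when the contig
#' terminates within `k` genes on that side, the situation drawn as a "0"
#' box in neighborhood figures.
#'
#' @param gs a [genome_set()]
#' @param gene_id query gene
#' @param k neighbors per side (default 15)
#' @return object of class `neighbor_block`: `query`, `upstream`,
#'   `downstream` (data.frames `gene_id`, `offset`), `end_upstream`,
#'   `end_downstream`, `k`
#' @export
build_block <- function(gs, gene_id, k = 15) {
  nb <- neighbors_on_contig(gs, gene_id, k)
  q <- locus_of(gs, gene_id)
  up <- data.frame(gene_id = nb$upstream$gene_id,
                   offset = seq_len(nrow(nb$upstream)), stringsAsFactors = FALSE)
  down <- data.frame(gene_id = nb$downstream$gene_id,
                     offset = seq_len(nrow(nb$downstream)), stringsAsFactors = FALSE)
  structure(list(query = gene_id, upstream = up, downstream = down,
                 end_upstream = q$position - 1 < k,
                 end_downstream = nb$contig_length - q$position < k,
                 k = k),
            class = "neighbor_block")
}

block_neighbors <- function(block, exclude = character()) {
  up <- block$upstream; up$side <- rep("up", nrow(up))
  down <- block$downstream; down$side <- rep("down", nrow(down))
  nb <- rbind(up, down)
  nb[!nb$gene_id %in% exclude, , drop = FALSE]
}

#' Synteny weight configuration
#'
#' The per-match weight multiplies the three evidence sources for shared
#' neighbors: proximity to the query genes, sequence similarity of the
#' matched neighbor pair, and (inversely, log-scaled) the size of the
#' sequence cluster the pair belongs to — small clusters are less likely to
#' flank both queries by chance and therefore weigh more.
#'
#' @param strong_min minimum shared-neighbor count for a `strong` edge
#'   (default 5); counts 1..`strong_min`-1 are `weak`, 0 is `none`
#' @return list of weight settings
#' @export
synteny_weights <- function(strong_min = 5) {
  list(strong_min = strong_min)
}

#' Score synteny between two neighbor blocks
#'
#' For every sequence cluster represented in both blocks, neighbor pairs are
#' matched one-to-one greedily by ascending offset sum (near-query
#' conservation first). Each matched pair contributes
#' `w = w_dist * w_sim * w_clu` with
#' `w_dist = ((k - off_a + 1) + (k - off_b + 1)) / (2k)`,
#' `w_sim` the identity fraction of the matched pair (1 when the network has
#' no direct edge for the pair, recorded in the match table), and
#' `w_clu = 1 / (1 + log10(cluster_size))`. The edge strength is the sum of
#' weights; the category is `strong`/`weak`/`none` by the shared-neighbor
#' count. Scoring is symmetric in the two blocks, and the query genes
#' themselves never count as shared neighbors.
#'
#' @param block_a,block_b [build_block()] results
#' @param clusters a [cluster_at()] assignment covering every neighbor
#' @param net similarity network (for matched-pair identities)
#' @param weights_cfg a [synteny_weights()] list
#' @return object of class `synteny_edge`: `gene_a`, `gene_b`, `matches`
#'   data.frame, `raw_count`, `strength`, `category`
#' @export
score_synteny <- function(block_a, block_b, clusters, net,
                          weights_cfg = synteny_weights()) {
  k <- block_a$k
  stopifnot(identical(k, block_b$k))
  queries <- c(block_a$query, block_b$query)
  na_ <- block_neighbors(block_a, exclude = queries)
  nb_ <- block_neighbors(block_b, exclude = queries)
  cl_a <- clusters$membership[na_$gene_id]
  cl_b <- clusters$membership[nb_$gene_id]
  un <- c(na_$gene_id[is.na(cl_a)], nb_$gene_id[is.na(cl_b)])
  if (length(un))
    stop("neighbor(s) lack a cluster assignment: ",
         paste(head(unique(un), 5), collapse = ", "),
         " (re-cluster at the fallback threshold)")
  shared <- intersect(unique(cl_a), unique(cl_b))
  acc <- list()
  for (cl in shared) {
    ca <- na_[cl_a == cl, , drop = FALSE]
    cb <- nb_[cl_b == cl, , drop = FALSE]
    cand <- expand.grid(ia = seq_len(nrow(ca)), ib = seq_len(nrow(cb)))
    cand$sum <- ca$offset[cand$ia] + cb$offset[cand$ib]
    ga <- ca$gene_id[cand$ia]; gb <- cb$gene_id[cand$ib]
    cand <- cand[order(cand$sum, pmin(ga, gb), pmax(ga, gb)), , drop = FALSE]
    used_a <- logical(nrow(ca)); used_b <- logical(nrow(cb))
    sel_a <- integer(); sel_b <- integer()
    for (r in seq_len(nrow(cand))) {
      ia <- cand$ia[r]; ib <- cand$ib[r]
      if (used_a[ia] || used_b[ib]) next
      used_a[ia] <- used_b[ib] <- TRUE
      sel_a <- c(sel_a, ia); sel_b <- c(sel_b, ib)
    }
    acc[[cl]] <- data.frame(neighbor_a = ca$gene_id[sel_a],
                            neighbor_b = cb$gene_id[sel_b],
                            cluster_id = cl,
                            offset_a = ca$offset[sel_a],
                            offset_b = cb$offset[sel_b],
                            identity_pct = NA_real_,
                            cluster_size = unname(clusters$sizes[cl]),
                            weight = NA_real_, stringsAsFactors = FALSE)
  }
  matches <- if (length(acc)) do.call(rbind, acc) else
    data.frame(neighbor_a = character(), neighbor_b = character(),
               cluster_id = character(), offset_a = integer(),
               offset_b = integer(), identity_pct = numeric(),
               cluster_size = integer(), weight = numeric(),
               stringsAsFactors = FALSE)
  rownames(matches) <- NULL
  if (nrow(matches)) {
    matches$identity_pct <- edge_identity(net, matches$neighbor_a, matches$neighbor_b)
    w_dist <- ((k - matches$offset_a + 1) + (k - matches$offset_b + 1)) / (2 * k)
    w_sim <- ifelse(is.na(matches$identity_pct), 1, matches$identity_pct / 100)
    w_clu <- 1 / (1 + log10(matches$cluster_size))
    matches$weight <- w_dist * w_sim * w_clu
  }
  raw <- nrow(matches)
  structure(list(gene_a = block_a$query, gene_b = block_b$query,
                 matches = matches, raw_count = raw,
                 strength = sum(matches$weight),
                 category = if (raw == 0) "none"
                            else if (raw >= weights_cfg$strong_min) "strong"
                            else "weak",
                 evidence_level = NA_character_),
            class = "synteny_edge")
}

edge_identity <- function(net, a, b) {
  # vectorized: identity of the network edge for each (a[i], b[i]) pair,
  # NA where no direct edge exists
  if (!length(a)) return(numeric())
  eid <- suppressWarnings(igraph::get_edge_ids(net, rbind(a, b), error = FALSE))
  out <- rep(NA_real_, length(a))
  hit <- !is.na(eid) & eid > 0
  out[hit] <- igraph::E(net)$identity_pct[eid[hit]]
  out
}

#' All-vs-all synteny network over a family
#'
#' Builds +/-`k` neighbor blocks for every unflagged family member, assigns
#' every neighbor to a sequence cluster at the conservative threshold
#' `cluster_t`, and scores all member pairs. Pairs with no shared neighbor
#' whose blocks contain neighbors left unclustered (singletons) at
#' `cluster_t` are rescored with clusters formed at the permissive
#' `fallback_t`; an edge recovered this way is marked as
#' corroboration-level evidence (`evidence_level` `"E-40"`-style, i.e. the
#' fallback exponent).
#'
#' @param fam a [merge_families()] result (flags respected)
#' @param gs a [genome_set()]
#' @param net similarity network
#' @param cluster_t conservative clustering threshold (default 1e-50)
#' @param fallback_t corroboration threshold (default 1e-40)
#' @param k neighbors per side (default 15)
#' @param weights_cfg a [synteny_weights()] list
#' @return list of `synteny_edge` objects (one per unordered member pair)
#' @export
synteny_network <- function(fam, gs, net, cluster_t = 1e-50,
                            fallback_t = 1e-40, k = 15,
                            weights_cfg = synteny_weights()) {
  members <- unflagged_members(fam)
  if (!length(members)) stop("family has no unflagged members")
  blocks <- lapply(members, build_block, gs = gs, k = k)
  names(blocks) <- members
  all_nb <- unique(unlist(lapply(blocks, function(b)
    c(b$upstream$gene_id, b$downstream$gene_id))))
  all_nb <- setdiff(all_nb, members)
  known <- intersect(all_nb, igraph::V(net)$name)
  net_aug <- if (length(setdiff(all_nb, known)))
    igraph::add_vertices(net, length(setdiff(all_nb, known)),
                         name = setdiff(all_nb, known)) else net
  clus <- cluster_at(net_aug, cluster_t, include = all_nb)
  clus_fb <- NULL
  edges <- list()
  if (length(members) < 2) return(edges)
  pairs <- combn(members, 2)
  main_exp <- round(log10(cluster_t))
  fb_exp <- round(log10(fallback_t))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    e <- score_synteny(blocks[[a]], blocks[[b]], clus, net_aug, weights_cfg)
    e$evidence_level <- paste0("E", main_exp)
    if (e$category == "none") {
      nb_ab <- c(blocks[[a]]$upstream$gene_id, blocks[[a]]$downstream$gene_id,
                 blocks[[b]]$upstream$gene_id, blocks[[b]]$downstream$gene_id)
      if (any(startsWith(unname(clus$membership[intersect(nb_ab, names(clus$membership))]), "S"))) {
        if (is.null(clus_fb))
          clus_fb <- cluster_at(net_aug, fallback_t, include = all_nb)
        e2 <- score_synteny(blocks[[a]], blocks[[b]], clus_fb, net_aug, weights_cfg)
        if (e2$category != "none") {
          e2$evidence_level <- paste0("E", fb_exp)
          e <- e2
        }
      }
    }
    edges[[length(edges) + 1L]] <- e
  }
  edges
}

#' Flatten synteny edges to a data.frame
#' @param edges list of `synteny_edge` objects
#' @param keep_none keep category-`none` pairs (default FALSE)
#' @return data.frame `gene_a, gene_b, raw_count, strength, category,
#'   evidence_level`
#' @export
synteny_edge_table <- function(edges, keep_none = FALSE) {
  df <- do.call(rbind, lapply(edges, function(e)
    data.frame(gene_a = e$gene_a, gene_b = e$gene_b, raw_count = e$raw_count,
               strength = e$strength, category = e$category,
               evidence_level = e$evidence_level, stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(gene_a = character(), gene_b = character(),
                     raw_count = integer(), strength = numeric(),
                     category = character(), evidence_level = character())
  if (!keep_none) df <- df[df$category != "none", , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Neighborhood report table
#'
#' One row per neighbor of each query gene (query, side, offset, neighbor,
#' cluster id and size), the tabular analogue of a neighborhood figure.
#' `truncate` limits the displayed offsets per side (figures conventionally
#' truncate to 5).
#'
#' @param blocks named list of [build_block()] results
#' @param clusters a [cluster_at()] assignment
#' @param truncate keep offsets `<= truncate` (NULL = all)
#' @return data.frame
#' @export
neighborhood_report <- function(blocks, clusters, truncate = NULL) {
  rows <- lapply(blocks, function(b) {
    nb <- block_neighbors(b)
    if (!nrow(nb)) return(NULL)
    data.frame(query = b$query, side = nb$side, offset = nb$offset,
               neighbor_id = nb$gene_id,
               cluster_id = unname(clusters$membership[nb$gene_id]),
               cluster_size = unname(clusters$sizes[clusters$membership[nb$gene_id]]),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) return(data.frame())
  if (!is.null(truncate)) df <- df[df$offset <= truncate, , drop = FALSE]
  rownames(df) <- NULL
  df
}
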