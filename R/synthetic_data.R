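#' Simulation configuration
#'
#' Describes a genome-evolution simulation down a species tree: an ancestral
#' genome of unrelated random proteins evolves by per-branch gene-level
#' events (tandem/dispersed duplication, loss, translocation, local
#' gene-order shuffling), an optional whole-genome duplication on the marked
#' branch followed by stochastic ohnolog retention, and uniform-rate amino
#' acid substitution. The configuration plus the RNG seed fully determine
#' the output.
#'
#' @param species_tree a [species_tree()]; defaults to the 14-species yeast
#'   fixture tree with its WGD mark ([fixture_species_tree()])
#' @param genes_per_contig genes per ancestral contig (default 50)
#' @param contigs_per_genome ancestral contigs (default 3)
#' @param family_seed_count number of ancestral genes designated as the
#'   focal family (placed mid-contig so full +/-15 neighborhoods exist)
#' @param rates per-gene per-branch event probabilities:
#'   `duplication_tandem`, `duplication_dispersed`, `loss`, `translocation`
#'   (mutually exclusive per gene per branch) and `neighborhood_shuffle`
#'   (per contig per branch). Defaults make loss the commonest event and
#'   interchromosomal relocations an order of magnitude rarer, mirroring
#'   the strong gene-order conservation of the yeasts the method targets
#' @param substitution expected substitutions/site per branch (default 0.03;
#'   on the fixture tree this yields typical between-species identities of
#'   roughly 75-90%)
#' @param protein_length ancestral protein length (default 200)
#' @param wgd_retention retention probability of each WGD-created gene copy
#'   (default 0.15, emulating massive post-WGD ohnolog loss)
#' @param protect_lineages ancestral gene ids exempt from stochastic loss,
#'   duplication and relocation (tandem duplication and shuffling still
#'   apply). Used to condition a simulation on the survival of a planted
#'   focal-family history; planted events still act on protected lineages
#' @param planted_events list of deterministic events to inject, each a list
#'   with `branch` (selector as in [resolve_branch()]), `type`
#'   (`duplication_tandem`, `duplication_dispersed`, `loss`,
#'   `translocation`), `lineage` (ancestral gene id), `origin` (which copy:
#'   `ancestral`, `wgd`, `dispersed`, `tandem`), and for dispersed
#'   duplications `target_contig`/`insert_at`
#' @param sequences simulate protein sequences (FALSE = gene content only,
#'   used for fast birth-death calibration checks)
#' @param rng_seed integer seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(species_tree = fixture_species_tree(),
                       genes_per_contig = 50, contigs_per_genome = 3,
                       family_seed_count = 1,
                       rates = list(), substitution = 0.03,
                       protein_length = 200, wgd_retention = 0.15,
                       protect_lineages = character(),
                       planted_events = list(), sequences = TRUE,
                       rng_seed = 1) {
  r <- modifyList(list(duplication_tandem = 0.001, duplication_dispersed = 1e-5,
                       loss = 0.003, translocation = 1e-5,
                       neighborhood_shuffle = 0.05), rates)
  probs <- unlist(r)
  if (any(probs < 0 | probs > 1)) stop("event rates must be probabilities in [0,1]")
  if (r$loss >= 1) stop("loss rate of 1 would empty the genomes")
  if (genes_per_contig < 1 || contigs_per_genome < 1)
    stop("genome dimensions imply empty genomes")
  if (family_seed_count > contigs_per_genome)
    stop("at most one family seed per contig is placed")
  structure(list(species_tree = species_tree,
                 genes_per_contig = genes_per_contig,
                 contigs_per_genome = contigs_per_genome,
                 family_seed_count = family_seed_count,
                 rates = r, substitution = substitution,
                 protein_length = protein_length,
                 wgd_retention = wgd_retention,
                 protect_lineages = protect_lineages,
                 planted_events = planted_events,
                 sequences = sequences,
                 rng_seed = rng_seed),
            class = "sim_config")
}

#' The fixture species tree
#'
#' A rooted 14-species Saccharomycetaceae-style tree: four Saccharomyces
#' species sister to a Nakaseomyces representative (cagl), then the
#' Kazachstania pair (kaaf, kana) and the Naumovozyma pair (naca, nada)
#' inside the post-WGD clade, with Zygosaccharomyces / Torulaspora /
#' Lachancea / Kluyveromyces codes as pre-WGD outgroups. The WGD mark sits
#' on the stem of the post-WGD clade.
#'
#' @return a [species_tree()] with WGD mark
#' @export
fixture_species_tree <- function() {
  nwk <- paste0("(((((((sace,sapa)SS1,saku)SS2,saar)Saccharomyces,cagl)NakSac,",
                "(kaaf,kana)Kazachstania)KNS,(naca,nada)Naumovozyma)postWGD,",
                "((zyro,zyba)Zygosaccharomyces,(tode,(lakl,klla)Lachancea)preLK)preWGD)root;")
  species_tree(ape::read.tree(text = nwk), wgd = "postWGD")
}

#' Qualitative presence pattern of the studied family
#'
#' Hard-coded fixture encoding the published species-level pattern for the
#' Snq2/Pdr18-like family on the fixture species tree: every species
#' carries the `snq2` sub-lineage (single homolog in the Nakaseomyces,
#' Naumovozyma and Kazachstania species), while the `pdr18` sub-lineage
#' occurs exclusively in the four Saccharomyces species. Used by the
#' lineage tests and the worked example: a duplication placed on the WGD
#' branch implies the loss of the `pdr18` copy in the five non-Saccharomyces
#' species of the post-WGD core clade.
#'
#' @return list with `presence` (species x sub-lineage count matrix) and
#'   `species_tree`
#' @export
paper_pattern_fixture <- function() {
  st <- fixture_species_tree()
  species <- sort(st$phy$tip.label)
  pm <- matrix(0L, length(species), 2, dimnames = list(species, c("pdr18", "snq2")))
  pm[, "snq2"] <- 1L
  pm[c("sace", "sapa", "saku", "saar"), "pdr18"] <- 1L
  list(presence = pm, species_tree = st)
}

## ---- internal simulation machinery -------------------------------------

new_registry <- function() {
  e <- new.env(parent = emptyenv())
  e$counter <- 0L
  e$lineage <- character()
  e$origin <- character()
  e$group <- character()
  e
}

register_instance <- function(reg, id, lineage, origin, group) {
  reg$lineage[id] <- lineage
  reg$origin[id] <- origin
  reg$group[id] <- group
  id
}

spawn_instance <- function(reg, src, origin) {
  reg$counter <- reg$counter + 1L
  id <- paste0(reg$lineage[[src]], "_",
               c(wgd = "w", tandem = "t", dispersed = "x", translocation = "m")[[origin]],
               reg$counter)
  group <- if (origin == "tandem") reg$group[[src]] else id
  register_instance(reg, id, reg$lineage[[src]], origin, group)
}

#' Apply one logged event to a genome layout
#'
#' The layout is a named list of contigs, each an ordered character vector
#' of gene instance ids. Events carry complete placement details, so the
#' log can be replayed deterministically without the simulator's RNG.
#'
#' @param layout named list of character vectors
#' @param ev one event record from the simulator's event log
#' @return the modified layout
#' @export
apply_sim_event <- function(layout, ev) {
  find_instance <- function(id) {
    for (cn in names(layout)) {
      i <- match(id, layout[[cn]])
      if (!is.na(i)) return(list(contig = cn, pos = i))
    }
    NULL
  }
  insert_at <- function(v, x, at) append(v, x, after = at - 1L)
  switch(ev$type,
    WGD = {
      for (cn in names(ev$details$new_contigs))
        layout[[cn]] <- ev$details$new_contigs[[cn]]
      layout
    },
    loss = {
      w <- find_instance(ev$instance)
      if (!is.null(w)) layout[[w$contig]] <- layout[[w$contig]][-w$pos]
      layout
    },
    duplication_tandem = {
      w <- find_instance(ev$instance)
      if (is.null(w)) stop("tandem source not in layout: ", ev$instance)
      layout[[w$contig]] <- insert_at(layout[[w$contig]], ev$details$new, w$pos + 1L)
      layout
    },
    duplication_dispersed = {
      layout[[ev$details$target_contig]] <-
        insert_at(layout[[ev$details$target_contig]], ev$details$new,
                  ev$details$insert_at)
      layout
    },
    translocation = {
      w <- find_instance(ev$instance)
      if (is.null(w)) stop("translocation source not in layout: ", ev$instance)
      layout[[w$contig]] <- layout[[w$contig]][-w$pos]
      layout[[ev$details$target_contig]] <-
        insert_at(layout[[ev$details$target_contig]], ev$instance,
                  ev$details$insert_at)
      layout
    },
    shuffle = {
      idx <- ev$details$start + seq_along(ev$details$perm) - 1L
      layout[[ev$details$contig]][idx] <- layout[[ev$details$contig]][idx][ev$details$perm]
      layout
    },
    stop("unknown event type: ", ev$type))
}

mutate_sequences <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  for (id in names(seqs)) {
    s <- seqs[[id]]
    n <- rbinom(1L, length(s), rate)
    if (n == 0L) next
    pos <- sample.int(length(s), n)
    repl <- sample(.AA_ALPHABET, n, replace = TRUE)
    clash <- repl == s[pos]
    while (any(clash)) {
      repl[clash] <- sample(.AA_ALPHABET, sum(clash), replace = TRUE)
      clash <- repl == s[pos]
    }
    s[pos] <- repl
    seqs[[id]] <- s
  }
  seqs
}

#' Simulate a multi-species genome set with a known event history
#'
#' Evolves an ancestral genome down the configured species tree and returns
#' the leaf genomes as a [genome_set()], a ground-truth table per leaf gene
#' (instance, ancestral lineage, neighborhood-origin group, copy origin,
#' family membership), the "true" pairwise hit table computed from known
#' homology (only genes of the same ancestral lineage are homologous; no
#' indels, so identity is positionwise), and a replayable event log.
#' Everything is deterministic under `rng_seed`.
#'
#' @param cfg a [sim_config()]
#' @return list with `genome_set`, `truth`, `hits`, `event_log`,
#'   `ancestral_layout`, `leaf_layouts`, `species_tree`, `family_lineages`,
#'   `planted_instances` (new instance ids created by planted events), `cfg`
#' @export
simulate_genomes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed)
  st <- cfg$species_tree
  phy <- st$phy
  reg <- new_registry()
  log_env <- new.env(parent = emptyenv())
  log_env$events <- list()
  log_env$planted_new <- character()
  push_event <- function(ev) log_env$events[[length(log_env$events) + 1L]] <- ev

  # ancestral genome
  L <- cfg$protein_length
  layout <- list()
  seqs <- list()
  gi <- 0L
  fam_positions <- integer()
  for (cix in seq_len(cfg$contigs_per_genome)) {
    ids <- character(cfg$genes_per_contig)
    for (p in seq_len(cfg$genes_per_contig)) {
      gi <- gi + 1L
      id <- sprintf("g%03d", gi)
      register_instance(reg, id, id, "ancestral", id)
      ids[p] <- id
      if (cfg$sequences) seqs[[id]] <- sample(.AA_ALPHABET, L, replace = TRUE)
    }
    layout[[paste0("c", cix)]] <- ids
  }
  fam_lineages <- character()
  mid <- max(1L, cfg$genes_per_contig %/% 2L)
  for (f in seq_len(cfg$family_seed_count))
    fam_lineages <- c(fam_lineages, layout[[paste0("c", f)]][mid])
  ancestral_layout <- layout

  planted_node <- vapply(cfg$planted_events, function(pe)
    resolve_branch(st, pe$branch), integer(1))

  leaf_layouts <- list()
  leaf_seqs <- list()

  resolve_target <- function(state, lineage, origin) {
    all_inst <- unlist(state$layout, use.names = FALSE)
    hit <- all_inst[reg$lineage[all_inst] == lineage & reg$origin[all_inst] == origin]
    if (length(hit)) hit[[1]] else NA_character_
  }

  descend <- function(node, state) {
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    for (child in kids) {
      s <- state
      blab <- branch_label(phy, child)
      # 1. WGD on the marked branch, then stochastic ohnolog retention
      if (!is.null(st$wgd_node) && child == st$wgd_node) {
        copies_src <- character(); copies_new <- character()
        new_contigs <- list()
        for (cn in names(s$layout)) {
          news <- vapply(s$layout[[cn]], function(src) spawn_instance(reg, src, "wgd"),
                         character(1), USE.NAMES = FALSE)
          if (cfg$sequences) for (i in seq_along(news)) s$seqs[[news[i]]] <- s$seqs[[s$layout[[cn]][i]]]
          copies_src <- c(copies_src, s$layout[[cn]]); copies_new <- c(copies_new, news)
          new_contigs[[paste0(cn, "w")]] <- news
        }
        ev <- list(branch_node = child, branch = blab, type = "WGD",
                   instance = NA_character_,
                   details = list(copies = data.frame(src = copies_src, new = copies_new,
                                                      stringsAsFactors = FALSE),
                                  new_contigs = new_contigs))
        s$layout <- apply_sim_event(s$layout, ev); push_event(ev)
        lost <- copies_new[runif(length(copies_new)) > cfg$wgd_retention]
        for (id in lost) {
          ev <- list(branch_node = child, branch = blab, type = "loss",
                     instance = id, details = list())
          s$layout <- apply_sim_event(s$layout, ev); push_event(ev)
          s$seqs[[id]] <- NULL
        }
      }
      # 2. planted events for this branch
      for (pi in seq_along(cfg$planted_events)) {
        if (planted_node[pi] != child) next
        pe <- cfg$planted_events[[pi]]
        src <- resolve_target(s, pe$lineage, pe$origin %||% "ancestral")
        if (is.na(src)) next   # targeted copy no longer exists on this branch
        ev <- switch(pe$type,
          loss = list(branch_node = child, branch = blab, type = "loss",
                      instance = src, details = list(planted = TRUE)),
          duplication_tandem = {
            new <- spawn_instance(reg, src, "tandem")
            if (cfg$sequences) s$seqs[[new]] <- s$seqs[[src]]
            log_env$planted_new <- c(log_env$planted_new, new)
            list(branch_node = child, branch = blab, type = "duplication_tandem",
                 instance = src, details = list(new = new, planted = TRUE))
          },
          duplication_dispersed = {
            new <- spawn_instance(reg, src, "dispersed")
            if (cfg$sequences) s$seqs[[new]] <- s$seqs[[src]]
            log_env$planted_new <- c(log_env$planted_new, new)
            list(branch_node = child, branch = blab, type = "duplication_dispersed",
                 instance = src,
                 details = list(new = new, target_contig = pe$target_contig,
                                insert_at = pe$insert_at, planted = TRUE))
          },
          stop("unsupported planted event type: ", pe$type))
        if (ev$type == "loss") s$seqs[[src]] <- NULL
        s$layout <- apply_sim_event(s$layout, ev); push_event(ev)
      }
      # 3. stochastic per-gene events (at most one per gene per branch)
      r <- cfg$rates
      genes_now <- unlist(s$layout, use.names = FALSE)
      u <- runif(length(genes_now))
      for (i in seq_along(genes_now)) {
        id <- genes_now[i]
        ev <- NULL
        if (reg$lineage[[id]] %in% cfg$protect_lineages &&
            u[i] < r$loss + r$duplication_tandem + r$duplication_dispersed + r$translocation) {
          if (u[i] >= r$loss && u[i] < r$loss + r$duplication_tandem) {
            # tandem duplication is allowed for protected lineages
          } else next
        }
        if (u[i] < r$loss) {
          ev <- list(branch_node = child, branch = blab, type = "loss",
                     instance = id, details = list())
          s$seqs[[id]] <- NULL
        } else if (u[i] < r$loss + r$duplication_tandem) {
          new <- spawn_instance(reg, id, "tandem")
          if (cfg$sequences) s$seqs[[new]] <- s$seqs[[id]]
          ev <- list(branch_node = child, branch = blab, type = "duplication_tandem",
                     instance = id, details = list(new = new))
        } else if (u[i] < r$loss + r$duplication_tandem + r$duplication_dispersed) {
          new <- spawn_instance(reg, id, "dispersed")
          if (cfg$sequences) s$seqs[[new]] <- s$seqs[[id]]
          tc <- sample(names(s$layout), 1)
          ev <- list(branch_node = child, branch = blab, type = "duplication_dispersed",
                     instance = id,
                     details = list(new = new, target_contig = tc,
                                    insert_at = sample.int(length(s$layout[[tc]]) + 1L, 1)))
        } else if (u[i] < r$loss + r$duplication_tandem + r$duplication_dispersed + r$translocation) {
          tc <- sample(names(s$layout), 1)
          ev <- list(branch_node = child, branch = blab, type = "translocation",
                     instance = id,
                     details = list(target_contig = tc,
                                    insert_at = sample.int(
                                      length(s$layout[[tc]]) + (tc != contig_of(s$layout, id)), 1)))
        }
        if (!is.null(ev)) { s$layout <- apply_sim_event(s$layout, ev); push_event(ev) }
      }
      # 4. local gene-order shuffling
      for (cn in names(s$layout)) {
        len <- length(s$layout[[cn]])
        if (len >= 4 && runif(1) < r$neighborhood_shuffle) {
          start <- sample.int(len - 3L, 1)
          ev <- list(branch_node = child, branch = blab, type = "shuffle",
                     instance = NA_character_,
                     details = list(contig = cn, start = start, perm = sample.int(4L)))
          s$layout <- apply_sim_event(s$layout, ev); push_event(ev)
        }
      }
      # 5. substitutions
      if (cfg$sequences) s$seqs <- mutate_sequences(s$seqs, cfg$substitution)
      if (child <= length(phy$tip.label)) {
        leaf_layouts[[phy$tip.label[child]]] <<- s$layout
        leaf_seqs[[phy$tip.label[child]]] <<- s$seqs
      } else descend(child, s)
    }
  }
  descend(root_node(phy), list(layout = layout, seqs = seqs))

  # assemble the leaf genome set + truth table
  rows <- list(); prot <- character(); strands <- character(0)
  for (sp in phy$tip.label) {
    lay <- leaf_layouts[[sp]]
    for (cn in names(lay)) {
      inst <- lay[[cn]]
      if (!length(inst)) next
      gene_ids <- paste(sp, inst, sep = "_")
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_ids, genome_id = sp, contig_id = cn,
        position = seq_along(inst),
        strand = sample(c("+", "-"), length(inst), replace = TRUE),
        instance = inst,
        lineage = unname(reg$lineage[inst]),
        group = unname(reg$group[inst]),
        origin = unname(reg$origin[inst]),
        stringsAsFactors = FALSE)
      if (cfg$sequences)
        prot[gene_ids] <- vapply(leaf_seqs[[sp]][inst], paste, character(1), collapse = "")
    }
  }
  truth <- do.call(rbind, rows)
  truth$family <- truth$lineage %in% fam_lineages
  gs <- NULL
  if (cfg$sequences) {
    gs <- genome_set(truth[, c("gene_id", "genome_id", "contig_id", "position", "strand")],
                     prot, setNames(phy$tip.label, phy$tip.label))
  }
  hits <- if (cfg$sequences) true_hit_table(truth, leaf_seqs, L) else NULL
  list(genome_set = gs, truth = truth, hits = hits,
       event_log = log_env$events,
       ancestral_layout = ancestral_layout, leaf_layouts = leaf_layouts,
       species_tree = st, family_lineages = fam_lineages,
       planted_instances = log_env$planted_new, cfg = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

contig_of <- function(layout, id) {
  for (cn in names(layout)) if (id %in% layout[[cn]]) return(cn)
  NA_character_
}

#' True hit table from known homology
#'
#' Genes descending from the same ancestral gene are homologous; all other
#' pairs are not. Identity is the positionwise match fraction (the simulator
#' introduces no indels), similarity adds a fixed fraction of the
#' mismatched positions as positive substitutions, and the e-value comes
#' from a calibrated bit-score model (`raw = 5*matches - mismatches`,
#' Karlin-Altschul with the gapped constants) so that sequence divergence
#' maps onto a realistic e-value scale: identical 200-residue proteins
#' score far below E-100 and ~50% identity sits near the E-40/E-50 window.
#'
#' @param truth truth table from [simulate_genomes()]
#' @param leaf_seqs per-species list of per-instance character vectors
#' @param L protein length
#' @return hit data.frame in the [ingest_hits()] layout
#' @export
true_hit_table <- function(truth, leaf_seqs, L) {
  Ntot <- L * nrow(truth)
  qs <- list(); ss <- list(); ms <- list()
  for (lin in unique(truth$lineage)) {
    idx <- which(truth$lineage == lin)
    n <- length(idx)
    if (n < 2) next
    # integer-encode the lineage's sequences and count pairwise matches by
    # summing per-letter indicator cross-products (no indels: equal lengths)
    M <- matrix(match(unlist(lapply(idx, function(i)
      leaf_seqs[[truth$genome_id[i]]][[truth$instance[i]]]), use.names = FALSE),
      .AA_ALPHABET), nrow = n, byrow = TRUE)
    matches <- matrix(0L, n, n)
    for (a in seq_along(.AA_ALPHABET)) {
      ind <- M == a
      if (any(ind)) matches <- matches + tcrossprod(ind)
    }
    pr <- which(upper.tri(matches), arr.ind = TRUE)
    qs[[lin]] <- truth$gene_id[idx[pr[, 1]]]
    ss[[lin]] <- truth$gene_id[idx[pr[, 2]]]
    ms[[lin]] <- matches[pr]
  }
  if (!length(qs))
    return(data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), identity_pct = numeric(),
                      similarity_pct = numeric(), score = numeric(),
                      aln_length = integer(), stringsAsFactors = FALSE))
  m <- unlist(ms, use.names = FALSE)
  idn <- 100 * m / L
  raw <- 5 * m - (L - m)
  data.frame(query_id = unlist(qs, use.names = FALSE),
             subject_id = unlist(ss, use.names = FALSE),
             evalue = karlin_altschul_evalue(raw, L, Ntot),
             identity_pct = idn,
             similarity_pct = idn + 0.4 * (100 - idn),
             score = raw, aln_length = L, stringsAsFactors = FALSE)
}

#' Replay an event log from the ancestral genome
#'
#' Re-applies the logged events (which carry complete placement details)
#' down the species tree and returns the per-leaf genome layouts. Replaying
#' the log of a simulation reproduces its leaf gene content exactly — the
#' ground-truth contract that parameter-recovery tests rely on.
#'
#' @param sim a [simulate_genomes()] result
#' @return named list of leaf layouts (contig -> instance vector)
#' @export
replay_event_log <- function(sim) {
  phy <- sim$species_tree$phy
  by_node <- split(sim$event_log,
                   vapply(sim$event_log, `[[`, numeric(1), "branch_node"))
  out <- list()
  walk <- function(node, layout) {
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    for (child in kids) {
      lay <- layout
      for (ev in by_node[[as.character(child)]] %||% list())
        lay <- apply_sim_event(lay, ev)
      if (child <= length(phy$tip.label)) out[[phy$tip.label[child]]] <<- lay
      else walk(child, lay)
    }
  }
  walk(root_node(phy), sim$ancestral_layout)
  out
}

#' Write a simulation to its on-disk formats
#'
#' Emits the genome-set files (FASTA, gene-order TSV, manifest), the
#' tabular hit file, the Newick species tree and a JSON event log. Output
#' is byte-identical for identical configurations and seeds.
#'
#' @param sim a [simulate_genomes()] result
#' @param dir output directory
#' @return invisibly, the file paths
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_genome_set(sim$genome_set, dir)
  hp <- file.path(dir, "hits.tsv")
  write_hits(sim$hits, hp)
  np <- file.path(dir, "species_tree.nwk")
  ape::write.tree(sim$species_tree$phy, np)
  lp <- file.path(dir, "event_log.json")
  slim <- lapply(sim$event_log, function(ev) {
    ev$details$copies <- NULL       # WGD copy map is bulky; contigs suffice
    ev
  })
  jsonlite::write_json(slim, lp, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", na = "null")
  tp <- file.path(dir, "truth.tsv")
  write.table(sim$truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, hits = hp, tree = np, event_log = lp, truth = tp))
}
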