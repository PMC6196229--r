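#' Read all-vs-all pairwise hits in blast tabular format
#'
#' Expects the 12-column outfmt-6 dialect
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`) plus an optional 13th column `ppos` carrying the
#' percentage of similar (positive-scoring) residues. Self-hits
#' (query == subject) are dropped; everything else is retained. When the
#' similarity column is absent, similarity is imputed as identity with a
#' one-time warning.
#'
#' @param path tabular hit file
#' @return data.frame of pairwise hits with columns `query_id`, `subject_id`,
#'   `evalue`, `identity_pct`, `similarity_pct`, `score`, `aln_length`
#' @export
ingest_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), identity_pct = numeric(),
                      similarity_pct = numeric(), score = numeric(),
                      aln_length = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 12L & nf != 13L)
  if (length(bad))
    stop("malformed hit row at line ", bad[1], ": expected 12 or 13 fields, got ", nf[bad[1]])
  has_ppos <- nf[1] == 13L
  if (!all(nf == nf[1]))
    stop("malformed hit file: mixed 12- and 13-column rows (first at line ",
         which(nf != nf[1])[1], ")")
  m <- do.call(rbind, parts)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) stop("malformed ", what, " at line ", which(is.na(v))[1])
    v
  }
  h <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    evalue = num(11, "e-value"),
    identity_pct = num(3, "identity"),
    similarity_pct = if (has_ppos) num(13, "ppos") else NA_real_,
    score = num(12, "bit score"),
    aln_length = as.integer(num(4, "alignment length")),
    stringsAsFactors = FALSE
  )
  if (!has_ppos) {
    warning("no similarity (ppos) column; imputing similarity_pct = identity_pct")
    h$similarity_pct <- h$identity_pct
  }
  if (any(h$evalue < 0)) stop("negative e-value at line ", which(h$evalue < 0)[1])
  h <- h[h$query_id != h$subject_id, , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Write pairwise hits in the 13-column tabular dialect
#'
#' Inverse of [ingest_hits()] for the fields the pipeline uses; positional
#' columns (qstart..send, mismatch, gapopen) are emitted as placeholders
#' consistent with the alignment length.
#'
#' @param hits data.frame as returned by [ingest_hits()] or [compute_hits()]
#' @param path output file
#' @export
write_hits <- function(hits, path) {
  n <- nrow(hits)
  mism <- round(hits$aln_length * (100 - hits$identity_pct) / 100)
  out <- data.frame(hits$query_id, hits$subject_id,
                    hits$identity_pct, hits$aln_length, mism, 0L,
                    1L, hits$aln_length, 1L, hits$aln_length,
                    format(hits$evalue, digits = 6, scientific = TRUE, trim = TRUE),
                    hits$score, hits$similarity_pct)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Compute all-vs-all pairwise hits by local alignment
#'
#' Smith-Waterman local alignment with BLOSUM62 and affine gaps
#' (open 11, extend 1), with e-values from the Karlin-Altschul formula
#' `E = K * m * N * exp(-lambda * S)` using the gapped constants
#' `lambda = 0.267`, `K = 0.041`, where `m` is the query length and `N` the
#' total residue count of the set. Identity and similarity percentages are
#' measured over aligned columns (similarity = positive substitution score).
#' Intended for small sets; externally computed tabular hits are the primary
#' input path for anything genome-scale.
#'
#' @param gs a [genome_set()] (needs at least 2 loci)
#' @param params list of alignment parameters; recognised entries
#'   `gap_open` (11), `gap_ext` (1), `matrix` ("BLOSUM62"),
#'   `lambda` (0.267), `K` (0.041), `max_evalue` (1e-3): hits with a larger
#'   e-value fall below the reporting floor and are dropped — a floor suited
#'   to homolog detection, still far above every threshold the pipeline
#'   applies downstream.
#' @return data.frame of hits in the [ingest_hits()] layout
#' @export
compute_hits <- function(gs, params = list()) {
  p <- modifyList(list(gap_open = 11, gap_ext = 1, matrix = "BLOSUM62",
                       lambda = 0.267, K = 0.041, max_evalue = 1e-3), params)
  seqs <- gs$proteins
  empty <- !nzchar(seqs)
  if (any(empty)) {
    warning("skipping empty sequence(s): ", paste(names(seqs)[empty], collapse = ", "))
    seqs <- seqs[!empty]
  }
  if (length(seqs) < 2) stop("need at least 2 sequences")
  utils::data(list = p$matrix, package = "Biostrings", envir = environment())
  submat <- get(p$matrix, envir = environment())
  Ntot <- sum(nchar(seqs))
  ids <- names(seqs)
  rows <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j) next
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[i]), Biostrings::AAString(seqs[j]),
      type = "local", substitutionMatrix = p$matrix,
      gapOpening = p$gap_open, gapExtension = p$gap_ext)
    S <- Biostrings::score(aln)
    ev <- karlin_altschul_evalue(S, nchar(seqs[i]), Ntot, p$lambda, p$K)
    if (!is.finite(ev) || ev > p$max_evalue) next
    qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ncol_aln <- length(qa)
    idn <- sum(qa == sa)
    both <- qa != "-" & sa != "-"
    colscore <- submat[cbind(match(qa[both], rownames(submat)),
                             match(sa[both], colnames(submat)))]
    pos <- sum(colscore > 0, na.rm = TRUE)   # positives include identities
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = ids[i], subject_id = ids[j], evalue = ev,
      identity_pct = 100 * idn / ncol_aln,
      similarity_pct = 100 * pos / ncol_aln,
      score = S, aln_length = ncol_aln, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), identity_pct = numeric(),
                      similarity_pct = numeric(), score = numeric(),
                      aln_length = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Karlin-Altschul e-value for a raw local alignment score
#' @param S raw score
#' @param m query length (residues)
#' @param N total residues searched
#' @param lambda,K gapped Karlin-Altschul constants
#' @return e-value (may underflow to 0 for very high scores)
#' @export
karlin_altschul_evalue <- function(S, m, N, lambda = 0.267, K = 0.041) {
  # computed in log space so long alignments do not underflow prematurely
  log10e <- log10(K) + log10(m) + log10(N) - lambda * S / log(10)
  10^pmax(log10e, -320)
}

#' Build an undirected similarity network from directed pairwise hits
#'
#' Each unordered gene pair becomes one edge carrying the best (minimum)
#' e-value over the directed hits that produced it, together with that best
#' hit's identity/similarity/score. Zero e-values are floored at
#' `10^log_floor` for log-scale operations; the floor is recorded on the
#' graph.
#'
#' @param hits data.frame from [ingest_hits()]/[compute_hits()]
#' @param nodes optional character vector of additional isolated nodes to
#'   carry (genes with no hits)
#' @param log_floor exponent used in place of e-value 0 (default -180)
#' @return an `igraph` object (the similarity network)
#' @export
build_network <- function(hits, nodes = NULL, log_floor = -180) {
  h <- hits
  if (nrow(h)) {
    h$evalue <- pmax(h$evalue, 10^log_floor)
    a <- pmin(h$query_id, h$subject_id)
    b <- pmax(h$query_id, h$subject_id)
    key <- paste(a, b, sep = "\r")
    o <- order(key, h$evalue)
    h <- h[o, , drop = FALSE]; a <- a[o]; b <- b[o]; key <- key[o]
    keep <- !duplicated(key)          # per pair, the minimum-e-value hit
    edges <- data.frame(from = a[keep], to = b[keep],
                        best_evalue = h$evalue[keep],
                        identity_pct = h$identity_pct[keep],
                        similarity_pct = h$similarity_pct[keep],
                        score = h$score[keep], stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        best_evalue = numeric(), identity_pct = numeric(),
                        similarity_pct = numeric(), score = numeric())
  }
  verts <- sort(unique(c(edges$from, edges$to, nodes)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = verts))
  igraph::graph_attr(g, "log_floor") <- log_floor
  g
}

#' Threshold-constrain a similarity network
#'
#' Keeps edges with best e-value at or below `threshold`; all nodes are
#' retained. Constraining is monotone: a more permissive threshold yields a
#' superset of edges.
#'
#' @param net similarity network ([build_network()])
#' @param threshold e-value cutoff (> 0)
#' @return constrained `igraph`
#' @export
constrain <- function(net, threshold) {
  stopifnot(threshold > 0)
  drop <- igraph::E(net)[igraph::E(net)$best_evalue > threshold]
  igraph::delete_edges(net, drop)
}

#' Sequence clusters at an e-value threshold
#'
#' Clusters are the connected components of the constrained network over
#' nodes incident to at least one qualifying edge; genes listed in `include`
#' that end up with no qualifying edge become singleton clusters of size 1.
#'
#' @param net similarity network
#' @param threshold e-value cutoff
#' @param include genes guaranteed a cluster assignment (singletons if
#'   isolated); must be nodes of `net`
#' @return list with `threshold`, `membership` (named cluster ids) and
#'   `sizes` (named integer member counts)
#' @export
cluster_at <- function(net, threshold, include = character()) {
  if (length(include)) {
    missing <- setdiff(include, igraph::V(net)$name)
    if (length(missing))
      stop("include gene(s) not in network: ", paste(head(missing, 5), collapse = ", "))
  }
  g <- constrain(net, threshold)
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  keep <- names(deg)[deg > 0]
  mem <- comp$membership[keep]
  # stable ids: number components by their lexicographically first member
  first <- tapply(names(mem), mem, min)
  relabel <- setNames(paste0("C", seq_along(sort(first))), names(sort(first)))
  membership <- setNames(unname(relabel[as.character(mem)]), names(mem))
  singles <- setdiff(include, names(membership))
  if (length(singles)) {
    singles <- sort(singles)
    membership <- c(membership,
                    setNames(paste0("S", seq_along(singles)), singles))
  }
  sizes <- table(membership)
  list(threshold = threshold,
       membership = membership,
       sizes = setNames(as.integer(sizes), names(sizes)))
}

#' Export a similarity network as edge-list TSV
#' @param net similarity network
#' @param path output TSV (`gene_a gene_b best_evalue identity_pct similarity_pct`)
#' @export
write_network_tsv <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  names(el)[1:2] <- c("gene_a", "gene_b")
  write.table(el[, c("gene_a", "gene_b", "best_evalue", "identity_pct", "similarity_pct")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a similarity network as GraphML
#' @param net similarity network
#' @param path output file
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
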