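#' Pairwise distance matrix from similarity-network identities
#'
#' Distance between two members is `1 - identity_fraction` of the best
#' pairwise hit connecting them. Pairs with no hit in the network get the
#' maximal observed distance plus `eps` (reported via a message). Distances
#' are uncorrected; an optional Poisson correction `-log(identity)` is
#' available since the lineage logic downstream depends on topology, not on
#' absolute branch lengths.
#'
#' @param net similarity network
#' @param members character vector of gene ids (>= 2), all nodes of `net`
#' @param eps padding added for missing pairs (default 0.01)
#' @param poisson apply the Poisson correction (default FALSE)
#' @return symmetric numeric matrix with zero diagonal, dimnames = members
#' @export
distances_from_hits <- function(net, members, eps = 0.01, poisson = FALSE) {
  members <- sort(unique(members))
  if (length(members) < 2) stop("need at least 2 members")
  missing <- setdiff(members, igraph::V(net)$name)
  if (length(missing)) stop("member(s) absent from network: ",
                            paste(head(missing, 5), collapse = ", "))
  sub <- igraph::induced_subgraph(net, members)
  el <- igraph::as_data_frame(sub, what = "edges")
  n <- length(members)
  d <- matrix(NA_real_, n, n, dimnames = list(members, members))
  diag(d) <- 0
  if (nrow(el)) {
    i <- match(el$from, members); j <- match(el$to, members)
    d[cbind(i, j)] <- d[cbind(j, i)] <- 1 - el$identity_pct / 100
  }
  if (anyNA(d)) {
    fill <- max(d, na.rm = TRUE) + eps
    message("distances_from_hits: ", sum(is.na(d)) / 2,
            " pair(s) without a hit set to max observed + ", eps)
    d[is.na(d)] <- fill
  }
  if (poisson) {
    off <- row(d) != col(d)
    d[off] <- -log(pmax(1 - d[off], 1e-6))
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining on a symmetric distance matrix.
#' Negative branch lengths (which NJ can produce on non-additive input) are
#' clamped to zero with the deficit moved to the adjacent branch so that
#' path lengths through the node are preserved. Additive matrices are
#' recovered exactly.
#'
#' @param dm symmetric matrix with zero diagonal and dimnames (>= 3 taxa)
#' @return an unrooted `ape::phylo` tree
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix is not symmetric")
  tr <- ape::nj(dm)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sib <- which(tr$edge[, 1] == parent & seq_along(tr$edge.length) != e)
    if (length(sib)) tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
  }
  tr
}

#' Leaf-to-leaf path-length matrix of a tree
#' @param tree `phylo` with branch lengths
#' @return symmetric matrix ordered by sorted tip label
#' @export
tree_path_lengths <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[order(rownames(m)), order(colnames(m))]
}

#' Root a tree on its most divergent leaf
#'
#' Re-roots on the pendant edge of the leaf with the largest mean distance
#' to all other leaves (the customary outgroup choice when no external
#' outgroup exists); ties break lexicographically. Rooting never changes
#' leaf-to-leaf path lengths.
#'
#' @param tree `phylo` whose tips all appear in `dm`
#' @param dm distance matrix (as in [distances_from_hits()])
#' @return rooted `phylo`
#' @export
root_by_most_divergent <- function(tree, dm) {
  tips <- tree$tip.label
  if (!all(tips %in% rownames(dm))) stop("tree tips missing from distance matrix")
  sub <- dm[tips, tips, drop = FALSE]
  mean_d <- rowSums(sub) / (length(tips) - 1)
  out <- sort(names(mean_d)[mean_d == max(mean_d)])[1]
  rooted <- ape::root(tree, outgroup = out, resolve.root = TRUE)
  attr(rooted, "outgroup") <- out
  rooted
}

p_distance_matrix <- function(aln) {
  # aln: character matrix, rows = sequences, columns = aligned positions
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- aln[i, ] != "-" & aln[j, ] != "-"
    d[i, j] <- d[j, i] <- if (any(ok)) mean(aln[i, ok] != aln[j, ok]) else 1
  }
  d
}

read_alignment_matrix <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  lens <- unique(Biostrings::width(s))
  if (length(lens) != 1)
    stop("sequences are not aligned (unequal lengths); bootstrap needs columns")
  m <- do.call(rbind, strsplit(as.character(s), ""))
  rownames(m) <- sub("\\s.*$", "", names(s))
  m
}

#' NJ tree with bootstrap support from an alignment
#'
#' Builds the p-distance NJ tree from an aligned protein FASTA and attaches
#' bipartition supports in `[0, 1]` obtained from `B` column-resampled
#' replicates (supports end up in `node.label`). Column resampling requires
#' an alignment: supports cannot be computed from a hit table alone, and a
#' missing/unaligned input is an explicit error.
#'
#' @param alignment path to an aligned FASTA, or a character matrix
#'   (rows = sequences)
#' @param B number of bootstrap replicates
#' @param seed RNG seed (same seed, same supports)
#' @return `phylo` with `node.label` = support fractions
#' @export
bootstrap_support <- function(alignment, B = 100, seed = 1) {
  if (is.null(alignment)) stop("no alignment available: bootstrap requires aligned columns")
  m <- if (is.character(alignment) && length(alignment) == 1) {
    if (!file.exists(alignment)) stop("no alignment available: file not found: ", alignment)
    read_alignment_matrix(alignment)
  } else if (is.matrix(alignment)) alignment
  else stop("alignment must be a FASTA path or a character matrix")
  stopifnot(B >= 1)
  main <- nj_tree(p_distance_matrix(m))
  set.seed(seed)
  counts <- ape::boot.phylo(main, m,
                            FUN = function(x) nj_tree(p_distance_matrix(x)),
                            B = B, quiet = TRUE, trees = FALSE)
  support <- counts / B
  support[is.na(support)] <- 1   # the trivial (root) partition is always present
  main$node.label <- support
  main
}
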