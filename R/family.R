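#' Seeded traversal of the similarity network
#'
#' Returns the connected component of the threshold-constrained network that
#' contains the seed (breadth-first reachability). Traversal is monotone in
#' the threshold and always contains the seed; two seeds lying in the same
#' component at a threshold retrieve identical sets.
#'
#' @param net similarity network ([build_network()])
#' @param seed gene id (must be a node)
#' @param threshold e-value cutoff
#' @return character vector of member gene ids (sorted)
#' @export
traverse <- function(net, seed, threshold) {
  if (!seed %in% igraph::V(net)$name) stop("unknown seed: ", seed)
  g <- constrain(net, threshold)
  sort(igraph::subcomponent(g, seed, mode = "all")$name)
}

#' Family-size sweep across an e-value grid
#'
#' Retrieves the traversal component of `seed` at every grid threshold,
#' from stringent to permissive. Counts are non-decreasing along the grid.
#'
#' @param net similarity network
#' @param seed gene id
#' @param grid integer/numeric vector of e-value exponents sorted stringent
#'   to permissive (e.g. `seq(-200, -20, by = 2)`); threshold i is
#'   `10^grid[i]`
#' @return list of class `sweep_curve`: `seed_id`, `grid`, `counts`
#' @export
sweep_family <- function(net, seed, grid = seq(-200, -20, by = 2)) {
  if (!length(grid)) stop("empty sweep grid")
  if (is.unsorted(grid)) stop("grid must be sorted stringent -> permissive (ascending exponents)")
  counts <- vapply(grid, function(e) length(traverse(net, seed, 10^e)), integer(1))
  structure(list(seed_id = seed, grid = grid, counts = counts),
            class = "sweep_curve")
}

#' @export
print.sweep_curve <- function(x, ...) {
  cat("sweep_curve for seed", x$seed_id, ":", length(x$grid), "thresholds,",
      "family size", min(x$counts), "->", max(x$counts), "\n")
  invisible(x)
}

#' Write a sweep curve as TSV (exponent, count)
#' @param curve a [sweep_family()] result
#' @param path output TSV
#' @export
write_sweep_tsv <- function(curve, path) {
  write.table(data.frame(exponent = curve$grid, count = curve$counts),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select a working threshold from a sweep curve (plateau rule)
#'
#' Finds the longest run of at least `stability_steps` consecutive grid
#' points whose family sizes stay within `tol_frac` (relative to the run's
#' first count) and returns the most stringent grid point opening that run;
#' ties are broken toward stringency. This formalises the usual practice of
#' picking the threshold where the retrieved family size stops growing
#' before the next jump onto an unrelated family. Runs where the traversal
#' retrieves only the seed (count 1) are not plateaus: they mark thresholds
#' stricter than the seed's nearest edge, so they never qualify.
#'
#' @param curve a [sweep_family()] result
#' @param stability_steps minimum run length (>= 2; default 5)
#' @param tol_frac relative tolerance within a run (default 0.01)
#' @return list with `exponent` and `evalue`
#' @export
select_threshold <- function(curve, stability_steps = 5, tol_frac = 0.01) {
  stopifnot(stability_steps >= 2)
  n <- length(curve$counts)
  if (!n) stop("empty sweep curve")
  run_len <- integer(n)
  for (i in seq_len(n)) {
    j <- i
    while (j < n && abs(curve$counts[j + 1] - curve$counts[i]) <= tol_frac * curve$counts[i])
      j <- j + 1
    run_len[i] <- j - i + 1
  }
  ok <- which(run_len >= stability_steps & curve$counts > 1)
  if (!length(ok))
    stop("no plateau: no run of ", stability_steps,
         " thresholds with counts within ", tol_frac, "; choose a threshold manually")
  best <- ok[which.max(run_len[ok])]   # which.max takes the first (most stringent) tie
  list(exponent = curve$grid[best], evalue = 10^curve$grid[best])
}

#' Merge per-seed traversal results into one family
#'
#' Takes the union of member sets from independent seeded traversals and
#' records each seed's threshold. Overlap between sets is reported (the
#' expectation for well-separated seeds is disjoint sets).
#'
#' @param results list of lists, each with `seed`, `threshold` (e-value) and
#'   `members` (character vector)
#' @return object of class `family_result` with `seeds`, `thresholds`,
#'   `members` (sorted union) and `flags` (initially empty)
#' @export
merge_families <- function(results) {
  if (!length(results)) stop("need at least one traversal result")
  seeds <- vapply(results, `[[`, character(1), "seed")
  thresholds <- setNames(vapply(results, `[[`, numeric(1), "threshold"), seeds)
  sets <- lapply(results, `[[`, "members")
  if (length(sets) > 1) {
    for (i in seq_along(sets)) for (j in seq_len(i - 1)) {
      ov <- intersect(sets[[i]], sets[[j]])
      if (length(ov))
        warning("traversals from seeds ", seeds[j], " and ", seeds[i],
                " overlap in ", length(ov), " gene(s)")
    }
  }
  members <- sort(unique(c(unlist(sets), seeds)))
  structure(list(seeds = seeds, thresholds = thresholds, members = members,
                 flags = list()),
            class = "family_result")
}

#' @export
print.family_result <- function(x, ...) {
  cat("family_result:", length(x$members), "members from",
      length(x$seeds), "seed(s);", length(x$flags), "flagged\n")
  invisible(x)
}

add_flag <- function(fam, gene_ids, flag) {
  for (g in gene_ids) fam$flags[[g]] <- sort(unique(c(fam$flags[[g]], flag)))
  fam
}

#' Genes of a family that are not excluded from analysis
#'
#' Members flagged `fragment` or `manual_exclude` stay listed in the family
#' but are excluded from pairwise synteny scoring and lineage partitioning.
#'
#' @param fam a [merge_families()] result
#' @return character vector
#' @export
unflagged_members <- function(fam) {
  excl <- names(fam$flags)[vapply(fam$flags, function(f)
    any(f %in% c("fragment", "manual_exclude")), logical(1))]
  setdiff(fam$members, excl)
}

#' Flag suspect family members (fragments, long branches)
#'
#' A member is flagged `fragment` when its protein is shorter than
#' `len_frac` of the median member length (candidate truncated ORF or
#' frameshift), and `long_branch` when its mean pairwise distance to the
#' other members exceeds the member median by more than `mad_mult` raw
#' median absolute deviations (candidate false positive). Flags never remove
#' members from the family listing.
#'
#' @param fam a [merge_families()] result
#' @param gs a [genome_set()] resolving every member
#' @param net similarity network providing pairwise identities
#' @param len_frac fragment length fraction (default 0.5)
#' @param mad_mult long-branch MAD multiplier (default 3)
#' @return the `family_result` with updated `flags`
#' @export
flag_suspects <- function(fam, gs, net, len_frac = 0.5, mad_mult = 3) {
  lens <- nchar(gs$proteins[fam$members])
  if (anyNA(lens)) stop("member(s) missing from genome set: ",
                        paste(fam$members[is.na(lens)], collapse = ", "))
  med_len <- median(lens)
  fam <- add_flag(fam, fam$members[lens < len_frac * med_len], "fragment")
  if (length(fam$members) >= 3) {
    dm <- distances_from_hits(net, fam$members)
    mean_d <- rowSums(dm) / (ncol(dm) - 1)
    cut <- median(mean_d) + mad_mult * mad(mean_d, constant = 1)
    if (mad(mean_d, constant = 1) > 0 || any(mean_d > cut))
      fam <- add_flag(fam, names(mean_d)[mean_d > cut], "long_branch")
  }
  fam
}

#' Apply a user-supplied exclusion list
#'
#' Interloper genes gathered by a permissive traversal (e.g. members of an
#' unrelated transporter family bridged by a promiscuous domain) are marked
#' `manual_exclude`; they stay listed but drop out of downstream scoring.
#'
#' @param fam a [merge_families()] result
#' @param exclude character vector of gene ids
#' @return updated `family_result`
#' @export
apply_exclusions <- function(fam, exclude) {
  add_flag(fam, intersect(exclude, fam$members), "manual_exclude")
}
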