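#' @importFrom stats median mad setNames rbinom runif
#' @importFrom utils read.delim write.table combn head tail modifyList
NULL

.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Multi-genome gene catalog
#'
#' Bundles protein sequences, gene order and a genome-to-species manifest
#' into a validated, indexed container used by every downstream stage.
#' Gene order is ordinal (rank along the contig), not base-pair coordinates:
#' neighborhood analysis reasons purely in gene ranks. Strand is stored but
#' never filters neighborhood membership.
#'
#' @param loci data.frame with columns `gene_id`, `genome_id`, `contig_id`,
#'   `position` (integer rank, 1-based, consecutive within a contig) and
#'   `strand` (`"+"`/`"-"`). Extra columns (e.g. `start`, `end`) are carried
#'   through untouched as opaque metadata.
#' @param proteins named character vector of amino-acid sequences
#'   (20-letter alphabet plus `X`), names matching `gene_id` exactly.
#' @param species named character vector mapping `genome_id` to a species
#'   code (conventionally 4 letters: first two of genus + species, with an
#'   optional strain suffix on the genome id).
#' @return An object of class `genome_set`.
#' @export
genome_set <- function(loci, proteins, species) {
  stopifnot(is.data.frame(loci))
  need <- c("gene_id", "genome_id", "contig_id", "position", "strand")
  miss <- setdiff(need, names(loci))
  if (length(miss)) stop("gene table lacks column(s): ", paste(miss, collapse = ", "))
  loci$gene_id <- as.character(loci$gene_id)
  loci$genome_id <- as.character(loci$genome_id)
  loci$contig_id <- as.character(loci$contig_id)
  loci$position <- as.integer(loci$position)
  loci$strand <- as.character(loci$strand)

  dup <- loci$gene_id[duplicated(loci$gene_id)]
  if (length(dup)) stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  if (!all(loci$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")

  in_tab <- setdiff(loci$gene_id, names(proteins))
  in_fa <- setdiff(names(proteins), loci$gene_id)
  if (length(in_tab) || length(in_fa))
    stop("gene table / FASTA mismatch; missing protein for: ",
         paste(head(in_tab, 5), collapse = ", "),
         if (length(in_fa)) paste0("; unplaced record(s): ", paste(head(in_fa, 5), collapse = ", ")))
  proteins <- proteins[loci$gene_id]

  bad_seq <- loci$gene_id[!grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", proteins)]
  if (length(bad_seq))
    stop("invalid/empty protein sequence for: ", paste(head(bad_seq, 5), collapse = ", "))

  loci <- loci[order(loci$genome_id, loci$contig_id, loci$position), , drop = FALSE]
  rownames(loci) <- NULL
  key <- paste(loci$genome_id, loci$contig_id, sep = "\r")
  for (k in unique(key)) {
    pos <- loci$position[key == k]
    if (!identical(pos, seq_len(length(pos))))
      stop("positions on contig '", sub("\r", ":", k),
           "' are not consecutive integers starting at 1")
  }

  species <- setNames(as.character(species), names(species))
  no_sp <- setdiff(unique(loci$genome_id), names(species))
  if (length(no_sp)) stop("manifest lacks species code for genome(s): ",
                          paste(no_sp, collapse = ", "))

  structure(list(
    loci = loci,
    proteins = proteins[loci$gene_id],
    species = species,
    index = setNames(seq_len(nrow(loci)), loci$gene_id)
  ), class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set:", length(unique(x$loci$genome_id)), "genome(s),",
      nrow(x$loci), "gene loci,",
      length(unique(paste(x$loci$genome_id, x$loci$contig_id))), "contig(s)\n")
  invisible(x)
}

n_loci <- function(gs) nrow(gs$loci)

locus_of <- function(gs, gene_id) {
  i <- gs$index[gene_id]
  if (is.na(i)) stop("unknown gene id: ", gene_id)
  gs$loci[i, , drop = FALSE]
}

#' Species code of the genome carrying a gene
#' @param gs a [genome_set()]
#' @param gene_ids character vector of gene ids
#' @return character vector of species codes
#' @export
species_of <- function(gs, gene_ids) {
  i <- gs$index[gene_ids]
  if (anyNA(i)) stop("unknown gene id(s): ",
                     paste(gene_ids[is.na(i)], collapse = ", "))
  unname(gs$species[gs$loci$genome_id[i]])
}

#' Load a genome set from FASTA + gene-order table + manifest
#'
#' @param fasta_paths character vector of protein FASTA files (record id =
#'   gene id; one file per genome or combined).
#' @param gene_table_path TSV with header
#'   `gene_id  genome_id  contig_id  position  strand` (extra columns kept).
#' @param manifest_path TSV with header `genome_id  species_code`
#'   (further columns such as `species_name` are ignored).
#' @return a [genome_set()]
#' @export
load_genome_set <- function(fasta_paths, gene_table_path, manifest_path) {
  seqs <- do.call(c, lapply(fasta_paths, function(p) {
    s <- Biostrings::readAAStringSet(p)
    setNames(as.character(s), sub("\\s.*$", "", names(s)))
  }))
  tab <- read.delim(gene_table_path, stringsAsFactors = FALSE)
  man <- read.delim(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "species_code") %in% names(man)))
    stop("manifest needs columns genome_id, species_code")
  genome_set(tab, seqs, setNames(man$species_code, man$genome_id))
}

#' Write a genome set back to its on-disk formats
#'
#' Emits `proteins.faa`, `gene_table.tsv` and `manifest.tsv` under `dir`;
#' [load_genome_set()] on the emitted files round-trips every locus field.
#'
#' @param gs a [genome_set()]
#' @param dir output directory (created if absent)
#' @return invisibly, the three file paths
#' @export
write_genome_set <- function(gs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "proteins.faa")
  writeLines(paste0(">", names(gs$proteins), "\n", unname(gs$proteins)), fa)
  tab <- file.path(dir, "gene_table.tsv")
  write.table(gs$loci, tab, sep = "\t", quote = FALSE, row.names = FALSE)
  man <- file.path(dir, "manifest.tsv")
  write.table(data.frame(genome_id = names(gs$species),
                         species_code = unname(gs$species)),
              man, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, gene_table = tab, manifest = man))
}

#' Ordered chromosomal neighbors of a gene
#'
#' Returns up to `k` loci on each side of `gene_id` on its own contig,
#' nearest-first, truncated at contig ends. Membership ignores strand.
#'
#' @param gs a [genome_set()]
#' @param gene_id query gene
#' @param k maximum neighbors per side (the neighborhood analyses use 15)
#' @return list with data.frames `upstream` and `downstream` (nearest-first)
#' @export
neighbors_on_contig <- function(gs, gene_id, k) {
  stopifnot(k >= 1)
  q <- locus_of(gs, gene_id)
  on_contig <- gs$loci[gs$loci$genome_id == q$genome_id &
                       gs$loci$contig_id == q$contig_id, , drop = FALSE]
  p <- q$position
  up <- on_contig[on_contig$position < p & on_contig$position >= p - k, , drop = FALSE]
  up <- up[order(-up$position), , drop = FALSE]        # nearest first
  down <- on_contig[on_contig$position > p & on_contig$position <= p + k, , drop = FALSE]
  down <- down[order(down$position), , drop = FALSE]
  rownames(up) <- rownames(down) <- NULL
  list(upstream = up, downstream = down, contig_length = nrow(on_contig))
}
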