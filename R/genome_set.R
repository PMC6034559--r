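#' Construct a genome set
#'
#' A `genome_set` is the pan-genome universe the marker-discovery stage
#' operates on: a named collection of genomes, each a table of gene
#' records, tagged with the clade role it plays (inclusion clade, exclusion
#' clade, or the single reference genome whose genes are scored).
#'
#' @param genomes named list; each element a data frame with columns
#'   `gene_id` (unique within the genome) and `sequence` (uppercase ACGT for
#'   nucleotide sets, standard residues for protein sets).
#' @param clade_label one of `"inclusion"`, `"exclusion"`, `"reference"`.
#' @param alphabet `"DNA"` or `"AA"`.
#' @return an object of class `genome_set`.
#' @export
genome_set <- function(genomes, clade_label = c("inclusion", "exclusion", "reference"),
                       alphabet = c("DNA", "AA")) {
  clade_label <- match.arg(clade_label)
  alphabet <- match.arg(alphabet)
  stopifnot(is.list(genomes))
  if (length(genomes) > 0 && is.null(names(genomes))) {
    stop("genomes must be a named list (genome ids as names)", call. = FALSE)
  }
  genomes <- lapply(genomes, function(g) {
    g <- as_tibble(g)
    stopifnot(all(c("gene_id", "sequence") %in% names(g)))
    if (anyDuplicated(g$gene_id)) {
      stop("duplicate gene ids within a genome", call. = FALSE)
    }
    if (nrow(g) > 0 && any(!nzchar(g$sequence))) {
      stop("empty gene sequence", call. = FALSE)
    }
    g$sequence <- toupper(g$sequence)
    if (alphabet == "DNA") .check_dna(g$sequence) else .check_aa(g$sequence)
    g
  })
  structure(list(genomes = genomes, clade_label = clade_label,
                 alphabet = alphabet),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("<genome_set>", x$clade_label, "clade,", length(x$genomes), "genome(s),",
      sum(vapply(x$genomes, nrow, 0L)), "genes\n")
  invisible(x)
}

#' Number of genomes in a genome set
#' @param x a `genome_set`.
#' @return integer count.
#' @export
n_genomes <- function(x) {
  stopifnot(inherits(x, "genome_set"))
  length(x$genomes)
}

#' Flatten a genome set to one gene table
#'
#' @param x a `genome_set`.
#' @return a tibble with columns `genome_id`, `gene_id`, `sequence`.
#' @export
genes_table <- function(x) {
  stopifnot(inherits(x, "genome_set"))
  if (length(x$genomes) == 0) {
    return(tibble(genome_id = character(), gene_id = character(),
                  sequence = character()))
  }
  out <- do.call(rbind, lapply(names(x$genomes), function(gid) {
    g <- x$genomes[[gid]]
    tibble(genome_id = gid, gene_id = g$gene_id, sequence = g$sequence)
  }))
  as_tibble(out)
}

#' Write a genome set to FASTA
#'
#' Headers follow the convention `genomeID|geneID`; sequences are wrapped
#' at 60 columns.
#'
#' @param x a `genome_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome_set <- function(x, path) {
  tab <- genes_table(x)
  write_fasta(tibble(id = paste0(tab$genome_id, "|", tab$gene_id),
                     desc = "", seq = tab$sequence),
              path, alphabet = x$alphabet)
}

#' Read a genome set from FASTA
#'
#' Inverse of [write_genome_set()]: headers of the form `genomeID|geneID`
#' are split back into genomes.
#'
#' @param path FASTA file.
#' @param clade_label clade role to tag the set with.
#' @param alphabet `"DNA"` or `"AA"`.
#' @return a `genome_set`.
#' @export
read_genome_set <- function(path, clade_label = "inclusion", alphabet = "DNA") {
  recs <- read_fasta(path, alphabet = alphabet)
  parts <- strsplit(recs$id, "|", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("FASTA ids must look like genomeID|geneID", call. = FALSE)
  }
  genome_id <- vapply(parts, `[`, "", 1L)
  gene_id <- vapply(parts, `[`, "", 2L)
  genomes <- lapply(split(seq_along(gene_id), genome_id), function(i) {
    tibble(gene_id = gene_id[i], sequence = recs$seq[i])
  })
  genome_set(genomes, clade_label = clade_label, alphabet = alphabet)
}
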