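#' Local sequence alignment (Smith-Waterman)
#'
#' Maximal-scoring local alignment with a linear gap penalty, computed in
#' compiled code with a deterministic traceback (diagonal preferred over a
#' gap in the subject, over a gap in the query; the reported cell is the
#' best-scoring one with the smallest query end, then smallest subject
#' end). Identity is the percentage of alignment columns (gap columns
#' included) that match; query coverage is the aligned query span as a
#' percentage of the query length.
#'
#' @param query,subject sequences (single strings, same alphabet).
#' @param match,mismatch,gap scoring parameters; `gap` is the per-base
#'   linear gap penalty (no separate opening cost).
#' @param alphabet `"DNA"` (default) or `"AA"`; both sequences are
#'   validated against it.
#' @return `NULL` when no positive-scoring alignment exists; otherwise a
#'   list with `score`, `identity`, `query_coverage`, `matches`,
#'   `columns`, and 0-based half-open coordinates `qstart`, `qend`,
#'   `sstart`, `send`.
#' @export
align_local <- function(query, subject, match = 1, mismatch = -1, gap = -2,
                        alphabet = c("DNA", "AA")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(query), is.character(subject),
            length(query) == 1L, length(subject) == 1L)
  if (!nzchar(query) || !nzchar(subject)) {
    stop("empty sequence", call. = FALSE)
  }
  if (alphabet == "DNA") .check_dna(c(query, subject))
  else .check_aa(c(query, subject))
  if (gap > 0 || mismatch > 0) {
    stop("mismatch and gap penalties must be <= 0", call. = FALSE)
  }
  hit <- .sw_align_cpp(query, subject, match, mismatch, gap)
  if (hit$score <= 0) return(NULL)
  hit
}

# precompute both strands of every gene of a genome once, so repeated
# queries against the same genome skip revalidation and re-complementing
.prep_genome <- function(genome_tbl) {
  list(gene_id = genome_tbl$gene_id,
       fwd = genome_tbl$sequence,
       rev = vapply(genome_tbl$sequence, revcomp, "", USE.NAMES = FALSE))
}

# best hit of `query` against any gene of a prepared genome, both strands;
# returns NULL if nothing scores > 0 (ties: lexicographically first gene)
.best_hit_in_genome <- function(query, prep, scoring) {
  best <- NULL
  for (i in seq_along(prep$gene_id)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") prep$fwd[i] else prep$rev[i]
      hit <- .sw_align_cpp(query, s, scoring$match, scoring$mismatch,
                           scoring$gap)
      if (hit$score > 0 &&
          (is.null(best) || hit$score > best$score ||
           (hit$score == best$score && prep$gene_id[i] < best$subject_gene_id))) {
        hit$subject_gene_id <- prep$gene_id[i]
        hit$strand <- strand
        best <- hit
      }
    }
  }
  best
}

#' Score reference genes for conservation across an inclusion pan-genome
#'
#' For every reference gene, finds its best local-alignment hit in each
#' inclusion genome (both strands searched). A gene is *conserved* when
#' every inclusion genome yields a hit with identity and query coverage at
#' or above the thresholds. The conservation score is the mean over
#' inclusion genomes of `identity/100 * query_coverage/100` (a genome with
#' no hit contributes 0), so it lies in [0, 1].
#'
#' @param reference a `genome_set` with one genome (the gene source).
#' @param inclusion a `genome_set` of inclusion-clade genomes (>= 1).
#' @param identity_min,coverage_min conservation thresholds, percent.
#' @param scoring list with `match`, `mismatch`, `gap`.
#' @return a tibble of marker candidates: `gene_id`, `conserved`,
#'   `conservation_score`, `n_genomes_hit`, `exclusion_hit` (initialized
#'   `FALSE`), `rank` (`NA` until [rank_and_select()]), plus a list-column
#'   `hits` of per-genome best hits.
#' @export
conservation_scan <- function(reference, inclusion,
                              identity_min = 70, coverage_min = 70,
                              scoring = list(match = 1, mismatch = -1, gap = -2)) {
  stopifnot(inherits(reference, "genome_set"), inherits(inclusion, "genome_set"))
  if (n_genomes(inclusion) == 0) {
    stop("inclusion set must contain at least one genome", call. = FALSE)
  }
  ref_tbl <- genes_table(reference)
  inc_ids <- sort(names(inclusion$genomes))
  preps <- lapply(inclusion$genomes[inc_ids], .prep_genome)

  rows <- lapply(seq_len(nrow(ref_tbl)), function(i) {
    gid <- ref_tbl$gene_id[i]
    qseq <- ref_tbl$sequence[i]
    hits <- lapply(inc_ids, function(gm) {
      .best_hit_in_genome(qseq, preps[[gm]], scoring)
    })
    names(hits) <- inc_ids
    passes <- vapply(hits, function(h) {
      !is.null(h) && h$identity >= identity_min && h$query_coverage >= coverage_min
    }, TRUE)
    contrib <- vapply(hits, function(h) {
      if (is.null(h)) 0 else (h$identity / 100) * (h$query_coverage / 100)
    }, 0)
    tibble(gene_id = gid,
           conserved = all(passes),
           conservation_score = mean(contrib),
           n_genomes_hit = sum(passes),
           exclusion_hit = FALSE,
           rank = NA_integer_,
           hits = list(hits))
  })
  do.call(rbind, rows)
}

#' Subtract candidates homologous to an exclusion clade
#'
#' Flags every candidate that has any local-alignment hit meeting the
#' (deliberately permissive) exclusion thresholds in *any* exclusion
#' genome, and drops flagged candidates from the marker set. An empty
#' exclusion set subtracts nothing.
#'
#' @param candidates output of [conservation_scan()]; the query sequences
#'   are re-read from `reference`.
#' @param reference the reference `genome_set` the candidates came from.
#' @param exclusion a `genome_set` of exclusion-clade genomes.
#' @param identity_min_excl,coverage_min_excl "some homology" thresholds,
#'   percent.
#' @param scoring list with `match`, `mismatch`, `gap`.
#' @return `candidates` with `exclusion_hit` filled in; the marker set is
#'   the rows with `conserved & !exclusion_hit`.
#' @export
subtract_exclusion <- function(candidates, reference, exclusion,
                               identity_min_excl = 50, coverage_min_excl = 50,
                               scoring = list(match = 1, mismatch = -1, gap = -2)) {
  stopifnot(inherits(reference, "genome_set"))
  stopifnot(inherits(exclusion, "genome_set"))
  ref_tbl <- genes_table(reference)
  seqs <- setNames(ref_tbl$sequence, ref_tbl$gene_id)
  preps <- lapply(exclusion$genomes, .prep_genome)

  candidates$exclusion_hit <- vapply(seq_len(nrow(candidates)), function(i) {
    qseq <- seqs[[candidates$gene_id[i]]]
    for (gm in names(exclusion$genomes)) {
      h <- .best_hit_in_genome(qseq, preps[[gm]], scoring)
      if (!is.null(h) && h$identity >= identity_min_excl &&
          h$query_coverage >= coverage_min_excl) {
        return(TRUE)
      }
    }
    FALSE
  }, TRUE)
  candidates
}

#' Rank surviving markers and select the top k
#'
#' Markers (conserved candidates without an exclusion hit) are sorted by
#' conservation score descending, ties broken by gene id ascending, and
#' the first `min(k, n)` are returned with ranks 1..n.
#'
#' @param candidates candidate table carrying `conservation_score`,
#'   `conserved` and `exclusion_hit`.
#' @param k number of markers to select (>= 0).
#' @return the selected rows, ordered, with `rank` assigned.
#' @export
rank_and_select <- function(candidates, k) {
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  markers <- candidates[candidates$conserved & !candidates$exclusion_hit, ]
  ord <- order(-markers$conservation_score, markers$gene_id)
  markers <- markers[ord, ]
  markers <- head(markers, k)
  markers$rank <- seq_len(nrow(markers))
  markers
}

#' Full subtractive marker discovery
#'
#' Convenience wrapper chaining [conservation_scan()],
#' [subtract_exclusion()] and [rank_and_select()].
#'
#' @inheritParams conservation_scan
#' @inheritParams subtract_exclusion
#' @param k markers to select.
#' @return list with `candidates` (all reference genes, scored) and
#'   `markers` (the ranked selection).
#' @export
discover_markers <- function(reference, inclusion, exclusion, k = 19L,
                             identity_min = 70, coverage_min = 70,
                             identity_min_excl = 50, coverage_min_excl = 50,
                             scoring = list(match = 1, mismatch = -1, gap = -2)) {
  cand <- conservation_scan(reference, inclusion,
                            identity_min = identity_min,
                            coverage_min = coverage_min, scoring = scoring)
  cand <- subtract_exclusion(cand, reference, exclusion,
                             identity_min_excl = identity_min_excl,
                             coverage_min_excl = coverage_min_excl,
                             scoring = scoring)
  list(candidates = cand, markers = rank_and_select(cand, k))
}
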