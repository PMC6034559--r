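#' Oligo melting temperature (Wallace rule)
#'
#' `Tm = 2(A+T) + 4(G+C)` degrees C — the classic rule of thumb for short
#' oligos; exact and closed-form, which is what the designer's constraint
#' logic needs. Nearest-neighbor thermodynamics is a deliberate
#' non-feature here.
#'
#' @param oligo a non-empty ACGT string.
#' @return melting temperature in degrees C.
#' @export
melting_temperature <- function(oligo) {
  stopifnot(is.character(oligo), length(oligo) == 1L, nzchar(oligo))
  .check_dna(oligo, "oligo")
  b <- strsplit(oligo, "", fixed = TRUE)[[1]]
  gc <- sum(b %in% c("G", "C"))
  2 * (length(b) - gc) + 4 * gc
}

#' Construct a primer pair
#'
#' @param name pair label.
#' @param forward,reverse primer sequences, both written 5'->3' (the
#'   reverse primer in reverse-complement orientation relative to the
#'   template plus strand).
#' @param target_gene_id optional id of the gene the pair targets.
#' @param expected_product_length optional expected amplicon length, bp.
#' @return a list of class `primer_pair` with Tm and GC annotations.
#' @export
primer_pair <- function(name, forward, reverse, target_gene_id = NA_character_,
                        expected_product_length = NA_integer_) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  .check_dna(c(forward, reverse), "primer")  # IUPAC degenerate bases rejected
  structure(list(name = name, forward = forward, reverse = reverse,
                 tm_forward = melting_temperature(forward),
                 tm_reverse = melting_temperature(reverse),
                 gc_forward = .gc_percent(forward),
                 gc_reverse = .gc_percent(reverse),
                 expected_product_length = expected_product_length,
                 target_gene_id = target_gene_id),
            class = "primer_pair")
}

# enumerate candidate oligo windows of a template passing the single-primer
# constraints; returns start (0-based), length, gc, tm
.candidate_oligos <- function(template, len_range, gc_range, tm_range) {
  n <- nchar(template)
  b <- strsplit(template, "", fixed = TRUE)[[1]]
  gc_cum <- c(0, cumsum(b %in% c("G", "C")))  # gc_cum[i+1] = GCs in b[1..i]
  rows <- list()
  for (l in seq(len_range[1], len_range[2])) {
    if (l > n) next
    starts <- 0:(n - l)
    gc_count <- gc_cum[starts + l + 1] - gc_cum[starts + 1]
    gc <- 100 * gc_count / l
    tm <- 2 * (l - gc_count) + 4 * gc_count  # Wallace rule, vectorized
    keep <- gc >= gc_range[1] & gc <= gc_range[2] &
      tm >= tm_range[1] & tm <= tm_range[2]
    if (any(keep)) {
      rows[[length(rows) + 1L]] <-
        tibble(start = starts[keep], len = l, gc = gc[keep], tm = tm[keep])
    }
  }
  if (length(rows) == 0) {
    return(tibble(start = integer(), len = integer(),
                  gc = numeric(), tm = numeric()))
  }
  do.call(rbind, rows)
}

#' Design candidate primer pairs for a template
#'
#' Exhaustively enumerates forward/reverse windows satisfying the
#' single-primer constraints (length, GC, Tm), pairs them under the
#' product-length and Tm-difference constraints, and ranks pairs by an
#' additive penalty: `|dTm| + mean(|GC - 50|) + |product - 150|`
#' (unit weights; Tm in degrees C, GC in percent, product in bp).
#' Ties are broken by forward start, then product length, then reverse
#' length, so output is deterministic. Infeasible constraints yield an
#' empty table, not an error.
#'
#' @param template template sequence (plus strand), ACGT.
#' @param target_gene_id label copied onto the designed pairs.
#' @param primer_length,gc_range,tm_range,product_range,max_tm_diff
#'   constraint bounds (defaults: 18-25 nt, 40-60% GC, 55-62 C, 80-300 bp
#'   product, |dTm| <= 3 C).
#' @param max_pairs truncate the ranked list to this many pairs.
#' @return a tibble of pairs: `name`, `forward`, `reverse`, `tm_forward`,
#'   `tm_reverse`, `gc_forward`, `gc_reverse`, `fwd_start`, `rev_end`
#'   (0-based half-open template coordinates of the amplicon),
#'   `product_length`, `penalty`, `target_gene_id`.
#' @export
design_primers <- function(template, target_gene_id = NA_character_,
                           primer_length = c(18L, 25L),
                           gc_range = c(40, 60),
                           tm_range = c(55, 62),
                           product_range = c(80L, 300L),
                           max_tm_diff = 3,
                           max_pairs = 20L) {
  template <- toupper(template)
  .check_dna(template, "template")
  if (nchar(template) < primer_length[1]) {
    stop("template shorter than the minimum primer length", call. = FALSE)
  }
  empty <- tibble(name = character(), forward = character(),
                  reverse = character(), tm_forward = numeric(),
                  tm_reverse = numeric(), gc_forward = numeric(),
                  gc_reverse = numeric(), fwd_start = integer(),
                  rev_end = integer(), product_length = integer(),
                  penalty = numeric(), target_gene_id = character())

  cand <- .candidate_oligos(template, primer_length, gc_range, tm_range)
  if (nrow(cand) == 0) return(empty)
  # forward primers are plus-strand windows; reverse primers are the
  # reverse complement of a window, characterized by its end coordinate
  fwd <- cand
  rev <- cand
  rev$end <- rev$start + rev$len

  pairs <- list()
  for (i in seq_len(nrow(fwd))) {
    s <- fwd$start[i]
    lo <- s + max(product_range[1], fwd$len[i])  # no primer overlap
    hi <- s + product_range[2]
    sel <- which(rev$end >= lo & rev$end <= hi &
                   rev$start >= s + fwd$len[i] &
                   abs(rev$tm - fwd$tm[i]) <= max_tm_diff)
    if (length(sel) == 0) next
    pairs[[length(pairs) + 1L]] <- tibble(
      fwd_start = s, fwd_len = fwd$len[i],
      tm_forward = fwd$tm[i], gc_forward = fwd$gc[i],
      rev_end = rev$end[sel], rev_len = rev$len[sel],
      tm_reverse = rev$tm[sel], gc_reverse = rev$gc[sel])
  }
  if (length(pairs) == 0) return(empty)
  p <- do.call(rbind, pairs)
  p$product_length <- p$rev_end - p$fwd_start
  p$penalty <- abs(p$tm_forward - p$tm_reverse) +
    (abs(p$gc_forward - 50) + abs(p$gc_reverse - 50)) / 2 +
    abs(p$product_length - 150)
  p <- p[order(p$penalty, p$fwd_start, p$product_length, p$rev_len), ]
  p <- head(p, max_pairs)

  p$forward <- substring(template, p$fwd_start + 1, p$fwd_start + p$fwd_len)
  p$reverse <- vapply(seq_len(nrow(p)), function(i) {
    revcomp(substring(template, p$rev_end[i] - p$rev_len[i] + 1, p$rev_end[i]))
  }, "")
  p$name <- sprintf("%s_p%02d", ifelse(is.na(target_gene_id), "pair",
                                       target_gene_id), seq_len(nrow(p)))
  p$target_gene_id <- target_gene_id
  p[, c("name", "forward", "reverse", "tm_forward", "tm_reverse",
        "gc_forward", "gc_reverse", "fwd_start", "rev_end",
        "product_length", "penalty", "target_gene_id")]
}

# plus-strand binding sites of `oligo_site` (already in plus-strand
# orientation) in `template`: 0-based starts and mismatch counts, with the
# base at `exact_pos` (1-based within the site) required to match exactly
.binding_sites <- function(oligo_site, template, max_mismatches, exact_pos) {
  lp <- nchar(oligo_site)
  n <- nchar(template)
  if (n < lp) return(tibble(start = integer(), mismatches = integer()))
  pr <- utf8ToInt(oligo_site)
  tb <- utf8ToInt(template)
  offs <- seq_len(n - lp + 1L)
  mm <- integer(length(offs))
  for (j in seq_len(lp)) mm <- mm + (tb[offs + j - 1L] != pr[j])
  keep <- mm <= max_mismatches & tb[offs + exact_pos - 1L] == pr[exact_pos]
  tibble(start = offs[keep] - 1L, mismatches = mm[keep])
}

# amplicon scan of one template string, plus-strand orientation only
.scan_template <- function(pair, template, max_mismatches, max_product) {
  lf <- nchar(pair$forward); lr <- nchar(pair$reverse)
  fsites <- .binding_sites(pair$forward, template, max_mismatches,
                           exact_pos = lf)  # 3' end of forward
  rsite_seq <- revcomp(pair$reverse)
  rsites <- .binding_sites(rsite_seq, template, max_mismatches,
                           exact_pos = 1L)  # 3' end of reverse
  if (nrow(fsites) == 0 || nrow(rsites) == 0) {
    return(tibble(start = integer(), end = integer(),
                  product_length = integer(),
                  mismatches_forward = integer(),
                  mismatches_reverse = integer()))
  }
  out <- list()
  for (i in seq_len(nrow(fsites))) {
    s <- fsites$start[i]
    ends <- rsites$start + lr
    sel <- which(ends - s >= lf + lr & ends - s <= max_product &
                   rsites$start >= s + lf)
    if (length(sel) == 0) next
    out[[length(out) + 1L]] <- tibble(
      start = s, end = ends[sel],
      product_length = ends[sel] - s,
      mismatches_forward = fsites$mismatches[i],
      mismatches_reverse = rsites$mismatches[sel])
  }
  if (length(out) == 0) {
    return(tibble(start = integer(), end = integer(),
                  product_length = integer(),
                  mismatches_forward = integer(),
                  mismatches_reverse = integer()))
  }
  do.call(rbind, out)
}

#' In-silico PCR
#'
#' Reports every site in a genome set where the forward primer binds the
#' plus strand and the reverse primer binds the minus strand downstream
#' within `max_product` bp, with at most `max_mismatches_per_primer`
#' mismatches per primer and an exactly matching 3'-terminal base (the
#' polymerase-extension end). Both template orientations are searched;
#' hits found on the reverse-complemented template are reported with
#' strand `"-"` and coordinates mapped back to the plus strand.
#'
#' @param pair a [primer_pair()] (or one row of [design_primers()] output).
#' @param genomes a `genome_set`.
#' @param max_mismatches_per_primer allowed mismatches per primer.
#' @param max_product maximum amplicon length scanned for, bp.
#' @return a tibble of amplicons: `genome_id`, `gene_id`, `start`, `end`
#'   (0-based half-open, plus strand), `strand`, `product_length`,
#'   `mismatches_forward`, `mismatches_reverse`.
#' @export
insilico_pcr <- function(pair, genomes, max_mismatches_per_primer = 0L,
                         max_product = 3000L) {
  if (inherits(pair, "data.frame")) {
    stopifnot(nrow(pair) == 1L)
    pair <- primer_pair(pair$name, pair$forward, pair$reverse,
                        target_gene_id = pair$target_gene_id)
  }
  stopifnot(inherits(pair, "primer_pair"), inherits(genomes, "genome_set"))
  tab <- genes_table(genomes)
  out <- list()
  for (i in seq_len(nrow(tab))) {
    tmpl <- tab$sequence[i]
    L <- nchar(tmpl)
    plus <- .scan_template(pair, tmpl, max_mismatches_per_primer, max_product)
    if (nrow(plus) > 0) {
      plus$strand <- "+"
    }
    minus <- .scan_template(pair, revcomp(tmpl), max_mismatches_per_primer,
                            max_product)
    if (nrow(minus) > 0) {
      minus$strand <- "-"
      new_start <- L - minus$end
      minus$end <- L - minus$start
      minus$start <- new_start
    }
    both <- rbind(plus, minus)
    if (nrow(both) > 0) {
      both$genome_id <- tab$genome_id[i]
      both$gene_id <- tab$gene_id[i]
      out[[length(out) + 1L]] <- both
    }
  }
  if (length(out) == 0) {
    return(tibble(genome_id = character(), gene_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  product_length = integer(),
                  mismatches_forward = integer(),
                  mismatches_reverse = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$genome_id, res$gene_id, res$start, res$strand), ]
  res[, c("genome_id", "gene_id", "start", "end", "strand", "product_length",
          "mismatches_forward", "mismatches_reverse")]
}

#' Primer-pair specificity verdict
#'
#' A pair is `specific` when it amplifies at least once in every inclusion
#' genome and never in any exclusion genome; `non_specific` when any
#' exclusion genome yields an amplicon (this takes precedence); and
#' `non_universal` when some inclusion genome yields none.
#'
#' @param pair a [primer_pair()] or one-row designer output.
#' @param inclusion,exclusion non-empty `genome_set`s.
#' @param max_mismatches_per_primer,max_product forwarded to
#'   [insilico_pcr()].
#' @return a list with `verdict` (one of `"specific"`, `"non_specific"`,
#'   `"non_universal"`), `inclusion_amplicons` and `exclusion_amplicons`
#'   (per-genome hit counts).
#' @export
specificity_check <- function(pair, inclusion, exclusion,
                              max_mismatches_per_primer = 1L,
                              max_product = 3000L) {
  stopifnot(inherits(inclusion, "genome_set"), inherits(exclusion, "genome_set"))
  if (n_genomes(inclusion) == 0 || n_genomes(exclusion) == 0) {
    stop("genome sets must be non-empty", call. = FALSE)
  }
  inc_hits <- insilico_pcr(pair, inclusion, max_mismatches_per_primer,
                           max_product)
  exc_hits <- insilico_pcr(pair, exclusion, max_mismatches_per_primer,
                           max_product)
  inc_counts <- vapply(names(inclusion$genomes), function(g) {
    sum(inc_hits$genome_id == g)
  }, 0L)
  exc_counts <- vapply(names(exclusion$genomes), function(g) {
    sum(exc_hits$genome_id == g)
  }, 0L)
  verdict <- if (sum(exc_counts) > 0) "non_specific"
  else if (any(inc_counts == 0)) "non_universal"
  else "specific"
  list(verdict = verdict, inclusion_amplicons = inc_counts,
       exclusion_amplicons = exc_counts)
}
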