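# standard monoisotopic residue masses, Da
.AA_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)
.WATER_MONO <- 18.010565

#' Monoisotopic peptide mass
#'
#' Sum of the standard monoisotopic residue masses plus one water
#' (18.010565 Da).
#'
#' @param peptide amino-acid string(s), standard 20 residues.
#' @return mass in Da (vectorized).
#' @export
monoisotopic_mass <- function(peptide) {
  .check_aa(peptide)
  vapply(strsplit(peptide, "", fixed = TRUE), function(r) {
    sum(.AA_MONO_MASS[r]) + .WATER_MONO
  }, 0)
}

#' Count internal missed tryptic cleavages
#'
#' A missed cleavage is a K or R at a non-terminal position that is not
#' followed by P (trypsin does not cut before proline).
#'
#' @param peptide amino-acid string(s).
#' @return integer count(s).
#' @export
missed_cleavage_count <- function(peptide) {
  .check_aa(peptide)
  vapply(strsplit(peptide, "", fixed = TRUE), function(r) {
    n <- length(r)
    if (n < 2) return(0L)
    i <- seq_len(n - 1L)
    sum(r[i] %in% c("K", "R") & r[i + 1L] != "P")
  }, 0L)
}

#' In-silico tryptic digestion
#'
#' Cleaves after every K or R not followed by P, then enumerates all
#' peptides spanning 0 to `max_missed` internal missed cleavage sites.
#' With `max_missed = 0` and `min_length = 1` the emitted peptides
#' concatenate back to the protein exactly.
#'
#' @param protein a single protein sequence.
#' @param max_missed maximum internal missed cleavages (default 2).
#' @param min_length minimum peptide length kept (default 4).
#' @return a tibble with `peptide`, `start` (0-based position in the
#'   protein), `missed_cleavages`, `length`, `monoisotopic_mass`.
#' @export
digest <- function(protein, max_missed = 2L, min_length = 4L) {
  stopifnot(is.character(protein), length(protein) == 1L, nzchar(protein))
  .check_aa(protein, "protein")
  r <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(r)
  # cut points: after position i when r[i] is K/R and r[i+1] is not P
  i <- seq_len(max(n - 1L, 0L))
  cuts <- i[r[i] %in% c("K", "R") & r[i + 1L] != "P"]
  bounds <- c(0L, cuts, n)  # base peptide j spans (bounds[j], bounds[j+1]]
  nb <- length(bounds) - 1L

  rows <- list()
  for (j in seq_len(nb)) {
    for (m in 0:max_missed) {
      if (j + m > nb) break
      s <- bounds[j]; e <- bounds[j + m + 1L]
      if (e - s < min_length) next
      rows[[length(rows) + 1L]] <-
        list(peptide = substring(protein, s + 1L, e), start = s,
             missed_cleavages = m, length = e - s)
    }
  }
  if (length(rows) == 0) {
    return(tibble(peptide = character(), start = integer(),
                  missed_cleavages = integer(), length = integer(),
                  monoisotopic_mass = numeric()))
  }
  out <- tibble(peptide = vapply(rows, `[[`, "", "peptide"),
                start = vapply(rows, `[[`, 0L, "start"),
                missed_cleavages = vapply(rows, `[[`, 0L, "missed_cleavages"),
                length = vapply(rows, `[[`, 0L, "length"))
  out$monoisotopic_mass <- monoisotopic_mass(out$peptide)
  out
}

#' Mass match within a ppm tolerance
#'
#' `TRUE` when `|observed - theoretical| / theoretical * 1e6` is at or
#' below the tolerance (boundary inclusive, sign-symmetric).
#'
#' @param theoretical,observed masses in Da, > 0 (vectorized).
#' @param tolerance_ppm tolerance in parts per million (default 15).
#' @return logical.
#' @export
ppm_match <- function(theoretical, observed, tolerance_ppm = 15) {
  if (any(theoretical <= 0) || any(observed <= 0)) {
    stop("masses must be > 0", call. = FALSE)
  }
  abs(observed - theoretical) / theoretical * 1e6 <= tolerance_ppm
}

#' Apply the peptide identification filters
#'
#' Keeps peptides of length >= `min_length` with at most `max_missed`
#' internal missed tryptic cleavages (KP rule applied) — the acceptance
#' filters applied to MS-identified peptides before uniqueness calling.
#'
#' @param peptides character vector of peptide sequences.
#' @param min_length minimum length (default 4).
#' @param max_missed maximum missed cleavages (default 2).
#' @return the retained peptides.
#' @export
filter_peptides <- function(peptides, min_length = 4L, max_missed = 2L) {
  .check_aa(peptides)
  peptides[nchar(peptides) >= min_length &
             missed_cleavage_count(peptides) <= max_missed]
}

.as_protein_table <- function(x) {
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("prot%03d", seq_along(x))
    return(tibble(id = ids, seq = unname(toupper(x))))
  }
  x <- as_tibble(x)
  stopifnot(all(c("id", "seq") %in% names(x)))
  x$seq <- toupper(x$seq)
  x
}

#' Call clade-unique peptides by exact substring search
#'
#' Applies the identification filters ([filter_peptides()]), then searches
#' each retained peptide as an exact substring of every inclusion and
#' background protein. Full-length 100%-identity matching of a short
#' peptide is equivalent to substring containment, so this reproduces the
#' "100% matching to inclusion-clade proteins only" uniqueness rule
#' deterministically. A peptide is unique when it occurs in at least one
#' inclusion protein and no background protein.
#'
#' @param peptides character vector of candidate (e.g. MS-identified)
#'   peptides.
#' @param inclusion_proteome inclusion-clade proteins: a tibble with
#'   `id`/`seq` columns (as from [read_fasta()] or [generate_proteomes()])
#'   or a (named) character vector.
#' @param background_proteomes background proteins, same formats, or a
#'   list of them.
#' @param min_length,max_missed identification filters.
#' @return a tibble with `peptide`, `inclusion_matches` and
#'   `background_matches` (list-columns of protein ids),
#'   `n_inclusion`, `n_background`, `unique`.
#' @export
call_unique_peptides <- function(peptides, inclusion_proteome,
                                 background_proteomes,
                                 min_length = 4L, max_missed = 2L) {
  inc <- .as_protein_table(inclusion_proteome)
  if (nrow(inc) == 0) stop("empty inclusion proteome", call. = FALSE)
  if (is.list(background_proteomes) && !is.data.frame(background_proteomes)) {
    bg <- do.call(rbind, lapply(background_proteomes, .as_protein_table))
  } else {
    bg <- .as_protein_table(background_proteomes)
  }
  peptides <- filter_peptides(unique(peptides), min_length, max_missed)

  rows <- lapply(peptides, function(p) {
    in_inc <- inc$id[vapply(inc$seq, grepl, TRUE, pattern = p, fixed = TRUE)]
    in_bg <- bg$id[vapply(bg$seq, grepl, TRUE, pattern = p, fixed = TRUE)]
    tibble(peptide = p,
           inclusion_matches = list(in_inc),
           background_matches = list(in_bg),
           n_inclusion = length(in_inc),
           n_background = length(in_bg),
           unique = length(in_inc) >= 1 && length(in_bg) == 0)
  })
  if (length(rows) == 0) {
    return(tibble(peptide = character(), inclusion_matches = list(),
                  background_matches = list(), n_inclusion = integer(),
                  n_background = integer(), unique = logical()))
  }
  do.call(rbind, rows)
}
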