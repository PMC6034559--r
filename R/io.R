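#' Read a FASTA file
#'
#' Thin, validating wrapper around [Biostrings::readBStringSet()]. Record
#' ids are the first whitespace-delimited header token, the remainder is
#' kept as the description, sequences are uppercased, and line wrapping is
#' irrelevant.
#'
#' @param path file to read.
#' @param alphabet `"DNA"`, `"AA"`, or `NULL` to skip alphabet validation.
#' @return a tibble with columns `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path, alphabet = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id)) {
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  seq <- toupper(as.character(set))
  if (!is.null(alphabet)) {
    if (alphabet == "DNA") .check_dna(seq, "FASTA sequence")
    else if (alphabet == "AA") .check_aa(seq, "FASTA sequence")
    else stop("unknown alphabet: ", alphabet, call. = FALSE)
  }
  tibble(id = id, desc = desc, seq = unname(seq))
}

#' Write a FASTA file
#'
#' Sequences are wrapped at 60 columns. Round-trips with [read_fasta()] on
#' the (id, seq) pairs.
#'
#' @param records data frame with columns `id` and `seq` (optional `desc`).
#' @param path output path.
#' @param alphabet optional alphabet check before writing (`"DNA"`/`"AA"`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, alphabet = NULL) {
  records <- as_tibble(records)
  stopifnot(all(c("id", "seq") %in% names(records)))
  if (anyDuplicated(records$id)) stop("duplicate FASTA ids", call. = FALSE)
  seq <- toupper(records$seq)
  if (!is.null(alphabet)) {
    if (alphabet == "DNA") .check_dna(seq) else .check_aa(seq)
  }
  set <- Biostrings::BStringSet(seq)
  desc <- if ("desc" %in% names(records)) records$desc
          else rep("", nrow(records))
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# deterministic CSV writer used by the pipeline: comma, UTF-8, header row,
# no row names, no quoting surprises
.write_table <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
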