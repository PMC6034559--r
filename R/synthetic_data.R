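#' Simulation configuration
#'
#' One object holds every knob of the synthetic-data module. Defaults are
#' the study conditions the pipeline is exercised under: a desk-scale
#' pan-genome (a reference genome plus three further inclusion-clade
#' genomes against three exclusion-clade genomes), sIgA group medians of
#' 118.60 and 69.21 ug/ml for 23 SFB-positive and 24 SFB-negative subjects
#' aged 8-48 months, and a qPCR standard curve with slope -3.3219 Ct per
#' log10(copies) (perfect doubling per cycle) and intercept 37 Ct.
#'
#' @param seed root seed; each generator derives its own stream from it by
#'   a fixed offset, so modules are individually reproducible.
#' @param n_inclusion_genomes number of inclusion-clade genomes, counting
#'   the reference.
#' @param n_exclusion_genomes number of exclusion-clade genomes.
#' @param n_reference_genes genes in the reference genome.
#' @param n_conserved how many reference genes recur in every inclusion
#'   genome; must be <= `n_reference_genes`.
#' @param n_exclusion_shared how many conserved genes also occur in the
#'   exclusion genomes; must be <= `n_conserved`.
#' @param gene_length_bp length of every simulated gene.
#' @param point_mutation_rate per-base substitution probability applied to
#'   each non-reference gene copy; must be < 0.25.
#' @param siga_median_pos,siga_median_neg sIgA group medians, ug/ml.
#' @param siga_log_sd log-scale standard deviation of the log-normal sIgA
#'   model (dimensionless); 0 gives the degenerate all-equal-the-median
#'   limit.
#' @param n_pos_subjects,n_neg_subjects cohort group sizes.
#' @param curve_slope standard-curve slope, Ct per log10(copies); must be
#'   negative (amplification).
#' @param curve_intercept Ct at a single template copy.
#' @param ct_noise_sd Gaussian noise on simulated Ct values.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_inclusion_genomes = 4L,
                       n_exclusion_genomes = 3L,
                       n_reference_genes = 12L,
                       n_conserved = 6L,
                       n_exclusion_shared = 2L,
                       gene_length_bp = 300L,
                       point_mutation_rate = 0.02,
                       siga_median_pos = 118.60,
                       siga_median_neg = 69.21,
                       siga_log_sd = 0.4,
                       n_pos_subjects = 23L,
                       n_neg_subjects = 24L,
                       curve_slope = -3.3219,
                       curve_intercept = 37,
                       ct_noise_sd = 0.2) {
  cfg <- list(seed = as.integer(seed),
              n_inclusion_genomes = as.integer(n_inclusion_genomes),
              n_exclusion_genomes = as.integer(n_exclusion_genomes),
              n_reference_genes = as.integer(n_reference_genes),
              n_conserved = as.integer(n_conserved),
              n_exclusion_shared = as.integer(n_exclusion_shared),
              gene_length_bp = as.integer(gene_length_bp),
              point_mutation_rate = point_mutation_rate,
              siga_median_pos = siga_median_pos,
              siga_median_neg = siga_median_neg,
              siga_log_sd = siga_log_sd,
              n_pos_subjects = as.integer(n_pos_subjects),
              n_neg_subjects = as.integer(n_neg_subjects),
              curve_slope = curve_slope,
              curve_intercept = curve_intercept,
              ct_noise_sd = ct_noise_sd)
  counts <- cfg[c("n_inclusion_genomes", "n_exclusion_genomes",
                  "n_reference_genes", "n_conserved", "n_exclusion_shared",
                  "n_pos_subjects", "n_neg_subjects", "gene_length_bp")]
  if (any(unlist(counts) < 0L)) stop("counts must be >= 0", call. = FALSE)
  if (cfg$n_conserved > cfg$n_reference_genes) {
    stop("n_conserved must be <= n_reference_genes", call. = FALSE)
  }
  if (cfg$n_exclusion_shared > cfg$n_conserved) {
    stop("n_exclusion_shared must be <= n_conserved", call. = FALSE)
  }
  if (cfg$point_mutation_rate < 0 || cfg$point_mutation_rate >= 0.25) {
    stop("point_mutation_rate must be in [0, 0.25)", call. = FALSE)
  }
  if (cfg$siga_median_pos <= 0 || cfg$siga_median_neg <= 0) {
    stop("sIgA medians must be positive", call. = FALSE)
  }
  if (cfg$siga_log_sd < 0) stop("siga_log_sd must be >= 0", call. = FALSE)
  if (cfg$curve_slope >= 0) {
    stop("curve_slope must be negative (amplification)", call. = FALSE)
  }
  if (cfg$ct_noise_sd < 0) stop("ct_noise_sd must be >= 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# fixed per-generator seed offsets (module-level reproducibility)
.SEED_OFFSETS <- c(pangenome = 0L, siga = 101L, qpcr = 202L,
                   proteome = 303L, abundance = 404L)

.seed_for <- function(config, stream) {
  set.seed(config$seed + .SEED_OFFSETS[[stream]])
}

.mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(b)) < rate
  if (any(hit)) {
    b[hit] <- vapply(b[hit], function(x) sample(setdiff(.DNA_BASES, x), 1L),
                     "", USE.NAMES = FALSE)
  }
  paste(b, collapse = "")
}

#' Generate a pan-genome with planted marker genes
#'
#' Builds the genome universe for the subtractive marker-discovery stage: a
#' reference genome whose genes are the candidates; further inclusion-clade
#' genomes in which exactly `n_conserved` reference genes recur (each copy
#' independently mutated at `point_mutation_rate`); and exclusion-clade
#' genomes that carry copies of `n_exclusion_shared` of those conserved
#' genes plus unrelated random genes. The planted marker set — the ground
#' truth the discovery stage must recover — is the conserved genes minus
#' the exclusion-shared ones.
#'
#' @param config a [sim_config()].
#' @return a list with elements `reference`, `inclusion`, `exclusion`
#'   (each a [genome_set()]) and `truth` (a `planted_truth` list with
#'   `marker_gene_ids`, `conserved_gene_ids`, `exclusion_shared_gene_ids`).
#' @export
generate_pangenome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .seed_for(config, "pangenome")

  gene_ids <- sprintf("gene%03d", seq_len(config$n_reference_genes))
  ref_seqs <- vapply(gene_ids, function(i) .random_dna(config$gene_length_bp),
                     "", USE.NAMES = FALSE)
  names(ref_seqs) <- gene_ids
  conserved <- sort(sample(gene_ids, config$n_conserved))
  shared <- sort(sample(conserved, config$n_exclusion_shared))

  n_filler_inc <- config$n_reference_genes - config$n_conserved
  inclusion <- list()
  for (k in seq_len(max(config$n_inclusion_genomes - 1L, 0L))) {
    copies <- vapply(conserved, function(g) {
      .mutate_dna(ref_seqs[[g]], config$point_mutation_rate)
    }, "", USE.NAMES = FALSE)
    filler_ids <- sprintf("inc%02d_rand%03d", k, seq_len(n_filler_inc))
    filler <- vapply(seq_len(n_filler_inc),
                     function(i) .random_dna(config$gene_length_bp), "")
    inclusion[[sprintf("inc%02d", k)]] <-
      tibble(gene_id = c(conserved, filler_ids),
             sequence = c(copies, filler))
  }

  n_filler_exc <- config$n_reference_genes - config$n_exclusion_shared
  exclusion <- list()
  for (k in seq_len(config$n_exclusion_genomes)) {
    copies <- vapply(shared, function(g) {
      .mutate_dna(ref_seqs[[g]], config$point_mutation_rate)
    }, "", USE.NAMES = FALSE)
    filler_ids <- sprintf("exc%02d_rand%03d", k, seq_len(n_filler_exc))
    filler <- vapply(seq_len(n_filler_exc),
                     function(i) .random_dna(config$gene_length_bp), "")
    exclusion[[sprintf("exc%02d", k)]] <-
      tibble(gene_id = c(shared, filler_ids),
             sequence = c(copies, filler))
  }

  truth <- structure(
    list(marker_gene_ids = setdiff(conserved, shared),
         conserved_gene_ids = conserved,
         exclusion_shared_gene_ids = shared,
         planted_unique_peptides = character(),
         true_loads = NULL),
    class = "planted_truth")

  list(reference = genome_set(list(ref = tibble(gene_id = gene_ids,
                                                sequence = unname(ref_seqs))),
                              clade_label = "reference"),
       inclusion = genome_set(inclusion, clade_label = "inclusion"),
       exclusion = genome_set(exclusion, clade_label = "exclusion"),
       truth = truth)
}

#' Generate a synthetic sIgA cohort
#'
#' Subjects in each colonization group draw their luminal sIgA
#' concentration from a log-normal distribution whose log-median is the
#' log of the configured group median (so the population median is exactly
#' the parameter) with common log-sd `siga_log_sd`. Ages are uniform over
#' 8-48 months. Optionally adds per-subject qRT-PCR Ct pairs for Th17
#' marker genes, with the target genes expressed higher (lower dCt versus
#' actin) in the SFB-positive group.
#'
#' @param config a [sim_config()].
#' @param expression_genes character vector of marker gene names to
#'   simulate Ct pairs for, or `NULL` for none.
#' @param expression_log2fc log2 fold elevation of each marker gene in the
#'   positive group.
#' @return a tibble (one row per subject) with columns `subject_id`,
#'   `age_months`, `sfb_status` (`"positive"`/`"negative"`), `siga_ug_ml`,
#'   and, when requested, `ct_actin` plus one `ct_<gene>` column per gene.
#' @export
generate_siga_cohort <- function(config,
                                 expression_genes = c("IL17A", "RORC"),
                                 expression_log2fc = 1.5) {
  stopifnot(inherits(config, "sim_config"))
  .seed_for(config, "siga")
  n_pos <- config$n_pos_subjects
  n_neg <- config$n_neg_subjects
  n <- n_pos + n_neg
  status <- rep(c("positive", "negative"), c(n_pos, n_neg))
  siga <- c(rlnorm(n_pos, meanlog = log(config$siga_median_pos),
                   sdlog = config$siga_log_sd),
            rlnorm(n_neg, meanlog = log(config$siga_median_neg),
                   sdlog = config$siga_log_sd))
  out <- tibble(subject_id = sprintf("S%03d", seq_len(n)),
                age_months = round(runif(n, 8, 48), 1),
                sfb_status = status,
                siga_ug_ml = siga)
  if (n > 0 && length(expression_genes) > 0) {
    out$ct_actin <- round(rnorm(n, mean = 20, sd = config$ct_noise_sd), 3)
    base_dct <- 8  # marker genes ~2^-8 of actin in the negative group
    for (g in expression_genes) {
      dct <- ifelse(status == "positive", base_dct - expression_log2fc,
                    base_dct)
      out[[paste0("ct_", g)]] <-
        round(out$ct_actin + dct + rnorm(n, 0, config$ct_noise_sd), 3)
    }
  }
  out
}

#' Simulate a qPCR run from true bacterial loads
#'
#' Standard-curve points span 10^1 to 10^7 template copies; every Ct is
#' drawn from the log-linear model
#' `Ct = intercept + slope * log10(copies) + N(0, ct_noise_sd)`. Sample
#' Cts come from the same model applied to the true loads (converted to
#' copies per reaction by `1/conversion`), so the planted loads are exactly
#' recoverable when `ct_noise_sd = 0`.
#'
#' @param config a [sim_config()].
#' @param true_loads named numeric vector, CFU/ml per sample id; all > 0.
#' @param target assay label attached to the sample rows.
#' @param curve_replicates technical replicates per curve level.
#' @param sample_replicates technical replicates per sample.
#' @param conversion copies-to-CFU/ml factor (see [quantify()]); the
#'   generator divides loads by it to obtain template copies.
#' @return a list of class `qpcr_run` with tibbles `curve`
#'   (`copies`, `replicate`, `ct`) and `samples`
#'   (`sample_id`, `target`, `replicate`, `ct`), plus `conversion` and the
#'   generating `true_loads`.
#' @export
generate_qpcr_run <- function(config, true_loads, target = "SFB",
                              curve_replicates = 3L, sample_replicates = 2L,
                              conversion = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (length(true_loads) > 0 &&
      (is.null(names(true_loads)) || any(!nzchar(names(true_loads))))) {
    stop("true_loads must be a named vector", call. = FALSE)
  }
  if (any(true_loads <= 0)) stop("loads must be > 0", call. = FALSE)
  .seed_for(config, "qpcr")

  model_ct <- function(copies) {
    config$curve_intercept + config$curve_slope * log10(copies) +
      rnorm(length(copies), 0, config$ct_noise_sd)
  }
  levels <- 10^(1:7)
  curve <- tibble(copies = rep(levels, each = curve_replicates),
                  replicate = rep(seq_len(curve_replicates), length(levels)))
  curve$ct <- model_ct(curve$copies)

  n_s <- length(true_loads)
  samples <- tibble(sample_id = rep(names(true_loads), each = sample_replicates),
                    target = target,
                    replicate = rep(seq_len(sample_replicates), n_s))
  copies <- rep(unname(true_loads), each = sample_replicates) / conversion
  samples$ct <- model_ct(copies)

  structure(list(curve = curve, samples = samples, conversion = conversion,
                 true_loads = true_loads),
            class = "qpcr_run")
}

#' The published SFB-unique peptide set
#'
#' The 18 SFB-specific peptide sequences identified by mass spectrometry in
#' human ileal luminal fluid, shipped as a plain-text fixture. These are the
#' default peptides [generate_proteomes()] plants.
#'
#' @return a tibble with columns `no`, `peptide`, `protein`.
#' @export
sfb_marker_peptides <- function() {
  path <- system.file("extdata", "sfb_unique_peptides.tsv",
                      package = "raretaxa", mustWork = TRUE)
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

.random_aa <- function(n, exclude = character()) {
  paste(sample(setdiff(.AA_RESIDUES, exclude), n, replace = TRUE),
        collapse = "")
}

# grow a protein of length n whose every 4-mer avoids `forbidden`
.grow_avoiding <- function(n, forbidden) {
  res <- character(n)
  for (i in seq_len(n)) {
    if (i < 4) {
      res[i] <- sample(.AA_RESIDUES, 1L)
      next
    }
    ctx <- paste(res[(i - 3):(i - 1)], collapse = "")
    ok <- .AA_RESIDUES[!(paste0(ctx, .AA_RESIDUES) %in% forbidden)]
    if (length(ok) == 0) return(NULL)  # dead end; caller restarts
    res[i] <- sample(ok, 1L)
  }
  paste(res, collapse = "")
}

.kmers4 <- function(seqs) {
  unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < 4) return(character())
    substring(s, 1:(n - 3), 4:n)
  }), use.names = FALSE)
}

#' Generate inclusion and background proteomes with planted unique peptides
#'
#' Each planted peptide is embedded in one inclusion protein between clean
#' tryptic boundaries: the residue before it is K, the peptide's first
#' residue is not P, and a peptide not ending in K/R is placed at the
#' protein's C-terminus — so tryptic digestion (with enough allowed missed
#' cleavages) releases it exactly. Background proteins are grown so that no
#' 4-mer of the inclusion proteome occurs in them; consequently no tryptic
#' peptide of length >= 4 is shared between the proteomes and every planted
#' peptide is unique to the inclusion side by construction.
#'
#' @param config a [sim_config()].
#' @param planted_peptides character vector of peptides to plant; defaults
#'   to the 18 published SFB-unique peptides ([sfb_marker_peptides()]).
#' @param n_filler_inclusion random inclusion proteins carrying no planted
#'   peptide.
#' @param n_background,background_length_aa background proteome size.
#' @return a list with `inclusion` and `background` (tibbles with `id`,
#'   `desc`, `seq`) and `truth` (a `planted_truth` with
#'   `planted_unique_peptides`).
#' @export
generate_proteomes <- function(config,
                               planted_peptides = sfb_marker_peptides()$peptide,
                               n_filler_inclusion = 4L,
                               n_background = 6L,
                               background_length_aa = 250L) {
  stopifnot(inherits(config, "sim_config"))
  planted_peptides <- as.character(planted_peptides)
  .check_aa(planted_peptides, "planted peptide")
  if (any(substring(planted_peptides, 1, 1) == "P")) {
    stop("planted peptides must not start with P (trypsin cannot release them)",
         call. = FALSE)
  }
  .seed_for(config, "proteome")

  hosts <- vapply(planted_peptides, function(pep) {
    # flanks avoid K/R/P: no extra cleavage sites, no KP suppression
    prefix <- paste0(.random_aa(sample(8:14, 1L), exclude = c("K", "R", "P")), "K")
    last <- substring(pep, nchar(pep), nchar(pep))
    suffix <- if (last %in% c("K", "R")) {
      .random_aa(sample(8:14, 1L), exclude = c("K", "R", "P"))
    } else ""
    paste0(prefix, pep, suffix)
  }, "", USE.NAMES = FALSE)

  filler <- vapply(seq_len(n_filler_inclusion), function(i) {
    .random_aa(sample(180:260, 1L))
  }, "")

  inclusion <- tibble(
    id = c(sprintf("incprot%03d", seq_along(hosts)),
           sprintf("incfill%03d", seq_along(filler))),
    desc = c(rep("planted-host", length(hosts)),
             rep("inclusion-filler", length(filler))),
    seq = c(hosts, filler))

  forbidden <- unique(.kmers4(inclusion$seq))
  background <- character(n_background)
  for (k in seq_len(n_background)) {
    repeat {
      s <- .grow_avoiding(background_length_aa, forbidden)
      if (!is.null(s)) break
    }
    background[k] <- s
  }
  background <- tibble(id = sprintf("bgprot%03d", seq_len(n_background)),
                       desc = rep("background", n_background),
                       seq = background)

  truth <- structure(
    list(marker_gene_ids = character(),
         conserved_gene_ids = character(),
         exclusion_shared_gene_ids = character(),
         planted_unique_peptides = planted_peptides,
         true_loads = NULL),
    class = "planted_truth")

  list(inclusion = inclusion, background = background, truth = truth)
}

#' Generate a two-group taxon relative-abundance table
#'
#' Emulates the compositional shift between SFB-positive and SFB-negative
#' gut communities: *Clostridia*, *Coriobacteriia* and
#' *Deltaproteobacteria* are elevated in the positive group, while
#' *Bacteroides*, *Escherichia* and *Klebsiella* are elevated in the
#' negative group; the remaining genera are undirected. Rows are
#' normalized to sum to 1.
#'
#' @param config a [sim_config()].
#' @param n_per_group samples per group.
#' @param log2_shift magnitude of each directional taxon shift.
#' @return a tibble with `sample_id`, `sfb_status`, then one relative
#'   abundance column per taxon.
#' @export
generate_abundance_table <- function(config, n_per_group = 3L,
                                     log2_shift = 1.5) {
  stopifnot(inherits(config, "sim_config"))
  .seed_for(config, "abundance")
  up_pos <- c("Clostridia", "Coriobacteriia", "Deltaproteobacteria")
  up_neg <- c("Bacteroides", "Escherichia", "Klebsiella")
  neutral <- c("Eubacterium", "Prevotella", "Roseburia", "Faecalibacterium")
  taxa <- c(up_pos, up_neg, neutral)
  base <- setNames(rep(0, length(taxa)), taxa)
  base[c("Bacteroides", "Prevotella", "Eubacterium")] <- 2  # dominant genera

  n <- 2L * n_per_group
  status <- rep(c("positive", "negative"), each = n_per_group)
  mat <- matrix(0, n, length(taxa), dimnames = list(NULL, taxa))
  for (i in seq_len(n)) {
    shift <- setNames(rep(0, length(taxa)), taxa)
    if (status[i] == "positive") shift[up_pos] <- log2_shift
    else shift[up_neg] <- log2_shift
    raw <- 2^(base + shift + rnorm(length(taxa), 0, 0.3))
    mat[i, ] <- raw / sum(raw)
  }
  out <- tibble(sample_id = sprintf("M%02d", seq_len(n)), sfb_status = status)
  for (t in taxa) out[[t]] <- mat[, t]
  out
}

#' Write planted truth to JSON
#'
#' @param truth a `planted_truth` list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_planted_truth <- function(truth, path) {
  stopifnot(inherits(truth, "planted_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = FALSE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}
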