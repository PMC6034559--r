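#' Run the full detection workflow on synthetic data
#'
#' End-to-end driver: simulate the pan-genome, proteomes, qPCR run and
#' cohort from one [sim_config()]; discover and rank marker genes; design
#' primers for each marker and screen their specificity by in-silico PCR;
#' quantify loads and call positivity; call clade-unique peptides; and
#' compute the cohort statistics. All inputs and six result files are
#' written under `outdir`:
#' `markers.csv`, `primers.csv`, `quant.csv`, `unique_peptides.csv`,
#' `cohort_stats.csv` and `manifest.json` (versions, seed, parameters and
#' input checksums — sufficient to reproduce the run bit for bit).
#' Any stage failure aborts with a stage-labeled error and leaves a
#' `FAILED` marker file naming the stage.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param k number of markers to select.
#' @param max_mismatches_per_primer mismatch allowance for the specificity
#'   screen.
#' @return invisibly, a list with the in-memory results
#'   (`markers`, `primers`, `quant`, `unique_peptides`, `cohort_stats`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = sim_config(), outdir, k = 19L,
                         max_mismatches_per_primer = 1L) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  input_dir <- file.path(outdir, "inputs")
  dir.create(input_dir, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  unlink(file.path(outdir, "FAILED"))

  # -- simulate ------------------------------------------------------------
  sim <- stage("simulate", {
    pg <- generate_pangenome(config)
    prot <- generate_proteomes(config)
    cohort <- generate_siga_cohort(config)
    abund <- generate_abundance_table(config)
    set.seed(config$seed + 505L)  # planted loads, own stream
    loads <- setNames(10^runif(8, 2, 7), sprintf("LF%02d", 1:8))
    run <- generate_qpcr_run(config, loads)
    write_genome_set(pg$reference, file.path(input_dir, "reference.fasta"))
    write_genome_set(pg$inclusion, file.path(input_dir, "inclusion.fasta"))
    write_genome_set(pg$exclusion, file.path(input_dir, "exclusion.fasta"))
    write_fasta(prot$inclusion, file.path(input_dir, "inclusion_proteome.fasta"))
    write_fasta(prot$background, file.path(input_dir, "background_proteome.fasta"))
    write_planted_truth(pg$truth, file.path(input_dir, "planted_truth.json"))
    .write_table(cohort, file.path(input_dir, "cohort.csv"))
    list(pg = pg, prot = prot, cohort = cohort, abund = abund,
         run = run, loads = loads)
  })

  # -- discover markers ----------------------------------------------------
  markers <- stage("discover-markers", {
    disc <- discover_markers(sim$pg$reference, sim$pg$inclusion,
                             sim$pg$exclusion, k = k)
    m <- disc$markers
    m$hits <- NULL
    .write_table(m, file.path(outdir, "markers.csv"))
    m
  })

  # -- design primers + in-silico PCR --------------------------------------
  primers <- stage("design-primers", {
    ref_tbl <- genes_table(sim$pg$reference)
    rows <- list()
    for (g in markers$gene_id) {
      tmpl <- ref_tbl$sequence[ref_tbl$gene_id == g]
      des <- design_primers(tmpl, target_gene_id = g, max_pairs = 1L)
      if (nrow(des) == 0) next
      des$verdict <- if (n_genomes(sim$pg$exclusion) > 0) {
        specificity_check(des[1, ], sim$pg$inclusion, sim$pg$exclusion,
                          max_mismatches_per_primer = max_mismatches_per_primer)$verdict
      } else NA_character_  # no exclusion clade: specificity undefined
      rows[[length(rows) + 1L]] <- des
    }
    p <- if (length(rows) > 0) do.call(rbind, rows) else
      tibble(name = character(), forward = character(), reverse = character(),
             verdict = character())
    .write_table(p, file.path(outdir, "primers.csv"))
    p
  })

  # -- quantify ------------------------------------------------------------
  quant <- stage("quantify", {
    q <- quantify_run(sim$run)
    q$true_load <- unname(sim$loads[q$sample_id])
    .write_table(q, file.path(outdir, "quant.csv"))
    q
  })

  # -- peptide uniqueness --------------------------------------------------
  uniq <- stage("uniqueness", {
    u <- call_unique_peptides(sim$prot$truth$planted_unique_peptides,
                              sim$prot$inclusion, sim$prot$background)
    out <- u[, c("peptide", "n_inclusion", "n_background", "unique")]
    .write_table(out, file.path(outdir, "unique_peptides.csv"))
    out
  })

  # -- cohort statistics ---------------------------------------------------
  cohort_stats <- stage("cohort-stats", {
    ch <- sim$cohort
    pos <- ch$siga_ug_ml[ch$sfb_status == "positive"]
    neg <- ch$siga_ug_ml[ch$sfb_status == "negative"]
    siga_cmp <- compare_groups(pos, neg, test = "student_t")
    rows <- list(tibble(
      analysis = "siga", metric = "median_positive_vs_negative",
      value_a = siga_cmp$median_a, value_b = siga_cmp$median_b,
      statistic = siga_cmp$statistic, p_value = siga_cmp$p_value))

    ct_cols <- grep("^ct_(?!actin)", names(ch), perl = TRUE, value = TRUE)
    for (cc in ct_cols) {
      fold <- relative_expression(ch[[cc]], ch$ct_actin)
      cmp <- compare_groups(fold[ch$sfb_status == "positive"],
                            fold[ch$sfb_status == "negative"],
                            test = "student_t")
      rows[[length(rows) + 1L]] <- tibble(
        analysis = "expression", metric = sub("^ct_", "", cc),
        value_a = cmp$mean_a, value_b = cmp$mean_b,
        statistic = cmp$statistic, p_value = cmp$p_value)
    }

    taxa <- setdiff(names(sim$abund), c("sample_id", "sfb_status"))
    H <- apply(as.matrix(sim$abund[, taxa]), 1, shannon_index)
    sh_cmp <- compare_groups(H[sim$abund$sfb_status == "positive"],
                             H[sim$abund$sfb_status == "negative"],
                             test = "student_t")
    rows[[length(rows) + 1L]] <- tibble(
      analysis = "diversity", metric = "shannon_positive_vs_negative",
      value_a = sh_cmp$mean_a, value_b = sh_cmp$mean_b,
      statistic = sh_cmp$statistic, p_value = sh_cmp$p_value)

    st <- do.call(rbind, rows)
    .write_table(st, file.path(outdir, "cohort_stats.csv"))
    st
  })

  # -- manifest ------------------------------------------------------------
  manifest <- stage("manifest", {
    inputs <- list.files(input_dir, full.names = TRUE)
    m <- list(
      package = "raretaxa",
      version = as.character(utils::packageVersion("raretaxa")),
      seed = config$seed,
      parameters = unclass(config),
      k = k,
      max_mismatches_per_primer = max_mismatches_per_primer,
      input_checksums = as.list(setNames(unname(tools::md5sum(inputs)),
                                         basename(inputs))),
      outputs = c("markers.csv", "primers.csv", "quant.csv",
                  "unique_peptides.csv", "cohort_stats.csv"))
    jsonlite::write_json(m, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    m
  })

  invisible(list(markers = markers, primers = primers, quant = quant,
                 unique_peptides = uniq, cohort_stats = cohort_stats,
                 manifest = manifest))
}
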