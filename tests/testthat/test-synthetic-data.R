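test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_conserved = 11, n_reference_genes = 10),
               "n_conserved")
  expect_error(sim_config(n_exclusion_shared = 5, n_conserved = 4),
               "n_exclusion_shared")
  expect_error(sim_config(point_mutation_rate = 0.3), "mutation")
  expect_error(sim_config(siga_median_pos = 0), "median")
  expect_error(sim_config(curve_slope = 0.1), "slope")
})

test_that("pan-genome generator plants the expected marker set", {
  cfg <- sim_config(seed = 1, n_inclusion_genomes = 3, n_exclusion_genomes = 2,
                    n_reference_genes = 10, n_conserved = 4,
                    n_exclusion_shared = 1)
  pg <- generate_pangenome(cfg)
  expect_length(pg$truth$marker_gene_ids, 3)  # 4 conserved - 1 shared
  expect_setequal(pg$truth$marker_gene_ids,
                  setdiff(pg$truth$conserved_gene_ids,
                          pg$truth$exclusion_shared_gene_ids))
  expect_equal(n_genomes(pg$inclusion), 2)  # reference counted separately
  expect_equal(n_genomes(pg$exclusion), 2)
  expect_equal(nrow(genes_table(pg$reference)), 10)
})

test_that("mutation-free conserved copies are identical to the reference", {
  cfg <- sim_config(seed = 3, point_mutation_rate = 0)
  pg <- generate_pangenome(cfg)
  ref <- genes_table(pg$reference)
  for (gm in names(pg$inclusion$genomes)) {
    g <- pg$inclusion$genomes[[gm]]
    for (gid in pg$truth$conserved_gene_ids) {
      expect_identical(g$sequence[g$gene_id == gid],
                       ref$sequence[ref$gene_id == gid])
    }
  }
})

test_that("planted truth matches a brute-force scan of the emitted genomes", {
  cfg <- sim_config(seed = 11, point_mutation_rate = 0)
  pg <- generate_pangenome(cfg)
  ref <- genes_table(pg$reference)
  present_in_all <- function(gs, seqs) {
    vapply(seqs, function(s) {
      all(vapply(gs$genomes, function(g) s %in% g$sequence, TRUE))
    }, TRUE)
  }
  present_in_any <- function(gs, seqs) {
    vapply(seqs, function(s) {
      any(vapply(gs$genomes, function(g) s %in% g$sequence, TRUE))
    }, TRUE)
  }
  conserved_scan <- ref$gene_id[present_in_all(pg$inclusion, ref$sequence)]
  shared_scan <- ref$gene_id[present_in_any(pg$exclusion, ref$sequence)]
  expect_setequal(conserved_scan, pg$truth$conserved_gene_ids)
  expect_setequal(shared_scan, pg$truth$exclusion_shared_gene_ids)
  expect_setequal(setdiff(conserved_scan, shared_scan),
                  pg$truth$marker_gene_ids)
})

test_that("generators are deterministic under the seed (byte-identical FASTA)", {
  cfg <- sim_config(seed = 5)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_genome_set(generate_pangenome(cfg)$inclusion, f1)
  write_genome_set(generate_pangenome(cfg)$inclusion, f2)
  expect_identical(readLines(f1), readLines(f2))

  p1 <- tempfile(fileext = ".fasta"); p2 <- tempfile(fileext = ".fasta")
  write_fasta(generate_proteomes(cfg)$inclusion, p1)
  write_fasta(generate_proteomes(cfg)$inclusion, p2)
  expect_identical(readLines(p1), readLines(p2))

  r1 <- generate_qpcr_run(cfg, c(s1 = 1e4))
  r2 <- generate_qpcr_run(cfg, c(s1 = 1e4))
  expect_identical(r1$curve$ct, r2$curve$ct)
  expect_identical(r1$samples$ct, r2$samples$ct)
})

test_that("sIgA cohort hits the configured medians and degenerate limits", {
  cfg <- sim_config(seed = 7)
  ch <- generate_siga_cohort(cfg)
  expect_equal(nrow(ch), 47)
  expect_equal(sum(ch$sfb_status == "positive"), 23)
  pos_med <- median(ch$siga_ug_ml[ch$sfb_status == "positive"])
  expect_lt(abs(pos_med - 118.60) / 118.60, 0.25)
  expect_true(all(ch$age_months >= 8 & ch$age_months <= 48))

  # degenerate log-sd: every value equals the group median
  ch0 <- generate_siga_cohort(sim_config(siga_log_sd = 0))
  expect_equal(ch0$siga_ug_ml[ch0$sfb_status == "positive"],
               rep(118.60, 23))
  expect_equal(ch0$siga_ug_ml[ch0$sfb_status == "negative"],
               rep(69.21, 24))

  # empty positive group is not an error
  ch_empty <- generate_siga_cohort(sim_config(n_pos_subjects = 0))
  expect_equal(sum(ch_empty$sfb_status == "positive"), 0)
})

test_that("over 200 replicates the mean positive-group sample median is within 5% of the parameter", {
  meds <- vapply(1:200, function(s) {
    ch <- generate_siga_cohort(sim_config(seed = s))
    median(ch$siga_ug_ml[ch$sfb_status == "positive"])
  }, 0)
  expect_lt(abs(mean(meds) - 118.60) / 118.60, 0.05)
})

test_that("qPCR generator follows the log-linear model exactly when noise-free", {
  cfg <- sim_config(seed = 2, curve_slope = -3.3219, curve_intercept = 37,
                    ct_noise_sd = 0)
  run <- generate_qpcr_run(cfg, c(s1 = 1e4, s2 = 1))
  ct1 <- run$samples$ct[run$samples$sample_id == "s1"]
  expect_equal(unique(ct1), 37 - 3.3219 * 4, tolerance = 1e-12)  # 23.7124
  ct2 <- run$samples$ct[run$samples$sample_id == "s2"]
  expect_equal(unique(ct2), 37)  # load of 1 copy -> Ct = intercept
  expect_equal(sort(unique(run$curve$copies)), 10^(1:7))
  expect_error(generate_qpcr_run(cfg, c(s1 = -5)), "loads")
})

test_that("proteome generator releases planted peptides and isolates the background", {
  cfg <- sim_config(seed = 9)
  pr <- generate_proteomes(cfg, planted_peptides = "EMMDQPEFK")
  host <- pr$inclusion$seq[pr$inclusion$desc == "planted-host"]
  expect_true(any(grepl("EMMDQPEFK", host, fixed = TRUE)))
  peps <- digest(host[1], max_missed = 2, min_length = 4)
  expect_true("EMMDQPEFK" %in% peps$peptide)
  expect_false(any(grepl("EMMDQPEFK", pr$background$seq, fixed = TRUE)))
  expect_error(generate_proteomes(cfg, planted_peptides = "EMXK"),
               "non-standard")
})

test_that("with no planted peptides the proteomes share no peptide of length >= 4", {
  pr <- generate_proteomes(sim_config(seed = 13), planted_peptides = character())
  inc_peps <- unique(unlist(lapply(pr$inclusion$seq, function(s) {
    digest_oracle(s, max_missed = 2, min_length = 4)
  })))
  shared <- vapply(inc_peps, function(p) {
    any(grepl(p, pr$background$seq, fixed = TRUE))
  }, TRUE)
  expect_false(any(shared))
})

test_that("abundance tables carry the planted directional taxon shifts", {
  ab <- generate_abundance_table(sim_config(seed = 4), n_per_group = 5)
  pos <- ab$sfb_status == "positive"
  for (t in c("Clostridia", "Coriobacteriia", "Deltaproteobacteria")) {
    expect_gt(mean(ab[[t]][pos]), mean(ab[[t]][!pos]))
  }
  for (t in c("Bacteroides", "Escherichia", "Klebsiella")) {
    expect_lt(mean(ab[[t]][pos]), mean(ab[[t]][!pos]))
  }
  taxa <- setdiff(names(ab), c("sample_id", "sfb_status"))
  expect_equal(rowSums(as.matrix(ab[, taxa])), rep(1, nrow(ab)))
})
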