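test_that("Wallace-rule melting temperature is exact", {
  expect_equal(melting_temperature("AAAA"), 8)
  expect_equal(melting_temperature("GGGG"), 16)
  # 20-mer with 10 G/C and 10 A/T
  expect_equal(melting_temperature(strrep("GA", 10)), 60)
  expect_error(melting_temperature("ACGN"), "non-ACGT")
  expect_error(primer_pair("p", "ACGR", "ACGT"), "non-ACGT")  # IUPAC rejected
})

test_that("infeasible design constraints give an empty table, not an error", {
  short <- random_dna_str(60)  # shorter than the minimum product length
  expect_equal(nrow(design_primers(short)), 0)
  expect_equal(nrow(design_primers(strrep("A", 500))), 0)  # GC unsatisfiable
  expect_error(design_primers("ACGT"), "shorter")  # below min primer length
})

test_that("every designed pair re-validates against the constraints", {
  set.seed(55)
  tmpl <- random_dna_str(500)
  des <- design_primers(tmpl, target_gene_id = "g", max_pairs = 50)
  expect_gt(nrow(des), 0)
  for (i in seq_len(nrow(des))) {
    f <- des$forward[i]; r <- des$reverse[i]
    for (p in c(f, r)) {
      expect_true(nchar(p) >= 18 && nchar(p) <= 25)
      gc <- 100 * lengths(regmatches(p, gregexpr("[GC]", p))) / nchar(p)
      expect_true(gc >= 40 && gc <= 60)
      b <- strsplit(p, "")[[1]]
      tm_oracle <- 2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
      expect_true(tm_oracle >= 55 && tm_oracle <= 62)
    }
    expect_lte(abs(des$tm_forward[i] - des$tm_reverse[i]), 3)
    expect_true(des$product_length[i] >= 80 && des$product_length[i] <= 300)
    expect_gte(des$product_length[i], nchar(f) + nchar(r))
    # primers really are the template windows they claim to be
    expect_identical(substr(tmpl, des$fwd_start[i] + 1,
                            des$fwd_start[i] + nchar(f)), f)
    expect_identical(revcomp(substr(tmpl, des$rev_end[i] - nchar(r) + 1,
                                    des$rev_end[i])), r)
  }
  # deterministic: same call, same result
  expect_identical(des, design_primers(tmpl, target_gene_id = "g",
                                       max_pairs = 50))
})

test_that("in-silico PCR finds a constructed amplicon and nothing else", {
  set.seed(66)
  fwd <- "ACGTGCATGCATCGATGCAA"
  rev <- "TGCACGTAGCTAGCTAGGTT"
  tmpl <- paste0(fwd, random_dna_str(100), revcomp(rev))
  gs <- genome_set(list(g1 = tibble::tibble(gene_id = "t1", sequence = tmpl)))
  pp <- primer_pair("p", fwd, rev)
  hits <- insilico_pcr(pp, gs, max_mismatches_per_primer = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$product_length, nchar(fwd) + 100 + nchar(rev))
  expect_equal(hits$start, 0L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches_forward, 0L)

  # absent primers -> empty result
  gs2 <- genome_set(list(g1 = tibble::tibble(gene_id = "t1",
                                             sequence = random_dna_str(300))))
  expect_equal(nrow(insilico_pcr(pp, gs2, 0)), 0)
})

test_that("in-silico PCR is strand-symmetric", {
  set.seed(67)
  fwd <- "GATTACAGATTACAGGCGCA"
  rev <- "CCATGGTACCATGGTAGGCA"
  tmpl <- paste0(random_dna_str(30), fwd, random_dna_str(120),
                 revcomp(rev), random_dna_str(30))
  pp <- primer_pair("p", fwd, rev)
  gs_fw <- genome_set(list(g = tibble::tibble(gene_id = "t", sequence = tmpl)))
  gs_rc <- genome_set(list(g = tibble::tibble(gene_id = "t",
                                              sequence = revcomp(tmpl))))
  h1 <- insilico_pcr(pp, gs_fw, 0)
  h2 <- insilico_pcr(pp, gs_rc, 0)
  expect_equal(nrow(h1), 1)
  expect_equal(nrow(h2), 1)
  expect_equal(h1$product_length, h2$product_length)
  expect_setequal(c(h1$strand, h2$strand), c("+", "-"))
  # coordinates map to mirrored positions
  L <- nchar(tmpl)
  expect_equal(h2$start, L - h1$end)
  expect_equal(h2$end, L - h1$start)
})

test_that("with zero mismatches the binding sites equal the primers exactly", {
  set.seed(68)
  tmpl <- random_dna_str(400)
  des <- design_primers(tmpl, max_pairs = 3)
  gs <- genome_set(list(g = tibble::tibble(gene_id = "t", sequence = tmpl)))
  for (i in seq_len(nrow(des))) {
    pp <- primer_pair(des$name[i], des$forward[i], des$reverse[i])
    hits <- insilico_pcr(pp, gs, 0)
    expect_gt(nrow(hits), 0)
    for (j in seq_len(nrow(hits))) {
      s <- hits$start[j]; e <- hits$end[j]
      amplicon <- substr(tmpl, s + 1, e)
      if (hits$strand[j] == "-") amplicon <- revcomp(amplicon)
      expect_identical(substr(amplicon, 1, nchar(pp$forward)), pp$forward)
      expect_identical(revcomp(substr(amplicon,
                                      nchar(amplicon) - nchar(pp$reverse) + 1,
                                      nchar(amplicon))), pp$reverse)
    }
  }
})

test_that("specificity verdicts follow the planted truth", {
  cfg <- sim_config(seed = 71, point_mutation_rate = 0,
                    n_reference_genes = 8, n_conserved = 4,
                    n_exclusion_shared = 2, gene_length_bp = 400)
  pg <- generate_pangenome(cfg)
  ref <- genes_table(pg$reference)
  design_for <- function(gid) {
    des <- design_primers(ref$sequence[ref$gene_id == gid],
                          target_gene_id = gid, max_pairs = 1)
    primer_pair(des$name[1], des$forward[1], des$reverse[1])
  }
  marker <- pg$truth$marker_gene_ids[1]
  shared <- pg$truth$exclusion_shared_gene_ids[1]
  ref_only <- setdiff(ref$gene_id, pg$truth$conserved_gene_ids)[1]

  expect_equal(specificity_check(design_for(marker), pg$inclusion,
                                 pg$exclusion, 0)$verdict, "specific")
  expect_equal(specificity_check(design_for(shared), pg$inclusion,
                                 pg$exclusion, 0)$verdict, "non_specific")
  expect_equal(specificity_check(design_for(ref_only), pg$inclusion,
                                 pg$exclusion, 0)$verdict, "non_universal")
  expect_error(specificity_check(design_for(marker),
                                 genome_set(setNames(list(), character())),
                                 pg$exclusion), "non-empty")
})
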