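test_that("align_local handles the boundary cases", {
  hit <- align_local("ACGTACGTACGT", "ACGTACGTACGT")
  expect_equal(hit$identity, 100)
  expect_equal(hit$query_coverage, 100)
  expect_equal(hit$score, 12)

  expect_null(align_local("AAAA", "CCCC"))  # no positive-scoring alignment

  hit <- align_local("ACGTACGTAC", "ACGTTCGTAC")
  expect_equal(hit$score, 8)
  expect_equal(hit$identity, 90)
  expect_equal(hit$query_coverage, 100)

  expect_error(align_local("", "ACGT"), "empty")
  expect_error(align_local("ACGT", "ACGN"), "non-ACGT")
})

test_that("align_local matches the exhaustive DP oracle on random pairs", {
  set.seed(101)
  for (rep in 1:60) {
    q <- random_dna_str(sample(10:80, 1))
    s <- random_dna_str(sample(10:80, 1))
    got <- align_local(q, s)
    want <- sw_oracle(q, s)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$score, want$score)
      expect_equal(got$identity, want$identity)
      expect_equal(got$query_coverage, want$query_coverage)
      expect_equal(got$qend, want$qend)
      expect_equal(got$send, want$send)
    }
  }
})

test_that("conservation scan marks every gene conserved against exact copies", {
  cfg <- sim_config(seed = 21, point_mutation_rate = 0)
  pg <- generate_pangenome(cfg)
  # inclusion genome that is an exact copy of the reference
  ref_genes <- pg$reference$genomes$ref
  inc <- genome_set(list(copy1 = ref_genes), clade_label = "inclusion")
  cand <- conservation_scan(pg$reference, inc)
  expect_true(all(cand$conserved))
  expect_equal(cand$conservation_score, rep(1, nrow(cand)))
})

test_that("a gene absent from one inclusion genome is not conserved", {
  ref <- genome_set(list(ref = tibble::tibble(
    gene_id = c("gA", "gB"),
    sequence = c(random_dna_str(120), random_dna_str(120)))),
    clade_label = "reference")
  g_full <- ref$genomes$ref
  g_partial <- g_full[g_full$gene_id == "gA", ]
  inc <- genome_set(list(i1 = g_full, i2 = g_partial))
  cand <- conservation_scan(ref, inc)
  expect_true(cand$conserved[cand$gene_id == "gA"])
  expect_false(cand$conserved[cand$gene_id == "gB"])
})

test_that("homologs on the reverse strand are still found", {
  set.seed(77)
  seqs <- c(random_dna_str(150), random_dna_str(150))
  ref <- genome_set(list(ref = tibble::tibble(gene_id = c("g1", "g2"),
                                              sequence = seqs)),
                    clade_label = "reference")
  flipped <- tibble::tibble(gene_id = c("g1", "g2"),
                            sequence = vapply(seqs, revcomp, ""))
  inc <- genome_set(list(i1 = flipped))
  cand <- conservation_scan(ref, inc)
  expect_true(all(cand$conserved))
})

test_that("exclusion subtraction follows the planted truth and its edge cases", {
  cfg <- sim_config(seed = 1, n_inclusion_genomes = 3, n_exclusion_genomes = 2,
                    n_reference_genes = 10, n_conserved = 4,
                    n_exclusion_shared = 1, point_mutation_rate = 0)
  pg <- generate_pangenome(cfg)
  cand <- conservation_scan(pg$reference, pg$inclusion)
  cand <- subtract_exclusion(cand, pg$reference, pg$exclusion)
  markers <- cand[cand$conserved & !cand$exclusion_hit, ]
  expect_setequal(markers$gene_id, pg$truth$marker_gene_ids)
  expect_equal(nrow(markers), 3)

  # exclusion set = reference itself -> everything subtracted
  cand2 <- subtract_exclusion(conservation_scan(pg$reference, pg$inclusion),
                              pg$reference,
                              genome_set(list(x = pg$reference$genomes$ref),
                                         clade_label = "exclusion"))
  expect_true(all(cand2$exclusion_hit))

  # empty exclusion set -> vacuous subtraction
  cand3 <- subtract_exclusion(conservation_scan(pg$reference, pg$inclusion),
                              pg$reference,
                              genome_set(setNames(list(), character()),
                                         clade_label = "exclusion"))
  expect_false(any(cand3$exclusion_hit))
  expect_setequal(cand3$gene_id[cand3$conserved],
                  pg$truth$conserved_gene_ids)
})

test_that("rank_and_select orders by score with lexicographic tie-break", {
  cand <- tibble::tibble(
    gene_id = c("gC", "gA", "gB"),
    conserved = TRUE,
    conservation_score = c(0.9, 0.8, 0.8),
    n_genomes_hit = 1L, exclusion_hit = FALSE, rank = NA_integer_)
  sel <- rank_and_select(cand, 2)
  expect_equal(sel$gene_id, c("gC", "gA"))
  expect_equal(sel$rank, 1:2)
  expect_equal(rank_and_select(cand, 10)$gene_id, c("gC", "gA", "gB"))
  expect_equal(nrow(rank_and_select(cand, 0)), 0)
  expect_error(rank_and_select(cand, -1), "k")
})

test_that("marker recovery is exact on planted pan-genomes (mutated and not)", {
  for (mu in c(0, 0.02)) {
    for (seed in c(31, 32, 33)) {
      cfg <- sim_config(seed = seed, point_mutation_rate = mu,
                        n_reference_genes = 8, n_conserved = 4,
                        n_exclusion_shared = 2, gene_length_bp = 200)
      pg <- generate_pangenome(cfg)
      disc <- discover_markers(pg$reference, pg$inclusion, pg$exclusion,
                               k = 8)
      expect_setequal(disc$markers$gene_id, pg$truth$marker_gene_ids)
    }
  }
})

test_that("scores are invariant to genome input order and exclusion only shrinks the marker set", {
  cfg <- sim_config(seed = 41, n_reference_genes = 6, n_conserved = 3,
                    n_exclusion_shared = 1, gene_length_bp = 150)
  pg <- generate_pangenome(cfg)
  cand1 <- conservation_scan(pg$reference, pg$inclusion)
  inc_rev <- genome_set(rev(pg$inclusion$genomes), clade_label = "inclusion")
  cand2 <- conservation_scan(pg$reference, inc_rev)
  expect_equal(cand1$conservation_score, cand2$conservation_score)
  expect_equal(cand1$conserved, cand2$conserved)

  # monotonicity: adding an exclusion genome never enlarges the marker set
  sub1 <- subtract_exclusion(cand1, pg$reference,
                             genome_set(pg$exclusion$genomes[1],
                                        clade_label = "exclusion"))
  sub2 <- subtract_exclusion(cand1, pg$reference, pg$exclusion)
  m1 <- sub1$gene_id[sub1$conserved & !sub1$exclusion_hit]
  m2 <- sub2$gene_id[sub2$conserved & !sub2$exclusion_hit]
  expect_true(all(m2 %in% m1))

  # monotonicity: adding an inclusion genome never enlarges the conserved set
  inc_less <- genome_set(pg$inclusion$genomes[1], clade_label = "inclusion")
  cand_less <- conservation_scan(pg$reference, inc_less)
  expect_true(all(cand1$gene_id[cand1$conserved] %in%
                    cand_less$gene_id[cand_less$conserved]))
})
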