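test_that("generation is byte-deterministic per seed", {
  cfg <- synth_config(n_species = 5, genomes_per_species = 2,
                      copies_per_genome = 3, seq_length = 300,
                      intragenomic_subs = 4, interspecies_subs = 30,
                      seed = 42)
  a <- generate_community(cfg)
  b <- generate_community(cfg)
  expect_identical(a$copies, b$copies)
  expect_identical(a$ground_truth$genomes, b$ground_truth$genomes)
  d1 <- tempfile(); d2 <- tempfile()
  write_community(a, d1); write_community(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  c2 <- generate_community(synth_config(n_species = 5, genomes_per_species = 2,
                                        copies_per_genome = 3, seq_length = 300,
                                        intragenomic_subs = 4,
                                        interspecies_subs = 30, seed = 43))
  expect_false(identical(a$copies$aligned_seq, c2$copies$aligned_seq))
})

test_that("zero intragenomic substitutions give one ASV per genome", {
  cm <- generate_community(synth_config(n_species = 4, genomes_per_species = 1,
                                        copies_per_genome = 7,
                                        seq_length = 400,
                                        intragenomic_subs = 0,
                                        interspecies_subs = 40, seed = 6))
  expect_true(all(cm$ground_truth$genomes$true_n_asvs == 1))
  expect_true(all(cm$ground_truth$genomes$copy_number == 7))
})

test_that("substitution counts map exactly to ground-truth distances", {
  cm <- generate_community(synth_config(n_species = 6, genomes_per_species = 1,
                                        copies_per_genome = 3,
                                        seq_length = 1500,
                                        intragenomic_subs = c(0L, 30L),
                                        intergenomic_subs = 0,
                                        interspecies_subs = 200, seed = 12))
  gt <- cm$ground_truth$genomes
  expect_true(all(gt$true_n_asvs == 2))
  expect_true(all(gt$max_intragenomic_distance == 30 / 1500))
  # recompute from the emitted sequences with the package's own engine
  for (acc in gt$accession) {
    seqs <- cm$copies$aligned_seq[cm$copies$accession == acc]
    m <- dist_matrix(seqs)
    expect_equal(max(m), 0.02, tolerance = 1e-12)
  }
  expect_true(all(cm$ground_truth$species_pairs$min_distance >= 200 / 1500 / 2))
})

test_that("ground truth recomputed from emitted files matches exactly", {
  cm <- generate_community(synth_config(n_species = 5, genomes_per_species = 2,
                                        copies_per_genome = 4, seq_length = 500,
                                        intragenomic_subs = 5,
                                        interspecies_subs = 60, seed = 77))
  dir <- tempfile()
  paths <- write_community(cm, dir)
  catalog <- read_catalog(paths["fasta"], paths["metadata"], quiet = TRUE)
  recomputed <- catalog$copies |>
    dplyr::group_by(accession) |>
    dplyr::summarise(true_n_asvs = dplyr::n_distinct(unaligned_seq),
                     max_d = max(dist_matrix(aligned_seq)))
  gt <- cm$ground_truth$genomes[order(cm$ground_truth$genomes$accession), ]
  expect_equal(recomputed$true_n_asvs, gt$true_n_asvs)
  expect_equal(recomputed$max_d, gt$max_intragenomic_distance,
               tolerance = 1e-12)
})

test_that("injected shared variants appear as multi-species ASVs", {
  cm <- generate_community(synth_config(n_species = 6, genomes_per_species = 1,
                                        copies_per_genome = 2, seq_length = 500,
                                        intragenomic_subs = 10,
                                        interspecies_subs = 60, seed = 9))
  tab0 <- dereplicate(tibble::tibble(sequence = cm$copies$unaligned_seq,
                                     accession = cm$copies$accession,
                                     species_key = cm$copies$species_key))
  expect_equal(rrnsplit:::asv_multi_fraction(tab0), 0)
  cm2 <- inject_shared_variant(cm, "Synthetica species001",
                               "Synthetica species005", seed = 3)
  expect_equal(nrow(cm2$ground_truth$shared_asvs), 1)
  tab <- dereplicate(tibble::tibble(sequence = cm2$copies$unaligned_seq,
                                    accession = cm2$copies$accession,
                                    species_key = cm2$copies$species_key))
  n_multi <- sum(tapply(tab$members$species_key, tab$members$asv_id,
                        function(x) length(unique(x))) >= 2)
  expect_equal(n_multi, 1)
  expect_error(inject_shared_variant(cm, "Synthetica species001", "nope"),
               "not found")
})

test_that("impossible separation constraints raise a generation error", {
  expect_error(generate_community(
    synth_config(n_species = 20, genomes_per_species = 1,
                 copies_per_genome = 1, seq_length = 4,
                 intragenomic_subs = 0, intergenomic_subs = 0,
                 interspecies_subs = 4, seed = 1)),
    "generation error")
  expect_error(synth_config(intragenomic_subs = 40, interspecies_subs = 75),
               "well_separated")
})

test_that("indel columns exercise the gap policies without breaking truth", {
  cm <- generate_community(synth_config(n_species = 4, genomes_per_species = 1,
                                        copies_per_genome = 3, seq_length = 300,
                                        intragenomic_subs = 3,
                                        interspecies_subs = 30,
                                        indel_columns = 10, seed = 15))
  widths <- nchar(cm$copies$aligned_seq)
  expect_true(all(widths == widths[1]))
  expect_true(any(grepl("-", cm$copies$aligned_seq, fixed = TRUE)))
  # within-genome insertion patterns are shared, so distances are unchanged
  gt <- cm$ground_truth$genomes
  expect_true(all(gt$max_intragenomic_distance <= 6 / 300 + 1e-12))
  expect_true(all(gt$true_n_asvs == 3))
})
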