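small_community <- function(seed = 21, n_species = 8, copies = 3,
                            genomes = 2, intragenomic = 6) {
  generate_community(synth_config(
    n_species = n_species, genomes_per_species = genomes,
    copies_per_genome = copies, seq_length = 600,
    intragenomic_subs = intragenomic, intergenomic_subs = 1,
    interspecies_subs = 90, seed = seed))
}

test_that("one genome is sampled per species, deterministically", {
  catalog <- as_catalog(small_community())
  sub <- sample_one_genome_per_species(catalog, seed = 4)
  expect_equal(nrow(sub$genomes), 8)
  expect_equal(anyDuplicated(sub$genomes$species_key), 0)
  sub2 <- sample_one_genome_per_species(catalog, seed = 4)
  expect_identical(sub$genomes$accession, sub2$genomes$accession)
  # a species with a single genome is always selected
  one <- subset_catalog(catalog, catalog$genomes$accession[1])
  expect_equal(sample_one_genome_per_species(one, 1)$genomes$accession,
               catalog$genomes$accession[1])
})

test_that("genome intactness reflects OTU co-membership of its ASVs", {
  tab <- dereplicate(tibble::tibble(
    sequence = c("AAAA", "CCCC", "CCCC", "GGGG"),
    accession = c("G1", "G1", "G2", "G2"),
    species_key = c("s one", "s one", "s two", "s two")))
  split_part <- opticlust_partition(
    neighbor_set(data.frame(i = integer(), j = integer(),
                            distance = numeric()), 3, 0.1), 0.03)
  expect_false(genome_intact("G1", tab, split_part))
  merged <- neighbor_set(data.frame(i = c(1, 2), j = c(2, 3),
                                    distance = 0.01), 3, 0.1)
  merged_part <- opticlust_partition(merged, 0.03)
  expect_true(genome_intact("G1", tab, merged_part))
  one_asv <- dereplicate(tibble::tibble(sequence = c("AAAA", "AAAA"),
                                        accession = "G1", species_key = "s"))
  expect_true(genome_intact("G1", one_asv, split_part))
  bad <- opticlust_partition(neighbor_set(
    data.frame(i = integer(), j = integer(), distance = numeric()), 1, 0.1),
    0.03)
  expect_error(genome_intact("G1", tab, bad), "consistency error")
})

test_that("identical copies keep every genome intact from the first threshold", {
  cm <- generate_community(synth_config(
    n_species = 6, genomes_per_species = 1, copies_per_genome = 4,
    seq_length = 400, intragenomic_subs = 0, intergenomic_subs = 0,
    interspecies_subs = 40, seed = 3))
  cfg <- stat_config(thresholds = c(0.0025, 0.05), n_randomizations = 2,
                     min_species_per_copy_class = 0, master_seed = 9)
  res <- collapse_threshold_curve(as_catalog(cm), region_full(400), cfg)
  expect_true(all(res$intact_curves$fraction_intact == 1))
  expect_true(all(res$collapse$collapse_threshold == 0.0025))
})

test_that("the collapse threshold recovers the constructed intragenomic distance", {
  # every genome: two identical copies plus one at exactly 12/600 = 0.02
  cm <- generate_community(synth_config(
    n_species = 25, genomes_per_species = 1, copies_per_genome = 3,
    seq_length = 600, intragenomic_subs = c(0L, 12L), intergenomic_subs = 0,
    interspecies_subs = 90, seed = 31))
  expect_true(all(cm$ground_truth$genomes$max_intragenomic_distance == 0.02))
  cfg <- stat_config(thresholds = seq(0.005, 0.04, by = 0.005),
                     n_randomizations = 3, min_species_per_copy_class = 0,
                     master_seed = 2)
  for (clusterer in c("opticlust", "complete")) {
    cfg$clusterer <- clusterer
    res <- collapse_threshold_curve(as_catalog(cm), region_full(600), cfg)
    expect_equal(res$collapse_summary$copy_class, 3L)
    expect_equal(res$collapse_summary$median_collapse_threshold, 0.02)
  }
})

test_that("copy classes below the species floor are excluded", {
  cm <- small_community(seed = 55, n_species = 6, copies = 2, genomes = 1)
  cfg <- stat_config(thresholds = c(0.01, 0.03), n_randomizations = 1,
                     min_species_per_copy_class = 100, master_seed = 1)
  res <- collapse_threshold_curve(as_catalog(cm), region_full(600), cfg)
  expect_equal(nrow(res$collapse), 0)  # 6 species never exceeds the floor
  cfg$min_species_per_copy_class <- 0L
  res2 <- collapse_threshold_curve(as_catalog(cm), region_full(600), cfg)
  expect_gt(nrow(res2$collapse), 0)
})

test_that("a variant shared by two species is the only multi-species ASV", {
  cm <- generate_community(synth_config(
    n_species = 10, genomes_per_species = 1,
    copies_per_genome = dist_explicit(c(2, 2, rep(1, 8))),
    seq_length = 600, intragenomic_subs = 30, intergenomic_subs = 0,
    interspecies_subs = 90, seed = 13))
  cm <- inject_shared_variant(cm, "Synthetica species001",
                              "Synthetica species002", seed = 5)
  cfg <- stat_config(thresholds = c(0.0025, 0.0050), n_randomizations = 2,
                     min_species_per_copy_class = 0, master_seed = 7)
  res <- multispecies_fraction_curve(as_catalog(cm), region_full(600), cfg)
  expect_equal(unique(res$lump_curves$asv_fraction_multi), 1 / 11)
  # no clustering below the interspecies separation can lump species
  expect_true(all(res$lump_curves$fraction_multi > 0))
})

test_that("well-separated species never produce multi-species units", {
  cm <- small_community(seed = 77)
  cfg <- stat_config(thresholds = c(0.01, 0.05, 0.1), n_randomizations = 2,
                     min_species_per_copy_class = 0, master_seed = 3)
  res <- multispecies_fraction_curve(as_catalog(cm), region_full(600), cfg)
  expect_true(all(res$lump_curves$fraction_multi == 0))
  expect_true(all(res$lump_curves$asv_fraction_multi == 0))
})

test_that("a threshold above the diameter lumps everything into one OTU", {
  seqs <- c("AAAAAAAAAA", "AAAAAAAAAC", "AAAAAAAACC")
  tab <- dereplicate(tibble::tibble(sequence = seqs,
                                    accession = paste0("G", 1:3),
                                    species_key = paste("sp", 1:3)))
  nbrs <- neighbor_pairs(seqs, d_max = 0.5)
  part <- opticlust_partition(nbrs, 0.2)
  expect_equal(length(unique(part$otu_of)), 1)
  expect_equal(rrnsplit:::multi_species_fraction(tab, part), 1)
})

test_that("ASV-level multi-species fraction equals the threshold-zero OTU fraction", {
  cm <- generate_community(synth_config(
    n_species = 10, genomes_per_species = 1,
    copies_per_genome = dist_explicit(c(2, 2, rep(1, 8))),
    seq_length = 600, intragenomic_subs = 30, intergenomic_subs = 0,
    interspecies_subs = 90, seed = 19))
  cm <- inject_shared_variant(cm, "Synthetica species003",
                              "Synthetica species004", seed = 2)
  catalog <- as_catalog(cm)
  region <- region_full(600)
  tbl <- extract_region_catalog(catalog, region, ref_id = NULL)
  tab <- dereplicate(tbl, region$name)
  nbrs <- neighbor_pairs(tab$asvs$aligned_rep, d_max = 0.1)
  part0 <- opticlust_partition(nbrs, 0)
  expect_equal(rrnsplit:::asv_multi_fraction(tab),
               rrnsplit:::multi_species_fraction(tab, part0))
})

test_that("randomization summaries use linear-interpolation quantiles", {
  expect_equal(summarize_randomizations(c(0.1, 0.2, 0.3))$median, 0.2)
  expect_equal(summarize_randomizations(rep(0.07, 5))$iqr, 0)
  s <- summarize_randomizations(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$iqr, unname(diff(quantile(1:100, c(0.25, 0.75)))))
  expect_equal(s$iqr, 49.5)
})

test_that("replicate statistics are reproducible from the master seed", {
  catalog <- as_catalog(small_community(seed = 91))
  cfg <- stat_config(thresholds = c(0.01, 0.03), n_randomizations = 3,
                     min_species_per_copy_class = 0, master_seed = 123)
  regions <- rbind(region_full(600), tibble::tibble(name = "half",
                   ref_start = 101L, ref_end = 400L))
  r1 <- run_split_lump(catalog, regions, cfg)
  r2 <- run_split_lump(catalog, regions, cfg)
  expect_identical(r1$intact_curves, r2$intact_curves)
  expect_identical(r1$lump_curves, r2$lump_curves)
})
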