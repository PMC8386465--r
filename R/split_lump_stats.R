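# Genome-splitting threshold curves and multi-species (lumping) fractions
# under the species-controlled randomization design: one genome is sampled
# per species, the pooled ASV set is clustered across the threshold grid,
# and medians are taken over randomizations.

#' Configuration for the split/lump statistics
#'
#' Defaults follow the study design: a threshold grid from 0.25% to 10.00%
#' in 0.25-point increments, a 95% confidence level for the collapse
#' threshold, 100 randomizations, and copy-number classes kept only when
#' present in more than 100 species.
#'
#' @param thresholds increasing grid of clustering thresholds.
#' @param confidence fraction of genomes that must be intact for a class to
#'   have collapsed at a threshold.
#' @param n_randomizations number of one-genome-per-species resamplings.
#' @param min_species_per_copy_class classes present in at most this many
#'   species (per randomization) are excluded from the collapse curves.
#' @param master_seed integer; every replicate's seed derives from it.
#' @param gap_policy an [gap_policy()] for the pairwise distances.
#' @param d_max sparsity cutoff for the neighbor set (>= max(thresholds)).
#' @param clusterer `"opticlust"` or `"complete"` (furthest neighbor).
#' @param restarts restarts for the MCC clusterer.
#' @param boundary_policy region boundary policy, see [extract_region()].
#' @return an `rrn_stat_config` list.
#' @export
stat_config <- function(thresholds = seq(0.0025, 0.1, by = 0.0025),
                        confidence = 0.95,
                        n_randomizations = 100L,
                        min_species_per_copy_class = 100L,
                        master_seed = 1L,
                        gap_policy = rrnsplit::gap_policy(),
                        d_max = max(thresholds),
                        clusterer = c("opticlust", "complete"),
                        restarts = 1L,
                        boundary_policy = c("drop", "keep")) {
  stopifnot(all(diff(thresholds) > 0), confidence > 0, confidence < 1,
            n_randomizations >= 1, d_max >= max(thresholds))
  structure(list(thresholds = thresholds, confidence = confidence,
                 n_randomizations = as.integer(n_randomizations),
                 min_species_per_copy_class = as.integer(min_species_per_copy_class),
                 master_seed = as.integer(master_seed),
                 gap_policy = gap_policy, d_max = d_max,
                 clusterer = match.arg(clusterer),
                 restarts = as.integer(restarts),
                 boundary_policy = match.arg(boundary_policy)),
            class = "rrn_stat_config")
}

#' Sample one genome per species
#'
#' Uniformly selects one genome from each resolved species; genomes without
#' a resolvable species key are excluded.  Deterministic for a fixed seed.
#'
#' @param catalog an `rrn_catalog`.
#' @param seed integer seed.
#' @return an `rrn_catalog` subset with exactly one genome per species.
#' @export
sample_one_genome_per_species <- function(catalog, seed = 1L) {
  g <- catalog$genomes |>
    dplyr::filter(.data$species_resolved) |>
    dplyr::arrange(.data$species_key, .data$accession)
  picked <- with_seed_local(seed, {
    vapply(split(g$accession, g$species_key), function(accs) {
      accs[sample.int(length(accs), 1L)]
    }, character(1))
  })
  subset_catalog(catalog, unname(picked))
}

#' Is a genome intact in a partition?
#'
#' A genome is intact when every ASV holding any of its copies belongs to
#' the same OTU.
#'
#' @param accession genome accession.
#' @param table an `rrn_asv_table` containing the genome's copies.
#' @param partition an `rrn_partition` over the table's ASVs.
#' @return logical.
#' @export
genome_intact <- function(accession, table, partition) {
  asvs <- unique(table$members$asv_id[table$members$accession == accession])
  if (any(asvs > partition$n_items))
    stop("consistency error: ASV not assigned in partition", call. = FALSE)
  length(unique(partition$otu_of[asvs])) == 1
}

# Vectorized intactness for all genomes in a table.
genomes_intact <- function(table, partition) {
  if (max(c(0L, table$members$asv_id)) > partition$n_items)
    stop("consistency error: ASV not assigned in partition", call. = FALSE)
  table$members |>
    dplyr::distinct(.data$accession, .data$asv_id) |>
    dplyr::mutate(otu = partition$otu_of[.data$asv_id]) |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(intact = dplyr::n_distinct(.data$otu) == 1,
                     n_asvs = dplyr::n(), .groups = "drop")
}

# Fraction of OTUs containing >= 2 species.
multi_species_fraction <- function(table, partition) {
  tab <- table$members |>
    dplyr::filter(!is.na(.data$species_key)) |>
    dplyr::mutate(otu = partition$otu_of[.data$asv_id]) |>
    dplyr::group_by(.data$otu) |>
    dplyr::summarise(multi = dplyr::n_distinct(.data$species_key) >= 2,
                     .groups = "drop")
  n_otus <- length(unique(partition$otu_of))
  sum(tab$multi) / n_otus
}

# Fraction of ASVs containing >= 2 species (threshold-free).
asv_multi_fraction <- function(table) {
  per_asv <- table$members |>
    dplyr::filter(!is.na(.data$species_key)) |>
    dplyr::group_by(.data$asv_id) |>
    dplyr::summarise(multi = dplyr::n_distinct(.data$species_key) >= 2,
                     .groups = "drop")
  sum(per_asv$multi) / nrow(table$asvs)
}

# One replicate: extract the region from the subset, dereplicate, compute
# neighbor pairs once, and cluster at every grid threshold.
replicate_stats <- function(subset, region, cfg, ref, replicate_seed) {
  span <- map_reference_coordinates(ref, region$ref_start, region$ref_end)
  ex <- extract_region(subset$copies$aligned_seq, span, cfg$boundary_policy)
  sp <- subset$genomes$species_key[match(subset$copies$accession,
                                         subset$genomes$accession)]
  tbl <- tibble::tibble(accession = subset$copies$accession,
                        species_key = sp,
                        sequence = ex$region_seq,
                        aligned_region = ex$aligned_region)[!ex$dropped, ]
  table <- dereplicate(tbl, region$name)
  nbrs <- neighbor_pairs(table$asvs$aligned_rep, cfg$d_max, cfg$gap_policy)
  cluster_one <- function(t) {
    if (cfg$clusterer == "complete") complete_linkage_partition(nbrs, t)
    else opticlust_partition(nbrs, t, seed = replicate_seed,
                             restarts = cfg$restarts)
  }
  copy_class <- table$members |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(copy_class = sum(.data$count), .groups = "drop")
  intact <- purrr::map_dfr(cfg$thresholds, function(t) {
    part <- cluster_one(t)
    genomes_intact(table, part) |>
      dplyr::left_join(copy_class, by = "accession") |>
      dplyr::group_by(.data$copy_class) |>
      dplyr::summarise(fraction_intact = mean(.data$intact),
                       n_species = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(threshold = t, fraction_multi =
                      multi_species_fraction(table, part))
  })
  lump <- intact |>
    dplyr::distinct(.data$threshold, .data$fraction_multi) |>
    dplyr::mutate(asv_fraction_multi = asv_multi_fraction(table))
  list(intact = dplyr::select(intact, -"fraction_multi"),
       lump = lump, n_asvs = nrow(table$asvs))
}

collapse_from_fractions <- function(thresholds, fractions, confidence) {
  ok <- fractions >= confidence
  if (!any(ok)) NA_real_ else thresholds[which(ok)[1]]
}

#' Run the full split/lump randomization analysis
#'
#' For each region and each randomization replicate: sample one genome per
#' species, trim the subset's copies to the region, dereplicate into ASVs,
#' cluster the pooled ASV set at every grid threshold, and record per
#' copy-number class the fraction of genomes whose ASVs fall in one OTU,
#' plus the fraction of OTUs (and ASVs) containing multiple species.
#'
#' @param catalog an `rrn_catalog`.
#' @param regions region table (rows with `name`, `ref_start`, `ref_end`).
#' @param cfg an [stat_config()].
#' @param ref_id reference record id for coordinate mapping; `NULL` uses
#'   the first copy (exact for columnar alignments).
#' @return list of tidy tibbles: `intact_curves`, `collapse`,
#'   `collapse_summary`, `lump_curves`, `lump_summary`, `asv_counts`.
#' @export
run_split_lump <- function(catalog, regions, cfg = stat_config(),
                           ref_id = NULL) {
  ref <- find_reference(catalog, ref_id)
  res <- purrr::map_dfr(seq_len(nrow(regions)), function(ri) {
    region <- regions[ri, ]
    purrr::map_dfr(seq_len(cfg$n_randomizations), function(r) {
      seed_r <- derive_seed(cfg$master_seed, r)
      subset <- sample_one_genome_per_species(catalog, seed_r)
      st <- replicate_stats(subset, region, cfg, ref, seed_r)
      dplyr::bind_rows(
        st$intact |> dplyr::mutate(kind = "intact"),
        st$lump |> dplyr::mutate(kind = "lump", copy_class = NA_integer_,
                                 n_species = NA_integer_)
      ) |>
        dplyr::mutate(region = region$name, replicate = r,
                      n_asvs = st$n_asvs)
    })
  })
  intact_curves <- res |>
    dplyr::filter(.data$kind == "intact") |>
    dplyr::select("region", "copy_class", "threshold", "replicate",
                  "fraction_intact", "n_species") |>
    dplyr::arrange(.data$region, .data$copy_class, .data$threshold,
                   .data$replicate)
  collapse <- intact_curves |>
    dplyr::group_by(.data$region, .data$copy_class, .data$replicate) |>
    dplyr::summarise(
      n_species = .data$n_species[1],
      collapse_threshold = collapse_from_fractions(
        .data$threshold, .data$fraction_intact, cfg$confidence),
      .groups = "drop") |>
    dplyr::filter(.data$n_species > cfg$min_species_per_copy_class)
  collapse_summary <- collapse |>
    dplyr::group_by(.data$region, .data$copy_class) |>
    dplyr::summarise(
      median_collapse_threshold = median_or_none(.data$collapse_threshold),
      iqr = iqr_linear(.data$collapse_threshold),
      n_replicates = dplyr::n(), .groups = "drop")
  lump_curves <- res |>
    dplyr::filter(.data$kind == "lump") |>
    dplyr::select("region", "threshold", "replicate", "fraction_multi",
                  "asv_fraction_multi", "n_asvs") |>
    dplyr::arrange(.data$region, .data$threshold, .data$replicate)
  lump_summary <- lump_curves |>
    dplyr::group_by(.data$region, .data$threshold) |>
    dplyr::summarise(
      median_fraction_multi = stats::median(.data$fraction_multi),
      iqr_fraction_multi = iqr_linear(.data$fraction_multi),
      median_asv_fraction_multi = stats::median(.data$asv_fraction_multi),
      iqr_asv_fraction_multi = iqr_linear(.data$asv_fraction_multi),
      .groups = "drop")
  asv_counts <- res |>
    dplyr::distinct(.data$region, .data$replicate, .data$n_asvs)
  list(intact_curves = intact_curves, collapse = collapse,
       collapse_summary = collapse_summary, lump_curves = lump_curves,
       lump_summary = lump_summary, asv_counts = asv_counts)
}

#' Genome-splitting threshold curves
#'
#' The Fig-1-style quantity: per copy-number class, the fraction of genomes
#' whose ASVs land in a single OTU at each threshold, and the smallest grid
#' threshold at which that fraction reaches the confidence level (`NA` when
#' no grid value does).
#'
#' @inheritParams run_split_lump
#' @return list with `intact_curves`, `collapse`, `collapse_summary`.
#' @export
collapse_threshold_curve <- function(catalog, regions, cfg = stat_config(),
                                     ref_id = NULL) {
  run_split_lump(catalog, regions, cfg, ref_id)[
    c("intact_curves", "collapse", "collapse_summary")]
}

#' Multi-species ASV/OTU fractions
#'
#' The Fig-2-style quantity: per threshold, the fraction of OTUs containing
#' sequences from at least two species, together with the threshold-free
#' ASV-level fraction.
#'
#' @inheritParams run_split_lump
#' @return list with `lump_curves`, `lump_summary`.
#' @export
multispecies_fraction_curve <- function(catalog, regions,
                                        cfg = stat_config(), ref_id = NULL) {
  run_split_lump(catalog, regions, cfg, ref_id)[
    c("lump_curves", "lump_summary")]
}

# Median over replicates where "never collapsed on the grid" (NA) sits
# beyond the top of the grid; a non-finite median stays NA (reported NONE).
median_or_none <- function(x) {
  m <- stats::median(ifelse(is.na(x), Inf, x))
  if (!is.finite(m)) NA_real_ else m
}

iqr_linear <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7)))
}

#' Summarize per-replicate statistics across randomizations
#'
#' Median and interquartile range (linear-interpolation quantiles, type 7)
#' of a replicate-level statistic.
#'
#' @param values numeric vector, one value per randomization replicate.
#' @param name statistic label.
#' @return one-row tibble with `statistic`, `n`, `median`, `iqr`, `min`,
#'   `max`.
#' @export
summarize_randomizations <- function(values, name = "statistic") {
  tibble::tibble(statistic = name, n = length(values),
                 median = stats::median(values), iqr = iqr_linear(values),
                 min = min(values), max = max(values))
}
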