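# ASV dereplication and per-genome / per-species variant statistics.

#' Dereplicate region sequences into ASVs
#'
#' Exact string equality (after degapping, uppercasing and U->T
#' normalization upstream) defines ASV membership; sequences containing N
#' are compared literally.  ASV ids are dense integers assigned by first
#' occurrence in input order, so permuting the input permutes ids but not
#' the partition.
#'
#' @param region_tbl tibble with columns `sequence`, `accession`,
#'   `species_key`, and optionally `aligned_region` (used to keep one
#'   aligned exemplar per ASV for distance computation).
#' @param region_name label stored on the table.
#' @return an `rrn_asv_table`: list with `asvs` (asv_id, sequence,
#'   aligned_rep), `members` (asv_id, accession, species_key, count),
#'   `n_seqs`, `region_name`.
#' @export
dereplicate <- function(region_tbl, region_name = "") {
  if (nrow(region_tbl) == 0) {
    return(structure(list(
      asvs = tibble::tibble(asv_id = integer(), sequence = character(),
                            aligned_rep = character()),
      members = tibble::tibble(asv_id = integer(), accession = character(),
                               species_key = character(), count = integer()),
      n_seqs = 0L, region_name = region_name), class = "rrn_asv_table"))
  }
  seqs <- region_tbl$sequence
  uniq <- unique(seqs)
  asv_id <- match(seqs, uniq)
  first <- match(uniq, seqs)
  aligned_rep <- if ("aligned_region" %in% names(region_tbl))
    region_tbl$aligned_region[first] else uniq
  members <- tibble::tibble(asv_id = asv_id,
                            accession = region_tbl$accession,
                            species_key = region_tbl$species_key) |>
    dplyr::count(.data$asv_id, .data$accession, .data$species_key,
                 name = "count") |>
    dplyr::arrange(.data$asv_id, .data$accession)
  structure(list(
    asvs = tibble::tibble(asv_id = seq_along(uniq), sequence = uniq,
                          aligned_rep = aligned_rep),
    members = members, n_seqs = length(seqs), region_name = region_name),
    class = "rrn_asv_table")
}

#' @export
print.rrn_asv_table <- function(x, ...) {
  cat("<rrn_asv_table> ", nrow(x$asvs), " ASVs from ", x$n_seqs,
      " sequences", if (nzchar(x$region_name)) paste0(" [", x$region_name, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Per-genome variant statistics
#'
#' For each genome with at least one surviving copy: the number of copies,
#' the number of distinct ASVs among them, and their ratio (the
#' "variants per copy" statistic).
#'
#' @param table an `rrn_asv_table`.
#' @return tibble with `accession`, `species_key`, `copy_number`, `n_asvs`,
#'   `variants_per_copy`.
#' @export
genome_variant_stats <- function(table) {
  table$members |>
    dplyr::group_by(.data$accession, .data$species_key) |>
    dplyr::summarise(copy_number = sum(.data$count),
                     n_asvs = dplyr::n_distinct(.data$asv_id),
                     .groups = "drop") |>
    dplyr::mutate(variants_per_copy = .data$n_asvs / .data$copy_number)
}

#' Headline variants-per-copy averages, three ways
#'
#' The average number of distinct variants per gene copy can be summarised
#' as (i) the unweighted mean over genomes of each genome's ratio (the
#' default headline), (ii) the mean over species of the per-species mean
#' ratio, or (iii) the pooled ratio (total ASV count over total copy
#' count).  All three are reported side by side.
#'
#' @param stats tibble from [genome_variant_stats()].
#' @return one-row tibble with `genome_mean`, `species_mean`, `pooled`.
#' @export
variants_per_copy_summary <- function(stats) {
  by_species <- stats |>
    dplyr::filter(!is.na(.data$species_key)) |>
    dplyr::group_by(.data$species_key) |>
    dplyr::summarise(m = mean(.data$variants_per_copy), .groups = "drop")
  tibble::tibble(genome_mean = mean(stats$variants_per_copy),
                 species_mean = mean(by_species$m),
                 pooled = sum(stats$n_asvs) / sum(stats$copy_number))
}

#' Species-level variant accumulation
#'
#' Pools distinct variants across all genomes of each species and relates
#' them to the species' typical copy number: the ratio of total distinct
#' variants to the median (or mean) copies per genome grows with the number
#' of genomes sampled.
#'
#' @param table an `rrn_asv_table`.
#' @param copy_summary `"median"` (default, robust to assembly outliers) or
#'   `"mean"`.
#' @return tibble with `species_key`, `n_genomes`, `total_distinct_variants`,
#'   `copies_per_genome`, `variants_per_operon_ratio`.
#' @export
species_accumulation <- function(table, copy_summary = c("median", "mean")) {
  copy_summary <- match.arg(copy_summary)
  fun <- if (copy_summary == "median") stats::median else mean
  per_genome <- table$members |>
    dplyr::group_by(.data$species_key, .data$accession) |>
    dplyr::summarise(copy_number = sum(.data$count), .groups = "drop")
  table$members |>
    dplyr::filter(!is.na(.data$species_key)) |>
    dplyr::group_by(.data$species_key) |>
    dplyr::summarise(n_genomes = dplyr::n_distinct(.data$accession),
                     total_distinct_variants = dplyr::n_distinct(.data$asv_id),
                     .groups = "drop") |>
    dplyr::left_join(per_genome |>
                       dplyr::group_by(.data$species_key) |>
                       dplyr::summarise(copies_per_genome = fun(.data$copy_number),
                                        .groups = "drop"),
                     by = "species_key") |>
    dplyr::mutate(variants_per_operon_ratio =
                    .data$total_distinct_variants / .data$copies_per_genome)
}

#' Partition of sequences induced by an ASV table
#'
#' @param table an `rrn_asv_table`.
#' @return integer vector: for input sequence order, which ASV each unique
#'   sequence belongs to (identity on asv ids).
#' @export
asv_partition <- function(table) {
  stats::setNames(table$asvs$asv_id, table$asvs$sequence)
}
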