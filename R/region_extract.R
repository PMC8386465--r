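# Hypervariable-region extraction: map E. coli reference coordinates to
# alignment columns, trim every aligned copy to the region, degap.

#' Standard 16S regions (E. coli K-12 MG1655 coordinates)
#'
#' The shipped table defines the commonly amplified fragments by 1-based
#' inclusive positions on the unaligned E. coli K-12 MG1655 (NC_000913) 16S
#' gene: full-length V1-V9 (28-1491), V3-V4 (358-786), V4 (534-786) and
#' V4-V5 (534-908).
#'
#' @return tibble with columns `name`, `ref_start`, `ref_end`.
#' @export
default_regions <- function() {
  path <- system.file("extdata", "regions.tsv", package = "rrnsplit")
  read_region_table(path)
}

#' Read a region definition table
#' @param path TSV with columns `name`, `ref_start`, `ref_end`.
#' @return tibble of validated region specs.
#' @export
read_region_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("name", "ref_start", "ref_end") %in% names(tab)),
            all(tab$ref_start >= 1), all(tab$ref_start <= tab$ref_end))
  tibble::as_tibble(tab[, c("name", "ref_start", "ref_end")])
}

#' Map reference coordinates to alignment columns
#'
#' Finds the alignment columns holding 1-based unaligned positions
#' `ref_start` and `ref_end` of the (gapped) reference sequence.
#'
#' @param ref_aligned the aligned reference sequence (gaps as `-` or `.`).
#' @param ref_start,ref_end 1-based inclusive positions on the unaligned
#'   reference.
#' @return list with `col_start`, `col_end` (1-based alignment columns).
#' @export
map_reference_coordinates <- function(ref_aligned, ref_start, ref_end) {
  stopifnot(ref_start >= 1, ref_start <= ref_end)
  chars <- strsplit(toupper(ref_aligned), "")[[1]]
  is_base <- !chars %in% c("-", ".")
  n_bases <- sum(is_base)
  if (ref_end > n_bases)
    stop("coordinate error: ref_end (", ref_end,
         ") beyond reference length (", n_bases, ")", call. = FALSE)
  pos <- cumsum(is_base)
  list(col_start = which(is_base & pos == ref_start)[1],
       col_end = which(is_base & pos == ref_end)[1])
}

#' Trim aligned sequences to an alignment column span
#'
#' Returns the degapped subsequence over `[col_start, col_end]` for each
#' input.  Under the default `"drop"` policy a sequence with a gap at either
#' boundary column is dropped (`NA`): a primer landing there could not
#' amplify it.  `"keep"` trims regardless.  Sequences whose trimmed region is
#' entirely gaps are always dropped.
#'
#' @param aligned character vector of aligned sequences (equal widths).
#' @param span list with `col_start`, `col_end` from
#'   [map_reference_coordinates()].
#' @param policy `"drop"` (default) or `"keep"`.
#' @return tibble with `region_seq` (degapped, `NA` when dropped),
#'   `aligned_region` (the raw column slice) and `dropped` + `drop_reason`.
#' @export
extract_region <- function(aligned, span, policy = c("drop", "keep")) {
  policy <- match.arg(policy)
  widths <- nchar(aligned)
  if (length(aligned) > 0 && (length(unique(widths)) != 1 ||
                              widths[1] < span$col_end))
    stop("alignment error: sequences do not share the alignment width ",
         "covering the requested span", call. = FALSE)
  slice <- substr(aligned, span$col_start, span$col_end)
  first <- substr(slice, 1, 1)
  last <- substr(slice, nchar(slice), nchar(slice))
  gap <- c("-", ".")
  boundary_gap <- first %in% gap | last %in% gap
  region <- degap_seq(slice)
  empty <- !nzchar(region)
  dropped <- empty | (policy == "drop" & boundary_gap)
  reason <- dplyr::case_when(
    empty ~ "all-gap region",
    policy == "drop" & boundary_gap ~ "gap at region boundary",
    TRUE ~ NA_character_
  )
  tibble::tibble(region_seq = ifelse(dropped, NA_character_, region),
                 aligned_region = slice, dropped = dropped,
                 drop_reason = reason)
}

# Locate the aligned reference in a catalog.  ref_id = NULL falls back to the
# first copy, which is exact for columnar (indel-free) alignments such as the
# synthetic communities.
find_reference <- function(catalog, ref_id = "NC_000913") {
  cp <- catalog$copies
  if (is.null(ref_id)) return(cp$aligned_seq[1])
  hit <- grepl(ref_id, cp$copy_id, fixed = TRUE) |
    cp$accession == ref_id
  if (!any(hit))
    stop("reference '", ref_id, "' not found in catalog", call. = FALSE)
  cp$aligned_seq[which(hit)[1]]
}

#' Extract a region from every copy of a catalog
#'
#' Maps the region's reference coordinates to columns using the named
#' reference sequence (or the first copy when `ref_id` is `NULL`) and trims
#' every copy, reporting drops.
#'
#' @param catalog an `rrn_catalog`.
#' @param region one row of a region table (list/row with `name`,
#'   `ref_start`, `ref_end`).
#' @param ref_id identifier of the reference record (matched against copy
#'   ids and accessions); `NULL` uses the first copy.
#' @param policy boundary policy, see [extract_region()].
#' @return tibble with one row per surviving copy: `copy_id`, `accession`,
#'   `species_key`, `sequence` (degapped region), `aligned_region`; the
#'   `"drops"` attribute holds the drop report.
#' @export
extract_region_catalog <- function(catalog, region, ref_id = "NC_000913",
                                   policy = c("drop", "keep")) {
  policy <- match.arg(policy)
  ref <- find_reference(catalog, ref_id)
  span <- map_reference_coordinates(ref, region$ref_start, region$ref_end)
  ex <- extract_region(catalog$copies$aligned_seq, span, policy)
  sp <- catalog$genomes$species_key[match(catalog$copies$accession,
                                          catalog$genomes$accession)]
  out <- tibble::tibble(copy_id = catalog$copies$copy_id,
                        accession = catalog$copies$accession,
                        species_key = sp,
                        sequence = ex$region_seq,
                        aligned_region = ex$aligned_region)
  drops <- out[ex$dropped, c("copy_id", "accession")]
  drops$reason <- ex$drop_reason[ex$dropped]
  out <- out[!ex$dropped, , drop = FALSE]
  attr(out, "drops") <- drops
  attr(out, "region_name") <- region$name
  out
}
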