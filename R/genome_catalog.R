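# Genome catalog: rrnDB-style sequences + metadata -> validated catalog of
# genomes, each with one species label and its set of 16S rRNA gene copies.

GAP_CHARS_RE <- "[.-]"

degap_seq <- function(x) chartr("U", "T", gsub(GAP_CHARS_RE, "", toupper(x)))

#' Derive a species key from an organism name
#'
#' Strain-level designations are discarded: the key is the first two
#' whitespace-separated tokens of the organism name after stripping square
#' brackets ("Candidatus" is kept as a prefix, making three tokens).
#' Names that cannot be resolved to a binomial — a single token, an "sp."
#' epithet, or an "unclassified" genus — yield `NA`; such genomes are kept in
#' the catalog but excluded from species-controlled resampling.
#'
#' @param organism character vector of organism names.
#' @return character vector of species keys (`NA` where unresolvable).
#' @examples
#' species_key_from_organism("Escherichia coli K-12")
#' @export
species_key_from_organism <- function(organism) {
  x <- stringr::str_squish(gsub("[][]", "", organism))
  toks <- strsplit(x, " +")
  vapply(toks, function(tk) {
    if (length(tk) == 0 || !nzchar(tk[1])) return(NA_character_)
    n_need <- if (identical(tolower(tk[1]), "candidatus")) 3L else 2L
    if (length(tk) < n_need) return(NA_character_)
    epithet <- tolower(tk[n_need])
    if (epithet %in% c("sp.", "sp") || tolower(tk[1]) == "unclassified")
      return(NA_character_)
    paste(tk[seq_len(n_need)], collapse = " ")
  }, character(1))
}

#' Parse a genome metadata table
#'
#' Reads a delimited table with one row per genome and returns the accession
#' and raw organism/taxonomy string for each, in file order.
#'
#' @param path path to a TSV (default) or CSV file with a header row.
#' @param accession_col,taxonomy_col column names holding the genome
#'   accession and the organism name.
#' @param delim field delimiter; guessed from the file extension when `NULL`.
#' @return tibble with columns `accession`, `organism`.
#' @export
parse_metadata <- function(path, accession_col = "accession",
                           taxonomy_col = "organism", delim = NULL) {
  if (is.null(delim))
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  for (col in c(accession_col, taxonomy_col)) {
    if (!col %in% names(tab))
      stop("metadata configuration error: required column '", col,
           "' not found in ", path, call. = FALSE)
  }
  acc <- as.character(tab[[accession_col]])
  dup <- acc[duplicated(acc)]
  if (length(dup) > 0)
    stop("metadata validation error: duplicate accession(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  tibble::tibble(accession = acc, organism = as.character(tab[[taxonomy_col]]))
}

#' Parse aligned or unaligned 16S sequences from FASTA
#'
#' One record per gene copy.  The genome accession is extracted from the
#' record header with a configurable regular expression whose first capture
#' group is the accession; the default takes everything before the first
#' `|` or whitespace.  `U` is normalized to `T` in the degapped sequence and
#' both `.` and `-` are treated as gap characters.
#'
#' @param path FASTA file path.
#' @param accession_pattern regex with one capture group for the accession.
#' @return tibble with columns `copy_id` (the full header), `accession`,
#'   `aligned_seq` (uppercased, gaps retained), `unaligned_seq`.
#' @export
parse_sequences <- function(path, accession_pattern = "^([^|[:space:]]+)") {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  aligned <- toupper(as.character(set))
  acc <- stringr::str_match(headers, accession_pattern)[, 2]
  if (anyNA(acc)) {
    bad <- headers[which(is.na(acc))[1]]
    stop("FASTA parse error: header does not match accession pattern: '",
         bad, "'", call. = FALSE)
  }
  unaligned <- degap_seq(aligned)
  if (any(!nzchar(unaligned))) {
    bad <- headers[which(!nzchar(unaligned))[1]]
    stop("FASTA validation error: empty sequence for record '", bad, "'",
         call. = FALSE)
  }
  tibble::tibble(copy_id = headers, accession = acc,
                 aligned_seq = unname(aligned), unaligned_seq = unname(unaligned))
}

new_catalog <- function(genomes, copies) {
  structure(list(genomes = genomes, copies = copies), class = "rrn_catalog")
}

#' Build a genome catalog from sequences and metadata
#'
#' Copies are grouped by accession and joined to the metadata; genomes whose
#' accession lacks a metadata row are dropped with a reported count (orphans).
#' Each genome gets a single species key via [species_key_from_organism()].
#'
#' @param seqs tibble from [parse_sequences()].
#' @param meta tibble from [parse_metadata()].
#' @param quiet suppress the orphan report message.
#' @return an `rrn_catalog`: list with `genomes` (accession, organism,
#'   species_key, species_resolved, copy_number) and `copies` tibbles.
#' @export
build_catalog <- function(seqs, meta, quiet = FALSE) {
  orphan <- !seqs$accession %in% meta$accession
  if (any(orphan) && !quiet)
    message("build_catalog: dropping ", sum(orphan),
            " orphan sequence(s) with no metadata row")
  copies <- seqs[!orphan, , drop = FALSE]
  genomes <- meta |>
    dplyr::filter(.data$accession %in% copies$accession) |>
    dplyr::mutate(species_key = species_key_from_organism(.data$organism),
                  species_resolved = !is.na(.data$species_key)) |>
    dplyr::left_join(dplyr::count(copies, .data$accession, name = "copy_number"),
                     by = "accession")
  cat <- new_catalog(genomes, copies)
  validate_catalog(cat)
  cat
}

validate_catalog <- function(catalog) {
  g <- catalog$genomes
  stopifnot(!anyDuplicated(g$accession), all(g$copy_number >= 1),
            all(catalog$copies$accession %in% g$accession))
  invisible(catalog)
}

#' @export
print.rrn_catalog <- function(x, ...) {
  cat("<rrn_catalog> ", nrow(x$genomes), " genomes, ",
      dplyr::n_distinct(x$genomes$species_key[x$genomes$species_resolved]),
      " resolved species, ", nrow(x$copies), " 16S copies\n", sep = "")
  invisible(x)
}

#' Number of 16S copies per genome
#' @param catalog an `rrn_catalog`.
#' @return named integer vector (accession -> copy number).
#' @export
copy_numbers <- function(catalog) {
  stats::setNames(as.integer(catalog$genomes$copy_number),
                  catalog$genomes$accession)
}

#' Restrict a catalog to a set of accessions
#' @param catalog an `rrn_catalog`.
#' @param accessions accessions to keep.
#' @return the subset `rrn_catalog`.
#' @export
subset_catalog <- function(catalog, accessions) {
  new_catalog(
    genomes = dplyr::filter(catalog$genomes, .data$accession %in% accessions),
    copies = dplyr::filter(catalog$copies, .data$accession %in% accessions)
  )
}

#' Write a catalog as aligned FASTA + metadata TSV
#'
#' Headers are the stored `copy_id` when the accession is recoverable from it
#' with the default pattern, otherwise `accession|copy_id`, so a written
#' catalog re-parses to an identical one.
#'
#' @param catalog an `rrn_catalog`.
#' @param fasta_path,meta_path output paths.
#' @export
write_catalog <- function(catalog, fasta_path, meta_path) {
  cp <- catalog$copies
  recovered <- stringr::str_match(cp$copy_id, "^([^|[:space:]]+)")[, 2]
  headers <- ifelse(recovered == cp$accession, cp$copy_id,
                    paste0(cp$accession, "|", cp$copy_id))
  set <- Biostrings::BStringSet(stats::setNames(cp$aligned_seq, headers))
  Biostrings::writeXStringSet(set, fasta_path)
  readr::write_tsv(catalog$genomes[, c("accession", "organism")], meta_path,
                   progress = FALSE)
  invisible(c(fasta = fasta_path, metadata = meta_path))
}

#' Read a catalog from FASTA + metadata TSV
#' @inheritParams write_catalog
#' @inheritParams parse_sequences
#' @inheritParams parse_metadata
#' @return an `rrn_catalog`.
#' @export
read_catalog <- function(fasta_path, meta_path,
                         accession_pattern = "^([^|[:space:]]+)",
                         accession_col = "accession",
                         taxonomy_col = "organism", quiet = FALSE) {
  build_catalog(parse_sequences(fasta_path, accession_pattern),
                parse_metadata(meta_path, accession_col, taxonomy_col),
                quiet = quiet)
}
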