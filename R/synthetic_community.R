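# Seeded generator of synthetic multi-copy-genome communities: species
# templates a controlled number of substitutions apart, genomes with 1-19
# 16S copies, and exact within-genome substitution counts, emitted in the
# same FASTA/TSV dialects the catalog reader consumes, with ground truth.

#' Distribution specifications for the community generator
#'
#' `dist_constant(k)` gives every unit the value `k`;
#' `dist_geometric(mean, min, max)` draws `min + Geometric(p)` truncated at
#' `max`, with `p = 1/(mean - min + 1)`; `dist_explicit(values)` assigns
#' the listed values in order (recycled).
#'
#' @param k,mean,min,max,values distribution parameters.
#' @return a `dist_spec` list.
#' @export
dist_constant <- function(k) {
  structure(list(kind = "constant", value = as.integer(k)),
            class = "dist_spec")
}

#' @rdname dist_constant
#' @export
dist_geometric <- function(mean, min = 1L, max = 19L) {
  stopifnot(mean >= min)
  structure(list(kind = "geometric", mean = mean, min = as.integer(min),
                 max = as.integer(max)), class = "dist_spec")
}

#' @rdname dist_constant
#' @export
dist_explicit <- function(values) {
  structure(list(kind = "explicit", values = as.integer(values)),
            class = "dist_spec")
}

dist_max <- function(spec) {
  switch(spec$kind, constant = spec$value, geometric = spec$max,
         explicit = max(spec$values))
}

draw_dist <- function(spec, n) {
  switch(spec$kind,
    constant = rep(spec$value, n),
    geometric = {
      p <- 1 / (spec$mean - spec$min + 1)
      pmin(spec$min + stats::rgeom(n, p), spec$max)
    },
    explicit = rep_len(spec$values, n),
    stop("unknown dist_spec kind: ", spec$kind)
  )
}

#' Configuration for the synthetic community generator
#'
#' Defaults emulate the structure of a curated genome database at desk
#' scale: 50 species, a skewed number of genomes per species (geometric,
#' mean 3.4, matching the genome-to-species ratio of a large curated
#' collection), 1-19 gene copies per genome (geometric, mean 4), 1500-bp
#' genes, per-copy substitution counts drawn geometrically with mean 1
#' (so roughly half of the non-template copies are identical to the genome
#' template, as intragenomic 16S copies typically are), 2 substitutions
#' between genomes of a species, and species templates at least 75
#' substitutions (5%) apart.
#'
#' @param n_species number of species.
#' @param genomes_per_species,copies_per_genome `dist_spec`s (or integers,
#'   taken as constants).
#' @param seq_length gene length in bp.
#' @param intragenomic_subs substitutions distinguishing each non-template
#'   copy from the genome template; a scalar, a vector over copies 2..k
#'   (recycled), or a `dist_spec` drawn per copy.
#' @param intergenomic_subs substitutions distinguishing each genome's
#'   template from its species template.
#' @param interspecies_subs minimum substitutions between species templates
#'   (rejection-sampled).
#' @param well_separated when `TRUE`, require `interspecies_subs` to exceed
#'   twice the largest within-species divergence
#'   (`intergenomic_subs + max(intragenomic_subs)`), guaranteeing no
#'   accidental cross-species identity.
#' @param indel_columns number of extra alignment columns in which each
#'   species carries either an inserted base or a gap (exercises the gap
#'   policies; 0 keeps the alignment strictly columnar).
#' @param n_rate per-position probability of masking a base as N.
#' @param seed integer seed; generation is byte-deterministic per seed.
#' @return an `rrn_synth_config` list.
#' @export
synth_config <- function(n_species = 50L,
                         genomes_per_species = dist_geometric(3.4, 1L, 30L),
                         copies_per_genome = dist_geometric(4, 1L, 19L),
                         seq_length = 1500L,
                         intragenomic_subs = dist_geometric(1, 0L, 30L),
                         intergenomic_subs = 2L,
                         interspecies_subs = 75L,
                         well_separated = TRUE,
                         indel_columns = 0L,
                         n_rate = 0,
                         seed = 1L) {
  if (is.numeric(genomes_per_species))
    genomes_per_species <- dist_constant(genomes_per_species)
  if (is.numeric(copies_per_genome))
    copies_per_genome <- dist_constant(copies_per_genome)
  max_intra <- if (inherits(intragenomic_subs, "dist_spec"))
    dist_max(intragenomic_subs) else max(intragenomic_subs)
  stopifnot(n_species >= 1, seq_length >= 1, max_intra >= 0,
            intergenomic_subs >= 0, interspecies_subs >= 0)
  if (well_separated &&
      interspecies_subs <= 2 * (max_intra + intergenomic_subs))
    stop("invalid config: with well_separated = TRUE, interspecies_subs ",
         "must exceed twice the within-species divergence ",
         "(intergenomic_subs + max intragenomic_subs)", call. = FALSE)
  structure(list(n_species = as.integer(n_species),
                 genomes_per_species = genomes_per_species,
                 copies_per_genome = copies_per_genome,
                 seq_length = as.integer(seq_length),
                 intragenomic_subs = if (inherits(intragenomic_subs, "dist_spec"))
                   intragenomic_subs else as.integer(intragenomic_subs),
                 intergenomic_subs = as.integer(intergenomic_subs),
                 interspecies_subs = as.integer(interspecies_subs),
                 well_separated = isTRUE(well_separated),
                 indel_columns = as.integer(indel_columns),
                 n_rate = n_rate, seed = as.integer(seed)),
            class = "rrn_synth_config")
}

BASES <- c("A", "C", "G", "T")

mutate_positions <- function(chars, positions) {
  for (p in positions) {
    chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
  }
  chars
}

hamming_chars <- function(a, b) sum(a != b)

#' Generate a synthetic multi-copy-genome community
#'
#' Species templates are drawn by mutating a common ancestor and
#' rejection-sampled to be mutually at least `interspecies_subs` apart
#' (bounded retries).  Each genome's template adds `intergenomic_subs`
#' substitutions; copies 2..k of a genome each add their configured
#' substitution count at positions never reused within the genome, so
#' substitution counts map exactly to Hamming distances.  Ground truth is
#' recomputed from the emitted sequences.
#'
#' @param cfg an [synth_config()].
#' @return an `rrn_community`: list with `copies` and `meta` tibbles (the
#'   catalog dialects), `ground_truth` (list of `genomes`, `species_pairs`,
#'   `shared_asvs` tibbles) and `cfg`.
#' @export
generate_community <- function(cfg = synth_config()) {
  with_seed_local(cfg$seed, {
    L <- cfg$seq_length
    ancestor <- sample(BASES, L, replace = TRUE)
    templates <- vector("list", cfg$n_species)
    for (s in seq_len(cfg$n_species)) {
      ok <- FALSE
      for (try in seq_len(100L)) {
        cand <- mutate_positions(ancestor,
                                 sample.int(L, cfg$interspecies_subs))
        if (s == 1 || all(vapply(templates[seq_len(s - 1)], hamming_chars,
                                 0, b = cand) >= cfg$interspecies_subs)) {
          templates[[s]] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("generation error: could not place ", cfg$n_species,
             " species templates at least ", cfg$interspecies_subs,
             " substitutions apart after 100 attempts", call. = FALSE)
    }
    n_genomes_per <- draw_dist(cfg$genomes_per_species, cfg$n_species)
    copy_counts <- draw_dist(cfg$copies_per_genome, sum(n_genomes_per))
    rows <- list()
    meta <- list()
    gi <- 0L
    for (s in seq_len(cfg$n_species)) {
      species <- sprintf("Synthetica species%03d", s)
      for (g in seq_len(n_genomes_per[s])) {
        gi <- gi + 1L
        acc <- sprintf("SYN%05d", gi)
        organism <- sprintf("%s strain%03d", species, g)
        k <- copy_counts[gi]
        used <- integer(0)
        gpos <- sample.int(L, cfg$intergenomic_subs)
        gtemplate <- mutate_positions(templates[[s]], gpos)
        used <- gpos
        subs <- if (k <= 1) integer(0)
        else if (inherits(cfg$intragenomic_subs, "dist_spec"))
          draw_dist(cfg$intragenomic_subs, k - 1)
        else rep_len(cfg$intragenomic_subs, k - 1)
        copies <- vector("list", k)
        copies[[1]] <- gtemplate
        for (cj in seq_len(k - 1)) {
          avail <- setdiff(seq_len(L), used)
          pos <- avail[sample.int(length(avail), subs[cj])]
          used <- c(used, pos)
          copies[[cj + 1]] <- mutate_positions(gtemplate, pos)
        }
        if (cfg$n_rate > 0) {
          copies <- lapply(copies, function(ch) {
            mask <- stats::runif(L) < cfg$n_rate
            ch[mask] <- "N"
            ch
          })
        }
        seqs <- vapply(copies, paste, "", collapse = "")
        rows[[gi]] <- tibble::tibble(
          copy_id = sprintf("%s|c%02d", acc, seq_len(k)),
          accession = acc, species_key = species, organism = organism,
          aligned_seq = seqs, unaligned_seq = seqs)
        meta[[gi]] <- tibble::tibble(accession = acc, organism = organism)
      }
    }
    copies <- dplyr::bind_rows(rows)
    meta <- dplyr::bind_rows(meta)
    if (cfg$indel_columns > 0) {
      copies <- add_indel_columns(copies, cfg$indel_columns)
    }
    community <- structure(list(copies = copies, meta = meta,
                                ground_truth = NULL, cfg = cfg),
                           class = "rrn_community")
    community$ground_truth <- compute_ground_truth(community)
    community
  })
}

# Insert extra alignment columns; within a species all copies share the
# insertion pattern (a base for that species or a gap), so within-genome
# ground-truth distances are unchanged under every gap policy.
add_indel_columns <- function(copies, n_cols) {
  L <- nchar(copies$aligned_seq[1])
  at <- sort(sample.int(L + 1L, n_cols, replace = TRUE))
  species <- unique(copies$species_key)
  ins <- matrix("-", length(species), n_cols,
                dimnames = list(species, NULL))
  for (k in seq_len(n_cols)) {
    has <- stats::runif(length(species)) < 0.5
    ins[has, k] <- sample(BASES, sum(has), replace = TRUE)
  }
  new_aligned <- vapply(seq_len(nrow(copies)), function(r) {
    ch <- strsplit(copies$aligned_seq[r], "")[[1]]
    pieces <- character(0)
    prev <- 1L
    for (k in seq_len(n_cols)) {
      pieces <- c(pieces,
                  if (at[k] > prev) paste(ch[prev:(at[k] - 1L)], collapse = "") else "",
                  ins[copies$species_key[r], k])
      prev <- at[k]
    }
    pieces <- c(pieces, if (prev <= L) paste(ch[prev:L], collapse = "") else "")
    paste(pieces, collapse = "")
  }, "")
  copies$aligned_seq <- new_aligned
  copies$unaligned_seq <- degap_seq(new_aligned)
  copies
}

# Ground truth recomputed from the emitted sequences: distinct-copy counts,
# max within-genome distance, and minimum between-species distances, all on
# the emitted alignment with every gap-vs-base column a difference.
compute_ground_truth <- function(community, shared = NULL) {
  pol <- gap_policy("each-gap-a-difference", count_terminal_gaps = TRUE)
  genomes <- community$copies |>
    dplyr::group_by(.data$accession, .data$species_key) |>
    dplyr::summarise(copy_number = dplyr::n(),
                     true_n_asvs = dplyr::n_distinct(.data$unaligned_seq),
                     max_intragenomic_distance = {
                       s <- .data$aligned_seq
                       if (length(s) < 2) 0 else max(dist_matrix(s, pol))
                     }, .groups = "drop")
  sp <- unique(community$copies$species_key)
  species_pairs <- NULL
  if (length(sp) >= 2) {
    m <- dist_matrix(community$copies$aligned_seq, pol)
    idx <- split(seq_len(nrow(community$copies)),
                 community$copies$species_key)[sp]
    cmb <- utils::combn(sp, 2)
    mins <- vapply(seq_len(ncol(cmb)), function(k) {
      min(m[idx[[cmb[1, k]]], idx[[cmb[2, k]]]])
    }, 0)
    species_pairs <- tibble::tibble(species_a = cmb[1, ], species_b = cmb[2, ],
                                    min_distance = mins)
  }
  if (is.null(shared))
    shared <- tibble::tibble(sequence = character(), species_a = character(),
                             species_b = character(), copy_id = character())
  list(genomes = genomes, species_pairs = species_pairs, shared_asvs = shared)
}

#' Force two species to share one identical gene copy
#'
#' Overwrites one (seeded-random) copy of one genome of `species_b` with an
#' exact copy of a sequence from `species_a`, emulating a gene version
#' found in genomes of different species; the shared ASV is recorded in the
#' ground truth.
#'
#' @param community an `rrn_community`.
#' @param species_a,species_b species keys present in the community.
#' @param seed integer seed for the choices.
#' @return the modified `rrn_community`.
#' @export
inject_shared_variant <- function(community, species_a, species_b, seed = 1L) {
  cp <- community$copies
  ia <- which(cp$species_key == species_a)
  ib <- which(cp$species_key == species_b)
  if (length(ia) == 0 || length(ib) == 0)
    stop("species not found in community: ",
         if (length(ia) == 0) species_a else species_b, call. = FALSE)
  with_seed_local(seed, {
    src <- ia[sample.int(length(ia), 1L)]
    dst <- ib[sample.int(length(ib), 1L)]
    cp$aligned_seq[dst] <- cp$aligned_seq[src]
    cp$unaligned_seq[dst] <- cp$unaligned_seq[src]
    community$copies <- cp
    shared <- dplyr::bind_rows(
      community$ground_truth$shared_asvs,
      tibble::tibble(sequence = cp$unaligned_seq[src],
                     species_a = species_a, species_b = species_b,
                     copy_id = cp$copy_id[dst]))
    community$ground_truth <- compute_ground_truth(community, shared)
    community
  })
}

#' @export
print.rrn_community <- function(x, ...) {
  cat("<rrn_community> ", dplyr::n_distinct(x$copies$species_key),
      " species, ", dplyr::n_distinct(x$copies$accession), " genomes, ",
      nrow(x$copies), " gene copies\n", sep = "")
  invisible(x)
}

#' Convert a community to a genome catalog
#' @param community an `rrn_community`.
#' @return an `rrn_catalog`.
#' @export
as_catalog <- function(community) {
  seqs <- community$copies[, c("copy_id", "accession", "aligned_seq",
                               "unaligned_seq")]
  build_catalog(seqs, community$meta, quiet = TRUE)
}

#' Write a community to disk
#'
#' Emits the aligned FASTA and metadata TSV the catalog reader consumes,
#' plus ground-truth tables and a key-value summary.
#'
#' @param community an `rrn_community`.
#' @param dir output directory (created if needed).
#' @return named vector of written paths.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "community.fasta")
  meta <- file.path(dir, "community_metadata.tsv")
  set <- Biostrings::BStringSet(stats::setNames(community$copies$aligned_seq,
                                                community$copies$copy_id))
  Biostrings::writeXStringSet(set, fasta)
  readr::write_tsv(community$meta, meta, progress = FALSE)
  gt_gen <- file.path(dir, "ground_truth_genomes.tsv")
  readr::write_tsv(community$ground_truth$genomes, gt_gen, progress = FALSE)
  gt_shared <- file.path(dir, "ground_truth_shared_asvs.tsv")
  readr::write_tsv(community$ground_truth$shared_asvs, gt_shared,
                   progress = FALSE)
  summary_path <- file.path(dir, "ground_truth_summary.txt")
  gt <- community$ground_truth
  writeLines(c(
    paste0("n_species\t", dplyr::n_distinct(community$copies$species_key)),
    paste0("n_genomes\t", dplyr::n_distinct(community$copies$accession)),
    paste0("n_copies\t", nrow(community$copies)),
    paste0("n_shared_asvs\t", nrow(gt$shared_asvs)),
    paste0("max_intragenomic_distance\t",
           max(gt$genomes$max_intragenomic_distance)),
    paste0("seed\t", community$cfg$seed)), summary_path)
  c(fasta = fasta, metadata = meta, ground_truth_genomes = gt_gen,
    ground_truth_shared = gt_shared, summary = summary_path)
}
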