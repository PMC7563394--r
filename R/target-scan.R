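#' Canonical seed-match site strings for a mature miRNA
#'
#' Derives the mRNA-sense DNA substrings whose presence in a 3'UTR
#' constitutes a canonical target site of the miRNA, following the standard
#' site-type definitions, Watson-Crick pairing only:
#'
#' * `6mer`: reverse complement of miRNA positions 2-7;
#' * `7mer-m8`: reverse complement of positions 2-8;
#' * `7mer-A1`: reverse complement of positions 2-7 followed by `A`;
#' * `8mer`: reverse complement of positions 2-8 followed by `A`.
#'
#' Positions are 1-based from the miRNA 5' end; the trailing `A` is the
#' UTR base opposite miRNA position 1, which favors an adenosine regardless
#' of pairing. All strings are returned 5'->3' in mRNA-sense DNA.
#'
#' @param mirna_seq Mature miRNA sequence, RNA 5'->3' (U accepted; T
#'   tolerated), length >= 8.
#' @return Named character vector with elements `8mer`, `7mer-m8`,
#'   `7mer-A1`, `6mer`.
#' @examples
#' seed_site_strings("UCAAGUAUCA")
#' @export
seed_site_strings <- function(mirna_seq) {
  stopifnot(is.character(mirna_seq), length(mirna_seq) == 1)
  seq <- toupper(mirna_seq)
  if (nchar(seq) < 8) {
    abort(paste0("miRNA sequence must be at least 8 nt (got ",
                 nchar(seq), ")"))
  }
  if (!grepl("^[ACGUT]+$", seq)) abort("miRNA sequence must be RNA (A/C/G/U)")
  m2_7 <- revcomp_rna_to_dna(substr(seq, 2, 7))
  m2_8 <- revcomp_rna_to_dna(substr(seq, 2, 8))
  c(`8mer` = paste0(m2_8, "A"),
    `7mer-m8` = m2_8,
    `7mer-A1` = paste0(m2_7, "A"),
    `6mer` = m2_7)
}

#' Find canonical seed-match sites of a miRNA on a 3'UTR
#'
#' Scans an mRNA-sense UTR sequence for every occurrence of the miRNA's
#' seed-match strings. Each site is anchored at an occurrence of the 6mer
#' core (reverse complement of miRNA positions 2-7); at every core locus
#' only the strongest applicable site type is reported
#' (`8mer > 7mer-m8 > 7mer-A1 > 6mer`). Distinct loci may overlap each
#' other. U and T compare as equal.
#'
#' @param utr A one-row UTR tibble (as from [read_utr_fasta()]) or a plain
#'   DNA character string.
#' @param mirna A one-row tibble with `name` and `sequence`, or a named
#'   character vector `c(name = sequence)`.
#' @return A tibble with columns `mirna_name`, `site_type`, `utr_start`,
#'   `utr_end` (1-based inclusive on the UTR sequence), ordered by
#'   `utr_start`.
#' @examples
#' find_seed_matches("GGGATACTTGAGGG", c("toy-miR" = "UCAAGUAUCA"))
#' @export
find_seed_matches <- function(utr, mirna) {
  seq <- utr_sequence(utr)
  mi <- as_mirna_row(mirna)
  sites <- seed_site_strings(mi$sequence)
  core <- sites[["6mer"]]
  m8_base <- substr(sites[["7mer-m8"]], 1, 1)
  n <- nchar(seq)
  if (n < 6) {
    return(tibble(mirna_name = character(), site_type = character(),
                  utr_start = integer(), utr_end = integer()))
  }
  starts <- which_substring(seq, core)
  if (length(starts) == 0) {
    return(tibble(mirna_name = character(), site_type = character(),
                  utr_start = integer(), utr_end = integer()))
  }
  has_m8 <- starts > 1 & substr_vec(seq, starts - 1L) == m8_base
  has_a1 <- starts + 6L <= n & substr_vec(seq, starts + 6L) == "A"
  site_type <- dplyr::case_when(
    has_m8 & has_a1 ~ "8mer",
    has_m8 ~ "7mer-m8",
    has_a1 ~ "7mer-A1",
    .default = "6mer"
  )
  utr_start <- ifelse(has_m8, starts - 1L, starts)
  utr_end <- ifelse(has_a1, starts + 6L, starts + 5L)
  tibble(mirna_name = mi$name, site_type = site_type,
         utr_start = as.integer(utr_start), utr_end = as.integer(utr_end))
}

# all start offsets (1-based) of fixed pattern in subject, overlaps allowed
which_substring <- function(subject, pattern) {
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject))
  as.integer(Biostrings::start(hits))
}

substr_vec <- function(s, at) substring(s, at, at)

utr_sequence <- function(utr) {
  if (is.character(utr) && length(utr) == 1) return(toupper(utr))
  if (is.data.frame(utr) && nrow(utr) == 1 && "sequence" %in% names(utr)) {
    return(toupper(utr$sequence))
  }
  abort("utr must be a one-row UTR tibble or a single DNA string")
}

as_mirna_row <- function(mirna) {
  if (is.data.frame(mirna) && nrow(mirna) == 1 &&
      all(c("name", "sequence") %in% names(mirna))) {
    return(list(name = mirna$name, sequence = mirna$sequence))
  }
  if (is.character(mirna) && length(mirna) == 1 && !is.null(names(mirna))) {
    return(list(name = names(mirna), sequence = unname(mirna)))
  }
  abort("mirna must be a one-row tibble with name/sequence or a named string")
}

#' Map a genomic variant position to its offset on a UTR sequence
#'
#' @param utr One-row UTR tibble with `spans`, `strand`, `chrom`.
#' @param variant One-row variant tibble (`chrom`, `pos`).
#' @return Integer offset (1-based) on the mRNA-sense sequence, or `NA` if
#'   the position falls outside the UTR's genomic span.
#' @export
utr_offset <- function(utr, variant) {
  stopifnot(is.data.frame(utr), nrow(utr) == 1)
  if (norm_chrom(utr$chrom) != norm_chrom(variant$chrom)) return(NA_integer_)
  spans <- utr$spans[[1]]
  spans <- spans[order(spans$start), , drop = FALSE]
  widths <- spans$end - spans$start + 1L
  offset_plus <- NA_integer_
  cum <- 0L
  for (i in seq_len(nrow(spans))) {
    if (variant$pos >= spans$start[i] && variant$pos <= spans$end[i]) {
      offset_plus <- cum + (variant$pos - spans$start[i] + 1L)
      break
    }
    cum <- cum + widths[i]
  }
  if (is.na(offset_plus)) return(NA_integer_)
  total <- sum(widths)
  if (utr$strand == "+") offset_plus else total - offset_plus + 1L
}

#' Apply a single-nucleotide variant to a UTR sequence
#'
#' Substitutes exactly one base of the mRNA-sense sequence. Alleles in the
#' variant are plus-strand genomic bases, so for minus-strand transcripts
#' the complemented alleles are applied at the mirrored offset. The
#' reference allele is checked against the stored sequence and a mismatch
#' is a hard error; the input is never modified.
#'
#' @param utr One-row UTR tibble.
#' @param variant One-row variant tibble (`chrom`, `pos`, `ref`, `alt`).
#' @return A one-row UTR tibble with the substituted sequence.
#' @export
apply_variant <- function(utr, variant) {
  off <- utr_offset(utr, variant)
  if (is.na(off)) {
    abort(paste0("Variant ", variant$chrom, ":", variant$pos,
                 " lies outside the UTR span of ", utr$transcript_id %||% "?"))
  }
  ref_mrna <- if (utr$strand == "+") toupper(variant$ref) else
    complement_dna(toupper(variant$ref))
  alt_mrna <- if (utr$strand == "+") toupper(variant$alt) else
    complement_dna(toupper(variant$alt))
  seq <- toupper(utr$sequence)
  observed <- substr(seq, off, off)
  if (observed != ref_mrna) {
    abort(paste0("Reference mismatch at ", variant$chrom, ":", variant$pos,
                 " (UTR offset ", off, "): expected ", ref_mrna,
                 " on the mRNA strand, found ", observed))
  }
  substr(seq, off, off) <- alt_mrna
  out <- utr
  out$sequence <- seq
  out
}

#' Classify the effect of an SNV on miRNA targeting
#'
#' Compares the seed-match sites overlapping the variant position on the
#' reference and alternate UTR alleles, across a whole miRNA library, and
#' assigns one of the three canonical damage scenarios (or none):
#'
#' * `loss`: the paired miRNA has at least one site overlapping the variant
#'   on the reference allele, none on the alternate, and no other library
#'   miRNA gains an overlapping site on the alternate;
#' * `substitution`: the paired miRNA loses its overlapping site and at
#'   least one *different* library miRNA has an alternate-only overlapping
#'   site;
#' * `gain`: the paired miRNA has no overlapping reference site and at
#'   least one library miRNA (any, including the paired one) has an
#'   alternate-only overlapping site;
#' * `none`: otherwise.
#'
#' A site "overlaps" the variant when the variant's UTR offset lies within
#' the site's span, the A1 position included. `gained_mirnas` always lists
#' every miRNA with an alternate-only overlapping site.
#'
#' @param utr One-row UTR tibble carrying the reference sequence.
#' @param variant One-row variant tibble.
#' @param paired_mirna Name of the curated pair's miRNA; must be present in
#'   `mirna_library`.
#' @param mirna_library Tibble of mature miRNAs (`name`, `sequence`).
#' @return A one-row tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `paired_mirna`, `classification`, `n_ref_sites`,
#'   `n_alt_sites`, `gained_mirnas` (comma-separated, `""` if none),
#'   `ref_sites`, `alt_sites` (list columns of site tibbles overlapping the
#'   variant).
#' @export
classify_snv_effect <- function(utr, variant, paired_mirna, mirna_library) {
  if (!paired_mirna %in% mirna_library$name) {
    abort(paste0("Paired miRNA not in library: ", paired_mirna))
  }
  alt_utr <- apply_variant(utr, variant)
  off_ref <- utr_offset(utr, variant)
  overlapping <- function(u, off) {
    hits <- purrr::map(seq_len(nrow(mirna_library)), function(i) {
      find_seed_matches(u, mirna_library[i, ])
    })
    sites <- bind_rows(hits)
    filter(sites, .data$utr_start <= off, .data$utr_end >= off)
  }
  ref_sites <- overlapping(utr, off_ref)
  alt_sites <- overlapping(alt_utr, off_ref)
  paired_ref <- paired_mirna %in% ref_sites$mirna_name
  paired_alt <- paired_mirna %in% alt_sites$mirna_name
  gained <- setdiff(unique(alt_sites$mirna_name),
                    unique(ref_sites$mirna_name))
  other_gained <- setdiff(gained, paired_mirna)
  classification <- if (paired_ref && !paired_alt) {
    if (length(other_gained) > 0) "substitution" else "loss"
  } else if (!paired_ref && length(gained) > 0) {
    "gain"
  } else {
    "none"
  }
  tibble(
    chrom = variant$chrom, pos = variant$pos,
    ref = variant$ref, alt = variant$alt,
    gene = utr$gene_symbol %||% NA_character_,
    paired_mirna = paired_mirna,
    classification = classification,
    n_ref_sites = nrow(ref_sites),
    n_alt_sites = nrow(alt_sites),
    gained_mirnas = paste(sort(gained), collapse = ","),
    ref_sites = list(ref_sites),
    alt_sites = list(alt_sites)
  )
}

#' Classify many variants against their curated pairs
#'
#' Vectorized driver over [classify_snv_effect()]: each variant is matched
#' to the UTRs of its assigned gene and to every mature miRNA paired with
#' that gene; one classification is produced per
#' (variant, UTR transcript, paired mature miRNA) combination.
#'
#' @param variants Variant tibble with a populated `gene` column.
#' @param utrs UTR tibble (possibly several transcripts per gene).
#' @param pairs Resolved pair tibble with columns `mature_mirna`,
#'   `gene_symbol` (as from [normalize_pairs()]; unresolved rows are
#'   ignored).
#' @param mirna_library Tibble of mature miRNAs (`name`, `sequence`).
#' @return A `target_changes` tibble: one row per classification, with a
#'   `transcript_id` column in addition to the [classify_snv_effect()]
#'   columns.
#' @export
classify_variants <- function(variants, utrs, pairs, mirna_library) {
  if ("resolved" %in% names(pairs)) pairs <- filter(pairs, .data$resolved)
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    v_utrs <- filter(utrs, .data$gene_symbol == v$gene)
    v_pairs <- filter(pairs, .data$gene_symbol == v$gene)
    for (j in seq_len(nrow(v_utrs))) {
      u <- v_utrs[j, ]
      if (is.na(utr_offset(u, v))) next
      for (m in unique(v_pairs$mature_mirna)) {
        res <- classify_snv_effect(u, v, m, mirna_library)
        res <- mutate(res, transcript_id = u$transcript_id, .before = 1)
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(transcript_id = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character(),
                  gene = character(), paired_mirna = character(),
                  classification = character(), n_ref_sites = integer(),
                  n_alt_sites = integer(), gained_mirnas = character(),
                  ref_sites = list(), alt_sites = list())
  }
  class(out) <- c("target_changes", class(out))
  out
}

#' Tally target-change classifications
#'
#' @param changes A tibble with a `classification` column (and optionally
#'   `gained_mirnas`), e.g. from [classify_variants()].
#' @return A tibble with one row per classification level (`loss`, `gain`,
#'   `substitution`, `none`, always all four) and column `n`, plus an
#'   attribute-free extra row is *not* added: the count of records matched
#'   with alternative miRNAs is returned in [glance.target_changes()].
#' @export
tally_classifications <- function(changes) {
  levels <- c("loss", "gain", "substitution", "none")
  counts <- table(factor(changes$classification, levels = levels))
  tibble(classification = levels, n = as.integer(counts))
}

#' @describeIn classify_variants One row per classification with list
#'   columns dropped.
#' @param x A `target_changes` object.
#' @param ... Unused.
#' @export
tidy.target_changes <- function(x, ...) {
  as_tibble(select(as.data.frame(x), -dplyr::any_of(c("ref_sites", "alt_sites"))))
}

#' @describeIn classify_variants One-row summary: total records, counts per
#'   classification, and how many records were matched with alternative
#'   miRNAs (non-empty `gained_mirnas`).
#' @export
glance.target_changes <- function(x, ...) {
  t <- tally_classifications(x)
  counts <- stats::setNames(as.list(t$n), paste0("n_", t$classification))
  as_tibble(c(list(n = nrow(x)), counts,
              list(n_alt_matched = sum(nzchar(x$gained_mirnas)))))
}
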