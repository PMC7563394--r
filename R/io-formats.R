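#' Read single-nucleotide variants from a VCF file
#'
#' Parses a VCF 4.x file and returns one row per ALT allele. Only single
#' nucleotide variants are kept: rows whose REF or an ALT allele is longer
#' than one base (indels, MNVs) are skipped with a warning. Positions stay
#' 1-based, as in the VCF itself; internally every coordinate in this
#' package is 1-based inclusive on the plus strand.
#'
#' @param path Path to a VCF file (plain text).
#' @return A tibble of variants with columns `chrom` (character, `chr`
#'   prefix preserved as written), `pos` (integer, 1-based), `ref`, `alt`
#'   (single uppercase bases) and `gene` (character, `NA` until assigned by
#'   the region filter).
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' writeLines(c("##fileformat=VCFv4.2",
#'              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
#'              "3\t13818646\t.\tT\tA\t.\t.\t."), vcf)
#' read_vcf(vcf)
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(),
                  ref = character(), alt = character(), gene = character()))
  }
  # body line numbers, for error messages: header lines + row index
  n_header <- length(vcf@meta) + 1L
  out <- vector("list", nrow(fix))
  skipped <- integer()
  for (i in seq_len(nrow(fix))) {
    line_no <- n_header + i
    chrom <- fix$CHROM[i]
    pos <- suppressWarnings(as.integer(fix$POS[i]))
    ref <- toupper(fix$REF[i])
    alts <- toupper(strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
    if (is.na(pos) || pos < 1L || is.na(ref) || length(alts) == 0 ||
        any(is.na(alts)) || !is_dna_string(ref, allow_n = FALSE)) {
      abort(paste0("Malformed VCF row at line ", line_no, " of ", path))
    }
    if (nchar(ref) != 1L) {
      skipped <- c(skipped, line_no)
      next
    }
    snv_alts <- alts[nchar(alts) == 1L & is_dna_string(alts, allow_n = FALSE)]
    dropped_alts <- setdiff(alts, c(snv_alts, "*", "."))
    if (length(dropped_alts) > 0) skipped <- c(skipped, line_no)
    snv_alts <- setdiff(snv_alts, ref)
    if (length(snv_alts) == 0) next
    out[[i]] <- tibble(chrom = chrom, pos = pos, ref = ref, alt = snv_alts)
  }
  if (length(skipped) > 0) {
    warn(paste0("Skipped ", length(unique(skipped)),
                " non-SNV record(s) at line(s) ",
                paste(unique(skipped), collapse = ", ")))
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(chrom = character(), pos = integer(),
                  ref = character(), alt = character(), gene = character()))
  }
  res$gene <- NA_character_
  res
}

#' Read transcript models with 5'UTR/CDS/3'UTR intervals
#'
#' Reads transcript region annotations and normalizes all coordinates to the
#' package-internal convention: 1-based, fully inclusive, plus strand. Two
#' dialects are supported:
#'
#' * `"gtf"`: standard GTF (already 1-based inclusive); feature types
#'   `five_prime_utr` (or `5UTR`/`five_prime_UTR`), `CDS`, and
#'   `three_prime_utr` (or `3UTR`/`three_prime_UTR`) are used, everything
#'   else is ignored. `transcript_id` and `gene_name` (falling back to
#'   `gene_id`) attributes are required.
#' * `"bed_tsv"`: 6-column BED-like TSV (0-based half-open), with the name
#'   field carrying `transcript_id|gene_symbol|region_kind`.
#'
#' @param path Path to the annotation file.
#' @param dialect Either `"gtf"` or `"bed_tsv"`.
#' @return A tibble with one row per region interval: columns
#'   `transcript_id`, `gene_symbol`, `chrom`, `strand`, `region_kind` (one of
#'   `five_prime_utr`, `cds`, `three_prime_utr`), `start`, `end`
#'   (1-based inclusive).
#' @export
read_transcript_models <- function(path, dialect = c("bed_tsv", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("Annotation file not found: ", path))
  if (dialect == "gtf") {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("Reading GTF requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path, format = "gtf")
    df <- as.data.frame(gr)
    kind <- canonical_region_kind(as.character(df$type))
    keep <- !is.na(kind)
    df <- df[keep, , drop = FALSE]
    kind <- kind[keep]
    if (nrow(df) == 0) abort("No UTR/CDS features found in GTF")
    gene <- df$gene_name %||% df$gene_id
    if (is.null(gene)) gene <- df$gene_id
    gene <- ifelse(is.na(gene) & !is.null(df$gene_id), df$gene_id, gene)
    models <- tibble(
      transcript_id = as.character(df$transcript_id),
      gene_symbol = as.character(gene),
      chrom = as.character(df$seqnames),
      strand = as.character(df$strand),
      region_kind = kind,
      start = as.integer(df$start),
      end = as.integer(df$end)
    )
  } else {
    cols <- readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), name = readr::col_character(),
      score = readr::col_character(), strand = readr::col_character()
    )
    bed <- readr::read_tsv(
      path,
      col_names = c("chrom", "start", "end", "name", "score", "strand"),
      col_types = cols, comment = "#", progress = FALSE
    )
    parts <- stringr::str_split_fixed(bed$name, stringr::fixed("|"), 3)
    if (any(parts == "")) {
      abort("bed_tsv name field must be 'transcript_id|gene_symbol|region_kind'")
    }
    kind <- canonical_region_kind(parts[, 3])
    if (anyNA(kind)) {
      abort(paste0("Unknown region kind: ",
                   paste(unique(parts[is.na(kind), 3]), collapse = ", ")))
    }
    models <- tibble(
      transcript_id = parts[, 1],
      gene_symbol = parts[, 2],
      chrom = bed$chrom,
      strand = bed$strand,
      region_kind = kind,
      start = bed$start + 1L,  # 0-based half-open -> 1-based inclusive
      end = bed$end
    )
  }
  validate_transcript_models(models)
  arrange(models, .data$transcript_id, .data$start)
}

canonical_region_kind <- function(x) {
  dplyr::case_match(
    tolower(x),
    c("five_prime_utr", "5utr", "5'utr", "utr5") ~ "five_prime_utr",
    "cds" ~ "cds",
    c("three_prime_utr", "3utr", "3'utr", "utr3") ~ "three_prime_utr",
    .default = NA_character_
  )
}

validate_transcript_models <- function(models) {
  if (any(models$start > models$end)) {
    bad <- models[models$start > models$end, ][1, ]
    abort(paste0("Interval with start > end for transcript ",
                 bad$transcript_id, " (", bad$start, " > ", bad$end, ")"))
  }
  if (!all(models$strand %in% c("+", "-"))) {
    abort("Transcript strand must be '+' or '-'")
  }
  per_tx <- split(models, models$transcript_id)
  for (tx in per_tx) {
    if (length(unique(tx$chrom)) > 1 || length(unique(tx$strand)) > 1) {
      abort(paste0("Transcript ", tx$transcript_id[1],
                   " mixes chromosomes or strands"))
    }
    for (kind in unique(tx$region_kind)) {
      iv <- tx[tx$region_kind == kind, ]
      if (nrow(iv) > 1) {
        iv <- iv[order(iv$start), ]
        if (any(iv$start[-1] <= iv$end[-nrow(iv)])) {
          abort(paste0("Overlapping ", kind, " intervals in transcript ",
                       tx$transcript_id[1]))
        }
      }
    }
  }
  invisible(models)
}

#' Write transcript models back to the BED-like TSV dialect
#'
#' Inverse of [read_transcript_models()] for `dialect = "bed_tsv"`; converts
#' internal 1-based inclusive intervals back to 0-based half-open.
#'
#' @param models Transcript-model tibble as returned by
#'   [read_transcript_models()].
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_transcript_models <- function(models, path) {
  out <- tibble(
    chrom = models$chrom,
    start = models$start - 1L,
    end = models$end,
    name = paste(models$transcript_id, models$gene_symbol,
                 models$region_kind, sep = "|"),
    score = ".",
    strand = models$strand
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(models)
}

#' Read 3'UTR sequences from FASTA
#'
#' Headers carry the transcript metadata the pipeline needs, in the form
#' `>transcript_id gene=SYMBOL chrom=CHROM strand=STRAND span=START-END[,START-END...]`
#' with genomic spans 1-based inclusive. Sequences are mRNA-sense DNA
#' (5'->3' of the transcript), so for minus-strand transcripts the sequence
#' is the reverse complement of the plus-strand genomic sequence.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `transcript_id`, `gene_symbol`, `chrom`,
#'   `strand`, `spans` (list column of data frames with `start`, `end`) and
#'   `sequence` (uppercase DNA character).
#' @export
read_utr_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  parse_field <- function(h, key) {
    m <- stringr::str_match(h, paste0(key, "=([^ ]+)"))[, 2]
    if (anyNA(m)) abort(paste0("UTR FASTA header missing '", key, "=': ", h[is.na(m)][1]))
    m
  }
  tid <- stringr::str_split_fixed(headers, " ", 2)[, 1]
  span_str <- parse_field(headers, "span")
  spans <- lapply(span_str, function(s) {
    iv <- stringr::str_split_fixed(strsplit(s, ",", fixed = TRUE)[[1]], "-", 2)
    data.frame(start = as.integer(iv[, 1]), end = as.integer(iv[, 2]))
  })
  utrs <- tibble(
    transcript_id = tid,
    gene_symbol = parse_field(headers, "gene"),
    chrom = parse_field(headers, "chrom"),
    strand = parse_field(headers, "strand"),
    spans = spans,
    sequence = toupper(as.character(seqs))
  )
  span_len <- vapply(utrs$spans, function(s) sum(s$end - s$start + 1L), integer(1))
  bad <- span_len != nchar(utrs$sequence)
  if (any(bad)) {
    abort(paste0("UTR sequence length disagrees with span for ",
                 utrs$transcript_id[bad][1]))
  }
  if (!all(is_dna_string(utrs$sequence))) {
    abort("UTR sequences must be over {A,C,G,T,N}")
  }
  utrs
}

#' Write 3'UTR sequences to FASTA
#'
#' Inverse of [read_utr_fasta()]; emits the same header dialect.
#'
#' @param utrs UTR tibble as returned by [read_utr_fasta()].
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_utr_fasta <- function(utrs, path) {
  span_str <- vapply(utrs$spans, function(s) {
    paste(paste0(s$start, "-", s$end), collapse = ",")
  }, character(1))
  headers <- paste0(utrs$transcript_id,
                    " gene=", utrs$gene_symbol,
                    " chrom=", utrs$chrom,
                    " strand=", utrs$strand,
                    " span=", span_str)
  x <- Biostrings::DNAStringSet(utrs$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path, width = 70)
  invisible(utrs)
}

#' Read mature miRNA sequences from a miRBase-dialect FASTA
#'
#' The first whitespace-separated token of each header is taken as the
#' mature name (e.g. `hsa-miR-137-3p`). Sequences are stored as RNA
#' (U, not T), uppercase.
#'
#' @param path Path to a FASTA file of mature miRNA sequences.
#' @return A tibble with columns `name` and `sequence` (RNA character).
#' @export
read_mirna_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  tibble(
    name = stringr::str_split_fixed(names(seqs), "\\s+", 2)[, 1],
    sequence = chartr("Tt", "Uu", toupper(as.character(seqs)))
  )
}

#' Write mature miRNA sequences to FASTA
#'
#' @param mirnas Tibble with columns `name` and `sequence`.
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_mirna_fasta <- function(mirnas, path) {
  x <- Biostrings::BStringSet(mirnas$sequence)
  names(x) <- mirnas$name
  Biostrings::writeXStringSet(x, path, width = 70)
  invisible(mirnas)
}

#' Read a curated miRNA-gene pair list
#'
#' @param path TSV with at least columns `mirna` and `gene`; an optional
#'   `source` column carries a free-text citation tag.
#' @return A tibble with columns `mirna`, `gene`, `source`.
#' @export
read_pairs <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, comment = "#")
  if (!all(c("mirna", "gene") %in% names(tb))) {
    abort("Pairs TSV must have columns 'mirna' and 'gene'")
  }
  if (any(!nzchar(tb$mirna)) || any(!nzchar(tb$gene)) ||
      anyNA(tb$mirna) || anyNA(tb$gene)) {
    abort("Pairs TSV contains empty miRNA or gene names")
  }
  if (!"source" %in% names(tb)) tb$source <- NA_character_
  select(tb, "mirna", "gene", "source")
}

#' Read a tissue expression matrix (GTEx-median-TPM-like)
#'
#' The TSV has one `gene` column and one column per tissue; an optional
#' sidecar file lists brain-tissue labels, one per line. The matrix is
#' returned in long (tidy) form.
#'
#' @param path TSV of genes x tissues.
#' @param brain_tissues Character vector of tissue labels to flag as brain,
#'   or a path to a one-label-per-line text file. Defaults to
#'   [gtex_brain_tissues()].
#' @return A long tibble with columns `gene`, `tissue`, `is_brain`, `tpm`.
#' @export
read_expression_matrix <- function(path, brain_tissues = gtex_brain_tissues()) {
  if (length(brain_tissues) == 1 && file.exists(brain_tissues)) {
    brain_tissues <- readLines(brain_tissues)
  }
  wide <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (!"gene" %in% names(wide)) abort("Expression TSV must have a 'gene' column")
  long <- tidyr::pivot_longer(wide, -"gene", names_to = "tissue",
                              values_to = "tpm")
  if (any(long$tpm < 0, na.rm = TRUE)) abort("Expression values must be >= 0")
  mutate(long, is_brain = .data$tissue %in% brain_tissues,
         .after = "tissue")
}

#' Default GTEx brain-tissue labels
#'
#' The 13 brain sub-tissue labels used by GTEx v7/v8 releases; used to flag
#' brain columns when ranking genes by brain enrichment.
#'
#' @return Character vector of 13 tissue labels.
#' @export
gtex_brain_tissues <- function() {
  c("Brain - Amygdala",
    "Brain - Anterior cingulate cortex (BA24)",
    "Brain - Caudate (basal ganglia)",
    "Brain - Cerebellar Hemisphere",
    "Brain - Cerebellum",
    "Brain - Cortex",
    "Brain - Frontal Cortex (BA9)",
    "Brain - Hippocampus",
    "Brain - Hypothalamus",
    "Brain - Nucleus accumbens (basal ganglia)",
    "Brain - Putamen (basal ganglia)",
    "Brain - Spinal cord (cervical c-1)",
    "Brain - Substantia nigra")
}

#' Write the annotated variant report
#'
#' Emits a TSV whose first five columns are `chr`, `pos`, `ref`, `alt`,
#' `VEP_Ensembl_Gene_Name`, followed by any annotation columns present
#' (e.g. `classification`, `paired_mirna`, `gained_mirnas`). Rows are
#' sorted by (chromosome, position, alt allele); chromosome order is
#' numeric where labels are numeric, lexicographic otherwise.
#'
#' @param variants Tibble of variants; must carry a non-missing `gene`
#'   column for every row.
#' @param path Output path.
#' @return The sorted tibble that was written, invisibly.
#' @export
write_report <- function(variants, path) {
  if (!"gene" %in% names(variants) ||
      (nrow(variants) > 0 && anyNA(variants$gene))) {
    abort("Every reported variant must carry a gene symbol")
  }
  sorted <- sort_variants(variants)
  out <- rename(sorted, chr = "chrom", VEP_Ensembl_Gene_Name = "gene")
  lead <- c("chr", "pos", "ref", "alt", "VEP_Ensembl_Gene_Name")
  out <- select(out, dplyr::all_of(lead), dplyr::everything())
  readr::write_tsv(out, path, progress = FALSE)
  invisible(sorted)
}

#' Read a report written by [write_report()]
#'
#' @param path Path to the report TSV.
#' @return A tibble in the internal variant layout (`chrom`, `pos`, `ref`,
#'   `alt`, `gene`, plus any annotation columns).
#' @export
read_report <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    chr = "c", pos = "i", ref = "c", alt = "c",
    VEP_Ensembl_Gene_Name = "c", .default = "c"
  ), progress = FALSE)
  need <- c("chr", "pos", "ref", "alt", "VEP_Ensembl_Gene_Name")
  if (!all(need %in% names(tb))) {
    abort("Report is missing required columns")
  }
  rename(tb, chrom = "chr", gene = "VEP_Ensembl_Gene_Name")
}

sort_variants <- function(variants) {
  key <- suppressWarnings(as.numeric(norm_chrom(variants$chrom)))
  ord <- order(is.na(key), key, norm_chrom(variants$chrom),
               variants$pos, variants$alt)
  variants[ord, , drop = FALSE]
}

#' The 22 reported 3'UTR SNVs altering miRNA targeting in ID genes
#'
#' A packaged fixture: the published set of 22 single-nucleotide variants
#' exclusively located in the 3'UTR across all covering transcript isoforms
#' of the intellectual-disability-associated genes GPR88, WNT7A and CDK6
#' (GRCh38 coordinates; one row per alternate allele).
#'
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `gene`.
#' @examples
#' id_utr_snvs() |> dplyr::count(gene)
#' @export
id_utr_snvs <- function() {
  path <- system.file("extdata", "id_utr_snvs.tsv", package = "seedshift",
                      mustWork = TRUE)
  read_report(path)
}
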