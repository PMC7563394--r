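#' Call the transcript region at each variant position
#'
#' For every variant, finds the transcript isoforms that cover its position
#' and records the annotated region kind (`five_prime_utr`, `cds`,
#' `three_prime_utr`) at that base per covering transcript. A transcript
#' covers the variant when the position falls inside any of its annotated
#' intervals; a position inside a transcript's genomic footprint (between
#' its first and last annotated base) but in no annotated interval is
#' recorded as `unannotated`, which counts against 3'UTR exclusivity.
#' Chromosome labels compare after stripping an optional `chr` prefix.
#'
#' @param variants Variant tibble (`chrom`, `pos`, ...).
#' @param models Transcript-model tibble from [read_transcript_models()].
#' @return A tibble with one row per (variant, covering transcript):
#'   columns `chrom`, `pos`, `ref`, `alt`, `transcript_id`, `gene_symbol`,
#'   `region_kind`, ordered by variant then `transcript_id`.
#' @export
call_region <- function(variants, models) {
  empty <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), transcript_id = character(),
                  gene_symbol = character(), region_kind = character())
  if (nrow(variants) == 0 || nrow(models) == 0) return(empty)
  footprint <- models |>
    group_by(.data$transcript_id, .data$gene_symbol) |>
    summarise(chrom = .data$chrom[1], fp_start = min(.data$start),
              fp_end = max(.data$end), .groups = "drop")
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    vchrom <- norm_chrom(v$chrom)
    covering <- footprint |>
      filter(norm_chrom(.data$chrom) == vchrom,
             .data$fp_start <= v$pos, .data$fp_end >= v$pos)
    if (nrow(covering) == 0) next
    for (j in seq_len(nrow(covering))) {
      tx <- covering$transcript_id[j]
      iv <- filter(models, .data$transcript_id == tx,
                   .data$start <= v$pos, .data$end >= v$pos)
      kind <- if (nrow(iv) > 0) iv$region_kind[1] else "unannotated"
      rows[[length(rows) + 1L]] <- tibble(
        chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        transcript_id = tx, gene_symbol = covering$gene_symbol[j],
        region_kind = kind
      )
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  arrange(out, .data$chrom, .data$pos, .data$alt, .data$transcript_id)
}

#' Keep variants exclusively located in the 3'UTR of all covering isoforms
#'
#' A variant passes when it is covered by at least one transcript and the
#' region kind at its position is `three_prime_utr` in *every* covering
#' transcript. A variant covered by no transcript fails (its region is
#' unknowable); a variant whose covering transcripts belong to two or more
#' different genes is flagged ambiguous and dropped. Kept variants receive
#' their gene assignment from the covering transcripts.
#'
#' @inheritParams call_region
#' @return A list with elements `kept` (variant tibble with `gene` filled
#'   in) and `dropped` (variant tibble with a `drop_reason` column: one of
#'   `not_exclusive_3utr`, `no_covering_transcript`, `ambiguous_gene`), and
#'   `calls` (the full per-transcript region-call audit table from
#'   [call_region()] with an `exclusive_3utr` flag). `kept` and `dropped`
#'   partition the input.
#' @export
filter_exclusive <- function(variants, models) {
  calls <- call_region(variants, models)
  vkey <- function(d) paste(norm_chrom(d$chrom), d$pos, d$ref, d$alt)
  keep_flag <- logical(nrow(variants))
  gene_of <- rep(NA_character_, nrow(variants))
  reason <- rep(NA_character_, nrow(variants))
  call_keys <- vkey(calls)
  for (i in seq_len(nrow(variants))) {
    mine <- calls[call_keys == vkey(variants[i, ]), ]
    if (nrow(mine) == 0) {
      reason[i] <- "no_covering_transcript"
    } else if (length(unique(mine$gene_symbol)) > 1) {
      reason[i] <- "ambiguous_gene"
    } else if (all(mine$region_kind == "three_prime_utr")) {
      keep_flag[i] <- TRUE
      gene_of[i] <- mine$gene_symbol[1]
    } else {
      reason[i] <- "not_exclusive_3utr"
    }
  }
  kept <- variants[keep_flag, , drop = FALSE]
  kept$gene <- gene_of[keep_flag]
  dropped <- variants[!keep_flag, , drop = FALSE]
  dropped$drop_reason <- reason[!keep_flag]
  if (nrow(calls) > 0) {
    excl <- tibble(key = vkey(variants), excl = keep_flag) |> distinct()
    calls$exclusive_3utr <- excl$excl[match(call_keys, excl$key)]
  }
  list(kept = as_tibble(kept), dropped = as_tibble(dropped), calls = calls)
}
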