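#' Extract a variant-centered window from a 3'UTR sequence
#'
#' Cuts a fixed-width window of the mRNA-sense UTR sequence around a
#' variant, for cross-species motif comparison. For an even width `w` the
#' window spans `w/2` bases ending at the variant and `w/2` bases after it,
#' so the variant sits at window offset `w/2`; an odd width centers the
#' variant exactly. Windows are clipped at the UTR boundaries, with the
#' variant offset adjusted accordingly.
#'
#' @param utr One-row UTR tibble.
#' @param variant One-row variant tibble (`chrom`, `pos`).
#' @param width Window width in nucleotides; default 100.
#' @return A one-row tibble with columns `chrom`, `pos`, `transcript_id`,
#'   `gene_symbol`, `width`, `window_start`, `window_end` (UTR offsets),
#'   `offset_of_variant` (1-based within the window) and `sequence`.
#' @export
extract_window <- function(utr, variant, width = 100) {
  stopifnot(width >= 1)
  off <- utr_offset(utr, variant)
  if (is.na(off)) {
    abort(paste0("Variant ", variant$chrom, ":", variant$pos,
                 " does not map into the UTR"))
  }
  len <- nchar(utr$sequence)
  start <- max(1L, off - as.integer(ceiling(width / 2)) + 1L)
  end <- min(len, off + as.integer(floor(width / 2)))
  tibble(
    chrom = variant$chrom, pos = variant$pos,
    transcript_id = utr$transcript_id,
    gene_symbol = utr$gene_symbol,
    width = as.integer(width),
    window_start = start, window_end = end,
    offset_of_variant = off - start + 1L,
    sequence = substr(toupper(utr$sequence), start, end)
  )
}

#' Write variant-centered windows as FASTA
#'
#' One record per window, headers
#' `>gene_symbol|transcript_id|chrom:pos offset=K`, ready for external
#' motif-discovery runs.
#'
#' @param windows Tibble of windows from [extract_window()] (row-bound).
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_windows_fasta <- function(windows, path) {
  x <- Biostrings::DNAStringSet(windows$sequence)
  names(x) <- paste0(windows$gene_symbol, "|", windows$transcript_id, "|",
                     windows$chrom, ":", windows$pos,
                     " offset=", windows$offset_of_variant)
  Biostrings::writeXStringSet(x, path, width = 70)
  invisible(windows)
}

#' Count motif occurrences and presence over a 3'UTR set
#'
#' Counts occurrences of a DNA motif and of its reverse complement in each
#' sequence, at every start offset (overlapping occurrences included). A
#' transcript is "present" when either orientation occurs at least once; a
#' palindromic motif is counted once per offset, not twice.
#'
#' @param utrs UTR tibble (or any tibble with a `sequence` column), or a
#'   character vector of sequences.
#' @param motif DNA motif string over A/C/G/T.
#' @return A list with `n_present`, `occurrence_count`, `n_total`, and
#'   `per_sequence` (a tibble with `occurrences` and `present` per input
#'   sequence).
#' @examples
#' count_motif(c("AAAA", "CCCC"), "AA")
#' @export
count_motif <- function(utrs, motif) {
  if (!is.character(motif) || length(motif) != 1 || !nzchar(motif)) {
    abort("Motif must be a non-empty DNA string")
  }
  motif <- toupper(motif)
  if (!grepl("^[ACGT]+$", motif)) abort("Motif alphabet must be A/C/G/T")
  seqs <- if (is.character(utrs)) toupper(utrs) else toupper(utrs$sequence)
  n_total <- length(seqs)
  if (n_total == 0) {
    return(list(n_present = 0L, occurrence_count = 0L, n_total = 0L,
                per_sequence = tibble(occurrences = integer(),
                                      present = logical())))
  }
  rc <- revcomp_dna(motif)
  subject <- Biostrings::DNAStringSet(seqs)
  fwd <- Biostrings::vcountPattern(motif, subject)
  occurrences <- if (rc == motif) fwd else
    fwd + Biostrings::vcountPattern(rc, subject)
  per_sequence <- tibble(occurrences = as.integer(occurrences),
                         present = occurrences > 0)
  list(n_present = sum(per_sequence$present),
       occurrence_count = sum(per_sequence$occurrences),
       n_total = n_total,
       per_sequence = per_sequence)
}

#' Fisher exact test on motif presence counts
#'
#' Builds the 2x2 presence/absence table
#' `[[n_present, n_total - n_present], [bg_present, bg_total - bg_present]]`
#' and computes the two-sided Fisher exact p-value (sum over all tables
#' with fixed margins whose hypergeometric probability does not exceed the
#' observed table's).
#'
#' @param n_present Foreground transcripts containing the motif (either
#'   orientation).
#' @param n_total Foreground transcripts tested.
#' @param bg_present Background transcripts containing the motif (a control
#'   set's observed count, or a rounded analytic expectation).
#' @param bg_total Background transcripts tested.
#' @return A `motif_presence_test` object (list with the table, counts and
#'   `p_value`); see [tidy.motif_presence_test()] and
#'   [glance.motif_presence_test()].
#' @export
fisher_presence_test <- function(n_present, n_total, bg_present, bg_total) {
  if (n_present > n_total || bg_present > bg_total) {
    abort("Present count exceeds total")
  }
  if (min(n_present, n_total, bg_present, bg_total) < 0) {
    abort("Counts must be non-negative")
  }
  tab <- matrix(c(n_present, n_total - n_present,
                  bg_present, bg_total - bg_present),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("foreground", "background"),
                                c("present", "absent")))
  p <- if (sum(tab) == 0) 1 else stats::fisher.test(tab)$p.value
  structure(list(table = tab,
                 n_present = as.integer(n_present),
                 n_total = as.integer(n_total),
                 bg_present = as.integer(round(bg_present)),
                 bg_total = as.integer(bg_total),
                 p_value = min(1, p)),
            class = "motif_presence_test")
}

#' Test motif presence in a 3'UTR set against a background
#'
#' High-level driver around [count_motif()] and [fisher_presence_test()].
#' Two background modes:
#'
#' * `"control"` (default): `background` is a second UTR set; its observed
#'   presence count forms the second table row.
#' * `"analytic"`: the expected number of present transcripts is computed
#'   from an i.i.d. nucleotide model using the foreground set's own base
#'   composition. Per transcript of length `L`, the chance that a window
#'   matches the motif or its reverse complement is summed from the base
#'   frequencies, and presence probability is
#'   `1 - (1 - p_window)^(L - m + 1)`; the summed expectation, rounded to
#'   the nearest integer, forms the second row with the same total.
#'
#' @param utrs Foreground UTR tibble or character vector of sequences.
#' @param motif DNA motif string.
#' @param background Control UTR set (mode `"control"`); ignored under
#'   `"analytic"`.
#' @param mode `"control"` or `"analytic"`.
#' @return A `motif_presence_test` object; the motif, occurrence counts and
#'   the expectation used are carried along.
#' @export
motif_presence_test <- function(utrs, motif, background = NULL,
                                mode = c("control", "analytic")) {
  mode <- match.arg(mode)
  fg <- count_motif(utrs, motif)
  if (mode == "control") {
    if (is.null(background)) {
      abort("mode = 'control' needs a background UTR set")
    }
    bg <- count_motif(background, motif)
    res <- fisher_presence_test(fg$n_present, fg$n_total,
                                bg$n_present, bg$n_total)
    res$expected_present <- bg$n_present
  } else {
    seqs <- if (is.character(utrs)) toupper(utrs) else toupper(utrs$sequence)
    expected <- analytic_expected_present(seqs, toupper(motif))
    res <- fisher_presence_test(fg$n_present, fg$n_total,
                                round(expected), fg$n_total)
    res$expected_present <- expected
  }
  res$motif <- toupper(motif)
  res$occurrence_count <- fg$occurrence_count
  res$mode <- mode
  res
}

# Expected number of sequences containing motif or its revcomp under an
# i.i.d. model with base frequencies pooled from the sequences themselves.
analytic_expected_present <- function(seqs, motif) {
  bases <- c("A", "C", "G", "T")
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(seqs))[, bases, drop = FALSE])
  freq <- counts / sum(counts)
  p_word <- function(w) prod(freq[strsplit(w, "")[[1]]])
  rc <- revcomp_dna(motif)
  p_window <- if (rc == motif) p_word(motif) else p_word(motif) + p_word(rc)
  m <- nchar(motif)
  lens <- nchar(seqs)
  windows <- pmax(0L, lens - m + 1L)
  sum(1 - (1 - p_window)^windows)
}

#' @describeIn fisher_presence_test One row per table cell in long form.
#' @param x A `motif_presence_test` object.
#' @param ... Unused.
#' @export
tidy.motif_presence_test <- function(x, ...) {
  tab <- x$table
  tibble(
    set = rep(rownames(tab), each = ncol(tab)),
    status = rep(colnames(tab), times = nrow(tab)),
    n = as.integer(t(tab))
  )
}

#' @describeIn fisher_presence_test One-row summary with counts, presence
#'   ratio and the Fisher p-value.
#' @export
glance.motif_presence_test <- function(x, ...) {
  tibble(
    motif = x$motif %||% NA_character_,
    n_present = x$n_present,
    n_total = x$n_total,
    presence_ratio = ifelse(x$n_total > 0, x$n_present / x$n_total, NA_real_),
    occurrence_count = x$occurrence_count %||% NA_integer_,
    expected_present = x$expected_present %||% NA_real_,
    bg_present = x$bg_present,
    bg_total = x$bg_total,
    p_value = x$p_value
  )
}

#' @export
print.motif_presence_test <- function(x, ...) {
  cat("Motif presence Fisher exact test",
      if (!is.null(x$motif)) paste0(" (", x$motif, ")"), "\n", sep = "")
  print(x$table)
  cat("p-value:", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' @describeIn fisher_presence_test Bar chart of presence proportions in
#'   foreground and background with the p-value annotated.
#' @param object A `motif_presence_test` object.
#' @export
autoplot.motif_presence_test <- function(object, ...) {
  d <- tidy(object) |>
    group_by(.data$set) |>
    mutate(prop = .data$n / sum(.data$n)) |>
    ungroup() |>
    filter(.data$status == "present")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$set, y = .data$prop)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::labs(
      x = NULL, y = "Fraction of transcripts with motif",
      title = paste0("Motif ", object$motif %||% "", " presence"),
      subtitle = paste0("Fisher exact p = ",
                        format(object$p_value, digits = 3))
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
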