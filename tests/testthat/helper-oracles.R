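# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the code paths they check: the seed-match oracle
# works by base-pairing rather than precomputed site strings, the region
# oracle enumerates every (variant, transcript, interval) triple, the Fisher
# oracle enumerates the hypergeometric support, and the motif oracle is a
# regex-free double loop.

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                              collapse = "")

# Watson-Crick pairing between a UTR DNA base and a miRNA RNA base
wc_pairs <- function(dna, rna) {
  (dna == "A" & rna == "U") | (dna == "T" & rna == "A") |
    (dna == "G" & rna == "C") | (dna == "C" & rna == "G")
}

# Seed-match oracle: slides a 6-nt window; a site core at s means UTR bases
# s..s+5 pair with miRNA positions 7..2 (antiparallel); the type is then
# upgraded by pairing at miRNA position 8 (UTR base s-1) and by an A at
# UTR position s+6. Reports the strongest type per core locus.
oracle_seed_matches <- function(utr_seq, mirna_name, mirna_seq) {
  u <- strsplit(toupper(utr_seq), "")[[1]]
  m <- strsplit(toupper(mirna_seq), "")[[1]]
  n <- length(u)
  out <- list()
  if (n >= 6) {
    for (s in seq_len(n - 5L)) {
      core <- all(wc_pairs(u[s:(s + 5L)], m[7:2]))
      if (!core) next
      has_m8 <- s > 1 && wc_pairs(u[s - 1L], m[8])
      has_a1 <- s + 6L <= n && u[s + 6L] == "A"
      type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8" else
        if (has_a1) "7mer-A1" else "6mer"
      out[[length(out) + 1L]] <- data.frame(
        mirna_name = mirna_name, site_type = type,
        utr_start = if (has_m8) s - 1L else s,
        utr_end = if (has_a1) s + 6L else s + 5L
      )
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(mirna_name = character(), site_type = character(),
                      utr_start = integer(), utr_end = integer())
  }
  res
}

# Region oracle: enumerate every (variant, transcript, interval) triple
oracle_region_calls <- function(variants, models) {
  strip <- function(x) sub("^chr", "", x, ignore.case = TRUE)
  out <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    for (tx in unique(models$transcript_id)) {
      iv <- models[models$transcript_id == tx, ]
      if (strip(iv$chrom[1]) != strip(v$chrom)) next
      inside_any <- FALSE
      kind <- NA_character_
      for (r in seq_len(nrow(iv))) {
        if (v$pos >= iv$start[r] && v$pos <= iv$end[r]) {
          inside_any <- TRUE
          kind <- iv$region_kind[r]
          break
        }
      }
      in_footprint <- v$pos >= min(iv$start) && v$pos <= max(iv$end)
      if (!inside_any && in_footprint) kind <- "unannotated"
      if (inside_any || in_footprint) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
          transcript_id = tx, gene_symbol = iv$gene_symbol[1],
          region_kind = kind
        )
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(NULL)
  res[order(res$chrom, res$pos, res$alt, res$transcript_id), , drop = FALSE]
}

# Two-sided Fisher oracle by exhaustive enumeration of the hypergeometric
# support (all tables with the observed margins; standard convention: sum
# probabilities not exceeding the observed table's, with a 1 + 1e-7 factor
# against floating-point ties)
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(n - r1, c1 - support) -
    lchoose(n, c1)
  p_obs <- exp(logp[support == a])
  sum(exp(logp)[exp(logp) <= p_obs * (1 + 1e-7)])
}

# Motif oracle: regex-free double loop over sequences and start offsets
oracle_count_motif <- function(seqs, motif) {
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", motif), "")[[1]]),
              collapse = "")
  pats <- unique(c(motif, rc))
  occ <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    m <- nchar(motif)
    count <- 0L
    if (nchar(s) >= m) {
      for (start in 1:(nchar(s) - m + 1L)) {
        w <- substr(s, start, start + m - 1L)
        for (p in pats) if (w == p) count <- count + 1L
      }
    }
    occ[i] <- count
  }
  list(n_present = sum(occ > 0), occurrence_count = sum(occ),
       n_total = length(seqs))
}

# one-row UTR tibble builder for unit tests
make_utr <- function(sequence, start = 101L, strand = "+",
                     transcript_id = "TX1", gene = "GENE1", chrom = "1") {
  tibble::tibble(
    transcript_id = transcript_id, gene_symbol = gene, chrom = chrom,
    strand = strand,
    spans = list(data.frame(start = start,
                            end = start + nchar(sequence) - 1L)),
    sequence = sequence
  )
}

make_variant <- function(pos, ref, alt, chrom = "1", gene = NA_character_) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 gene = gene)
}

# small transcript-model tibble builder
make_model <- function(transcript_id, gene, chrom, strand, kinds, starts, ends) {
  tibble::tibble(transcript_id = transcript_id, gene_symbol = gene,
                 chrom = chrom, strand = strand, region_kind = kinds,
                 start = as.integer(starts), end = as.integer(ends))
}
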