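#' Generate a complete synthetic study bundle with planted ground truth
#'
#' Emits every input the pipeline consumes - 3'UTR FASTA, transcript-model
#' TSV (BED-like dialect), VCF of planted variants, mature miRNA FASTA,
#' curated-pair TSV, gene-alias TSV and a tissue expression TSV - together
#' with the ground truth of what was planted, so every stage of the
#' pipeline can be validated end to end without any download.
#'
#' The generator works gene by gene: background 3'UTR sequence is drawn
#' i.i.d. at the requested GC content, seed-match sites are written in for
#' the planted events, and each event is then re-checked with an internal
#' loop-based scanner; an event whose realized classification disagrees
#' with its intended label is re-drawn (different position, allele or
#' helper miRNA), so the emitted labels are guaranteed consistent with the
#' emitted sequences. Multi-isoform gene models share the 3'UTR interval
#' for exclusive genes, while "non-exclusive" genes get a second isoform
#' whose CDS extends over the variant position, so the variant is 3'UTR in
#' one isoform and CDS in another. The default scale mimics a small curated
#' study: ~100 pairs over a few dozen genes, 2-4 isoforms per gene, UTRs of
#' 0.3-3 kb, 53 tissues of which 13 are brain.
#'
#' Identical seeds produce byte-identical bundles. The seed is surfaced in
#' a header comment of every output whose format permits comments.
#'
#' @param dir Output directory (created if missing).
#' @param n_loss,n_gain,n_substitution,n_none Planted 3'UTR-exclusive
#'   events of each classification, one gene per event.
#' @param n_nonexclusive Planted variants that must fail the isoform
#'   exclusivity filter.
#' @param n_filler_genes Genes with pairs but no variants.
#' @param n_pairs Total curated pairs to emit (padded with filler pairs,
#'   some via precursor-level miRNA names and gene aliases).
#' @param n_precursors Background miRNA precursors (two mature arms each).
#' @param utr_len_range 3'UTR length range, nucleotides.
#' @param gc Background GC content in (0, 1).
#' @param isoforms_range Isoforms per gene (min, max).
#' @param n_tissues,n_brain Expression tissues overall and brain subset.
#' @param brain_ratio Planted brain/non-brain mean expression ratio (rho).
#' @param noise_sd Lognormal noise sd (sdlog) on expression values.
#' @param n_brain_genes Genes planted as brain-enriched.
#' @param minus_strand_frac Fraction of genes placed on the minus strand.
#' @param n_aliases Genes that additionally get an alias entry, and whose
#'   pair rows use the alias instead of the official symbol.
#' @param seed Integer RNG seed; drives everything.
#' @return Invisibly, a list with `paths` (named file paths), the
#'   in-memory tibbles (`mirnas`, `utrs`, `models`, `variants`, `pairs`,
#'   `aliases`, `expression`), `ground_truth` (one row per planted variant:
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `paired_mirna`, `intended`,
#'   `exclusive`), `brain_genes`, and `seed`.
#' @export
synthesize_study <- function(dir,
                             n_loss = 8, n_gain = 4, n_substitution = 3,
                             n_none = 3, n_nonexclusive = 4,
                             n_filler_genes = 6, n_pairs = 100,
                             n_precursors = 12,
                             utr_len_range = c(300, 3000), gc = 0.45,
                             isoforms_range = c(2, 4),
                             n_tissues = 53, n_brain = 13,
                             brain_ratio = 10, noise_sd = 0.25,
                             n_brain_genes = 3,
                             minus_strand_frac = 0.5,
                             n_aliases = 10, seed = 1) {
  stopifnot(n_loss >= 0, n_gain >= 0, n_substitution >= 0, n_none >= 0,
            n_nonexclusive >= 0, gc > 0, gc < 1,
            n_brain >= 1, n_tissues > n_brain, seed == floor(seed))
  if (min(utr_len_range) < 60) {
    abort("3'UTRs must be at least 60 nt to host a planted site")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  withr::with_seed(as.integer(seed), {
    bundle <- build_bundle(
      n_loss, n_gain, n_substitution, n_none, n_nonexclusive,
      n_filler_genes, n_pairs, n_precursors, utr_len_range, gc,
      isoforms_range, n_tissues, n_brain, brain_ratio, noise_sd,
      n_brain_genes, minus_strand_frac, n_aliases
    )
  })
  bundle$seed <- as.integer(seed)
  bundle$paths <- write_bundle(bundle, dir)
  invisible(bundle)
}

# ---- internal construction -------------------------------------------------

random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# exhaustive window-comparison site finder used only for generation-time
# self-verification; the production scanner lives in find_seed_matches()
brute_find_sites <- function(seq, mirna_seq) {
  strs <- seed_site_strings(mirna_seq)
  n <- nchar(seq)
  hits <- list()
  for (type in c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
    pat <- strs[[type]]
    w <- nchar(pat)
    if (n < w) next
    starts <- which(substring(seq, 1:(n - w + 1L), w:n) == pat)
    for (s in starts) {
      hits[[length(hits) + 1L]] <- list(type = type, start = s,
                                        end = s + w - 1L)
    }
  }
  hits
}

# does any site of mirna_seq overlap off?
brute_overlaps <- function(seq, off, mirna_seq) {
  for (h in brute_find_sites(seq, mirna_seq)) {
    if (h$start <= off && h$end >= off) return(TRUE)
  }
  FALSE
}

brute_classify <- function(ref_seq, alt_seq, off, paired, lib) {
  ref_who <- lib$name[vapply(lib$sequence, function(s)
    brute_overlaps(ref_seq, off, s), logical(1))]
  alt_who <- lib$name[vapply(lib$sequence, function(s)
    brute_overlaps(alt_seq, off, s), logical(1))]
  gained <- setdiff(alt_who, ref_who)
  paired_ref <- paired %in% ref_who
  paired_alt <- paired %in% alt_who
  if (paired_ref && !paired_alt) {
    if (length(setdiff(gained, paired)) > 0) "substitution" else "loss"
  } else if (!paired_ref && length(gained) > 0) {
    "gain"
  } else {
    "none"
  }
}

subst_at <- function(seq, off, base) {
  substr(seq, off, off) <- base
  seq
}

build_bundle <- function(n_loss, n_gain, n_substitution, n_none,
                         n_nonexclusive, n_filler_genes, n_pairs,
                         n_precursors, utr_len_range, gc, isoforms_range,
                         n_tissues, n_brain, brain_ratio, noise_sd,
                         n_brain_genes, minus_strand_frac, n_aliases) {
  # -- miRNA library: background precursors with both arms, plus one helper
  #    mature per substitution event (its seed is derived from the planted
  #    alternate-allele window, so the substitution is guaranteed a gainer)
  prec_ids <- 9000 + seq_len(n_precursors)
  mirnas <- bind_rows(lapply(prec_ids, function(i) {
    tibble(name = paste0("hsa-miR-", i, c("-5p", "-3p")),
           sequence = c(random_rna(22), random_rna(22)))
  }))

  intended <- c(rep("loss", n_loss), rep("gain", n_gain),
                rep("substitution", n_substitution), rep("none", n_none))
  n_events <- length(intended)
  n_genes <- n_events + n_nonexclusive + n_filler_genes
  genes <- sprintf("SYNG%02d", seq_len(n_genes))
  gene_ids <- sprintf("SYNID%04d", seq_len(n_genes))
  strand <- ifelse(stats::runif(n_genes) < minus_strand_frac, "-", "+")
  utr_len <- sample(seq(utr_len_range[1], utr_len_range[2]), n_genes,
                    replace = TRUE)
  paired <- sample(mirnas$name, n_genes, replace = TRUE)

  # helper gainer miRNAs for substitution events are appended below once
  # their seed windows are known; reserve names now
  sub_idx <- which(intended == "substitution")
  helper_names <- if (length(sub_idx) > 0) {
    paste0("hsa-miR-", 9500 + seq_along(sub_idx), "-5p")
  } else character()

  utr_seq <- vapply(utr_len, random_dna, character(1), gc = gc)

  events <- vector("list", n_events)
  for (e in seq_len(n_events)) {
    g <- e  # one event gene per event
    lab <- intended[e]
    helper <- if (lab == "substitution") {
      helper_names[match(e, sub_idx)]
    } else NA_character_
    planted <- plant_event(utr_seq[g], lab, paired[g], mirnas, helper)
    utr_seq[g] <- planted$seq
    if (!is.null(planted$helper_row)) {
      mirnas <- bind_rows(mirnas, planted$helper_row)
    }
    events[[e]] <- tibble(gene_idx = g, offset = planted$offset,
                          ref_mrna = planted$ref, alt_mrna = planted$alt,
                          paired_mirna = paired[g], intended = lab)
  }
  events <- bind_rows(events)

  # final self-verification of every planted event against the full library
  for (e in seq_len(nrow(events))) {
    ev <- events[e, ]
    s <- utr_seq[ev$gene_idx]
    got <- brute_classify(s, subst_at(s, ev$offset, ev$alt_mrna),
                          ev$offset, ev$paired_mirna, mirnas)
    if (got != ev$intended) {
      abort(paste0("Generator self-check failed: planted '", ev$intended,
                   "' realized as '", got, "' in ", genes[ev$gene_idx]))
    }
  }

  # non-exclusive variants: offset within the first 50 UTR bases, which the
  # second isoform annotates as CDS
  nonexcl <- if (n_nonexclusive > 0) {
    idx <- n_events + seq_len(n_nonexclusive)
    tibble(
      gene_idx = idx,
      offset = sample(5:50, n_nonexclusive, replace = TRUE),
      intended = "filtered",
      paired_mirna = paired[idx]
    ) |>
      mutate(ref_mrna = substr_vec(utr_seq[.data$gene_idx], .data$offset),
             alt_mrna = vapply(.data$ref_mrna, function(b)
               sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1)))
  } else {
    tibble(gene_idx = integer(), offset = integer(), intended = character(),
           paired_mirna = character(), ref_mrna = character(),
           alt_mrna = character())
  }

  # -- gene models: per-gene genomic layout on its own chromosome
  layout <- build_gene_models(genes, strand, utr_len, isoforms_range,
                              n_events, n_nonexclusive, n_filler_genes)
  models <- layout$models
  utr3 <- layout$utr3  # canonical 3'UTR genomic interval per gene

  utrs <- tibble(
    transcript_id = paste0(genes, "-T1"),
    gene_symbol = genes,
    chrom = utr3$chrom,
    strand = strand,
    spans = lapply(seq_len(n_genes), function(g)
      data.frame(start = utr3$start[g], end = utr3$end[g])),
    sequence = utr_seq
  )

  # -- variants: map mRNA offsets to plus-strand genomic records
  all_events <- bind_rows(events, select(nonexcl, names(events)))
  to_genomic <- function(g, off) {
    if (strand[g] == "+") utr3$start[g] + off - 1L else utr3$end[g] - off + 1L
  }
  variants <- all_events |>
    mutate(
      chrom = utr3$chrom[.data$gene_idx],
      pos = as.integer(purrr::map2_int(.data$gene_idx, .data$offset,
                                       to_genomic)),
      ref = ifelse(strand[.data$gene_idx] == "+", .data$ref_mrna,
                   complement_dna(.data$ref_mrna)),
      alt = ifelse(strand[.data$gene_idx] == "+", .data$alt_mrna,
                   complement_dna(.data$alt_mrna)),
      gene = genes[.data$gene_idx],
      exclusive = .data$intended != "filtered"
    )
  ground_truth <- select(variants, "chrom", "pos", "ref", "alt", "gene",
                         "paired_mirna", "intended", "exclusive")

  # -- aliases and pairs
  alias_genes <- genes[seq_len(min(n_aliases, n_genes))]
  aliases <- tibble(
    alias = c(genes, paste0(alias_genes, "-alias1")),
    official_symbol = c(genes, alias_genes),
    gene_id = c(gene_ids, gene_ids[seq_along(alias_genes)])
  )
  event_pairs <- tibble(
    mirna = all_events$paired_mirna,
    gene = genes[all_events$gene_idx],
    source = "planted"
  )
  n_fill <- max(0L, n_pairs - nrow(event_pairs))
  filler_gene_pool <- if (n_filler_genes > 0) {
    genes[n_events + n_nonexclusive + seq_len(n_filler_genes)]
  } else genes
  precursor_names <- paste0("hsa-mir-", prec_ids)
  filler_pairs <- tibble(
    mirna = sample(c(mirnas$name, precursor_names), n_fill, replace = TRUE),
    gene = sample(filler_gene_pool, n_fill, replace = TRUE),
    source = "filler"
  )
  # exercise alias resolution: name some genes by their alias
  use_alias <- filler_pairs$gene %in% alias_genes &
    seq_len(nrow(filler_pairs)) %% 2 == 0
  filler_pairs$gene[use_alias] <- paste0(filler_pairs$gene[use_alias],
                                         "-alias1")
  pairs <- bind_rows(event_pairs, filler_pairs)

  # -- expression: lognormal noise around planted means
  tissues <- c(gtex_brain_tissues()[seq_len(min(n_brain, 13))],
               if (n_brain > 13)
                 paste0("Brain - Extra ", seq_len(n_brain - 13)),
               paste0("Tissue - ", sprintf("%02d", seq_len(n_tissues - n_brain))))
  is_brain <- seq_along(tissues) <= n_brain
  brain_genes <- genes[seq_len(min(n_brain_genes, n_genes))]
  base_tpm <- 20
  expression <- tidyr::expand_grid(gene = genes, tissue = tissues) |>
    left_join(tibble(tissue = tissues, is_brain = is_brain), by = "tissue") |>
    mutate(
      mu = ifelse(.data$gene %in% brain_genes & .data$is_brain,
                  base_tpm * brain_ratio, base_tpm),
      tpm = .data$mu * exp(stats::rnorm(dplyr::n(), 0, noise_sd) -
                             noise_sd^2 / 2)
    ) |>
    select("gene", "tissue", "is_brain", "tpm")

  list(mirnas = mirnas, utrs = utrs, models = models,
       variants = select(variants, "chrom", "pos", "ref", "alt", "gene"),
       pairs = pairs, aliases = aliases, expression = expression,
       ground_truth = ground_truth, brain_genes = brain_genes,
       brain_ratio = brain_ratio, noise_sd = noise_sd)
}

# plant one event into a UTR sequence; returns modified sequence, variant
# offset and mRNA-sense alleles (plus a helper miRNA row for substitutions)
plant_event <- function(seq, lab, paired_name, mirnas, helper_name,
                        max_tries = 200) {
  paired_seq <- mirnas$sequence[match(paired_name, mirnas$name)]
  len <- nchar(seq)
  for (try in seq_len(max_tries)) {
    p <- sample(60:(len - 20), 1)  # site anchor, clear of the CDS-side edge
    cand <- switch(
      lab,
      loss = plant_loss(seq, p, paired_seq),
      substitution = plant_substitution(seq, p, paired_seq, helper_name),
      gain = plant_gain(seq, p, paired_name, mirnas),
      none = plant_none(seq, p)
    )
    if (is.null(cand)) next
    lib <- mirnas
    if (!is.null(cand$helper_row)) lib <- bind_rows(lib, cand$helper_row)
    got <- brute_classify(cand$seq,
                          subst_at(cand$seq, cand$offset, cand$alt),
                          cand$offset, paired_name, lib)
    if (got == lab) return(cand)
  }
  abort(paste0("Could not plant a '", lab, "' event after ", max_tries,
               " attempts; UTR may be too short or library too dense"))
}

plant_loss <- function(seq, p, paired_seq) {
  site8 <- seed_site_strings(paired_seq)[["8mer"]]
  seq <- `substr<-`(seq, p, p + 7L, site8)
  j_rel <- sample(2:7, 1)  # hit the 6mer core so every site type dies
  off <- p + j_rel - 1L
  ref <- substr(seq, off, off)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  list(seq = seq, offset = off, ref = ref, alt = alt, helper_row = NULL)
}

plant_substitution <- function(seq, p, paired_seq, helper_name) {
  site8 <- seed_site_strings(paired_seq)[["8mer"]]
  seq <- `substr<-`(seq, p, p + 7L, site8)
  j_rel <- sample(4:5, 1)  # keeps the gainer window inside the planted site
  off <- p + j_rel - 1L
  ref <- substr(seq, off, off)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  alt_window <- substr(subst_at(seq, off, alt), off - 2L, off + 3L)
  # helper miRNA whose 6mer core equals the alternate-allele window
  core_rna <- chartr("T", "U", revcomp_dna(alt_window))
  helper_seq <- paste0(substr(random_rna(1), 1, 1), core_rna,
                       random_rna(15))
  list(seq = seq, offset = off, ref = ref, alt = alt,
       helper_row = tibble(name = helper_name, sequence = helper_seq))
}

plant_gain <- function(seq, p, paired_name, mirnas) {
  gainer <- sample(setdiff(mirnas$name, paired_name), 1)
  gainer_seq <- mirnas$sequence[match(gainer, mirnas$name)]
  site6 <- seed_site_strings(gainer_seq)[["6mer"]]
  j_rel <- sample(1:6, 1)
  correct <- substr(site6, j_rel, j_rel)
  broken <- sample(setdiff(c("A", "C", "G", "T"), correct), 1)
  ref_site <- `substr<-`(site6, j_rel, j_rel, broken)
  seq <- `substr<-`(seq, p, p + 5L, ref_site)
  off <- p + j_rel - 1L
  list(seq = seq, offset = off, ref = broken, alt = correct,
       helper_row = NULL)
}

plant_none <- function(seq, p) {
  off <- p
  ref <- substr(seq, off, off)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  list(seq = seq, offset = off, ref = ref, alt = alt, helper_row = NULL)
}

# genomic layout: each gene on its own chromosome; canonical isoform T1 is
# [5'UTR][CDS][3'UTR] in transcript order; extra isoforms share the 3'UTR
# interval except for non-exclusive genes, whose T2 CDS eats the first
# 60 UTR bases (mRNA side adjacent to the CDS)
build_gene_models <- function(genes, strand, utr_len, isoforms_range,
                              n_events, n_nonexclusive, n_filler_genes) {
  n_genes <- length(genes)
  rows <- list()
  utr3 <- tibble(chrom = paste0("chrS", seq_len(n_genes)),
                 start = NA_integer_, end = NA_integer_)
  for (g in seq_len(n_genes)) {
    l5 <- sample(100:300, 1)
    lc <- sample(400:900, 1)
    l3 <- utr_len[g]
    base <- 1000L
    if (strand[g] == "+") {
      iv5 <- c(base, base + l5 - 1L)
      ivc <- c(iv5[2] + 1L, iv5[2] + lc)
      iv3 <- c(ivc[2] + 1L, ivc[2] + l3)
    } else {
      iv3 <- c(base, base + l3 - 1L)
      ivc <- c(iv3[2] + 1L, iv3[2] + lc)
      iv5 <- c(ivc[2] + 1L, ivc[2] + l5)
    }
    utr3$start[g] <- iv3[1]
    utr3$end[g] <- iv3[2]
    nonexcl_gene <- g > n_events && g <= n_events + n_nonexclusive
    n_iso <- sample(isoforms_range[1]:isoforms_range[2], 1)
    for (k in seq_len(n_iso)) {
      tid <- paste0(genes[g], "-T", k)
      if (k >= 2 && nonexcl_gene) {
        # CDS extended over the first 60 mRNA bases of the 3'UTR
        if (strand[g] == "+") {
          ivc_k <- c(ivc[1], ivc[2] + 60L)
          iv3_k <- c(iv3[1] + 60L, iv3[2])
        } else {
          ivc_k <- c(ivc[1] - 60L, ivc[2])
          iv3_k <- c(iv3[1], iv3[2] - 60L)
        }
        iv5_k <- iv5
      } else {
        shrink <- 20L * (k - 1L)
        iv5_k <- if (strand[g] == "+") c(iv5[1] + shrink, iv5[2]) else
          c(iv5[1], iv5[2] - shrink)
        ivc_k <- ivc
        iv3_k <- iv3
      }
      rows[[length(rows) + 1L]] <- tibble(
        transcript_id = tid, gene_symbol = genes[g],
        chrom = utr3$chrom[g], strand = strand[g],
        region_kind = c("five_prime_utr", "cds", "three_prime_utr"),
        start = c(iv5_k[1], ivc_k[1], iv3_k[1]),
        end = c(iv5_k[2], ivc_k[2], iv3_k[2])
      )
    }
  }
  list(models = bind_rows(rows), utr3 = utr3)
}

# ---- serialization ---------------------------------------------------------

write_bundle <- function(bundle, dir) {
  p <- function(f) file.path(dir, f)
  seed_line <- paste0("# synthetic bundle, seed=", bundle$seed)
  paths <- list(
    utr_fasta = p("utrs.fasta"),
    models = p("transcript_models.tsv"),
    vcf = p("variants.vcf"),
    mirna_fasta = p("mirna_mature.fa"),
    pairs = p("pairs.tsv"),
    aliases = p("aliases.tsv"),
    expression = p("expression.tsv"),
    brain_tissues = p("brain_tissues.txt"),
    ground_truth = p("ground_truth.tsv")
  )
  write_utr_fasta(bundle$utrs, paths$utr_fasta)
  write_transcript_models(bundle$models, paths$models)
  write_synthetic_vcf(bundle$variants, paths$vcf, bundle$seed)
  write_mirna_fasta(bundle$mirnas, paths$mirna_fasta)
  write_tsv_commented(select(bundle$pairs, "mirna", "gene", "source"),
                      paths$pairs, seed_line)
  write_tsv_commented(bundle$aliases, paths$aliases, seed_line)
  wide <- tidyr::pivot_wider(
    select(bundle$expression, "gene", "tissue", "tpm"),
    names_from = "tissue", values_from = "tpm"
  )
  readr::write_tsv(wide, paths$expression, progress = FALSE)
  writeLines(unique(bundle$expression$tissue[bundle$expression$is_brain]),
             paths$brain_tissues)
  write_tsv_commented(bundle$ground_truth, paths$ground_truth, seed_line)
  paths
}

write_tsv_commented <- function(tb, path, comment_line) {
  body <- readr::format_tsv(tb)
  writeLines(c(comment_line, sub("\n$", "", body)), path)
}

write_synthetic_vcf <- function(variants, path, seed) {
  v <- sort_variants(variants)
  lines <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=seedshift synthetic bundle, seed=", seed),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", sep = "\t")
  )
  writeLines(lines, path)
}
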