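# a small, fast bundle shared by this file's tests
small_bundle <- function(dir, seed = 11) {
  synthesize_study(
    dir, n_loss = 4, n_gain = 3, n_substitution = 2, n_none = 2,
    n_nonexclusive = 3, n_filler_genes = 2, n_pairs = 20,
    n_precursors = 8, utr_len_range = c(300, 700),
    n_tissues = 24, n_brain = 6, seed = seed
  )
}

test_that("identical seeds give byte-identical bundles", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- small_bundle(d1)
  b2 <- small_bundle(d2)
  for (k in names(b1$paths)) {
    expect_identical(readLines(b1$paths[[k]]), readLines(b2$paths[[k]]),
                     label = k)
  }
  # and a different seed gives a different bundle
  d3 <- withr::local_tempdir()
  b3 <- small_bundle(d3, seed = 12)
  expect_false(identical(readLines(b1$paths$utr_fasta),
                         readLines(b3$paths$utr_fasta)))
})

test_that("planted classifications are recovered exactly by the pipeline path", {
  d <- withr::local_tempdir()
  b <- small_bundle(d)
  v <- suppressWarnings(read_vcf(b$paths$vcf))
  m <- read_transcript_models(b$paths$models)
  u <- read_utr_fasta(b$paths$utr_fasta)
  mi <- read_mirna_fasta(b$paths$mirna_fasta)
  flt <- filter_exclusive(v, m)
  # exclusivity filter keeps exactly the planted-exclusive set
  gt <- b$ground_truth
  expect_equal(
    sort(paste(flt$kept$chrom, flt$kept$pos, flt$kept$alt)),
    sort(paste(gt$chrom, gt$pos, gt$alt)[gt$exclusive])
  )
  expect_equal(nrow(flt$kept) + nrow(flt$dropped), nrow(v))
  # classification of each kept variant against its paired miRNA matches
  pairs <- tibble::tibble(mature_mirna = gt$paired_mirna[gt$exclusive],
                          gene_symbol = gt$gene[gt$exclusive],
                          resolved = TRUE)
  ch <- classify_variants(flt$kept, u, pairs, mi)
  merged <- dplyr::inner_join(
    tidy(ch), gt,
    by = c("chrom", "pos", "ref", "alt", "paired_mirna")
  )
  expect_equal(nrow(merged), sum(gt$exclusive))
  expect_equal(merged$classification, merged$intended)
  t <- tally_classifications(ch)
  expect_equal(t$n[t$classification == "loss"], 4L)
  expect_equal(t$n[t$classification == "gain"], 3L)
  expect_equal(t$n[t$classification == "substitution"], 2L)
  expect_equal(t$n[t$classification == "none"], 2L)
})

test_that("planted brain enrichment is recovered within noise", {
  d <- withr::local_tempdir()
  b <- small_bundle(d)
  e <- read_expression_matrix(b$paths$expression, b$paths$brain_tissues)
  r <- brain_enrichment_rank(e, pseudocount = 0.01)
  top <- r$gene[seq_along(b$brain_genes)]
  expect_setequal(top, b$brain_genes)
  # estimated log ratio within 3 SE of log(rho); per-gene SE of a lognormal
  # mean contrast with n_brain and n_other tissues
  n_b <- 6; n_o <- 18
  se <- b$noise_sd * sqrt(1 / n_b + 1 / n_o)
  for (g in b$brain_genes) {
    est <- log(r$mean_brain[r$gene == g] / r$mean_nonbrain[r$gene == g])
    expect_lt(abs(est - log(b$brain_ratio)), 3 * se + 3 * b$noise_sd^2)
  }
  # rho = 1 with no noise means all ratios exactly 1
  d2 <- withr::local_tempdir()
  b2 <- synthesize_study(d2, n_loss = 1, n_gain = 0, n_substitution = 0,
                         n_none = 0, n_nonexclusive = 0, n_filler_genes = 1,
                         n_pairs = 2, n_precursors = 4,
                         utr_len_range = c(300, 400), n_tissues = 10,
                         n_brain = 3, brain_ratio = 1, noise_sd = 0,
                         seed = 4)
  e2 <- read_expression_matrix(b2$paths$expression, b2$paths$brain_tissues)
  r2 <- brain_enrichment_rank(e2, pseudocount = 0)
  expect_true(all(r2$ratio == 1))
})

test_that("impossible configurations are refused", {
  d <- withr::local_tempdir()
  expect_error(
    synthesize_study(d, utr_len_range = c(20, 30), seed = 1),
    "at least 60"
  )
})

test_that("every planted event survives the independent scanner's scrutiny", {
  # the generator's self-check uses its own window scanner; cross-examine
  # the emitted bundle with the production scanner plus the pairing oracle
  d <- withr::local_tempdir()
  b <- small_bundle(d, seed = 21)
  gt <- b$ground_truth[b$ground_truth$exclusive, ]
  for (i in seq_len(nrow(gt))) {
    g <- gt[i, ]
    u <- b$utrs[b$utrs$gene_symbol == g$gene, ]
    v <- make_variant(g$pos, g$ref, g$alt, chrom = g$chrom)
    off <- utr_offset(u, v)
    mir_seq <- b$mirnas$sequence[b$mirnas$name == g$paired_mirna]
    ref_hits <- oracle_seed_matches(u$sequence, g$paired_mirna, mir_seq)
    ref_olap <- any(ref_hits$utr_start <= off & ref_hits$utr_end >= off)
    alt_seq <- apply_variant(u, v)$sequence
    alt_hits <- oracle_seed_matches(alt_seq, g$paired_mirna, mir_seq)
    alt_olap <- any(alt_hits$utr_start <= off & alt_hits$utr_end >= off)
    if (g$intended %in% c("loss", "substitution")) {
      expect_true(ref_olap, label = paste(g$gene, g$intended, "ref site"))
      expect_false(alt_olap, label = paste(g$gene, g$intended, "alt site"))
    }
    if (g$intended == "gain") {
      expect_false(ref_olap, label = paste(g$gene, "gain ref site"))
    }
  }
})
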