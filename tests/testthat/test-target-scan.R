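toy <- c("toy-miR" = "UCAAGUAUCA")

test_that("seed site strings are the reverse complements of positions 2-7/2-8", {
  s <- seed_site_strings(toy)
  expect_equal(s[["6mer"]], "TACTTG")
  expect_equal(s[["7mer-m8"]], "ATACTTG")
  expect_equal(s[["7mer-A1"]], "TACTTGA")
  expect_equal(s[["8mer"]], "ATACTTGA")
  # complement symmetry for an all-A miRNA
  expect_equal(seed_site_strings("AAAAAAAA")[["6mer"]], "TTTTTT")
  # too-short miRNA is a hard error
  expect_error(seed_site_strings("UCAAGUA"), "at least 8")
})

test_that("find_seed_matches reports the strongest type per locus", {
  hits <- find_seed_matches("GGGATACTTGAGGG", toy)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$site_type, "8mer")
  expect_equal(c(hits$utr_start, hits$utr_end), c(4L, 11L))
  # no complementarity at all
  expect_equal(nrow(find_seed_matches("CCCCCCCC", toy)), 0L)
  # 6mer only: position 7 is C, so no 7mer-A1
  h2 <- find_seed_matches("TACTTGC", toy)
  expect_equal(h2$site_type, "6mer")
  expect_equal(c(h2$utr_start, h2$utr_end), c(1L, 6L))
  # forcing the 8mer context away leaves a 7mer at the same core
  h3 <- find_seed_matches("GGGATACTTGCGGG", toy)  # A1 position now C
  expect_equal(h3$site_type, "7mer-m8")
  h4 <- find_seed_matches("GGGTTACTTGAGGG", toy)  # m8 position now T
  expect_equal(h4$site_type, "7mer-A1")
})

test_that("seed matcher equals the pairing-based brute-force oracle", {
  withr::local_seed(421)
  n_agree <- 0L
  for (rep in 1:300) {
    utr <- rand_dna(sample(30:200, 1), gc = runif(1, 0.3, 0.6))
    mir <- rand_rna(sample(18:23, 1))
    got <- as.data.frame(find_seed_matches(utr, c(m = mir)))
    want <- oracle_seed_matches(utr, "m", mir)
    got <- got[order(got$utr_start, got$site_type), ]
    want <- want[order(want$utr_start, want$site_type), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
    n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, 300L)
})

test_that("apply_variant substitutes one base and checks the reference", {
  utr <- make_utr("GGGATACTTGAGGG", start = 101L)
  v <- make_variant(107, "C", "G")
  out <- apply_variant(utr, v)
  expect_equal(out$sequence, "GGGATAGTTGAGGG")
  expect_equal(utr$sequence, "GGGATACTTGAGGG")  # input untouched
  # involution: alt -> ref restores the original
  back <- apply_variant(out, make_variant(107, "G", "C"))
  expect_equal(back$sequence, utr$sequence)
  # reference mismatch is a hard error naming the position
  expect_error(apply_variant(utr, make_variant(107, "A", "G")), "107")
  # outside the span is a hard error
  expect_error(apply_variant(utr, make_variant(90, "C", "G")), "outside")
})

test_that("minus-strand variants are complemented at the mirrored offset", {
  # mRNA-sense sequence of a minus-strand gene spanning genomic 101-114;
  # genomic plus strand reads revcomp(sequence)
  utr <- make_utr("GGGATACTTGAGGG", start = 101L, strand = "-")
  # mRNA offset 7 ('C') sits at genomic pos 114 - 7 + 1 = 108; plus-strand
  # base there is complement('C') = 'G'
  v <- make_variant(108, "G", "C")
  out <- apply_variant(utr, v)
  expect_equal(out$sequence, "GGGATAGTTGAGGG")
  expect_error(apply_variant(utr, make_variant(108, "C", "A")), "mismatch")
})

test_that("strand mirror: planted sites are found identically on both strands", {
  withr::local_seed(77)
  for (rep in 1:20) {
    seq <- rand_dna(80)
    site <- seed_site_strings(toy)[["8mer"]]
    substr(seq, 30, 37) <- site
    plus <- make_utr(seq, start = 1001L, strand = "+")
    minus <- make_utr(seq, start = 1001L, strand = "-")
    expect_equal(find_seed_matches(plus, toy), find_seed_matches(minus, toy))
    # a genomic variant hitting the same mRNA offset gives the same effect
    off <- 33L
    ref_mrna <- substr(seq, off, off)
    alt_mrna <- setdiff(c("A", "C", "G", "T"), ref_mrna)[1]
    v_plus <- make_variant(1000L + off, ref_mrna, alt_mrna)
    v_minus <- make_variant(1001L + 80L - off,
                            chartr("ACGT", "TGCA", ref_mrna),
                            chartr("ACGT", "TGCA", alt_mrna))
    expect_equal(apply_variant(plus, v_plus)$sequence,
                 apply_variant(minus, v_minus)$sequence)
  }
})

test_that("classification follows the loss/gain/substitution contract", {
  lib <- tibble::tibble(
    name = c("toy-miR", "other-miR"),
    sequence = c("UCAAGUAUCA", "UGGAAGACUAGUGAUUUUGUUGU")
  )
  # loss: toy 8mer destroyed, nothing gained
  seq <- paste0(strrep("C", 20), "ATACTTGA", strrep("C", 20))
  utr <- make_utr(seq, start = 1L, gene = "G1")
  v <- make_variant(24, substr(seq, 24, 24), "G")
  r <- classify_snv_effect(utr, v, "toy-miR", lib)
  expect_equal(r$classification, "loss")
  expect_equal(r$gained_mirnas, "")
  expect_equal(r$n_ref_sites, 1L)
  expect_equal(r$n_alt_sites, 0L)
  # gain: ref has a broken site of other-miR (6mer GTCTTCCA -> core)
  core6 <- seed_site_strings(lib$sequence[2])[["6mer"]]
  broken <- paste0("G", substr(core6, 2, 6))
  stopifnot(substr(core6, 1, 1) != "G")
  seq2 <- paste0(strrep("C", 20), broken, strrep("C", 20))
  utr2 <- make_utr(seq2, start = 1L, gene = "G1")
  v2 <- make_variant(21, "G", substr(core6, 1, 1))
  r2 <- classify_snv_effect(utr2, v2, "toy-miR", lib)
  expect_equal(r2$classification, "gain")
  expect_equal(r2$gained_mirnas, "other-miR")
  # none: variant far from any site
  v3 <- make_variant(5, "C", "A")
  r3 <- classify_snv_effect(utr, v3, "toy-miR", lib)
  expect_equal(r3$classification, "none")
  # unknown paired miRNA is an error
  expect_error(classify_snv_effect(utr, v, "nope", lib), "not in library")
})

test_that("tally_classifications counts every class and sums to the input", {
  ch <- tibble::tibble(classification = c("loss", "gain", "none"),
                       gained_mirnas = c("", "x", ""))
  t <- tally_classifications(ch)
  expect_equal(sort(t$classification),
               sort(c("loss", "gain", "substitution", "none")))
  expect_equal(sum(t$n), 3L)
  expect_equal(t$n[t$classification == "substitution"], 0L)
  t0 <- tally_classifications(ch[0, ])
  expect_equal(sum(t0$n), 0L)
})
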