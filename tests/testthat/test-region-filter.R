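two_iso <- dplyr::bind_rows(
  make_model(rep("TXa", 3), rep("G1", 3), rep("1", 3), rep("+", 3),
             c("five_prime_utr", "cds", "three_prime_utr"),
             c(100, 200, 801), c(199, 800, 1600)),
  make_model(rep("TXb", 3), rep("G1", 3), rep("1", 3), rep("+", 3),
             c("five_prime_utr", "cds", "three_prime_utr"),
             c(100, 200, 901), c(199, 900, 1600))
)

test_that("region calls record the kind per covering transcript", {
  v <- make_variant(c(850, 1000, 50), "A", "G")
  calls <- call_region(v, two_iso)
  # 850: 3'UTR of TXa, CDS of TXb
  at850 <- calls[calls$pos == 850, ]
  expect_equal(sort(at850$region_kind), c("cds", "three_prime_utr"))
  # 1000: 3'UTR in both
  expect_true(all(calls$region_kind[calls$pos == 1000] == "three_prime_utr"))
  # 50: covered by nothing
  expect_false(50 %in% calls$pos)
  # deterministic transcript order
  expect_equal(calls$transcript_id[calls$pos == 1000], c("TXa", "TXb"))
})

test_that("exclusivity keeps only all-3'UTR variants and partitions input", {
  v <- make_variant(c(850, 1000, 50), "A", "G")
  res <- filter_exclusive(v, two_iso)
  expect_equal(res$kept$pos, 1000L)
  expect_equal(res$kept$gene, "G1")
  expect_setequal(res$dropped$pos, c(850L, 50L))
  expect_equal(res$dropped$drop_reason[res$dropped$pos == 850],
               "not_exclusive_3utr")
  expect_equal(res$dropped$drop_reason[res$dropped$pos == 50],
               "no_covering_transcript")
  expect_equal(nrow(res$kept) + nrow(res$dropped), nrow(v))
  # empty input gives an empty partition
  e <- filter_exclusive(v[0, ], two_iso)
  expect_equal(nrow(e$kept) + nrow(e$dropped), 0L)
})

test_that("a position inside the footprint but unannotated fails exclusivity", {
  gap <- make_model(rep("TXg", 2), rep("G2", 2), rep("2", 2), rep("+", 2),
                    c("cds", "three_prime_utr"), c(100, 500), c(200, 900))
  v <- make_variant(300, "A", "G", chrom = "2")
  calls <- call_region(v, gap)
  expect_equal(calls$region_kind, "unannotated")
  expect_equal(nrow(filter_exclusive(v, gap)$kept), 0L)
})

test_that("covering transcripts of two genes make the variant ambiguous", {
  overlap <- dplyr::bind_rows(
    make_model("TX1", "G1", "1", "+", "three_prime_utr", 100, 500),
    make_model("TX2", "G2", "1", "-", "three_prime_utr", 300, 700)
  )
  v <- make_variant(400, "A", "G")
  res <- filter_exclusive(v, overlap)
  expect_equal(nrow(res$kept), 0L)
  expect_equal(res$dropped$drop_reason, "ambiguous_gene")
})

test_that("chr prefixes are stripped when matching chromosomes", {
  m <- make_model("TX1", "G1", "chr3", "+", "three_prime_utr", 100, 500)
  v <- make_variant(200, "T", "A", chrom = "3")
  expect_equal(nrow(filter_exclusive(v, m)$kept), 1L)
})

test_that("region calls match the triple-enumeration oracle on random instances", {
  withr::local_seed(99)
  for (rep in 1:25) {
    n_tx <- sample(1:50, 1)
    models <- dplyr::bind_rows(lapply(seq_len(n_tx), function(i) {
      base <- sample(1:2000, 1)
      l5 <- sample(20:100, 1); lc <- sample(50:300, 1); l3 <- sample(50:400, 1)
      make_model(rep(paste0("TX", i), 3),
                 rep(paste0("G", sample(1:5, 1)), 3),
                 rep(sample(c("1", "2"), 1), 3), rep("+", 3),
                 c("five_prime_utr", "cds", "three_prime_utr"),
                 c(base, base + l5, base + l5 + lc),
                 c(base + l5 - 1, base + l5 + lc - 1, base + l5 + lc + l3 - 1))
    }))
    v <- make_variant(sample(1:3500, 12), "A", "G",
                      chrom = sample(c("1", "2"), 12, replace = TRUE))
    got <- as.data.frame(call_region(v, models))
    want <- oracle_region_calls(v, models)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("adding a non-3'UTR covering transcript never rescues a variant", {
  v <- make_variant(1000, "A", "G")
  base_res <- filter_exclusive(v, two_iso)
  expect_equal(nrow(base_res$kept), 1L)
  extra <- make_model("TXc", "G1", "1", "+", "cds", 950, 1050)
  res <- filter_exclusive(v, dplyr::bind_rows(two_iso, extra))
  expect_equal(nrow(res$kept), 0L)
  # and a dropped variant can never become kept by adding transcripts
  v2 <- make_variant(850, "A", "G")
  expect_equal(nrow(filter_exclusive(v2, two_iso)$kept), 0L)
  extra2 <- make_model("TXd", "G1", "1", "+", "three_prime_utr", 800, 900)
  expect_equal(
    nrow(filter_exclusive(v2, dplyr::bind_rows(two_iso, extra2))$kept), 0L)
})
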