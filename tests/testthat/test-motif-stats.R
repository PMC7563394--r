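test_that("windows center the variant and clip at UTR boundaries", {
  utr <- make_utr(rand_dna(200), start = 1L)
  w <- extract_window(utr, make_variant(60, substr(utr$sequence, 60, 60), "A"),
                      width = 100)
  expect_equal(c(w$window_start, w$window_end), c(11L, 110L))
  expect_equal(w$offset_of_variant, 50L)
  expect_equal(nchar(w$sequence), 100L)
  # clipped at the 5' end
  w2 <- extract_window(utr, make_variant(3, substr(utr$sequence, 3, 3), "A"),
                       width = 100)
  expect_equal(w2$window_start, 1L)
  expect_equal(w2$offset_of_variant, 3L)
  # odd width centers exactly
  w3 <- extract_window(utr, make_variant(60, substr(utr$sequence, 60, 60), "A"),
                       width = 101)
  expect_equal(nchar(w3$sequence), 101L)
  expect_equal(w3$offset_of_variant, 51L)
  # outside the UTR is a hard error
  expect_error(extract_window(utr, make_variant(900, "A", "G")), "map")
})

test_that("motif counting covers both orientations with overlaps", {
  r <- count_motif(c("AAAA", "CCCC"), "AA")
  expect_equal(r$n_present, 1L)
  expect_equal(r$n_total, 2L)
  expect_equal(r$occurrence_count, 3L)  # overlapping starts 1,2,3; TT absent
  # presence via reverse complement only
  r2 <- count_motif("GT", "AC")
  expect_equal(r2$n_present, 1L)
  # palindromic motifs are counted once per offset
  r3 <- count_motif("CATG", "CATG")
  expect_equal(r3$occurrence_count, 1L)
  # empty input set
  r4 <- count_motif(character(), "AA")
  expect_equal(r4$n_total, 0L)
  expect_error(count_motif("ACGT", ""), "non-empty")
})

test_that("motif counting agrees with the double-loop oracle", {
  withr::local_seed(202)
  for (rep in 1:40) {
    seqs <- vapply(sample(10:80, 8, replace = TRUE), rand_dna, character(1))
    motif <- rand_dna(sample(2:6, 1))
    got <- count_motif(seqs, motif)
    want <- oracle_count_motif(seqs, motif)
    expect_equal(got$n_present, want$n_present)
    expect_equal(got$occurrence_count, want$occurrence_count)
  }
})

test_that("Fisher p matches exhaustive hypergeometric enumeration to 1e-12", {
  # degenerate and anchor tables
  expect_equal(fisher_presence_test(1, 1, 0, 1)$p_value, 1.0)
  expect_equal(fisher_presence_test(5, 10, 5, 10)$p_value, 1.0)
  grid <- expand.grid(a = c(0, 1, 2, 8), b = c(0, 2, 10),
                      c = c(0, 2, 5), d = c(1, 8, 20))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- fisher_presence_test(g$a, g$a + g$b, g$c, g$c + g$d)$p_value
    want <- oracle_fisher_two_sided(g$a, g$b, g$c, g$d)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # a skewed 10-vs-10 table
  expect_equal(fisher_presence_test(8, 10, 2, 10)$p_value,
               oracle_fisher_two_sided(8, 2, 2, 8), tolerance = 1e-12)
})

test_that("Fisher p is symmetric under swapping the table rows", {
  withr::local_seed(5)
  for (rep in 1:30) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c <- sample(0:15, 1); d <- sample(0:15, 1)
    p1 <- fisher_presence_test(a, a + b, c, c + d)$p_value
    p2 <- fisher_presence_test(c, c + d, a, a + b)$p_value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("one-sided enrichment p never increases with more foreground hits", {
  # fixed margins: moving a hit from background to foreground
  n <- 20
  p_one <- function(a, c) {
    tab <- matrix(c(a, n - a, c, n - c), nrow = 2, byrow = TRUE)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }
  # total present fixed at 19 across both sets: shifting one hit into the
  # foreground can only sharpen the enrichment signal
  for (k in 5:13) {
    expect_lte(p_one(k + 1, 18 - k), p_one(k, 19 - k))
  }
})

test_that("control and analytic background modes both run end to end", {
  withr::local_seed(31)
  fg <- vapply(rep(300, 40), rand_dna, character(1))
  bg <- vapply(rep(300, 40), rand_dna, character(1))
  res <- motif_presence_test(fg, "TTAACATCAA", bg, mode = "control")
  expect_s3_class(res, "motif_presence_test")
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  g <- glance(res)
  expect_equal(g$n_total, 40L)
  res2 <- motif_presence_test(fg, "ACGT", mode = "analytic")
  expect_equal(res2$bg_total, 40L)
  # under the iid model the expectation tracks the observed count closely
  expect_lt(abs(res2$expected_present - res2$n_present), 15)
  td <- tidy(res2)
  expect_equal(nrow(td), 4L)
  expect_equal(sum(td$n[td$set == "foreground"]), 40L)
})
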