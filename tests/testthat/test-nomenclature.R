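at <- alias_table(
  alias = c("WNT7A-alias1", "GPR88-alias1"),
  official_symbol = c("WNT7A", "GPR88"),
  gene_id = c("ENSG00000154764", "ENSG00000181656")
)

test_that("gene names resolve case-insensitively and idempotently", {
  r <- normalize_gene(c("GPR88", "wnt7a-ALIAS1"), at)
  expect_equal(r$official_symbol, c("GPR88", "WNT7A"))
  expect_equal(r$gene_id, c("ENSG00000181656", "ENSG00000154764"))
  expect_true(all(r$resolved))
  # idempotent on official symbols
  r2 <- normalize_gene(r$official_symbol, at)
  expect_equal(r2$official_symbol, r$official_symbol)
  # unknown names are marked, not dropped
  expect_warning(u <- normalize_gene("NO_SUCH_GENE", at), "Unresolved")
  expect_false(u$resolved)
  expect_true(is.na(u$official_symbol))
})

test_that("alias tables reject chains and ambiguous IDs at load", {
  expect_error(
    alias_table(c("A", "B"), c("B", "C"), c("ID1", "ID2")),
    "chain"
  )
  expect_error(
    alias_table(c("x", "y"), c("G", "G"), c("ID1", "ID2")),
    "more than one gene ID"
  )
})

mirs <- tibble::tibble(
  name = c("hsa-miR-137-3p", "hsa-miR-137-5p", "hsa-miR-155-5p",
           "hsa-miR-124-3p"),
  sequence = c("UUAUUGCUUAAGAAUACGCGUAG", "ACGGGUAUUCUUGGGUGGAUAAU",
               "UUAAUGCUAAUCGUGAUAGGGGUU", "UAAGGCACGCGGUGAAUGCC")
)
nm <- build_mirna_name_map(mirs)

test_that("precursor names expand to mature arms per the arm policy", {
  r <- normalize_mirna("hsa-mir-137", nm)
  expect_setequal(r$mature_name, c("hsa-miR-137-3p", "hsa-miR-137-5p"))
  r5 <- normalize_mirna("hsa-mir-137", nm, arm = "5p")
  expect_equal(r5$mature_name, "hsa-miR-137-5p")
  # canonical mature names pass through unchanged
  expect_equal(normalize_mirna("hsa-miR-137-3p", nm)$mature_name,
               "hsa-miR-137-3p")
  # legacy capitalization and missing species prefix are corrected
  expect_equal(normalize_mirna("miR-124-3p", nm)$mature_name,
               "hsa-miR-124-3p")
  expect_setequal(normalize_mirna("MIR137", nm)$mature_name,
                  c("hsa-miR-137-3p", "hsa-miR-137-5p"))
  expect_warning(u <- normalize_mirna("hsa-miR-999-5p", nm), "Unresolved")
  expect_false(u$resolved)
})

test_that("pair normalization conserves counts: input = resolved + unresolved", {
  pairs <- tibble::tibble(
    mirna = c("hsa-mir-137", "miR-155-5p", "hsa-miR-404-5p", "hsa-miR-124-3p"),
    gene = c("WNT7A-alias1", "GPR88", "WNT7A", "UNKNOWN_GENE")
  )
  expect_warning(res <- normalize_pairs(pairs, at, nm), "unresolved")
  input_pairs <- unique(paste(res$mirna_raw, res$gene_raw))
  expect_equal(length(input_pairs), nrow(pairs))
  n_unresolved <- sum(!res$resolved)
  n_resolved_pairs <- length(unique(
    paste(res$mirna_raw, res$gene_raw)[res$resolved]))
  expect_equal(n_resolved_pairs + n_unresolved, nrow(pairs))
  # the precursor-level pair expands to both arms, all resolved
  expect_equal(sum(res$resolved & res$mirna_raw == "hsa-mir-137"), 2L)
  expect_true(all(is.na(res$mature_mirna[!res$resolved])))
})
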