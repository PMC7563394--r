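#' Load a gene alias table
#'
#' Reads a TSV with columns `alias`, `official_symbol`, `gene_id` and builds
#' the lookup used by [normalize_gene()]. Aliases resolve case-insensitively
#' and in a single hop: a table in which some `official_symbol` is itself
#' listed as an alias of a different symbol (a chain, or a cycle) is
#' rejected at load time. Official symbols map to exactly one stable gene ID.
#'
#' @param path TSV with columns `alias`, `official_symbol`, `gene_id`.
#'   Official symbols should also appear as their own alias rows (identity
#'   rows); rows are added automatically where missing.
#' @return An object of class `alias_table`.
#' @export
read_alias_table <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, comment = "#")
  need <- c("alias", "official_symbol", "gene_id")
  if (!all(need %in% names(tb))) {
    abort("Alias TSV must have columns alias, official_symbol, gene_id")
  }
  alias_table(tb$alias, tb$official_symbol, tb$gene_id)
}

#' Build an alias table from vectors
#'
#' @param alias Character vector of aliases.
#' @param official_symbol Official symbol for each alias.
#' @param gene_id Stable gene ID for each official symbol.
#' @return An object of class `alias_table`.
#' @export
alias_table <- function(alias, official_symbol, gene_id) {
  tb <- distinct(tibble(alias = alias, official_symbol = official_symbol,
                        gene_id = gene_id))
  ids <- distinct(tb, .data$official_symbol, .data$gene_id)
  if (anyDuplicated(ids$official_symbol)) {
    dup <- ids$official_symbol[duplicated(ids$official_symbol)][1]
    abort(paste0("Official symbol maps to more than one gene ID: ", dup))
  }
  # single-hop check: an alias that is also some entry's official symbol
  # would need two hops (or loop) to resolve; reject at load
  chains <- tb$alias[toupper(tb$alias) %in% toupper(tb$official_symbol) &
                       toupper(tb$alias) != toupper(tb$official_symbol)]
  if (length(chains) > 0) {
    abort(paste0("Alias chain detected (alias is another entry's official ",
                 "symbol): ", chains[1]))
  }
  # identity rows so normalize_gene(official) is idempotent
  identity_rows <- mutate(ids, alias = .data$official_symbol)
  tb <- distinct(bind_rows(tb, identity_rows))
  key <- toupper(tb$alias)
  if (anyDuplicated(key)) {
    amb <- tb$alias[duplicated(key)][1]
    abort(paste0("Alias resolves ambiguously (case-insensitive): ", amb))
  }
  structure(list(map = stats::setNames(tb$official_symbol, key),
                 ids = stats::setNames(ids$gene_id, ids$official_symbol)),
            class = "alias_table")
}

#' Normalize gene names to official symbols and stable IDs
#'
#' Case-insensitive, single-hop, deterministic resolution; an already
#' official symbol returns itself. Unknown names are marked unresolved
#' (symbol and ID `NA`, `resolved = FALSE`) and logged with a warning -
#' never silently dropped.
#'
#' @param raw_name Character vector of gene names as curated.
#' @param aliases An `alias_table`.
#' @return A tibble with columns `raw_name`, `official_symbol`, `gene_id`,
#'   `resolved`.
#' @examples
#' at <- alias_table(c("WNT7A-alias1"), c("WNT7A"), c("ENSG00000154764"))
#' normalize_gene(c("WNT7A", "wnt7a-alias1"), at)
#' @export
normalize_gene <- function(raw_name, aliases) {
  stopifnot(inherits(aliases, "alias_table"))
  official <- unname(aliases$map[toupper(raw_name)])
  res <- tibble(
    raw_name = raw_name,
    official_symbol = official,
    gene_id = unname(aliases$ids[official]),
    resolved = !is.na(official)
  )
  if (any(!res$resolved)) {
    warn(paste0("Unresolved gene name(s): ",
                paste(unique(raw_name[!res$resolved]), collapse = ", ")))
  }
  res
}

#' Build a miRNA name map from a mature miRNA FASTA
#'
#' Harvests the canonical mature names from a miRBase-dialect mature FASTA
#' and derives (i) a precursor -> mature-products map (e.g. `hsa-mir-137`
#' expands to `hsa-miR-137-3p` and `hsa-miR-137-5p` when both arms are
#' present, or to the single unsuffixed mature `hsa-miR-137` for older
#' nomenclature) and (ii) a case-/punctuation-insensitive legacy map so
#' miscapitalized curated names (`MIR137`, `mir-137-3p`) still resolve.
#' The species prefix defaults to `hsa-` when absent.
#'
#' @param mirnas Tibble with a `name` column, as from [read_mirna_fasta()].
#' @return An object of class `mirna_name_map`.
#' @export
build_mirna_name_map <- function(mirnas) {
  canonical <- unique(mirnas$name)
  # precursor stem: mature name without the arm suffix, lowercased miR->mir
  stem <- sub("-[35]p$", "", canonical)
  precursor <- tolower(stem)
  by_precursor <- split(canonical, precursor)
  structure(list(
    canonical = canonical,
    canonical_key = stats::setNames(canonical, mirna_key(canonical)),
    precursor = by_precursor,
    precursor_key = stats::setNames(names(by_precursor),
                                    mirna_key(names(by_precursor)))
  ), class = "mirna_name_map")
}

# normalization key: lowercase, drop hyphens, ensure species prefix
mirna_key <- function(x) {
  x <- tolower(x)
  x <- gsub("-", "", x, fixed = TRUE)
  ifelse(grepl("^[a-z]{3}mir", x), x, paste0("hsa", x))
}

#' Normalize curated miRNA names to canonical mature names
#'
#' Precursor-level names (`hsa-mir-137`, `mir137`) expand to mature
#' products according to `arm`; mature-level names are case-corrected to
#' their canonical form. Unknown names return an empty match set with
#' `resolved = FALSE`.
#'
#' @param raw_name Character vector of curated miRNA names.
#' @param name_map A `mirna_name_map` from [build_mirna_name_map()].
#' @param arm Which precursor arm(s) to carry into scanning when a
#'   precursor-level name is given: `"both"` (default; union of sites),
#'   `"5p"` or `"3p"`.
#' @return A tibble with columns `raw_name`, `mature_name` (one row per
#'   mature product; `NA` when unresolved) and `resolved`.
#' @export
normalize_mirna <- function(raw_name, name_map, arm = c("both", "5p", "3p")) {
  arm <- match.arg(arm)
  stopifnot(inherits(name_map, "mirna_name_map"))
  one <- function(nm) {
    key <- mirna_key(nm)
    hit <- name_map$canonical_key[key]
    if (!is.na(hit)) return(unname(hit))
    prec <- name_map$precursor_key[key]
    if (!is.na(prec)) {
      matures <- name_map$precursor[[unname(prec)]]
      if (arm != "both") {
        armed <- matures[endsWith(matures, paste0("-", arm))]
        if (length(armed) > 0) matures <- armed
      }
      return(matures)
    }
    NA_character_
  }
  rows <- lapply(raw_name, function(nm) {
    m <- one(nm)
    tibble(raw_name = nm, mature_name = m, resolved = !anyNA(m))
  })
  res <- bind_rows(rows)
  if (any(!res$resolved)) {
    warn(paste0("Unresolved miRNA name(s): ",
                paste(unique(res$raw_name[!res$resolved]), collapse = ", ")))
  }
  res
}

#' Normalize a curated pair list end to end
#'
#' Resolves both members of every miRNA-gene pair; each input pair comes
#' back either fully resolved (possibly expanded to several mature arms) or
#' carried with an explicit unresolved marker, so
#' `n_input = n_resolved + n_unresolved` always holds.
#'
#' @param pairs Tibble with columns `mirna`, `gene` (and optionally
#'   `source`), as from [read_pairs()].
#' @param aliases An `alias_table`.
#' @param name_map A `mirna_name_map`.
#' @inheritParams normalize_mirna
#' @return A tibble with columns `mirna_raw`, `gene_raw`, `source`,
#'   `mature_mirna`, `gene_symbol`, `gene_id`, `resolved`. Unresolved pairs
#'   have one row with `NA` in the unresolvable fields.
#' @export
normalize_pairs <- function(pairs, aliases, name_map,
                            arm = c("both", "5p", "3p")) {
  arm <- match.arg(arm)
  if (!"source" %in% names(pairs)) pairs$source <- NA_character_
  rows <- purrr::pmap(list(pairs$mirna, pairs$gene, pairs$source),
                      function(m, g, src) {
    gr <- suppressWarnings(normalize_gene(g, aliases))
    mr <- suppressWarnings(normalize_mirna(m, name_map, arm = arm))
    ok <- gr$resolved[1] && all(mr$resolved)
    if (!ok) {
      return(tibble(mirna_raw = m, gene_raw = g, source = src,
                    mature_mirna = NA_character_,
                    gene_symbol = if (gr$resolved[1]) gr$official_symbol else NA_character_,
                    gene_id = if (gr$resolved[1]) gr$gene_id else NA_character_,
                    resolved = FALSE))
    }
    tibble(mirna_raw = m, gene_raw = g, source = src,
           mature_mirna = mr$mature_name,
           gene_symbol = gr$official_symbol, gene_id = gr$gene_id,
           resolved = TRUE)
  })
  out <- bind_rows(rows)
  n_unres <- sum(!out$resolved)
  if (n_unres > 0) {
    warn(paste0(n_unres, " pair(s) left unresolved and excluded downstream"))
  }
  out
}
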