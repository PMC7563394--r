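#' Assemble a pipeline run configuration
#'
#' Collects every input path and tunable parameter of the full workflow
#' into a plain list that can be validated ([validate_run_config()]),
#' serialized to/from YAML-like key-value text ([write_run_config()],
#' [read_run_config()]) and executed ([run_pipeline()]).
#'
#' @param vcf Path to the variant VCF.
#' @param utr_fasta Path to the 3'UTR FASTA (header dialect of
#'   [read_utr_fasta()]).
#' @param models Path to the transcript-model annotation.
#' @param models_dialect `"bed_tsv"` or `"gtf"`.
#' @param mirna_fasta Path to the mature miRNA FASTA.
#' @param pairs Path to the curated pair TSV.
#' @param aliases Path to the gene-alias TSV.
#' @param expression Optional path to the expression TSV.
#' @param brain_tissues Optional path to a brain-tissue label file; when
#'   `NULL` the GTEx default of [gtex_brain_tissues()] applies.
#' @param arm Precursor arm policy: `"both"`, `"5p"`, `"3p"`.
#' @param window_width Conservation window width (nt).
#' @param pseudocount Pseudocount for expression normalization and
#'   enrichment ratio.
#' @param fisher_mode `"control"` or `"analytic"` (see
#'   [motif_presence_test()]).
#' @param motif Optional DNA motif string to test over the UTR set.
#' @param motif_background Optional path to a control UTR FASTA for
#'   `fisher_mode = "control"`.
#' @param exclusivity_filter Apply the isoform 3'UTR-exclusivity filter
#'   (default `TRUE`).
#' @param seed Integer seed recorded in the run summary.
#' @param out_dir Output directory for all run artifacts.
#' @return A list of class `seedshift_config`.
#' @export
run_config <- function(vcf, utr_fasta, models, mirna_fasta, pairs, aliases,
                       expression = NULL, brain_tissues = NULL,
                       models_dialect = "bed_tsv", arm = "both",
                       window_width = 100, pseudocount = 1,
                       fisher_mode = "control", motif = NULL,
                       motif_background = NULL, exclusivity_filter = TRUE,
                       seed = 1, out_dir = "seedshift_run") {
  cfg <- list(vcf = vcf, utr_fasta = utr_fasta, models = models,
              models_dialect = models_dialect, mirna_fasta = mirna_fasta,
              pairs = pairs, aliases = aliases, expression = expression,
              brain_tissues = brain_tissues, arm = arm,
              window_width = window_width, pseudocount = pseudocount,
              fisher_mode = fisher_mode, motif = motif,
              motif_background = motif_background,
              exclusivity_filter = exclusivity_filter,
              seed = seed, out_dir = out_dir)
  class(cfg) <- "seedshift_config"
  cfg
}

#' Validate a run configuration without running it
#'
#' Returns every detectable problem - missing files, unknown modes - as a
#' tibble; an empty tibble means the configuration is runnable.
#'
#' @param config A `seedshift_config` from [run_config()].
#' @return A tibble with columns `field` and `problem` (zero rows iff OK).
#' @export
validate_run_config <- function(config) {
  problems <- list()
  add <- function(field, msg) {
    problems[[length(problems) + 1L]] <<- tibble(field = field, problem = msg)
  }
  required_paths <- c("vcf", "utr_fasta", "models", "mirna_fasta",
                      "pairs", "aliases")
  for (f in required_paths) {
    if (is.null(config[[f]])) add(f, "path not set")
    else if (!file.exists(config[[f]])) {
      add(f, paste0("file not found: ", config[[f]]))
    }
  }
  for (f in c("expression", "brain_tissues", "motif_background")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      add(f, paste0("file not found: ", config[[f]]))
    }
  }
  if (!config$models_dialect %in% c("bed_tsv", "gtf")) {
    add("models_dialect", paste0("unknown dialect: ", config$models_dialect))
  }
  if (!config$arm %in% c("both", "5p", "3p")) {
    add("arm", paste0("unknown arm policy: ", config$arm))
  }
  if (!config$fisher_mode %in% c("control", "analytic")) {
    add("fisher_mode", paste0("unknown Fisher mode: ", config$fisher_mode))
  }
  if (config$fisher_mode == "control" && !is.null(config$motif) &&
      is.null(config$motif_background)) {
    add("motif_background", "control-mode motif test needs a background FASTA")
  }
  if (!is.numeric(config$window_width) || config$window_width < 1) {
    add("window_width", "must be a positive number")
  }
  if (!is.null(config$motif) && !grepl("^[ACGTacgt]+$", config$motif)) {
    add("motif", "motif must be a DNA string over A/C/G/T")
  }
  if (length(problems) == 0) {
    return(tibble(field = character(), problem = character()))
  }
  bind_rows(problems)
}

#' Write / read a run configuration as flat key-value text
#'
#' One `key = value` line per set field; round-trips through
#' [read_run_config()].
#'
#' @param config A `seedshift_config`.
#' @param path File path.
#' @return `write_run_config()` the config invisibly; `read_run_config()`
#'   a `seedshift_config`.
#' @export
write_run_config <- function(config, path) {
  keep <- !vapply(config, is.null, logical(1))
  vals <- vapply(config[keep], function(v) as.character(v), character(1))
  writeLines(c("# seedshift run configuration",
               paste(names(config)[keep], "=", vals)), path)
  invisible(config)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), value = TRUE, invert = TRUE)
  kv <- stringr::str_match(lines, "^\\s*([a-z_]+)\\s*=\\s*(.*?)\\s*$")
  if (anyNA(kv[, 1])) abort("Malformed config line(s)")
  vals <- as.list(kv[, 3])
  names(vals) <- kv[, 2]
  for (num in c("window_width", "pseudocount", "seed")) {
    if (num %in% names(vals)) vals[[num]] <- as.numeric(vals[[num]])
  }
  if ("exclusivity_filter" %in% names(vals)) {
    vals$exclusivity_filter <- as.logical(vals$exclusivity_filter)
  }
  do.call(run_config, vals)
}

#' Run the full variant-prioritization workflow
#'
#' Executes the staged workflow: nomenclature normalization, isoform
#' 3'UTR-exclusivity filtering, allele-aware seed-site classification,
#' classification tallies, expression normalization with brain-enrichment
#' ranking, conservation-window extraction, and (optionally) the motif
#' presence Fisher test. Every stage writes its intermediate table under
#' `config$out_dir`, and a machine-readable JSON run summary records the
#' input/output counts of every stage. Any stage failure aborts with the
#' stage name in the message.
#'
#' @param config A `seedshift_config` from [run_config()].
#' @return Invisibly, a list with the in-memory stage results (`pairs`,
#'   `filter`, `changes`, `tally`, `enrichment`, `motif_test`, `summary`)
#'   and `paths` of the written artifacts.
#' @export
run_pipeline <- function(config) {
  problems <- validate_run_config(config)
  if (nrow(problems) > 0) {
    abort(paste0("Invalid configuration: ",
                 paste(problems$field, problems$problem, collapse = "; ")))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Stage [", name, "] failed: ", conditionMessage(e)))
    })
  }
  summary <- list(seed = config$seed)

  inputs <- stage("read_inputs", {
    list(
      variants = suppressWarnings(read_vcf(config$vcf)),
      utrs = read_utr_fasta(config$utr_fasta),
      models = read_transcript_models(config$models, config$models_dialect),
      mirnas = read_mirna_fasta(config$mirna_fasta),
      pairs = read_pairs(config$pairs),
      aliases = read_alias_table(config$aliases)
    )
  })
  summary$n_variants_in <- nrow(inputs$variants)
  summary$n_pairs_in <- nrow(inputs$pairs)

  resolved <- stage("nomenclature", {
    name_map <- build_mirna_name_map(inputs$mirnas)
    suppressWarnings(
      normalize_pairs(inputs$pairs, inputs$aliases, name_map,
                      arm = config$arm)
    )
  })
  n_unresolved_pairs <- length(unique(paste(
    resolved$mirna_raw, resolved$gene_raw)[!resolved$resolved]))
  summary$n_pairs_resolved <- summary$n_pairs_in - n_unresolved_pairs
  summary$n_pairs_unresolved <- n_unresolved_pairs
  readr::write_tsv(resolved, p("pairs_resolved.tsv"), progress = FALSE)

  flt <- stage("region_filter", {
    if (config$exclusivity_filter) {
      filter_exclusive(inputs$variants, inputs$models)
    } else {
      kept <- inputs$variants
      calls <- call_region(inputs$variants, inputs$models)
      gene_by_var <- calls |>
        distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
                 .data$gene_symbol)
      kept <- left_join(select(kept, -"gene"), gene_by_var,
                        by = c("chrom", "pos", "ref", "alt")) |>
        rename(gene = "gene_symbol")
      list(kept = kept,
           dropped = inputs$variants[0, ] |>
             mutate(drop_reason = character(0)),
           calls = calls)
    }
  })
  summary$n_variants_kept <- nrow(flt$kept)
  summary$n_variants_dropped <- nrow(flt$dropped)
  stopifnot(summary$n_variants_kept + summary$n_variants_dropped ==
              summary$n_variants_in)
  readr::write_tsv(flt$calls, p("region_calls.tsv"), progress = FALSE)
  readr::write_tsv(flt$dropped, p("variants_dropped.tsv"), progress = FALSE)

  changes <- stage("target_scan", {
    classify_variants(flt$kept, inputs$utrs, resolved, inputs$mirnas)
  })
  tally <- tally_classifications(changes)
  summary$n_classifications <- nrow(changes)
  summary$classification_tally <- stats::setNames(as.list(tally$n),
                                                  tally$classification)
  summary$n_alt_matched <- sum(nzchar(changes$gained_mirnas))
  stage("report", {
    write_report(tidy(changes) |> select(-"transcript_id"), p("report.tsv"))
  })
  readr::write_tsv(tally, p("classification_tally.tsv"), progress = FALSE)

  windows <- stage("windows", {
    rows <- list()
    for (i in seq_len(nrow(flt$kept))) {
      v <- flt$kept[i, ]
      for (j in which(inputs$utrs$gene_symbol == v$gene)) {
        u <- inputs$utrs[j, ]
        if (!is.na(utr_offset(u, v))) {
          rows[[length(rows) + 1L]] <-
            extract_window(u, v, config$window_width)
        }
      }
    }
    bind_rows(rows)
  })
  if (nrow(windows) > 0) write_windows_fasta(windows, p("windows.fasta"))
  summary$n_windows <- nrow(windows)

  enrichment <- NULL
  if (!is.null(config$expression)) {
    enrichment <- stage("expression", {
      brain <- config$brain_tissues %||% gtex_brain_tissues()
      expr <- read_expression_matrix(config$expression, brain)
      norm <- normalize_expression(expr, config$pseudocount)
      write_expression_matrix(norm, p("expression_normalized.tsv"))
      rank <- brain_enrichment_rank(expr, config$pseudocount)
      readr::write_tsv(rank, p("brain_enrichment.tsv"), progress = FALSE)
      rank
    })
    summary$n_expression_genes <- length(unique(enrichment$gene))
  }

  motif_test <- NULL
  if (!is.null(config$motif)) {
    motif_test <- stage("motif_stats", {
      bg <- if (config$fisher_mode == "control") {
        read_utr_fasta(config$motif_background)
      } else NULL
      res <- motif_presence_test(inputs$utrs, config$motif, bg,
                                 mode = config$fisher_mode)
      readr::write_tsv(glance(res), p("motif_test.tsv"), progress = FALSE)
      res
    })
    summary$motif_p_value <- motif_test$p_value
  }

  jsonlite::write_json(summary, p("run_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(pairs = resolved, filter = flt, changes = changes,
                 tally = tally, windows = windows, enrichment = enrichment,
                 motif_test = motif_test, summary = summary,
                 paths = list(out_dir = config$out_dir)))
}

#' Bar chart of target-change classifications
#'
#' @param object A `target_changes` tibble from [classify_variants()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.target_changes <- function(object, ...) {
  t <- tally_classifications(object)
  ggplot2::ggplot(t, ggplot2::aes(
    x = factor(.data$classification,
               levels = c("loss", "substitution", "gain", "none")),
    y = .data$n
  )) +
    ggplot2::geom_col(fill = "firebrick", width = 0.6) +
    ggplot2::labs(x = "Target-site change", y = "Variant classifications") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance
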