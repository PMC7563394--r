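#' Normalize a tissue expression matrix to a decibel-like scale
#'
#' Applies the elementwise transform `10 * log10(x + pseudocount)` to
#' non-negative TPM-like values. With the default pseudocount of 1 this
#' maps 0 to exactly 0, 9 to 10 and 99 to 20, and is strictly monotone, so
#' within-gene orderings are preserved.
#'
#' @param expr Long expression tibble with columns `gene`, `tissue`,
#'   `is_brain`, `tpm`, as from [read_expression_matrix()].
#' @param pseudocount Non-negative offset added before the log; default 1.
#' @return The input tibble with an added `norm` column
#'   (`10 * log10(tpm + pseudocount)`).
#' @examples
#' expr <- tibble::tibble(gene = "G", tissue = c("a", "b"),
#'                        is_brain = c(TRUE, FALSE), tpm = c(0, 99))
#' normalize_expression(expr)$norm  # 0, 20
#' @export
normalize_expression <- function(expr, pseudocount = 1) {
  need <- c("gene", "tissue", "tpm")
  if (!all(need %in% names(expr))) {
    abort("Expression tibble needs columns gene, tissue, tpm")
  }
  if (any(expr$tpm < 0, na.rm = TRUE)) {
    abort("Expression values must be non-negative")
  }
  mutate(expr, norm = 10 * log10(.data$tpm + pseudocount))
}

#' Rank genes by brain-tissue expression enrichment
#'
#' Computes, per gene, the mean expression over brain tissues and over
#' non-brain tissues, and their pseudocount-stabilized ratio
#' `(mean_brain + eps) / (mean_nonbrain + eps)`. Genes are returned sorted
#' by decreasing ratio, ties broken by gene label, so the ranking is
#' deterministic. The ratio is computed on the raw (TPM) scale; because the
#' normalization of [normalize_expression()] is strictly monotone it does
#' not change which tissues dominate, but means are taken on the scale of
#' the `value_col` you pass.
#'
#' @param expr Long expression tibble with columns `gene`, `tissue`,
#'   `is_brain` and the value column.
#' @param pseudocount Stabilizer `eps` added to both means; default 1.
#' @param value_col Name of the value column to average; default `"tpm"`.
#' @return A tibble with columns `gene`, `mean_brain`, `mean_nonbrain`,
#'   `ratio`, `rank`, sorted by decreasing `ratio`.
#' @export
brain_enrichment_rank <- function(expr, pseudocount = 1, value_col = "tpm") {
  if (!"is_brain" %in% names(expr) || anyNA(expr$is_brain)) {
    abort("Expression tibble needs a complete logical 'is_brain' column")
  }
  if (!any(expr$is_brain) || all(expr$is_brain)) {
    abort("Need at least one brain and one non-brain tissue to rank")
  }
  vals <- expr[[value_col]]
  if (is.null(vals)) abort(paste0("No such value column: ", value_col))
  out <- expr |>
    mutate(.value = vals) |>
    group_by(.data$gene) |>
    summarise(
      mean_brain = mean(.data$.value[.data$is_brain]),
      mean_nonbrain = mean(.data$.value[!.data$is_brain]),
      .groups = "drop"
    ) |>
    mutate(ratio = (.data$mean_brain + pseudocount) /
             (.data$mean_nonbrain + pseudocount)) |>
    arrange(dplyr::desc(.data$ratio), .data$gene) |>
    mutate(rank = dplyr::row_number())
  class(out) <- c("brain_enrichment", class(out))
  out
}

#' Write a normalized expression matrix as TSV (genes x tissues)
#'
#' Emits the wide layout suitable for external heatmap rendering.
#'
#' @param expr Long tibble with `gene`, `tissue` and the value column.
#' @param path Output path.
#' @param value_col Which column to spread; default `"norm"`.
#' @return The wide tibble, invisibly.
#' @export
write_expression_matrix <- function(expr, path, value_col = "norm") {
  wide <- tidyr::pivot_wider(
    select(expr, "gene", "tissue", dplyr::all_of(value_col)),
    names_from = "tissue", values_from = dplyr::all_of(value_col)
  )
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(wide)
}

#' @describeIn brain_enrichment_rank ggplot of per-gene brain vs non-brain
#'   means, point size by ratio.
#' @param object A `brain_enrichment` tibble.
#' @param ... Unused.
#' @export
autoplot.brain_enrichment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$mean_nonbrain, y = .data$mean_brain,
    size = .data$ratio, label = .data$gene
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Mean expression, non-brain tissues",
                  y = "Mean expression, brain tissues",
                  size = "Brain/non-brain ratio") +
    ggplot2::theme_minimal()
}

#' Heatmap of normalized expression across tissues
#'
#' Tile heatmap (genes x tissues) of the normalized values, brain tissues
#' grouped to the left, in the spirit of the usual GTEx gene-by-tissue
#' displays.
#'
#' @param expr Long tibble with `gene`, `tissue`, `is_brain` and a `norm`
#'   column (run [normalize_expression()] first).
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(expr) {
  if (!"norm" %in% names(expr)) {
    abort("Run normalize_expression() first: 'norm' column missing")
  }
  tissue_order <- expr |>
    distinct(.data$tissue, .data$is_brain) |>
    arrange(dplyr::desc(.data$is_brain), .data$tissue)
  expr <- mutate(expr, tissue = factor(.data$tissue,
                                       levels = tissue_order$tissue))
  ggplot2::ggplot(expr, ggplot2::aes(x = .data$tissue, y = .data$gene,
                                     fill = .data$norm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "10 log10(TPM + 1)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}
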