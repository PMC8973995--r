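#' Normalise gene symbols (RGD convention)
#'
#' Rat gene symbols carry an initial capital with the remainder lower-case.
#'
#' @param genes character vector.
#' @return normalised character vector.
#' @export
normalize_symbols <- function(genes) {
  paste0(
    toupper(substr(genes, 1, 1)),
    tolower(substr(genes, 2, nchar(genes)))
  )
}

#' Hypergeometric gene-set enrichment (EASE / Fisher)
#'
#' For each term with overlap k, list size n, term size K (within the
#' background) and background size N, computes the one-sided hypergeometric
#' upper tail P(overlap >= k). The default `mode = "ease"` is the DAVID-style
#' conservative variant computed with k - 1 in place of k (so singleton
#' overlaps score p = 1). Terms with no overlap are omitted; rows are sorted
#' by p ascending. Benjamini-Hochberg q-values are reported but never used
#' for filtering; the enrichment score is -log10(p).
#'
#' @param gene_list character vector of query genes (subset of background;
#'   genes outside the background are dropped with a warning).
#' @param gene_sets named list of gene vectors (see [read_gmt()]).
#' @param background character vector: the gene universe.
#' @param mode `"ease"` (default) or `"fisher"`.
#' @param namespace optional label column (e.g. `"GO_BP"`, `"KEGG"`).
#' @return tibble (`term`, `namespace`, `k`, `n`, `K`, `N`, `p_value`,
#'   `q_value`, `score`).
#' @export
#' @examples
#' sets <- list(t1 = c("A", "B", "C"), t2 = c("D", "E"))
#' enrich(c("A", "B"), sets, background = LETTERS[1:10], mode = "fisher")
enrich <- function(gene_list, gene_sets, background,
                   mode = c("ease", "fisher"), namespace = NA_character_) {
  mode <- match.arg(mode)
  if (length(gene_list) == 0) stop("empty gene list", call. = FALSE)
  if (length(background) == 0) stop("empty background", call. = FALSE)
  gene_list <- unique(normalize_symbols(gene_list))
  background <- unique(normalize_symbols(background))
  outside <- setdiff(gene_list, background)
  if (length(outside)) {
    warning(
      length(outside), " query gene(s) absent from the background were",
      " dropped", call. = FALSE
    )
    gene_list <- intersect(gene_list, background)
  }
  n <- length(gene_list)
  N <- length(background)
  rows <- purrr::imap(gene_sets, function(members, term) {
    members <- unique(normalize_symbols(members))
    K <- length(intersect(members, background))
    k <- length(intersect(members, gene_list))
    if (k == 0) return(NULL)
    k_eff <- if (mode == "ease") k - 1L else k
    p <- phyper(k_eff - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(
      term = term, namespace = namespace, k = k, n = n, K = K, N = N,
      p_value = p
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      term = character(), namespace = character(), k = integer(),
      n = integer(), K = integer(), N = integer(), p_value = numeric(),
      q_value = numeric(), score = numeric()
    ))
  }
  out |>
    dplyr::mutate(
      q_value = p.adjust(.data$p_value, "BH"),
      score = -log10(.data$p_value)
    ) |>
    dplyr::arrange(.data$p_value, .data$term)
}

#' Bubble-plot-ready top terms
#'
#' Selects the `top_n` most significant terms with the exact quantities a
#' bubble plot encodes: overlap count (bubble size) and -log10 p enrichment
#' score (colour).
#'
#' @param rows an [enrich()] tibble (sorted by p).
#' @param top_n number of rows to keep.
#' @return tibble (`term`, `k`, `score`) plus passthrough columns.
#' @export
bubble_table <- function(rows, top_n = 10L) {
  if (top_n <= 0) stop("top_n must be positive", call. = FALSE)
  head(rows, top_n)
}

#' Enrichment bubble plot
#'
#' @param rows an [enrich()] tibble.
#' @param top_n terms to display.
#' @return a ggplot object.
#' @export
plot_enrichment <- function(rows, top_n = 10L) {
  d <- bubble_table(rows, top_n) |>
    dplyr::mutate(term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(d, ggplot2::aes(
    .data$score, .data$term,
    size = .data$k, colour = .data$score
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "#27ae60", high = "#c0392b") +
    ggplot2::labs(
      x = "enrichment score (-log10 p)", y = NULL,
      size = "genes", colour = "score"
    ) +
    ggplot2::theme_minimal()
}
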