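#' Infer sample groups from column names
#'
#' Samples are assigned to `control`/`treated` by the `_ctrl`/`_trt` header
#' suffix convention used throughout the package.
#'
#' @param mat expression tibble (`feature_id` + sample columns).
#' @return tibble (`sample`, `group`).
#' @export
sample_groups <- function(mat) {
  samples <- setdiff(names(mat), "feature_id")
  group <- dplyr::case_when(
    grepl("_ctrl$", samples) ~ "control",
    grepl("_trt$", samples) ~ "treated",
    TRUE ~ NA_character_
  )
  if (anyNA(group)) {
    stop(
      "cannot infer group for sample(s): ",
      paste(samples[is.na(group)], collapse = ", "),
      "; use the _ctrl/_trt suffix or pass `samples` explicitly",
      call. = FALSE
    )
  }
  tibble::tibble(sample = samples, group = group)
}

#' Counts-per-million normalisation
#'
#' Scales every sample column so it sums to exactly 1e6 (TPM-style total
#' normalisation for equal-length small-RNA features).
#'
#' @param mat expression tibble, `feature_id` first, nonnegative values.
#' @return tibble of the same shape with normalised columns.
#' @export
#' @examples
#' m <- tibble::tibble(feature_id = c("a", "b", "c"), s1_ctrl = c(1, 1, 2))
#' normalize_cpm(m)
normalize_cpm <- function(mat) {
  samples <- setdiff(names(mat), "feature_id")
  for (s in samples) {
    v <- mat[[s]]
    if (any(v < 0)) stop("negative values in sample ", s, call. = FALSE)
    tot <- sum(v)
    if (tot <= 0) stop("sample ", s, " has an all-zero column", call. = FALSE)
    mat[[s]] <- v / tot * 1e6
  }
  mat
}

#' Class-specific fold-change threshold
#'
#' mRNAs are called at fold change >= 2.0 (or <= 0.5); tRF/tiRNAs and miRNAs
#' at a differential multiple of 1.2.
#'
#' @param feature_class one of `"mRNA"`, `"miRNA"`, `"tRF"`.
#' @return numeric threshold.
#' @export
de_threshold <- function(feature_class) {
  if (feature_class == "mRNA") 2.0 else 1.2
}

log_t_p <- function(x, y) {
  # pooled-variance two-sided t on log2(value + 1); degenerate zero-variance
  # inputs fall back to the limiting p-value (1 when means agree, 0 otherwise)
  lx <- log2(x + 1)
  ly <- log2(y + 1)
  out <- tryCatch(
    t.test(ly, lx, var.equal = TRUE)$p.value,
    error = function(e) NA_real_
  )
  if (is.na(out)) out <- if (isTRUE(all.equal(mean(lx), mean(ly)))) 1 else 0
  out
}

#' Two-group differential expression
#'
#' Fold change is the ratio of group means with a pseudocount
#' (`(mean treated + eps) / (mean control + eps)`); the p-value comes from a
#' two-sided pooled-variance t-test on `log2(value + 1)` (the pooled test
#' keeps type-I error calibrated at n = 3, where the Welch-Satterthwaite
#' approximation runs conservative). A feature is `up` when its
#' fold change reaches the class threshold and `p < alpha`, `down` for the
#' reciprocal threshold, otherwise `ns`. No multiple-testing correction is
#' applied to the direction call (matching the raw `P < 0.05` criterion the
#' pipeline targets); BH q-values are reported when `p_adjust = "BH"`.
#'
#' @param mat normalised expression tibble (see [normalize_cpm()]).
#' @param feature_class `"mRNA"`, `"miRNA"` or `"tRF"` (sets the default
#'   threshold).
#' @param fc_threshold override the class threshold.
#' @param alpha significance level on the raw p-value.
#' @param samples optional tibble (`sample`, `group` in control/treated);
#'   inferred from header suffixes when `NULL`.
#' @param pseudocount eps added to both group means before the ratio.
#' @param p_adjust `"none"` or `"BH"` (reported as `q_value`; never used for
#'   the direction call).
#' @return tibble (`feature_id`, `mean_ctrl`, `mean_trt`, `fold_change`,
#'   `log2_fc`, `p_value`, `q_value`, `direction`).
#' @export
de_test <- function(mat, feature_class = "mRNA", fc_threshold = NULL,
                    alpha = 0.05, samples = NULL, pseudocount = 1,
                    p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  samples <- samples %||% sample_groups(mat)
  ctrl_cols <- samples$sample[samples$group == "control"]
  trt_cols <- samples$sample[samples$group == "treated"]
  if (length(ctrl_cols) < 2 || length(trt_cols) < 2) {
    stop("need at least 2 replicates per group", call. = FALSE)
  }
  thr <- fc_threshold %||% de_threshold(feature_class)
  ctrl <- as.matrix(mat[, ctrl_cols])
  trt <- as.matrix(mat[, trt_cols])
  mean_ctrl <- rowMeans(ctrl)
  mean_trt <- rowMeans(trt)
  fc <- (mean_trt + pseudocount) / (mean_ctrl + pseudocount)
  p <- vapply(
    seq_len(nrow(mat)),
    function(i) log_t_p(ctrl[i, ], trt[i, ]),
    numeric(1)
  )
  q <- if (p_adjust == "BH") p.adjust(p, "BH") else rep(NA_real_, length(p))
  tibble::tibble(
    feature_id = mat$feature_id,
    feature_class = feature_class,
    mean_ctrl = mean_ctrl, mean_trt = mean_trt,
    fold_change = fc, log2_fc = log2(fc),
    p_value = p, q_value = q,
    direction = dplyr::case_when(
      fc >= thr & p < alpha ~ "up",
      fc <= 1 / thr & p < alpha ~ "down",
      TRUE ~ "ns"
    )
  )
}

#' Summarise differential-expression calls per class
#'
#' Produces the up/down/total table for one or several feature classes.
#'
#' @param results a [de_test()] tibble, or a named list of them (names used
#'   as class labels when the tibbles lack `feature_class`).
#' @return tibble (`feature_class`, `n_up`, `n_down`, `n_total`), where
#'   `n_total = n_up + n_down`.
#' @export
summarize_de <- function(results) {
  if (inherits(results, "data.frame")) results <- list(results)
  rows <- purrr::imap(results, function(res, nm) {
    cls <- if (is.character(nm) && nzchar(nm)) {
      nm
    } else if ("feature_class" %in% names(res) && nrow(res) > 0) {
      res$feature_class[1]
    } else {
      NA_character_
    }
    tibble::tibble(
      feature_class = cls,
      n_up = sum(res$direction == "up"),
      n_down = sum(res$direction == "down")
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(n_total = .data$n_up + .data$n_down)
}

#' Volcano plot of differential-expression results
#'
#' @param res a [de_test()] tibble.
#' @param alpha significance line.
#' @param fc_threshold fold-change lines (class default when `NULL`).
#' @return a ggplot object.
#' @export
plot_volcano <- function(res, alpha = 0.05, fc_threshold = NULL) {
  thr <- fc_threshold %||% de_threshold(res$feature_class[1] %||% "mRNA")
  ggplot2::ggplot(res, ggplot2::aes(
    .data$log2_fc, -log10(.data$p_value),
    colour = .data$direction
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(
      xintercept = c(-log2(thr), log2(thr)), linetype = "dashed",
      linewidth = 0.3
    ) +
    ggplot2::geom_hline(
      yintercept = -log10(alpha), linetype = "dashed", linewidth = 0.3
    ) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", ns = "grey70")
    ) +
    ggplot2::labs(
      x = "log2 fold change (treated / control)", y = "-log10 p",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
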