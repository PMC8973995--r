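#' Livak 2^-ddCt relative quantification
#'
#' Per sample, dCt = Ct_target - Ct_reference; ddCt subtracts the arithmetic
#' mean dCt of the calibrator group; RQ = 2^-ddCt (amplification efficiency
#' fixed at 2). By construction the geometric mean RQ of the calibrator
#' group is exactly 1.
#'
#' @param ct tibble (`sample`, `group`, `ct_target`, `ct_reference`); Ct
#'   values must lie in (0, 45) and every group needs >= 2 samples.
#' @param calibrator_group calibrator (reference) group label.
#' @return object of class `trf_ddct`: list with `samples` (per-sample
#'   tibble adding `dct`, `ddct`, `rq`), `groups` (per-group mean, SD, n of
#'   RQ) and `calibrator`.
#' @export
#' @examples
#' ct <- simulate_ct_table(ddct_true = 1.5, noise_sd = 0, seed = 1)
#' ddct(ct)$groups
ddct <- function(ct, calibrator_group = "control") {
  required <- c("sample", "group", "ct_target", "ct_reference")
  missing_cols <- setdiff(required, names(ct))
  if (length(missing_cols)) {
    stop("ct table lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  bad_ref <- ct$sample[is.na(ct$ct_reference)]
  if (length(bad_ref)) {
    stop("missing reference Ct for sample(s): ",
      paste(bad_ref, collapse = ", "),
      call. = FALSE
    )
  }
  vals <- c(ct$ct_target, ct$ct_reference)
  if (any(is.na(ct$ct_target)) || any(vals <= 0 | vals >= 45)) {
    stop("Ct values must lie in (0, 45)", call. = FALSE)
  }
  if (!calibrator_group %in% ct$group) {
    stop("calibrator group '", calibrator_group, "' absent", call. = FALSE)
  }
  if (any(table(ct$group) < 2)) {
    stop("every group needs >= 2 samples", call. = FALSE)
  }
  samples <- ct |>
    dplyr::mutate(dct = .data$ct_target - .data$ct_reference)
  cal_mean <- mean(samples$dct[samples$group == calibrator_group])
  samples <- samples |>
    dplyr::mutate(ddct = .data$dct - cal_mean, rq = 2^(-.data$ddct))
  groups <- samples |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(), mean_rq = mean(.data$rq), sd_rq = sd(.data$rq),
      geomean_rq = exp(mean(log(.data$rq))),
      .groups = "drop"
    )
  structure(
    list(samples = samples, groups = groups, calibrator = calibrator_group),
    class = "trf_ddct"
  )
}

#' @export
tidy.trf_ddct <- function(x, ...) x$samples

#' @export
glance.trf_ddct <- function(x, ...) {
  tibble::tibble(
    calibrator = x$calibrator,
    n_samples = nrow(x$samples),
    n_groups = nrow(x$groups)
  )
}

#' @export
print.trf_ddct <- function(x, ...) {
  cat("2^-ddCt quantification (calibrator: ", x$calibrator, ")\n", sep = "")
  print(x$groups)
  invisible(x)
}

#' Group comparison for validation measurements
#'
#' Two groups: two-sided Student t-test (equal variances). More than two:
#' one-way ANOVA followed by Tukey HSD on all pairs, with the ANOVA F row
#' first and one row per pair carrying the Tukey-adjusted p-value.
#'
#' @param data tibble of measurements.
#' @param value name of the value column.
#' @param group name of the group column.
#' @return tibble (`comparison`, `estimate`, `statistic`, `df`, `p_value`,
#'   `method`).
#' @export
#' @examples
#' d <- tibble::tibble(
#'   rq = c(1, 1.1, 0.9, 2, 2.2, 1.9),
#'   group = rep(c("control", "treated"), each = 3)
#' )
#' group_compare(d, "rq", "group")
group_compare <- function(data, value = "rq", group = "group") {
  v <- data[[value]]
  g <- factor(data[[group]])
  counts <- table(g)
  if (length(counts) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(counts < 2)) {
    stop("group(s) with < 2 values: ",
      paste(names(counts)[counts < 2], collapse = ", "),
      call. = FALSE
    )
  }
  if (length(counts) == 2) {
    lv <- levels(g)
    tt <- t.test(v[g == lv[2]], v[g == lv[1]], var.equal = TRUE)
    return(tibble::tibble(
      comparison = paste(lv[2], "-", lv[1]),
      estimate = unname(tt$estimate[1] - tt$estimate[2]),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, method = "Student t"
    ))
  }
  fit <- aov(v ~ g)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  dplyr::bind_rows(
    tibble::tibble(
      comparison = "overall", estimate = NA_real_,
      statistic = an$`F value`[1], df = an$Df[1],
      p_value = an$`Pr(>F)`[1], method = "one-way ANOVA"
    ),
    tibble::tibble(
      comparison = rownames(tk), estimate = tk[, "diff"],
      statistic = NA_real_, df = NA_real_, p_value = tk[, "p adj"],
      method = "Tukey HSD"
    )
  )
}

#' Bar plot of relative quantification by group
#'
#' @param x a `trf_ddct` object.
#' @return a ggplot object.
#' @export
plot_rq <- function(x) {
  ggplot2::ggplot(x$groups, ggplot2::aes(.data$group, .data$mean_rq)) +
    ggplot2::geom_col(fill = "grey75", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_rq - .data$sd_rq,
        ymax = .data$mean_rq + .data$sd_rq
      ),
      width = 0.2
    ) +
    ggplot2::geom_point(
      data = x$samples, ggplot2::aes(.data$group, .data$rq),
      position = ggplot2::position_jitter(width = 0.08), size = 1.5
    ) +
    ggplot2::labs(x = NULL, y = "relative quantity (2^-ddCt)") +
    ggplot2::theme_minimal()
}
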