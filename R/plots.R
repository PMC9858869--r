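#' Divergence-landscape plot
#'
#' Manhattan-style view of per-window FST along the genome, colouring
#' outlier windows and drawing the outlier threshold when present.
#'
#' @param object a `window_scan` tibble (ideally after [outlier_windows()]).
#' @param stat which window statistic to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.window_scan <- function(object, stat = c("fst", "dxy", "pi_a", "pi_b"),
                                 ...) {
  stat <- match.arg(stat)
  df <- tibble::as_tibble(object)
  df <- df[is.finite(df[[stat]]), ]
  df$mid <- (df$start + df$end) / 2
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data[[stat]])) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = stat) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0.1, "lines"),
                   axis.text.x = ggplot2::element_blank())
  if ("outlier" %in% names(df) && stat == "fst") {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$outlier),
                                 size = 0.8) +
      ggplot2::scale_colour_manual(values = c("FALSE" = "grey40",
                                              "TRUE" = "firebrick"))
    thr <- attr(object, "fst_threshold")
    if (!is.null(thr))
      p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                                   colour = "firebrick")
  } else {
    p <- p + ggplot2::geom_point(size = 0.8, colour = "grey40")
  }
  p
}

#' Joint-SFS heatmap
#'
#' @param object a [joint_sfs()].
#' @param log10_scale colour by log10 mass.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.joint_sfs <- function(object, log10_scale = TRUE, ...) {
  df <- tidyr::expand_grid(i = 0:object$projection[1],
                           j = 0:object$projection[2])
  df$mass <- as.numeric(object$counts[as.matrix(df[, c("i", "j")] + 1L)])
  if (log10_scale) df$mass <- log10(df$mass + 1e-12)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$mass)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (log10_scale) "log10 mass"
                                  else "mass") +
    ggplot2::labs(x = "deme B allele count", y = "deme A allele count") +
    ggplot2::theme_minimal()
}

#' LD-decay plot
#'
#' Binned mean r2 against distance with the fitted Hill-Weir curve and the
#' background level.
#'
#' @param object an `ld_decay_fit` from [fit_ld_decay()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ld_decay_fit <- function(object, ...) {
  b <- object$binned
  curve <- tibble::tibble(
    dist = exp(seq(log(max(1, min(b$bin))), log(max(b$bin)),
                   length.out = 400)))
  curve$r2 <- hill_weir_expectation(object$rho_per_bp * curve$dist, object$n)
  ggplot2::ggplot(b, ggplot2::aes(x = .data$bin, y = .data$r2)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$dist,
                                                  y = .data$r2),
                       colour = "firebrick") +
    ggplot2::geom_hline(yintercept = object$background_r2,
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "distance (bp)", y = expression(r^2)) +
    ggplot2::theme_minimal()
}

#' Model-comparison plot
#'
#' Delta-AIC per fitted demographic model.
#'
#' @param object a `demog_comparison` from [compare_models()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.demog_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$model <- factor(df$model, levels = rev(df$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_AIC, y = .data$model)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression(Delta * "AIC"), y = NULL) +
    ggplot2::theme_minimal()
}
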