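#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a profile matrix into long format
#'
#' @param x A `profile_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per feature/bin cell: `feature`, `bin`,
#'   `segment`, `nrc`.
#' @export
tidy.profile_matrix <- function(x, ...) {
  m <- x$values
  tibble(
    feature = rep(x$feature_ids, times = ncol(m)),
    bin = rep(x$bins$bin, each = nrow(m)),
    segment = rep(x$bins$segment, each = nrow(m)),
    nrc = as.vector(m)
  )
}

#' One-row summary of a profile matrix
#'
#' @param x A `profile_matrix`.
#' @param ... Unused.
#' @return Tibble with feature/bin counts, skipped-feature count and the
#'   grand mean NRC.
#' @export
glance.profile_matrix <- function(x, ...) {
  tibble(
    n_features = nrow(x$values),
    n_bins = ncol(x$values),
    n_skipped = x$n_skipped,
    grand_mean_nrc = mean(x$values, na.rm = TRUE)
  )
}

#' Plot the mean profile of a profile matrix
#'
#' @param object A `profile_matrix`.
#' @param ... Unused.
#' @return A ggplot: mean NRC per bin along the 5'->3' axis, with
#'   segment boundaries distinguishable by colour.
#' @export
autoplot.profile_matrix <- function(object, ...) {
  s <- profile_summary(object)
  s$bin <- factor(s$bin, levels = s$bin)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$bin, y = .data$mean_nrc,
    colour = .data$segment, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "bin (5' to 3')", y = "mean NRC (log2)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
      vjust = 0.5, hjust = 1))
}

#' Overlay several profile matrices in one panel
#'
#' @param profiles Named list of `profile_matrix` objects.
#' @return A ggplot with one coloured mean-NRC line per profile.
#' @export
plot_profiles <- function(profiles) {
  df <- bind_rows(purrr::imap(profiles, function(p, nm) {
    if (is.null(p)) return(NULL)
    s <- profile_summary(p)
    s$profile <- nm
    s$index <- seq_len(nrow(s))
    s
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$mean_nrc,
    colour = .data$profile)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "bin index (5' to 3')", y = "mean NRC (log2)") +
    ggplot2::theme_minimal()
}

#' Plot mark levels across gene-value quantiles
#'
#' @param qp Output of [quantile_profile()].
#' @return A ggplot: one line per mark across quantile bins, with the
#'   CGI-promoter percentage drawn as a dashed line on a secondary axis.
#' @export
plot_quantile_profile <- function(qp) {
  mark_cols <- grep("_mean$", names(qp), value = TRUE)
  long <- tidyr::pivot_longer(qp[, c("quantile", mark_cols)],
    -"quantile", names_to = "mark", values_to = "level")
  long$mark <- sub("_mean$", "", long$mark)
  scale <- max(abs(long$level), na.rm = TRUE) / 100
  ggplot2::ggplot(long, ggplot2::aes(x = .data$quantile, y = .data$level,
    colour = .data$mark)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(
      data = qp,
      ggplot2::aes(x = .data$quantile, y = .data$pct_cgi_promoter * scale),
      inherit.aes = FALSE, linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "CGI promoters (%)")
    ) +
    ggplot2::labs(x = "gene-value quantile", y = "mean mark level (log2)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
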