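#' @export
autoplot.overlap_model <- function(object, ...) {
  df <- tidy(object)
  df2 <- dplyr::bind_rows(df,
    dplyr::rename(df, study_a = "study_b", study_b = "study_a"),
    tibble::tibble(study_a = object$study_ids, study_b = object$study_ids,
                   r = 1, n_null = NA_integer_))
  ggplot2::ggplot(df2, ggplot2::aes(.data$study_a, .data$study_b,
                                    fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white",
                                 high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "r",
                  title = "Estimated inter-study correlation of z-statistics")
}

#' @export
autoplot.bottom_line_result <- function(object, ancestry = NULL, ...) {
  anc <- ancestry %||% names(object$per_ancestry)[1]
  s <- object$per_ancestry[[anc]]
  df <- tibble::as_tibble(as.data.frame(s))
  ggplot2::ggplot(df, ggplot2::aes(.data$pos / 1e6, -.data$log10p,
                                   colour = .data$provenance)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(5e-8), linetype = 2) +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)),
                  title = sprintf("Bottom-line associations, %s (%s)",
                                  object$trait, anc))
}

#' Bar chart of replication rates by consensus approach
#'
#' @param report Output of [leave_one_out_validate()] (or a row-bound stack
#'   of such reports).
#' @return A ggplot object.
#' @export
plot_replication <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(.data$approach, .data$rate)) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "steelblue") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "replication rate",
                  title = "Leave-one-out replication by approach")
}

#' Running-sum plot of an enrichment walk
#'
#' @inheritParams enrichment_walk
#' @return A ggplot object.
#' @export
plot_enrichment_walk <- function(ranking, reference) {
  n <- length(ranking)
  k <- length(unique(reference))
  hit <- ranking %in% reference
  walk <- cumsum(ifelse(hit, 1 / k, -1 / (n - k)))
  df <- tibble::tibble(rank = seq_len(n), walk = walk)
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$walk)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "rank", y = "running sum",
                  title = sprintf("Enrichment walk (score %.3f)",
                                  enrichment_walk(ranking, reference)))
}
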