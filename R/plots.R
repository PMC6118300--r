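#' Plot a null distribution with an optional observed value
#'
#' Histogram of the null statistic values; `observed` draws a reference
#' line where the observed statistic falls.
#'
#' @param object A `null_distribution`.
#' @param observed Optional observed statistic value.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.null_distribution <- function(object, observed = NULL, bins = 40,
                                       ...) {
  stat <- attr(object, "statistic") %||% "statistic"
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey35") +
    ggplot2::labs(x = stat, y = "count",
                  title = sprintf("%s null (%d matched values)", stat,
                                  nrow(object))) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "firebrick",
                                 linetype = 2)
  }
  p
}

#' Plot the sweep report's three null comparisons
#'
#' One panel per test (FST, carrier diversity, ROH) with the observed
#' value marked against its simulated null.
#'
#' @param object A `sweep_report`.
#' @param ... Unused.
#' @return A ggplot object (faceted).
#' @export
autoplot.sweep_report <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(test = "FST", value = object$fst_null$value,
           observed = object$obs_fst),
    tibble(test = "carrier pi", value = object$pi_null$value,
           observed = object$pi_member),
    tibble(test = "ROH (bp)", value = object$roh_null$value,
           observed = 2 * mean(object$obs_roh_downstream)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey35") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$observed),
                        colour = "firebrick", linetype = 2) +
    ggplot2::facet_wrap(~test, scales = "free") +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme_minimal()
}

#' LD decay profile of a deletion against flanking SNVs
#'
#' r-squared between the panel's deletion status and every SNV, by
#' position — the diagnostic used to pick target regions that tag a
#' structural variant.
#'
#' @param panel A [hap_panel()] with deletion status.
#' @param pop Optional single population to restrict to.
#' @return A tibble with `position` and `r2`.
#' @export
deletion_ld_profile <- function(panel, pop = NULL) {
  keep <- if (is.null(pop)) rep(TRUE, n_hap(panel)) else panel$pop == pop
  del <- panel$deletion[keep]
  if (is.null(del)) abort("panel has no deletion status.")
  r2 <- vapply(seq_len(n_sites(panel)), function(j) {
    r_squared(del, panel$alleles[keep, j])
  }, numeric(1))
  tibble(position = panel$positions, r2 = r2)
}

#' @rdname deletion_ld_profile
#' @param profile Output of `deletion_ld_profile()`.
#' @export
plot_deletion_ld <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$position, y = .data$r2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "position (bp)", y = expression(r^2)) +
    ggplot2::theme_minimal()
}
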