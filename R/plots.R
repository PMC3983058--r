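#' Plot an ensemble's radius-of-gyration histogram
#'
#' Histogram of per-conformer R_Gyr with the peak (solid blue), mean (solid
#' red), median (dashed red) and the FWHM bounds (dotted blue) marked.
#'
#' @param object A `conformer_ensemble`.
#' @param histogram_bin Bin width in Angstrom.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot conformer_ensemble
#' @export
autoplot.conformer_ensemble <- function(object, histogram_bin = 2, ...) {
  s <- ensemble_summary(object$rgyr, histogram_bin)
  df <- tibble::tibble(rgyr = object$rgyr)
  half <- s$fwhm / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rgyr)) +
    ggplot2::geom_histogram(binwidth = histogram_bin, fill = "grey80",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = s$peak, colour = "blue") +
    ggplot2::geom_vline(xintercept = s$mean, colour = "red") +
    ggplot2::geom_vline(xintercept = s$median, colour = "red",
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(s$peak - half, s$peak + half),
                        colour = "blue", linetype = "dotted") +
    ggplot2::labs(
      x = expression(R[Gyr] ~ "(Å)"), y = "conformers",
      title = sprintf("%s ensemble (n = %d)", object$preset, object$n),
      subtitle = sprintf("peak %.1f, mean %.1f, median %.1f, FWHM %.1f Å",
                         s$peak, s$mean, s$median, s$fwhm)
    ) +
    ggplot2::theme_minimal()
}

#' Plot secondary-structure content against ensemble size
#'
#' Relative frequency of PPII, alpha and beta conformations per R_Gyr bin.
#'
#' @param object An `ss_content_profile` from [ss_content_by_rgyr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ss_content_profile
#' @export
autoplot.ss_content_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as.data.frame(object)[, c("bin_mid", "f_ppii", "f_alpha", "f_beta")],
    -"bin_mid", names_to = "state", values_to = "frequency"
  )
  long$state <- factor(long$state, c("f_ppii", "f_alpha", "f_beta"),
                       c("PPII", "alpha", "beta"))
  ggplot2::ggplot(long, ggplot2::aes(.data$bin_mid, .data$frequency,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(PPII = "blue", alpha = "red",
                                            beta = "darkgreen")) +
    ggplot2::labs(x = expression(R[Gyr] ~ "bin (Å)"),
                  y = "relative frequency", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a force-extension trace with detected events
#'
#' @param object A `force_extension_trace`.
#' @param events Optional `wlc_events` tibble; peaks are marked when given.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot force_extension_trace
#' @export
autoplot.force_extension_trace <- function(object, events = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$extension, .data$force)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "extension (nm)", y = "force (pN)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(extension = events$peak_extension,
                            force = events$peak_force),
      colour = "red", shape = 4, size = 3
    )
  }
  p
}

#' Plot the disorder-consensus tier profile
#'
#' Per-residue vote fraction colored by tier, mirroring the four-color
#' rendering of consensus disorder predictions.
#'
#' @param object A `disorder_consensus`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot disorder_consensus
#' @export
autoplot.disorder_consensus <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$position, .data$vote_fraction,
                                       fill = .data$tier)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(
      less = "black", intermediate = "purple",
      disordered = "orange", extensive = "red"
    ), drop = FALSE) +
    ggplot2::labs(x = "residue", y = "fraction of programs calling disorder",
                  fill = "tier") +
    ggplot2::theme_minimal()
}
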