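#' Plot an axial slice of a volume
#'
#' Renders one axial slice of a scalar map (raster) or mask (filled
#' region), with optional mask contours overlaid — the working view for
#' checking fold maps, segmentations and dose against target volumes.
#'
#' @param v A [scalar_map()] or [smri_mask()].
#' @param k Slice index (1-based along the third axis); defaults to the
#'   slice with the most signal/membership.
#' @param overlays Optional named list of [smri_mask()]s drawn as contours.
#' @return A ggplot object.
#' @export
plot_slice <- function(v, k = NULL, overlays = list()) {
  g <- grid_of(v)
  if (is.null(k)) {
    w <- if (inherits(v, "smri_mask")) {
      apply(v$membership, 3, sum)
    } else {
      apply(v$values, 3, function(s) sum(abs(s), na.rm = TRUE))
    }
    k <- which.max(w)
  }
  xs <- grid_axis_mm(g, 1); ys <- grid_axis_mm(g, 2)
  df <- expand.grid(x = xs, y = ys)
  if (inherits(v, "smri_mask")) {
    df$value <- as.numeric(v$membership[, , k])
    lab <- v$label
  } else {
    df$value <- as.numeric(v$values[, , k])
    lab <- v$unit
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20", name = lab) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("axial slice %d (z = %.1f mm)", k,
                                  grid_axis_mm(g, 3)[k]))
  for (nm in names(overlays)) {
    m <- overlays[[nm]]
    if (!same_grid(grid_of(m), g)) next
    sl <- m$membership[, , k]
    if (!any(sl)) next
    dd <- expand.grid(x = xs, y = ys)
    dd$z <- as.numeric(sl)
    p <- p + ggplot2::geom_contour(
      data = dd, ggplot2::aes(x = .data$x, y = .data$y, z = .data$z),
      breaks = 0.5, colour = "white", inherit.aes = FALSE)
  }
  p
}

#' Plot cohort summaries
#'
#' Boxplots of the headline per-threshold quantities of a cohort run:
#' percent CTV2 volume increase, Dice overlap with CTV2, percent
#' abnormality beyond the 60 Gy isodose region, and recurrence coverage by
#' conventional vs sMRI target volumes.
#'
#' @param object A `smrirt_cohort` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smrirt_cohort <- function(object, ...) {
  rec <- dplyr::filter(object$records, .data$plan == "sMRI")
  long <- dplyr::bind_rows(
    tibble::tibble(threshold = rec$threshold, metric = "CTV2 volume increase (%)",
                   value = rec$pct_increase_ctv2),
    tibble::tibble(threshold = rec$threshold, metric = "Dice vs CTV2",
                   value = rec$dice_ctv2),
    tibble::tibble(threshold = rec$threshold,
                   metric = "Abnormality beyond 60 Gy IDL (%)",
                   value = rec$seg_outside_idl2_pct),
    tibble::tibble(threshold = rec$threshold,
                   metric = "Recurrence coverage, sMRI_CTV2 (%)",
                   value = rec$rec_coverage_smri_ctv2_pct)
  )
  long <- dplyr::filter(long, !is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$threshold),
                                     y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Cho/NAA fold threshold", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
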