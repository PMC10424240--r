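# Decomposition of apparent line widths (alw) into field-independent and
# field-dependent Gaussian parts and the ppm strain slope.
#
# Two independent Gaussian broadening mechanisms convolve, so their FWHMs
# add in quadrature:  alw^2 = lw0^2 + lw_fd(nu)^2.  The field-dependent part
# of the x-axis width grows linearly with microwave frequency when it is
# caused by a distribution of g-values (g-strain); the through-origin slope
# of lw_fd versus frequency, expressed in parts per million, is the scalar
# g-strain metric.

#' Field-dependent component of an apparent line width
#'
#' Inverts the quadrature combination `alw^2 = lw0^2 + lw_fd^2`. When the
#' apparent width falls below the field-independent floor (possible through
#' fit noise), the component is clamped to zero and flagged.
#'
#' @param alw apparent FWHM line width(s), MHz, >= 0.
#' @param lw0 field-independent FWHM, MHz, >= 0.
#' @return A data.frame with columns `lw_fd` (MHz) and `clamped` (logical).
#' @examples
#' field_dependent_width(52, 17) # sqrt(52^2 - 17^2) = 49.14 MHz
#' @export
field_dependent_width <- function(alw, lw0) {
  if (any(alw < 0) || any(lw0 < 0)) {
    stop("line widths must be non-negative", call. = FALSE)
  }
  clamped <- alw < lw0
  lw_fd <- ifelse(clamped, 0, suppressWarnings(sqrt(alw^2 - lw0^2)))
  data.frame(lw_fd = lw_fd, clamped = clamped)
}

#' Population-weighted mean of per-component line widths
#'
#' Used to collapse the per-component apparent widths of a multicomponent
#' fit into one width per band before the strain regression.
#'
#' @param values per-component widths, MHz.
#' @param weights component weights, summing to 1.
#' @return weighted mean, MHz.
#' @examples
#' weighted_alw(c(40, 37), c(0.69, 0.31)) # 39.07
#' @export
weighted_alw <- function(values, weights) {
  stopifnot(length(values) == length(weights))
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("weights must sum to 1", call. = FALSE)
  }
  sum(values * weights)
}

#' g-strain slope from apparent line widths versus frequency
#'
#' Removes the field-independent floor `lw0` in quadrature from each
#' apparent width, then fits a straight line through the origin to the
#' field-dependent widths versus microwave frequency. With width and
#' frequency in the same unit the slope is dimensionless; it is reported in
#' parts per million. Clamped points (alw < lw0) are excluded from the
#' regression and flagged.
#'
#' By default only the two highest bands (W, J; >= 90 GHz) enter the
#' regression: at lower frequencies the apparent width is dominated by the
#' field-independent floor and carries no slope information. The origin is
#' part of the model (through-origin fit), so the slope is
#' \eqn{s = \sum_i \nu_i w_i / \sum_i \nu_i^2}.
#'
#' @param frequency_GHz band frequencies, GHz (positive, distinct).
#' @param alw apparent widths at those bands, MHz.
#' @param lw0 field-independent FWHM, MHz. Defaults to 17, the floor used
#'   when synthesizing theoretical ensemble spectra; supply the
#'   experimentally estimated floor for measured series.
#' @param bands_used logical or index vector selecting the bands to regress
#'   (default: frequencies >= 90 GHz).
#' @return An object of class `strain_result`: a list with `slope_ppm`,
#'   `lw0`, and a data.frame `points` (frequency, alw, lw_fd, clamped,
#'   used).
#' @examples
#' strain_slope(c(93.993, 262.8436), c(24, 52), lw0 = 17) # 186 ppm
#' @export
strain_slope <- function(frequency_GHz, alw, lw0 = 17, bands_used = NULL) {
  stopifnot(length(frequency_GHz) == length(alw))
  if (any(frequency_GHz <= 0) || anyDuplicated(frequency_GHz)) {
    stop("frequencies must be positive and distinct", call. = FALSE)
  }
  if (is.null(bands_used)) bands_used <- frequency_GHz >= 90
  used <- rep(FALSE, length(frequency_GHz))
  used[bands_used] <- TRUE
  if (!any(used)) stop("no bands selected for the regression", call. = FALSE)
  fd <- field_dependent_width(alw, lw0)
  keep <- used & !fd$clamped
  pts <- data.frame(frequency_GHz = frequency_GHz, alw_MHz = alw,
                    lw_fd_MHz = fd$lw_fd, clamped = fd$clamped, used = keep)
  if (!any(keep)) stop("all selected bands are clamped below lw0",
                       call. = FALSE)
  # identical units: lw in MHz = 1e-3 GHz; slope * 1e6 -> ppm
  nu <- frequency_GHz[keep]
  w <- fd$lw_fd[keep] * 1e-3
  slope <- sum(nu * w) / sum(nu^2)
  structure(list(slope_ppm = slope * 1e6, lw0 = lw0, points = pts),
            class = "strain_result")
}

#' @export
print.strain_result <- function(x, ...) {
  cat(sprintf("<strain_result> slope = %.1f ppm (lw0 = %g MHz)\n",
              x$slope_ppm, x$lw0))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Strain slopes for every series of an apparent-line-width table
#'
#' Convenience wrapper running [strain_slope()] per series of a long-format
#' line width table (see [read_alw_table()]), taking population-weighted
#' means across components where a series has several.
#'
#' @param alw_table data.frame with columns `series`, `band`,
#'   `frequency_GHz`, one of `alw_xx`/`alw_yy`/`alw_zz`, and optionally
#'   `component` and `weight`.
#' @param axis which molecular axis to analyze, `"xx"`, `"yy"` or `"zz"`.
#' @param lw0 field-independent floor, MHz.
#' @param bands bands to regress on (character, matched against `band`),
#'   default W and J.
#' @return A data.frame with columns `series` and `slope_ppm`.
#' @export
strain_slopes_by_series <- function(alw_table, axis = "xx", lw0 = 17,
                                    bands = c("W", "J")) {
  col <- paste0("alw_", axis)
  stopifnot(col %in% names(alw_table))
  out <- lapply(split(alw_table, alw_table$series), function(d) {
    agg <- lapply(split(d, d$band), function(b) {
      w <- if (!is.null(b$weight) && !anyNA(b$weight) && nrow(b) > 1) {
        b$weight / sum(b$weight)
      } else rep(1 / nrow(b), nrow(b))
      data.frame(band = b$band[1], frequency_GHz = b$frequency_GHz[1],
                 alw = weighted_alw(b[[col]], w))
    })
    agg <- do.call(rbind, agg)
    agg <- agg[!is.na(agg$alw), ]
    sel <- agg$band %in% bands
    # a series may have no usable (non-missing, unclamped) point on an axis
    slope <- if (!any(sel)) NA_real_ else
      tryCatch(strain_slope(agg$frequency_GHz, agg$alw, lw0 = lw0,
                            bands_used = sel)$slope_ppm,
               error = function(e) NA_real_)
    data.frame(series = d$series[1], slope_ppm = slope)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
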