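#' Define a nitroxide spin system
#'
#' A spin system is one electron spin S = 1/2 coupled to a single \eqn{^{14}}N
#' nucleus (I = 1) through collinear g- and hyperfine tensors, the standard
#' high-field description of a nitroxide spin probe. Principal values are
#' given in the molecular (N-O) frame.
#'
#' @param g numeric length-3, principal g-values (g_xx, g_yy, g_zz),
#'   dimensionless. Each must lie in (1.5, 2.5), the physically sensible
#'   range for nitroxides.
#' @param A numeric length-3, principal hyperfine values (A_xx, A_yy, A_zz)
#'   in MHz. May be negative (sign does not affect resonance positions at
#'   the fields treated here).
#' @return An object of class `spin_system`.
#' @examples
#' sys <- spin_system(g = c(2.00834, 2.00598, 2.0023), A = c(14, 14, 100))
#' @export
spin_system <- function(g, A = c(0, 0, 0)) {
  g <- as.numeric(g)
  A <- as.numeric(A)
  if (length(g) == 1) g <- rep(g, 3)
  if (length(A) == 1) A <- rep(A, 3)
  if (length(g) != 3 || anyNA(g) || any(!is.finite(g))) {
    stop("`g` must be three finite principal values", call. = FALSE)
  }
  if (any(g <= 1.5 | g >= 2.5)) {
    stop("principal g-values outside the nitroxide range (1.5, 2.5): ",
         paste(format(g[g <= 1.5 | g >= 2.5]), collapse = ", "),
         call. = FALSE)
  }
  if (length(A) != 3 || anyNA(A) || any(!is.finite(A))) {
    stop("`A` must be three finite principal values in MHz", call. = FALSE)
  }
  structure(list(g = g, A = A, I = 1), class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat("<spin_system>  S = 1/2, I =", x$I, "\n")
  cat("  g:", format(x$g, digits = 7), "\n")
  cat("  A:", format(x$A), "MHz\n")
  invisible(x)
}

#' Anisotropic Gaussian line-width specification
#'
#' Full-width-at-half-maximum Gaussian broadenings, in MHz, along the three
#' molecular axes (the convention of EasySpin's `HStrain`). A single value
#' gives an isotropic width.
#'
#' @param fwhm numeric length 1 (isotropic) or 3, FWHM values in MHz, >= 0.
#' @return An object of class `linewidth_spec`.
#' @examples
#' linewidth_spec(17)            # isotropic 17 MHz
#' linewidth_spec(c(52, 28, 25)) # anisotropic
#' @export
linewidth_spec <- function(fwhm) {
  fwhm <- as.numeric(fwhm)
  if (length(fwhm) == 1) fwhm <- rep(fwhm, 3)
  if (length(fwhm) != 3 || anyNA(fwhm) || any(fwhm < 0)) {
    stop("line widths must be 1 or 3 non-negative FWHM values in MHz",
         call. = FALSE)
  }
  structure(list(fwhm = fwhm), class = "linewidth_spec")
}

as_linewidth_spec <- function(x) {
  if (inherits(x, "linewidth_spec")) x else linewidth_spec(x)
}

#' Orientation(s) of the static field in the molecular frame
#'
#' @param n numeric length-3 vector or n-by-3 matrix of direction cosines of
#'   the static field B0 in the molecular frame; each row is normalized to
#'   unit length.
#' @param weight quadrature weights, recycled to the number of orientations.
#' @return An object of class `orientation_grid` with elements `n` (matrix)
#'   and `weight`.
#' @export
orientation <- function(n, weight = NULL) {
  if (is.null(dim(n))) n <- matrix(as.numeric(n), nrow = 1)
  n <- as.matrix(n)
  if (ncol(n) != 3 || anyNA(n)) stop("orientations must be n x 3", call. = FALSE)
  len <- sqrt(rowSums(n^2))
  if (any(len == 0)) stop("zero orientation vector", call. = FALSE)
  n <- n / len
  if (is.null(weight)) weight <- rep(1 / nrow(n), nrow(n))
  weight <- rep_len(as.numeric(weight), nrow(n))
  structure(list(n = n, weight = weight), class = "orientation_grid")
}

#' Equal-area orientation grid over one octant
#'
#' Orientational quadrature for powder averaging of a system with collinear
#' orthorhombic tensors: the spectrum is invariant under inversion of any
#' molecular axis, so one octant suffices. Knots are midpoints of a uniform
#' grid in (cos(theta), phi), which makes every knot carry the same surface
#' area; weights sum to 1.
#'
#' @param grid_size knots per dimension; the grid has `grid_size^2`
#'   orientations.
#' @return An `orientation_grid`.
#' @export
octant_grid <- function(grid_size = 30) {
  stopifnot(grid_size >= 1)
  u <- (seq_len(grid_size) - 0.5) / grid_size          # cos(theta) in (0,1)
  phi <- (seq_len(grid_size) - 0.5) / grid_size * pi / 2
  g <- expand.grid(u = u, phi = phi)
  st <- sqrt(1 - g$u^2)
  orientation(cbind(st * cos(g$phi), st * sin(g$phi), g$u))
}

#' Effective g-value along a field direction
#'
#' For collinear principal frames the resonance position is governed by
#' \eqn{g_{eff}(n) = \sqrt{g_{xx}^2 n_x^2 + g_{yy}^2 n_y^2 + g_{zz}^2 n_z^2}}.
#'
#' @param system a [spin_system()].
#' @param orientation an [orientation()] object (or vector/matrix accepted by
#'   it).
#' @return numeric vector of effective g-values, one per orientation.
#' @export
effective_g <- function(system, orientation) {
  stopifnot(inherits(system, "spin_system"))
  o <- if (inherits(orientation, "orientation_grid")) orientation
       else orientation(orientation)
  sqrt(o$n^2 %*% system$g^2)[, 1]
}

# Effective hyperfine along n: A_eff^2 = sum g_i^2 A_i^2 n_i^2 / g_eff^2
effective_A <- function(system, o, g_eff = NULL) {
  if (is.null(g_eff)) g_eff <- effective_g(system, o)
  sqrt((o$n^2 %*% (system$g^2 * system$A^2))[, 1]) / g_eff
}

#' Resonance fields of the three nitrogen hyperfine lines
#'
#' Solves the fixed-frequency resonance condition for the three
#' \eqn{\Delta m_S = \pm 1, \Delta m_I = 0} transitions of the S = 1/2,
#' I = 1 spin Hamiltonian (electron Zeeman + hyperfine; nuclear Zeeman and
#' quadrupole omitted, as they are unresolved in frozen nitroxide spectra).
#'
#' The default solver diagonalizes the 6-dimensional Hamiltonian numerically
#' and brackets each transition in field by bisection. A first-order
#' closed form,
#' \deqn{B(m_I) = \frac{h(\nu - m_I A_{eff})}{g_{eff}\,\mu_B},}
#' with \eqn{A_{eff}^2 = \sum_i g_i^2 A_i^2 n_i^2 / g_{eff}^2}, is available
#' as `solver = "first_order"` and serves as an independent cross-check of
#' the exact solver.
#'
#' @param system a [spin_system()].
#' @param orientation an [orientation()] (possibly many rows).
#' @param frequency microwave frequency in GHz (> 0).
#' @param solver `"exact"` (matrix diagonalization + bisection) or
#'   `"first_order"`.
#' @param tol_mT bisection tolerance for the exact solver, mT.
#' @param amplitudes if `TRUE`, return exact transition moments as weights;
#'   by default the three lines carry equal weight (the high-field nitroxide
#'   regime).
#' @return A list with `fields` (n-by-3 matrix, mT; columns ordered from the
#'   m_I = +1 line at low field to m_I = -1 at high field for positive
#'   A_eff) and `amplitudes` (n-by-3, rows summing to 1).
#' @export
resonance_lines <- function(system, orientation, frequency,
                            solver = c("exact", "first_order"),
                            tol_mT = 1e-4, amplitudes = FALSE) {
  stopifnot(inherits(system, "spin_system"), frequency > 0)
  solver <- match.arg(solver)
  o <- if (inherits(orientation, "orientation_grid")) orientation
       else orientation(orientation)

  if (solver == "first_order") {
    g_eff <- effective_g(system, o)
    A_eff <- effective_A(system, o, g_eff)
    nu_MHz <- frequency * 1e3
    fields <- vapply(c(1, 0, -1), function(mI) {
      (nu_MHz - mI * A_eff) / (g_eff * epr_constants$mhz_per_mt)
    }, numeric(nrow(o$n)))
    fields <- matrix(fields, ncol = 3)
    amp <- matrix(1 / 3, nrow(fields), 3)
    return(list(fields = fields, amplitudes = amp))
  }

  # search window bracketing all nitroxide g-values, widened by the maximal
  # hyperfine offset
  margin <- mhz_to_mt(max(abs(system$A)) + 1, 2.5)
  B_lo <- max(field_from_freq(frequency, 2.5) - margin, 1e-3)
  B_hi <- field_from_freq(frequency, 1.5) + margin
  res <- .resfields_exact(system$g, system$A, o$n, frequency * 1e3,
                          B_lo, B_hi, tol_mT)
  # branches are sorted by transition frequency at fixed field; higher
  # frequency branch resonates at lower field, so flip to match the
  # first-order column order (low field first)
  fields <- res$fields[, 3:1, drop = FALSE]
  amp <- res$amplitudes[, 3:1, drop = FALSE]
  amp <- if (amplitudes) amp / rowSums(amp) else
    matrix(1 / 3, nrow(fields), 3)
  list(fields = fields, amplitudes = amp)
}

#' Convert an anisotropic line width to a field-domain FWHM
#'
#' The frequency-domain Gaussian FWHM along a field direction n is
#' \eqn{\Gamma(n) = \sqrt{n_x^2\Gamma_x^2 + n_y^2\Gamma_y^2 +
#' n_z^2\Gamma_z^2}} (MHz); conversion to field units uses the factor
#' \eqn{h/(g_{eff}\mu_B)}.
#'
#' @param lw a [linewidth_spec()] (or numeric accepted by it).
#' @param orientation an [orientation()].
#' @param g_eff effective g-value(s) at those orientations (> 0).
#' @return FWHM in mT, one value per orientation.
#' @export
linewidth_in_field <- function(lw, orientation, g_eff) {
  lw <- as_linewidth_spec(lw)
  o <- if (inherits(orientation, "orientation_grid")) orientation
       else orientation(orientation)
  stopifnot(all(g_eff > 0))
  gamma <- sqrt(o$n^2 %*% lw$fwhm^2)[, 1]
  mhz_to_mt(gamma, g_eff)
}
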