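# Ensemble spectrum synthesis: per-snapshot simulation, normalized summation
# ("theoretical spectrum"), and H-bond subensemble mean-parameter components.

#' Validate a snapshot EPR parameter table
#'
#' The snapshot table is the interchange schema between the trajectory /
#' quantum-chemistry side (out of scope here) and the spectral pipeline: one
#' row per trajectory frame with principal g- and A-values and an optional
#' H-bond count label.
#'
#' @param x a data.frame with columns `id`, `gxx`, `gyy`, `gzz`, `Axx_MHz`,
#'   `Ayy_MHz`, `Azz_MHz`, optionally `time_fs` and `n_hbonds`.
#' @return The validated data.frame (invisibly classed `snapshot_table`).
#' @export
snapshot_table <- function(x) {
  need <- c("id", "gxx", "gyy", "gzz", "Axx_MHz", "Ayy_MHz", "Azz_MHz")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("snapshot table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- c(need[-1], intersect("time_fs", names(x)))
  for (cl in num) {
    v <- x[[cl]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
      stop(sprintf("non-numeric or non-finite values in column '%s' (rows %s)",
                   cl, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  gs <- as.matrix(x[c("gxx", "gyy", "gzz")])
  if (any(gs <= 1.5 | gs >= 2.5)) {
    stop("g-values outside the nitroxide range (1.5, 2.5) in rows ",
         paste(utils::head(which(rowSums(gs <= 1.5 | gs >= 2.5) > 0), 5),
               collapse = ", "), call. = FALSE)
  }
  if ("n_hbonds" %in% names(x)) {
    h <- x$n_hbonds
    if (any(!is.na(h) & (h < 0 | h != round(h) | h > 4))) {
      stop("n_hbonds labels must be integers in 0..4", call. = FALSE)
    }
  }
  class(x) <- unique(c("snapshot_table", class(x)))
  x
}

snapshot_system <- function(row) {
  spin_system(c(row$gxx, row$gyy, row$gzz),
              c(row$Axx_MHz, row$Ayy_MHz, row$Azz_MHz))
}

#' Ensemble ("theoretical") spectrum from per-snapshot EPR parameters
#'
#' Simulates one powder spectrum per snapshot on a common field axis and
#' returns the normalized sum — the theoretical counterpart of a measured cw
#' spectrum for an ensemble whose g/A values scatter from frame to frame.
#' The default line width is the isotropic 17 MHz Gaussian that stands in
#' for all field-independent broadening, so that any frequency dependence of
#' the resulting apparent widths reflects the g-value scatter alone.
#'
#' @param snapshots a [snapshot_table()] (or coercible data.frame).
#' @param frequency microwave frequency in GHz.
#' @param lw a [linewidth_spec()] or numeric FWHM in MHz (default 17).
#' @param field_range,n_points,grid_size,solver as in [powder_spectrum()];
#'   the orientation grid geometry is computed once and shared across all
#'   snapshots, and the per-band default density matches
#'   [default_grid_size()] so that ensemble and fitted model spectra are
#'   orientationally converged to the same level.
#' @return An [epr_spectrum()] (absorption, unit area).
#' @export
theoretical_spectrum <- function(snapshots, frequency, lw = linewidth_spec(17),
                                 field_range = NULL, n_points = 1024,
                                 grid_size = NULL,
                                 solver = c("first_order", "exact")) {
  solver <- match.arg(solver)
  if (is.null(grid_size)) grid_size <- default_grid_size(frequency)
  snapshots <- snapshot_table(as.data.frame(snapshots))
  if (nrow(snapshots) == 0) stop("empty snapshot list", call. = FALSE)
  lw <- as_linewidth_spec(lw)
  systems <- lapply(seq_len(nrow(snapshots)),
                    function(i) snapshot_system(snapshots[i, ]))
  if (is.null(field_range)) {
    field_range <- auto_field_range(systems, frequency, lw)
  }
  grid <- octant_grid(grid_size)
  axis <- seq(field_range[1], field_range[2], length.out = n_points)
  dx <- axis[2] - axis[1]
  # accumulate width-class stick histograms across all snapshots, then
  # convolve once: the per-snapshot cost is a binning pass, so thousands of
  # snapshots on dense orientation grids stay cheap
  cls <- NULL
  sticks <- NULL
  for (s in systems) {
    ln <- powder_lines(s, lw, frequency, grid, solver, amplitudes = FALSE)
    sg <- pmax(ln$sigma, dx / 2)
    if (is.null(cls)) {
      lo <- min(sg) * 0.98
      hi <- max(sg) * 1.02
      cls <- if (hi - lo < 1e-12 * hi) lo else seq(lo, hi, length.out = 16)
    }
    st <- .class_sticks(axis, ln$centers, sg, ln$weights, cls)
    sticks <- if (is.null(sticks)) st else sticks + st
  }
  total <- convolve_classes(sticks, cls, axis)
  normalize_area(epr_spectrum(axis, total / length(systems), frequency))
}

#' Mean EPR parameters per H-bond subensemble
#'
#' Groups labeled snapshots by H-bond count and returns the arithmetic mean
#' g- and A-values of each subensemble together with its population weight
#' (label frequency). These summaries define the spectral components from
#' which multicomponent fits of the ensemble spectrum are seeded.
#'
#' @param snapshots a [snapshot_table()] with an `n_hbonds` column.
#' @return A data.frame with columns `n_hbonds`, `weight`, `n`, `gxx`,
#'   `gyy`, `gzz`, `Axx_MHz`, `Ayy_MHz`, `Azz_MHz`, ordered by `n_hbonds`.
#' @export
subensemble_means <- function(snapshots) {
  snapshots <- snapshot_table(as.data.frame(snapshots))
  if (!"n_hbonds" %in% names(snapshots) || anyNA(snapshots$n_hbonds)) {
    stop(paste("snapshots lack H-bond labels; classify the trajectory first",
               "(see count_hbonds()/label_snapshots())"), call. = FALSE)
  }
  cols <- c("gxx", "gyy", "gzz", "Axx_MHz", "Ayy_MHz", "Azz_MHz")
  sp <- split(snapshots, snapshots$n_hbonds)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(n_hbonds = d$n_hbonds[1], weight = nrow(d) / nrow(snapshots),
               n = nrow(d), as.list(colMeans(d[cols])))
  }))
  rownames(out) <- NULL
  out[order(out$n_hbonds), ]
}

#' Weighted multicomponent spectrum from subensemble summaries
#'
#' Simulates one powder spectrum per subensemble (at its mean g/A values)
#' and combines them with the population weights. Component traces are
#' returned alongside the total for overlay plots.
#'
#' @param summaries output of [subensemble_means()] (columns `weight`,
#'   `gxx`..`Azz_MHz`; weights must sum to 1).
#' @param frequency microwave frequency in GHz.
#' @param lw line width (default isotropic 17 MHz).
#' @param field_range,n_points,grid_size,solver as in
#'   [theoretical_spectrum()].
#' @return A list with `spectrum` (the weighted sum, unit area) and
#'   `components` (list of unit-area `epr_spectrum` objects on the same
#'   axis).
#' @export
tcomp_spectrum <- function(summaries, frequency, lw = linewidth_spec(17),
                           field_range = NULL, n_points = 1024,
                           grid_size = NULL,
                           solver = c("first_order", "exact")) {
  solver <- match.arg(solver)
  if (is.null(grid_size)) grid_size <- default_grid_size(frequency)
  lw <- as_linewidth_spec(lw)
  w <- summaries$weight
  if (abs(sum(w) - 1) > 1e-8) {
    stop("subensemble weights must sum to 1", call. = FALSE)
  }
  systems <- lapply(seq_len(nrow(summaries)),
                    function(i) snapshot_system(summaries[i, ]))
  if (is.null(field_range)) {
    field_range <- auto_field_range(systems, frequency, lw)
  }
  axis <- seq(field_range[1], field_range[2], length.out = n_points)
  grid <- octant_grid(grid_size)
  comps <- lapply(systems, function(s) {
    ln <- powder_lines(s, lw, frequency, grid, solver, amplitudes = FALSE)
    normalize_area(epr_spectrum(
      axis, accumulate_lines(axis, ln$centers, ln$sigma, ln$weights),
      frequency))
  })
  total <- Reduce(`+`, Map(function(sp, wi) sp$intensity * wi, comps, w))
  list(spectrum = normalize_area(epr_spectrum(axis, total, frequency)),
       components = comps)
}
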