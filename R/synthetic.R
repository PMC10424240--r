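# Synthetic-data generators: labeled snapshot ensembles with controlled
# subensemble structure and g-scatter, toy solvation trajectories with
# prescribed H-bond populations, and noisy pseudo-experimental spectra.
#
# The generators define the study conditions of the analysis: subensemble
# means and weights default to the solvated QM/MM values (two components at
# 0.69/0.31), and the snapshot-to-snapshot g_xx scatter defaults to the
# value whose frequency-proportional broadening corresponds to a 376 ppm
# strain slope.

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Gaussian g-scatter corresponding to a target strain slope
#'
#' A Gaussian distribution of a g-value with standard deviation
#' \eqn{\sigma_g} broadens the resonance frequency at fixed field by a FWHM
#' of \eqn{2\sqrt{2\ln 2}\,\sigma_g\,\nu/g}; the field-dependent width
#' therefore grows with frequency at a rate of
#' \eqn{2\sqrt{2\ln 2}\,\sigma_g/g} (dimensionless, i.e. ppm when scaled by
#' 1e6). Inverting gives the scatter to use when emulating a known slope:
#' \deqn{\sigma_g = \mathrm{slope} \times 10^{-6} \; g_{ref} / (2\sqrt{2\ln 2}).}
#'
#' @param target_slope_ppm desired strain slope, ppm (>= 0).
#' @param g_ref reference g-value (the mean of the scattered axis).
#' @return standard deviation of the g-value (dimensionless).
#' @examples
#' sigma_from_slope(376, 2.008) # about 3.2e-4
#' @export
sigma_from_slope <- function(target_slope_ppm, g_ref) {
  stopifnot(target_slope_ppm >= 0, g_ref > 0)
  target_slope_ppm * 1e-6 * g_ref * FWHM_TO_SIGMA
}

#' Per-axis strain slopes of the reference solvated ensemble
#'
#' Through-origin ppm slopes of the field-dependent width versus frequency
#' for each molecular axis, computed from the packaged per-band apparent
#' line widths of the solvated (explicit solvation) ensemble via
#' [strain_slopes_by_series()]. These are the default study conditions of
#' the snapshot generator: the g-scatter of a solvated nitroxide broadens
#' all three principal directions, most strongly x.
#'
#' @return Named numeric vector (`xx`, `yy`, `zz`), ppm.
#' @export
reference_axis_slopes <- function() {
  tab <- alw_reference()
  tab <- tab[tab$series == "qmmm", ]
  vapply(c(xx = "xx", yy = "yy", zz = "zz"), function(ax) {
    strain_slopes_by_series(tab, axis = ax)$slope_ppm
  }, numeric(1))
}

#' Specify a synthetic snapshot ensemble
#'
#' One row per H-bond subensemble: mean g- and A-values, population weight,
#' and per-axis Gaussian standard deviations of the snapshot scatter.
#'
#' @param means data.frame with columns `n_hbonds`, `weight`, `gxx`, `gyy`,
#'   `gzz`, `Axx_MHz`, `Ayy_MHz`, `Azz_MHz` (weights summing to 1). Default:
#'   the packaged solvated QM/MM subensemble table (see
#'   [tcomp_parameters()]).
#' @param sd_g per-axis standard deviations of the g-values, length 3;
#'   overrides `slope_ppm`. Default: per-axis scatter from
#'   [sigma_from_slope()] at the `slope_ppm` rates.
#' @param sd_A per-axis standard deviations of the A-values (MHz), length 3.
#' @param slope_ppm per-axis strain slopes emulated by the default
#'   g-scatter: length 3 (xx, yy, zz), or length 1 to set the g_xx slope
#'   while keeping the reference yy/zz slopes. Default:
#'   [reference_axis_slopes()], i.e. the slopes carried by the packaged
#'   solvated-ensemble width table.
#' @param cor_gxx_Azz optional correlation between the g_xx and A_zz
#'   scatter (nitroxides show an anticorrelation, so negative values are the
#'   physical choice); default 0 (independent axes).
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(means = NULL, sd_g = NULL, sd_A = c(0, 0, 0),
                          slope_ppm = NULL, cor_gxx_Azz = 0) {
  if (is.null(means)) means <- tcomp_parameters()
  need <- c("n_hbonds", "weight", "gxx", "gyy", "gzz",
            "Axx_MHz", "Ayy_MHz", "Azz_MHz")
  stopifnot(all(need %in% names(means)))
  if (abs(sum(means$weight) - 1) > 1e-8) {
    stop("subensemble weights must sum to 1", call. = FALSE)
  }
  if (is.null(sd_g)) {
    slopes <- reference_axis_slopes()
    if (!is.null(slope_ppm)) {
      if (length(slope_ppm) == 1) slopes[1] <- slope_ppm
      else if (length(slope_ppm) == 3) slopes[] <- slope_ppm
      else stop("slope_ppm must have length 1 or 3", call. = FALSE)
    }
    g_ref <- c(stats::weighted.mean(means$gxx, means$weight),
               stats::weighted.mean(means$gyy, means$weight),
               stats::weighted.mean(means$gzz, means$weight))
    sd_g <- mapply(sigma_from_slope, slopes, g_ref)
  }
  sd_g <- rep_len(as.numeric(sd_g), 3)
  sd_A <- rep_len(as.numeric(sd_A), 3)
  stopifnot(all(sd_g >= 0), all(sd_A >= 0),
            cor_gxx_Azz >= -1, cor_gxx_Azz <= 1)
  structure(list(means = means, sd_g = sd_g, sd_A = sd_A,
                 cor_gxx_Azz = cor_gxx_Azz), class = "ensemble_spec")
}

#' Generate a labeled snapshot ensemble
#'
#' Draws subensemble labels from the population weights (multinomial) and,
#' per snapshot, independent Gaussian g- and A-values about the subensemble
#' means. Reproducible for a fixed seed.
#'
#' @param spec an [ensemble_spec()].
#' @param n total number of snapshots.
#' @param seed RNG seed (integer) or `NULL` to use the current RNG state.
#' @return A [snapshot_table()] with `n_hbonds` labels.
#' @export
generate_snapshots <- function(spec, n = 1000, seed = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"), n >= 1)
  with_seed(seed, {
    m <- spec$means
    idx <- sample.int(nrow(m), n, replace = TRUE, prob = m$weight)
    gxx_dev <- stats::rnorm(n)
    azz_dev <- if (spec$cor_gxx_Azz != 0) {
      spec$cor_gxx_Azz * gxx_dev +
        sqrt(1 - spec$cor_gxx_Azz^2) * stats::rnorm(n)
    } else stats::rnorm(n)
    out <- data.frame(
      id = seq_len(n),
      time_fs = (seq_len(n) - 1) * 200,
      gxx = m$gxx[idx] + spec$sd_g[1] * gxx_dev,
      gyy = m$gyy[idx] + spec$sd_g[2] * stats::rnorm(n),
      gzz = m$gzz[idx] + spec$sd_g[3] * stats::rnorm(n),
      Axx_MHz = m$Axx_MHz[idx] + spec$sd_A[1] * stats::rnorm(n),
      Ayy_MHz = m$Ayy_MHz[idx] + spec$sd_A[2] * stats::rnorm(n),
      Azz_MHz = m$Azz_MHz[idx] + spec$sd_A[3] * azz_dev,
      n_hbonds = m$n_hbonds[idx]
    )
    snapshot_table(out)
  })
}

#' Specify a toy solvation trajectory
#'
#' Defines the generator for synthetic trajectory frames: prescribed H-bond
#' count populations, geometry distributions for bonded waters (placed
#' inside the H-bond criterion region), and filler waters placed outside the
#' criterion, some of them inside the first shell so that interstitial
#' waters exist.
#'
#' @param populations named numeric vector of H-bond count probabilities
#'   (names = counts), summing to 1. Default `c("1" = 0.10, "2" = 0.60,
#'   "3" = 0.30)`, the solvated-probe populations.
#' @param n_waters total waters per frame.
#' @param r_mean,r_sd bonded O...H distance distribution (Angstrom),
#'   truncated to (1.5, 2.5).
#' @param cos_mean,cos_sd bonded cos(theta) distribution, truncated to
#'   (-1, -0.8); with the distance truncation every bonded water satisfies
#'   the criterion by construction.
#' @param p_interstitial probability that a non-bonded water is placed
#'   inside the 3.3 A first shell.
#' @param box_length cubic box edge, Angstrom, or `NULL` for a non-periodic
#'   frame. Default 15.9581.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(populations = c("1" = 0.10, "2" = 0.60,
                                            "3" = 0.30),
                            n_waters = 10, r_mean = 1.85, r_sd = 0.15,
                            cos_mean = -0.95, cos_sd = 0.05,
                            p_interstitial = 0.3, box_length = 15.9581) {
  stopifnot(abs(sum(populations) - 1) < 1e-8, all(populations >= 0))
  counts <- as.integer(names(populations))
  if (anyNA(counts)) stop("populations must be named by H-bond count",
                          call. = FALSE)
  if (max(counts) > 6) {
    stop("more than 6 H-bonded waters cannot be placed around one acceptor",
         call. = FALSE)
  }
  if (max(counts) > n_waters) {
    stop("n_waters too small for the requested H-bond counts", call. = FALSE)
  }
  structure(list(populations = populations, counts = counts,
                 n_waters = n_waters, r_mean = r_mean, r_sd = r_sd,
                 cos_mean = cos_mean, cos_sd = cos_sd,
                 p_interstitial = p_interstitial, box_length = box_length),
            class = "trajectory_spec")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out < lo | out > hi)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

unit_perp <- function(v) {
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  p <- c(v[2] * ref[3] - v[3] * ref[2],
         v[3] * ref[1] - v[1] * ref[3],
         v[1] * ref[2] - v[2] * ref[1])
  p <- p / sqrt(sum(p^2))
  ang <- stats::runif(1, 0, 2 * pi)
  q <- c(v[2] * p[3] - v[3] * p[2],
         v[3] * p[1] - v[1] * p[3],
         v[1] * p[2] - v[2] * p[1])
  cos(ang) * p + sin(ang) * q
}

OH_BOND <- 0.97        # intramolecular O-H, Angstrom
HOH_ANGLE <- 104.5 * pi / 180

# one water donating an H-bond to the acceptor at `acc`
place_bonded_water <- function(acc, spec, existing_O) {
  for (try in 1:200) {
    v <- random_unit()
    r <- rtrunc_norm(1, spec$r_mean, spec$r_sd, 1.5, 2.5)
    ct <- rtrunc_norm(1, spec$cos_mean, spec$cos_sd, -1, -0.8)
    H1 <- acc + r * v
    st <- sqrt(1 - ct^2)
    t1 <- unit_perp(v)
    m <- ct * (-v) + st * t1                 # H -> donor O direction
    Od <- H1 + OH_BOND * m
    t2 <- unit_perp(m)
    m2 <- cos(HOH_ANGLE) * (-m) + sin(HOH_ANGLE) * t2
    H2 <- Od + OH_BOND * m2
    ok <- TRUE
    for (o in existing_O) if (sqrt(sum((Od - o)^2)) < 2.2) ok <- FALSE
    if (ok) return(rbind(Od, H1, H2))
  }
  stop("could not place a bonded water without steric clash", call. = FALSE)
}

# a water outside the H-bond criterion, optionally inside the first shell
place_free_water <- function(acc, spec, existing_O, interstitial) {
  for (try in 1:200) {
    u <- random_unit()
    d <- if (interstitial) stats::runif(1, 2.9, 3.25) else
      stats::runif(1, 3.6, 6.5)
    Ow <- acc + d * u
    # hydrogens on the far side of the water oxygen, both with a positive
    # component along the acceptor->O(water) direction: the angle at each H
    # between H->acceptor and H->O(water) then has cos(theta) > 0, putting
    # the criterion threshold below any realistic O...H distance
    tilt <- 30 * pi / 180
    t1 <- unit_perp(u)
    h1 <- cos(tilt) * u + sin(tilt) * t1
    t2 <- u - sum(u * h1) * h1          # in the (u, h1) plane, perp to h1
    t2 <- t2 / sqrt(sum(t2^2))
    h2 <- cos(HOH_ANGLE) * h1 + sin(HOH_ANGLE) * t2
    H1 <- Ow + OH_BOND * h1
    H2 <- Ow + OH_BOND * h2
    ok <- TRUE
    for (o in existing_O) if (sqrt(sum((Ow - o)^2)) < 2.5) ok <- FALSE
    if (ok) return(rbind(Ow, H1, H2))
  }
  stop("could not place a free water without steric clash", call. = FALSE)
}

#' Generate a toy solvation trajectory
#'
#' Per frame, draws an H-bond count from the prescribed populations, places
#' that many waters inside the H-bond criterion region around the acceptor
#' oxygen, and fills the remaining waters outside the criterion (a fraction
#' of them inside the 3.3 A first shell, i.e. interstitial). Coordinates are
#' wrapped into the periodic box when one is specified.
#'
#' @param spec a [trajectory_spec()].
#' @param n_frames number of frames.
#' @param seed RNG seed or `NULL`.
#' @return List of [trajectory_frame()] objects; the attribute
#'   `"target_counts"` carries the drawn per-frame H-bond counts.
#' @export
generate_trajectory <- function(spec, n_frames = 500, seed = NULL) {
  stopifnot(inherits(spec, "trajectory_spec"), n_frames >= 1)
  with_seed(seed, {
    L <- spec$box_length
    acc <- if (is.null(L)) c(0, 0, 0) else rep(L / 2, 3)
    targets <- spec$counts[sample.int(length(spec$counts), n_frames,
                                      replace = TRUE,
                                      prob = spec$populations)]
    frames <- lapply(targets, function(k) {
      waters <- list()
      oxy <- list()
      if (k > 0) for (i in seq_len(k)) {
        w <- place_bonded_water(acc, spec, oxy)
        waters <- c(waters, list(w))
        oxy <- c(oxy, list(w[1, ]))
      }
      n_free <- spec$n_waters - k
      if (n_free > 0) for (i in seq_len(n_free)) {
        inter <- stats::runif(1) < spec$p_interstitial
        w <- place_free_water(acc, spec, oxy, inter)
        waters <- c(waters, list(w))
        oxy <- c(oxy, list(w[1, ]))
      }
      if (!is.null(L)) waters <- lapply(waters, function(w) w %% L)
      trajectory_frame(acc, waters, box_length = L)
    })
    attr(frames, "target_counts") <- as.integer(targets)
    frames
  })
}

#' Add white Gaussian noise to a spectrum
#'
#' @param spectrum an [epr_spectrum()].
#' @param snr peak signal-to-noise ratio; the noise standard deviation is
#'   `max(abs(intensity)) / snr`.
#' @param seed RNG seed or `NULL`.
#' @return The noisy `epr_spectrum`.
#' @export
add_noise <- function(spectrum, snr, seed = NULL) {
  stopifnot(inherits(spectrum, "epr_spectrum"), snr > 0)
  with_seed(seed, {
    sd <- max(abs(spectrum$intensity)) / snr
    spectrum$intensity <- spectrum$intensity +
      stats::rnorm(length(spectrum$intensity), 0, sd)
    spectrum
  })
}
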