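# Geometric H-bond classification at the nitroxide oxygen.
#
# A water donates an H-bond to the probe oxygen when
#   r(O_a...H) < -1.71 cos(theta) + 1.37   [Angstrom]
# where theta is the angle at the hydrogen between the directions H->O_a
# (acceptor) and H->O_d (donor oxygen); an ideal linear H-bond has
# cos(theta) = -1, giving a 3.08 A distance ceiling.

HB_SLOPE <- -1.71
HB_INTERCEPT <- 1.37

#' Construct a trajectory frame
#'
#' @param acceptor_O length-3 position (Angstrom) of the nitroxide oxygen.
#' @param waters a list of waters, each a 3-by-3 matrix with rows O, H1, H2
#'   (Angstrom), or a single such matrix.
#' @param box_length optional cubic box edge (Angstrom); when present all
#'   distances use the minimum-image convention.
#' @return An object of class `trajectory_frame`.
#' @export
trajectory_frame <- function(acceptor_O, waters = list(), box_length = NULL) {
  acceptor_O <- as.numeric(acceptor_O)
  stopifnot(length(acceptor_O) == 3)
  if (is.matrix(waters)) waters <- list(waters)
  waters <- lapply(waters, function(w) {
    w <- as.matrix(w)
    if (!all(dim(w) == c(3, 3))) {
      stop("each water must be a 3x3 matrix (rows O, H1, H2)", call. = FALSE)
    }
    w
  })
  if (!is.null(box_length)) {
    stopifnot(is.numeric(box_length), box_length > 0)
    for (w in waters) {
      for (h in 2:3) {
        d <- sqrt(sum(min_image(w[h, ] - w[1, ], box_length)^2))
        if (d < 0.7 || d > 1.3) {
          stop(sprintf("intramolecular O-H distance %.2f A outside (0.7, 1.3)",
                       d), call. = FALSE)
        }
      }
    }
  }
  structure(list(acceptor_O = acceptor_O, waters = waters,
                 box_length = box_length), class = "trajectory_frame")
}

# minimum-image displacement for a cubic box (or identity when box is NULL)
min_image <- function(dvec, box_length = NULL) {
  if (is.null(box_length)) return(dvec)
  dvec - box_length * round(dvec / box_length)
}

#' H-bond geometry of one water relative to the acceptor oxygen
#'
#' Computes, for each of the two hydrogens, the acceptor-O to hydrogen
#' distance `r_OH` and the cosine of the angle at the hydrogen between the
#' acceptor-O and donor-O directions. Minimum-image convention is applied in
#' periodic frames.
#'
#' @param frame a [trajectory_frame()].
#' @param water_index index of the water in `frame$waters`.
#' @return A data.frame with two rows (one per hydrogen) and columns
#'   `water_index`, `hydrogen_index`, `r_OH`, `cos_theta`.
#' @export
hbond_geometry <- function(frame, water_index) {
  stopifnot(inherits(frame, "trajectory_frame"))
  if (water_index < 1 || water_index > length(frame$waters)) {
    stop("water_index out of range", call. = FALSE)
  }
  w <- frame$waters[[water_index]]
  L <- frame$box_length
  out <- lapply(1:2, function(h) {
    H <- w[h + 1, ]
    to_acc <- min_image(frame$acceptor_O - H, L)
    to_don <- min_image(w[1, ] - H, L)
    r <- sqrt(sum(to_acc^2))
    rd <- sqrt(sum(to_don^2))
    if (r < 0.1 || rd < 0.1) {
      stop("overlapping atoms (distance < 0.1 A)", call. = FALSE)
    }
    data.frame(water_index = water_index, hydrogen_index = h, r_OH = r,
               cos_theta = sum(to_acc * to_don) / (r * rd))
  })
  do.call(rbind, out)
}

#' Apply the geometric H-bond criterion
#'
#' @param geom a data.frame with columns `r_OH` (Angstrom) and `cos_theta`,
#'   e.g. from [hbond_geometry()].
#' @return logical vector: `TRUE` where
#'   `r_OH < -1.71 * cos_theta + 1.37`.
#' @export
is_hbonded <- function(geom) {
  stopifnot(all(c("r_OH", "cos_theta") %in% names(geom)))
  if (any(geom$r_OH <= 0) || any(abs(geom$cos_theta) > 1 + 1e-12)) {
    stop("invalid geometry: r_OH must be > 0 and cos_theta in [-1, 1]",
         call. = FALSE)
  }
  geom$r_OH < HB_SLOPE * geom$cos_theta + HB_INTERCEPT
}

#' Count waters donating an H-bond to the acceptor oxygen
#'
#' A water counts as bonded when at least one of its hydrogens satisfies the
#' criterion; a water bonded through both hydrogens still counts once (the
#' population statistics are per water molecule).
#'
#' @param frame a [trajectory_frame()].
#' @return A list with `count` and `bonded` (indices of bonded waters).
#' @export
count_hbonds <- function(frame) {
  stopifnot(inherits(frame, "trajectory_frame"))
  if (length(frame$waters) == 0) return(list(count = 0L, bonded = integer()))
  bonded <- which(vapply(seq_along(frame$waters), function(i) {
    any(is_hbonded(hbond_geometry(frame, i)))
  }, logical(1)))
  list(count = length(bonded), bonded = bonded)
}

#' H-bond count population distribution over a trajectory
#'
#' @param frames list of [trajectory_frame()] objects.
#' @return A data.frame with columns `n_hbonds` and `probability`
#'   (probabilities sum to 1), covering 0 up to the largest observed count.
#' @export
population_distribution <- function(frames) {
  if (length(frames) == 0) stop("no frames", call. = FALSE)
  counts <- vapply(frames, function(f) count_hbonds(f)$count, integer(1))
  tab <- tabulate(counts + 1L, nbins = max(counts) + 1L)
  data.frame(n_hbonds = seq_along(tab) - 1L,
             probability = tab / length(counts))
}

#' First-shell waters that are not H-bonded ("interstitial" waters)
#'
#' The first coordination shell of the acceptor oxygen extends to the first
#' minimum of the O(probe)-O(water) radial distribution function, 3.3 A for
#' this probe in water.
#'
#' @param frame a [trajectory_frame()].
#' @param r_cut first-shell cutoff on the O-O distance, Angstrom.
#' @return Integer indices of interstitial waters.
#' @export
interstitial_waters <- function(frame, r_cut = 3.3) {
  stopifnot(inherits(frame, "trajectory_frame"), r_cut > 0)
  if (length(frame$waters) == 0) return(integer())
  bonded <- count_hbonds(frame)$bonded
  in_shell <- which(vapply(frame$waters, function(w) {
    d <- min_image(w[1, ] - frame$acceptor_O, frame$box_length)
    sqrt(sum(d^2)) <= r_cut
  }, logical(1)))
  setdiff(in_shell, bonded)
}

#' Label a snapshot table with per-frame H-bond counts
#'
#' Fills (or overwrites) the `n_hbonds` column of a snapshot table from a
#' matching trajectory, pairing rows to frames by position.
#'
#' @param snapshots a [snapshot_table()].
#' @param frames list of [trajectory_frame()] of the same length.
#' @return The labeled snapshot table.
#' @export
label_snapshots <- function(snapshots, frames) {
  snapshots <- snapshot_table(as.data.frame(snapshots))
  if (nrow(snapshots) != length(frames)) {
    stop("snapshot table and trajectory differ in length", call. = FALSE)
  }
  snapshots$n_hbonds <- vapply(frames, function(f) count_hbonds(f)$count,
                               integer(1))
  snapshot_table(snapshots)
}
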