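# File formats: snapshot tables (CSV/JSON), multi-frame XYZ trajectories,
# long-format apparent line-width tables, and the packaged parameter
# fixtures used to seed and benchmark the analyses.

#' Read / write a snapshot EPR parameter table
#'
#' CSV columns (or JSON array of records): `id`, `time_fs`, `gxx`, `gyy`,
#' `gzz`, `Axx_MHz`, `Ayy_MHz`, `Azz_MHz`, optional `n_hbonds`. Both
#' encodings produce identical tables.
#'
#' @param path file path; format chosen by extension (`.json` vs anything
#'   else = CSV).
#' @return `read_snapshot_table` returns a validated [snapshot_table()].
#' @export
read_snapshot_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path)
  }
  snapshot_table(x)
}

#' @rdname read_snapshot_table
#' @param snapshots a [snapshot_table()].
#' @export
write_snapshot_table <- function(snapshots, path) {
  snapshots <- snapshot_table(as.data.frame(snapshots))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(unclass(snapshots)), path,
                         digits = NA, auto_unbox = TRUE)
  } else {
    utils::write.csv(as.data.frame(unclass(snapshots)), path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' Write a trajectory as multi-frame XYZ
#'
#' Element symbols: the acceptor oxygen is written first as `O`, then each
#' water as `O`, `H`, `H`. The comment line carries `box=<L>` for periodic
#' frames.
#'
#' @param frames list of [trajectory_frame()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    n <- 1 + 3 * length(f$waters)
    writeLines(as.character(n), con)
    writeLines(if (is.null(f$box_length)) "frame" else
      sprintf("frame box=%.6f", f$box_length), con)
    writeLines(sprintf("O %.6f %.6f %.6f",
                       f$acceptor_O[1], f$acceptor_O[2], f$acceptor_O[3]),
               con)
    for (w in f$waters) {
      el <- c("O", "H", "H")
      for (a in 1:3) {
        writeLines(sprintf("%s %.6f %.6f %.6f", el[a],
                           w[a, 1], w[a, 2], w[a, 3]), con)
      }
    }
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' Water molecules are reconstructed by assigning each hydrogen to its
#' nearest water oxygen (minimum-image when periodic); a grouping is
#' rejected unless every water ends up with exactly two hydrogens at
#' intramolecular O-H distances in (0.7, 1.3) Angstrom.
#'
#' @param path XYZ file.
#' @param acceptor_index 1-based index (within each frame's atom list) of
#'   the probe's N-O oxygen.
#' @param box cubic box edge in Angstrom; `NULL` reads it from a `box=`
#'   token on the comment line if present, otherwise non-periodic.
#' @param require_box error when a frame ends up without a box although
#'   periodic treatment was requested.
#' @return List of [trajectory_frame()] objects.
#' @export
read_xyz_trajectory <- function(path, acceptor_index = 1, box = NULL,
                                require_box = FALSE) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  fr <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i,
                       call. = FALSE)
    fr <- fr + 1
    comment <- lines[i + 1]
    L <- box
    if (is.null(L)) {
      m <- regmatches(comment, regexec("box=([0-9.eE+-]+)", comment))[[1]]
      if (length(m) == 2) L <- as.numeric(m[2])
    }
    if (require_box && is.null(L)) {
      stop("frame ", fr, ": periodic treatment requested but no box length",
           call. = FALSE)
    }
    rows <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    el <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (acceptor_index < 1 || acceptor_index > n) {
      stop("acceptor_index out of range in frame ", fr, call. = FALSE)
    }
    acc <- xyz[acceptor_index, ]
    rest <- setdiff(seq_len(n), acceptor_index)
    o_idx <- rest[el[rest] == "O"]
    h_idx <- rest[el[rest] == "H"]
    if (length(h_idx) != 2 * length(o_idx)) {
      stop(sprintf("frame %d: %d water oxygens but %d hydrogens", fr,
                   length(o_idx), length(h_idx)), call. = FALSE)
    }
    assigned <- lapply(o_idx, function(x) integer())
    names(assigned) <- as.character(o_idx)
    for (h in h_idx) {
      d <- vapply(o_idx, function(o) {
        sqrt(sum(min_image(xyz[h, ] - xyz[o, ], L)^2))
      }, numeric(1))
      o <- o_idx[which.min(d)]
      if (min(d) < 0.7 || min(d) > 1.3) {
        stop(sprintf(
          "frame %d: hydrogen at row %d is %.2f A from its nearest oxygen",
          fr, h, min(d)), call. = FALSE)
      }
      assigned[[as.character(o)]] <- c(assigned[[as.character(o)]], h)
    }
    waters <- lapply(o_idx, function(o) {
      hs <- assigned[[as.character(o)]]
      if (length(hs) != 2) {
        stop(sprintf("frame %d: water oxygen at row %d has %d hydrogens",
                     fr, o, length(hs)), call. = FALSE)
      }
      rbind(xyz[o, ], xyz[hs[1], ], xyz[hs[2], ])
    })
    frames[[fr]] <- trajectory_frame(acc, waters, box_length = L)
    i <- i + 2 + n
  }
  frames
}

#' Read / write a long-format apparent line-width table
#'
#' Columns: `series`, `component` (may be empty), `weight`, `band`,
#' `frequency_GHz`, `alw_xx`, `alw_yy`, `alw_zz` (MHz FWHM).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_alw_table <- function(path) {
  d <- utils::read.csv(path)
  need <- c("series", "band", "frequency_GHz", "alw_xx", "alw_yy", "alw_zz")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("alw table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d
}

#' Packaged benchmark parameter tables
#'
#' `exp_fit_parameters()` returns the two-component model fitted to the
#' four-band experimental spectra of the hexamethylimidazolidine nitroxide
#' probe in water (components differing in g_xx, shared g_yy/g_zz/A, one
#' apparent line-width triplet per band). `tcomp_parameters()` returns the
#' mean parameters and population weights of the H-bond subensembles from
#' the solvated ab initio ensemble (`"qmmm"`: explicit solvation;
#' `"ecrism"`: implicit), and `alw_reference()` the per-series apparent
#' line widths at the four bands.
#'
#' @param A_level which hyperfine values to return: `"revpbe0"` (consistent
#'   with the g-values) or `"ccsd"` (the more accurate coupled-cluster
#'   values).
#' @param series subensemble set.
#' @return `exp_fit_parameters()`: a [multicomponent_model()];
#'   `tcomp_parameters()`: data.frame with columns `n_hbonds`, `weight`,
#'   `gxx`..`Azz_MHz`; `alw_reference()`: long data.frame (see
#'   [read_alw_table()]).
#' @export
exp_fit_parameters <- function() {
  comp <- utils::read.csv(pkg_extdata("fit_parameters_exp.csv"))
  alw <- utils::read.csv(pkg_extdata("fit_alw_exp.csv"))
  multicomponent_model(g_xx = comp$gxx, weights = comp$weight,
                       g_yy = comp$gyy[1], g_zz = comp$gzz[1],
                       A = as.numeric(comp[1, c("Axx_MHz", "Ayy_MHz",
                                                "Azz_MHz")]),
                       alw = alw)
}

#' @rdname exp_fit_parameters
#' @export
tcomp_parameters <- function(series = c("qmmm", "ecrism"),
                             A_level = c("revpbe0", "ccsd")) {
  series <- match.arg(series)
  A_level <- match.arg(A_level)
  d <- utils::read.csv(pkg_extdata("subensemble_parameters.csv"))
  d <- d[d$series == series, ]
  if (A_level == "ccsd") {
    d$Axx_MHz <- d$Axx_ccsd_MHz
    d$Ayy_MHz <- d$Ayy_ccsd_MHz
    d$Azz_MHz <- d$Azz_ccsd_MHz
  }
  d$weight <- d$weight / sum(d$weight)
  d[c("n_hbonds", "weight", "gxx", "gyy", "gzz",
      "Axx_MHz", "Ayy_MHz", "Azz_MHz")]
}

#' @rdname exp_fit_parameters
#' @export
alw_reference <- function() {
  read_alw_table(pkg_extdata("alw_multifrequency.csv"))
}

pkg_extdata <- function(file) {
  p <- system.file("extdata", file, package = "gstrain")
  if (p == "") stop("packaged data file not found: ", file, call. = FALSE)
  p
}

#' Write a JSON run manifest
#'
#' Records inputs, configuration and seed of an analysis stage so that it
#' can be re-run.
#'
#' @param path output JSON path.
#' @param stage stage name.
#' @param config named list of configuration values.
#' @param seed RNG seed used (or NULL).
#' @param inputs,outputs character vectors of file paths.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, stage, config = list(), seed = NULL,
                               inputs = character(), outputs = character()) {
  jsonlite::write_json(list(
    stage = stage, timestamp = format(Sys.time(), tz = "UTC"),
    package_version = as.character(utils::packageVersion("gstrain")),
    seed = seed, config = config, inputs = inputs, outputs = outputs
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
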