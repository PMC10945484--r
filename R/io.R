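# Plain-text interchange: trajectory/thermogram/spectrum CSV with JSON
# sidecars, a minimal JCAMP-DX reader, and text PGM image frames.
#
# Image stacks are stored as plain-text PGM (P2) plus a JSON sidecar with
# the pixel size and ground truth; the environment has no TIFF/PNG codecs
# and all fixtures must stay text.

read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs; ",
           "use JSON instead", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Write / read a droplet-pair trajectory CSV
#'
#' Schema: columns `time_s`, `R1_um`, `R2_um`, `rc_um`, header mandatory.
#'
#' @param traj A trajectory data frame.
#' @param path File path.
#' @return `read_trajectory_csv` returns a `dib_trajectory` data frame.
#' @export
write_trajectory_csv <- function(traj, path) {
  check_trajectory(traj)
  utils::write.csv(traj[c("time_s", "R1_um", "R2_um", "rc_um")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "R1_um", "R2_um", "rc_um")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have header columns ",
         paste(need, collapse = ", "), call. = FALSE)
  out <- df[need]
  class(out) <- c("dib_trajectory", "data.frame")
  out
}

#' Write / read a thermogram CSV with JSON sidecar
#'
#' CSV columns `temp_C`, `heatflow_mW`; the sidecar (`<path>.json`)
#' carries `scan_rate_C_per_min` and `sample_moles`.
#'
#' @param tg A [thermogram()].
#' @param path CSV path; the sidecar is written next to it.
#' @param sidecar Sidecar path (defaults to `<path>.json`).
#' @return `read_thermogram_csv` returns a `thermogram`.
#' @export
write_thermogram_csv <- function(tg, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(tg, "thermogram"))
  utils::write.csv(as.data.frame(tg), path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(scan_rate_C_per_min = attr(tg, "scan_rate"),
                            sample_moles = attr(tg, "sample_moles")),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thermogram_csv
#' @export
read_thermogram_csv <- function(path, sidecar = paste0(path, ".json")) {
  df <- utils::read.csv(path)
  if (!all(c("temp_C", "heatflow_mW") %in% names(df)))
    stop("thermogram CSV must have columns temp_C, heatflow_mW",
         call. = FALSE)
  if (!file.exists(sidecar))
    stop("thermogram sidecar not found: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  thermogram(df$temp_C, df$heatflow_mW,
             scan_rate = meta$scan_rate_C_per_min,
             sample_moles = meta$sample_moles)
}

#' Write / read a Raman spectrum CSV
#'
#' Schema: columns `wavenumber_cm1`, `intensity`.
#'
#' @param spectrum A [raman_spectrum()].
#' @param path File path.
#' @return `read_spectrum_csv` returns a `raman_spectrum`.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("wavenumber_cm1", "intensity") %in% names(df)))
    stop("spectrum CSV must have columns wavenumber_cm1, intensity",
         call. = FALSE)
  raman_spectrum(df$wavenumber_cm1, df$intensity)
}

#' Read a JCAMP-DX spectrum
#'
#' Minimal reader for single-block JCAMP-DX files with either
#' `(X++(Y..Y))` tabular data (using `FIRSTX`/`LASTX`/`NPOINTS` and the
#' `XFACTOR`/`YFACTOR` scalings) or `(XY..XY)` point pairs.
#'
#' @param path File path.
#' @return A `raman_spectrum`.
#' @export
read_jcampdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(name, default = NA_real_) {
    rx <- paste0("^##", name, "=\\s*(.*)$")
    hit <- grep(rx, lines, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0L) return(default)
    as.numeric(sub(rx, "\\1", hit[1L], ignore.case = TRUE))
  }
  xfac <- get_field("XFACTOR", 1)
  yfac <- get_field("YFACTOR", 1)

  i_tab <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  i_pts <- grep("^##XYPOINTS=", lines, ignore.case = TRUE)
  i_end <- grep("^##END", lines, ignore.case = TRUE)
  if (length(i_end) == 0L) i_end <- length(lines) + 1L

  num <- function(s) as.numeric(strsplit(trimws(s), "[,;[:space:]]+")[[1L]])
  if (length(i_tab) > 0L) {
    body <- lines[seq.int(i_tab[1L] + 1L, i_end[1L] - 1L)]
    xs <- c(); ys <- c()
    for (ln in body) {
      v <- num(ln)
      if (length(v) < 2L) next
      ys <- c(ys, v[-1L])
      xs <- c(xs, v[1L])
    }
    npts <- get_field("NPOINTS", length(ys))
    firstx <- get_field("FIRSTX", xs[1L] * xfac)
    lastx <- get_field("LASTX")
    x <- if (!is.na(lastx) && npts > 1)
      seq(firstx, lastx, length.out = npts)
    else firstx + (seq_along(ys) - 1L) * 0  # degenerate; requires LASTX
    y <- ys * yfac
  } else if (length(i_pts) > 0L) {
    body <- lines[seq.int(i_pts[1L] + 1L, i_end[1L] - 1L)]
    v <- num(paste(body, collapse = " "))
    x <- v[seq(1L, length(v), by = 2L)] * xfac
    y <- v[seq(2L, length(v), by = 2L)] * yfac
  } else stop("no XYDATA or XYPOINTS block found in ", path, call. = FALSE)

  ord <- order(x)
  raman_spectrum(x[ord], y[ord])
}

#' Write / read an image frame as text PGM plus JSON sidecar
#'
#' The intensity grid is scaled to 16-bit greys in a plain-text (P2) PGM;
#' the sidecar stores the pixel size, timestamp, intensity scale and any
#' ground-truth geometry.
#'
#' @param frame An [image_frame()].
#' @param path PGM path; sidecar defaults to `<path>.json`.
#' @param sidecar Sidecar path.
#' @return `read_image_pgm` returns an `image_frame`.
#' @export
write_image_pgm <- function(frame, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(frame, "image_frame"))
  img <- frame$intensity
  hi <- max(img, 1e-12)
  grey <- round(img / hi * 65535)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(grey), nrow(grey)), "65535"), con)
  utils::write.table(grey, con, row.names = FALSE, col.names = FALSE)
  truth <- frame$truth
  jsonlite::write_json(
    list(pixel_size_um = frame$pixel_size, timestamp_s = frame$timestamp,
         intensity_scale = hi,
         truth = if (!is.null(truth))
           list(R1 = truth$R1, R2 = truth$R2, rc = truth$rc, d = truth$d)),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_image_pgm
#' @export
read_image_pgm <- function(path, sidecar = paste0(path, ".json")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1L] != "P2") stop("not a text (P2) PGM file: ", path,
                              call. = FALSE)
  hdr <- as.numeric(strsplit(paste(lines[2:3], collapse = " "),
                             "[[:space:]]+")[[1L]])
  ncols <- hdr[1L]; nrows <- hdr[2L]; maxval <- hdr[3L]
  vals <- as.numeric(strsplit(paste(lines[-(1:3)], collapse = " "),
                              "[[:space:]]+")[[1L]])
  vals <- vals[!is.na(vals)]
  img <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  else list(pixel_size_um = 1, timestamp_s = 0, intensity_scale = 1)
  truth <- NULL
  if (!is.null(meta$truth) && length(meta$truth) > 0L)
    truth <- droplet_pair_state(meta$truth$R1, meta$truth$R2,
                                meta$truth$rc)
  image_frame(img / maxval * meta$intensity_scale,
              pixel_size = meta$pixel_size_um,
              timestamp = meta$timestamp_s, truth = truth)
}
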