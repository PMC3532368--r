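#' Raster-scan acquisition parameters
#'
#' Timing and optics of a laser-scanning acquisition: within a line,
#' adjacent pixels are sampled `tau_p` apart (pixel residence time); lines
#' are `tau_l` apart; whole frames `frame_time` apart. `omega_0` is the
#' lateral 1/e^2 beam-waist radius of the two-photon focal spot; the default
#' 0.24 um derives from a measured point-spread-function FWHM of 0.28 um via
#' `omega_0 = FWHM / sqrt(2 log 2)`. `gamma` is the beam-geometry contrast
#' factor (default `2^-3/2` for a 3D Gaussian two-photon volume).
#'
#' @param tau_p Pixel residence time (s).
#' @param tau_l Line time (s).
#' @param delta_r Pixel size (um).
#' @param omega_0 Lateral beam waist (um).
#' @param gamma Beam-geometry factor (dimensionless).
#' @param frame_time Time between frame starts (s).
#' @return A list of class `"scan_params"`.
#' @export
scan_params <- function(tau_p = 1e-5, tau_l = 1e-3, delta_r = 0.1,
                        omega_0 = 0.24, gamma = 2^(-3 / 2),
                        frame_time = 0.52) {
  check_number(tau_p, "tau_p", min = 0, strict_min = TRUE)
  check_number(tau_l, "tau_l", min = 0, strict_min = TRUE)
  check_number(delta_r, "delta_r", min = 0, strict_min = TRUE)
  check_number(omega_0, "omega_0", min = 0, strict_min = TRUE)
  check_number(gamma, "gamma", min = 0, strict_min = TRUE)
  check_number(frame_time, "frame_time", min = 0, strict_min = TRUE)
  if (!(tau_p < tau_l && tau_l < frame_time)) {
    abort("scan timing must satisfy tau_p < tau_l < frame_time")
  }
  structure(
    list(tau_p = tau_p, tau_l = tau_l, delta_r = delta_r,
         omega_0 = omega_0, gamma = gamma, frame_time = frame_time),
    class = "scan_params"
  )
}

#' Photon-count image stack
#'
#' Container for a time-lapse movie of photon counts with its acquisition
#' metadata. `frames` is a 3D array indexed (frame, row, col) of
#' non-negative integers. `mode` records whether each frame is a snapshot
#' (whole frame sampled at one instant) or a raster scan (pixels sampled
#' sequentially; `scan` then carries the timing).
#'
#' @param frames 3D array (frame, row, col) of non-negative integer counts.
#' @param pixel_size Pixel size (um).
#' @param frame_interval Time between frames (s).
#' @param mode `"snapshot"` or `"raster"`.
#' @param scan A [scan_params()] object (required when `mode = "raster"`).
#' @return An object of class `"image_stack"`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval,
                        mode = c("snapshot", "raster"), scan = NULL) {
  mode <- match.arg(mode)
  if (length(dim(frames)) != 3L) abort("`frames` must be a 3D array")
  if (any(!is.finite(frames)) || any(frames < 0) ||
      any(frames != round(frames))) {
    abort("`frames` must contain non-negative integer photon counts")
  }
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  check_number(frame_interval, "frame_interval", min = 0, strict_min = TRUE)
  if (mode == "raster") {
    if (is.null(scan)) abort("raster mode requires `scan` parameters")
    stopifnot(inherits(scan, "scan_params"))
  }
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval, mode = mode, scan = scan),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<image_stack> %d frame(s) of %d x %d px (%s mode)\n",
    d[1], d[2], d[3], x$mode
  ))
  cat(sprintf("  pixel %g um, frame interval %g s, mean count %.3g\n",
              x$pixel_size, x$frame_interval, mean(x$frames)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

stack_schema_version <- "1.0"

sidecar_path <- function(path) paste0(path, ".meta")

#' Write / read photon-count stacks as multi-page TIFF + sidecar metadata
#'
#' Stacks are written as 16-bit unsigned multi-page TIFF; acquisition
#' metadata goes in a plain key-value sidecar file (`<path>.meta`) so runs
#' stay diff-able. The round trip is lossless for counts up to 65535;
#' larger counts raise an error rather than clipping silently. Reading a
#' TIFF without its sidecar (or with required keys missing) is an error
#' naming the missing keys.
#'
#' @param stack An [image_stack()].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (max(stack$frames) > 65535) {
    abort("photon counts exceed 65535: cannot write 16-bit TIFF without loss")
  }
  n <- dim(stack$frames)[1]
  pages <- lapply(seq_len(n), function(i) stack$frames[i, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  kv <- c(
    schema_version = stack_schema_version,
    pixel_size_um = format(stack$pixel_size, digits = 17),
    frame_interval_s = format(stack$frame_interval, digits = 17),
    mode = stack$mode
  )
  if (stack$mode == "raster") {
    s <- stack$scan
    kv <- c(kv,
      tau_p_s = format(s$tau_p, digits = 17),
      tau_l_s = format(s$tau_l, digits = 17),
      omega0_um = format(s$omega_0, digits = 17),
      gamma = format(s$gamma, digits = 17),
      frame_time_s = format(s$frame_time, digits = 17)
    )
  }
  writeLines(paste(names(kv), kv, sep = " = "), sidecar_path(path))
  invisible(path)
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    abort(paste0(
      "missing sidecar metadata file '", sc, "'; required keys: ",
      "pixel_size_um, frame_interval_s, mode"
    ))
  }
  lines <- readLines(sc)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  need <- c("pixel_size_um", "frame_interval_s", "mode")
  missing <- setdiff(need, names(vals))
  if (length(missing)) {
    abort(paste0("sidecar is missing required key(s): ",
                 paste(missing, collapse = ", ")))
  }
  if ("schema_version" %in% names(vals)) {
    major <- as.integer(strsplit(vals[["schema_version"]], "[.]")[[1]][1])
    if (!is.na(major) && major > 1L) {
      abort(sprintf("unsupported stack schema version %s",
                    vals[["schema_version"]]))
    }
  }
  vals
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  vals <- read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n <- length(pages)
  d <- dim(pages[[1]])
  frames <- array(0L, dim = c(n, d[1], d[2]))
  for (i in seq_len(n)) {
    frames[i, , ] <- as.integer(round(pages[[i]] * 65535))
  }
  mode <- vals[["mode"]]
  scan <- NULL
  if (identical(mode, "raster")) {
    need <- c("tau_p_s", "tau_l_s", "omega0_um")
    missing <- setdiff(need, names(vals))
    if (length(missing)) {
      abort(paste0("raster sidecar is missing key(s): ",
                   paste(missing, collapse = ", ")))
    }
    scan <- scan_params(
      tau_p = as.numeric(vals[["tau_p_s"]]),
      tau_l = as.numeric(vals[["tau_l_s"]]),
      delta_r = as.numeric(vals[["pixel_size_um"]]),
      omega_0 = as.numeric(vals[["omega0_um"]]),
      gamma = if ("gamma" %in% names(vals)) as.numeric(vals[["gamma"]]) else 2^(-3 / 2),
      frame_time = if ("frame_time_s" %in% names(vals))
        as.numeric(vals[["frame_time_s"]]) else
        as.numeric(vals[["frame_interval_s"]])
    )
  }
  image_stack(
    frames = frames,
    pixel_size = as.numeric(vals[["pixel_size_um"]]),
    frame_interval = as.numeric(vals[["frame_interval_s"]]),
    mode = mode, scan = scan
  )
}

#' Red/green temporal overlay of two frames
#'
#' Builds the classic mobility visualization: frame `t0` in the red channel
#' and frame `t1` in the green channel (blue empty), each min-max scaled.
#' Structures that have not moved between the two times appear
#' yellow/orange; displaced structures appear as separated red and green
#' copies.
#'
#' @param stack An [image_stack()].
#' @param t0_frame,t1_frame 1-based frame indices.
#' @return A numeric array `rows x cols x 3` with values in \[0, 1\].
#' @export
temporal_overlay <- function(stack, t0_frame = 1L, t1_frame) {
  stopifnot(inherits(stack, "image_stack"))
  n <- dim(stack$frames)[1]
  if (t0_frame < 1 || t0_frame > n || t1_frame < 1 || t1_frame > n) {
    abort("frame indices out of range")
  }
  scale01 <- function(m) {
    rng <- range(m)
    if (diff(rng) == 0) return(m * 0)
    (m - rng[1]) / diff(rng)
  }
  r <- scale01(stack$frames[t0_frame, , ])
  g <- scale01(stack$frames[t1_frame, , ])
  out <- array(0, dim = c(dim(r), 3L))
  out[, , 1] <- r
  out[, , 2] <- g
  out
}
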