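#' Read / write multi-page 8-bit grayscale TIFF stacks
#'
#' Frames are stored losslessly as 8-bit grayscale pages; reading returns
#' matrices with values 0-255 in frame order. 16-bit input is accepted and
#' rescaled to 0-255 with a warning; RGB input is rejected.
#'
#' @param frames List of matrices with values in `[0, 255]`.
#' @param path TIFF file path.
#' @return `write_stack` returns `path` invisibly; `read_stack` a list of
#'   matrices.
#' @export
write_stack <- function(frames, path) {
  if (inherits(frames, "holo_video")) frames <- unclass(frames)[seq_along(frames)]
  stopifnot(is.list(frames), length(frames) >= 1)
  pages <- lapply(frames, function(f) {
    if (min(f) < 0 || max(f) > 255) stop("frame values outside [0, 255]")
    matrix(as.numeric(f) / 255, nrow(f), ncol(f))
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) {
                      stop("malformed TIFF '", path, "': ",
                           conditionMessage(e))
                    })
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(pg) {
    if (length(dim(pg)) == 3L) {
      stop("RGB TIFF not supported: expected single-channel grayscale")
    }
    bits <- attr(pg, "bits.per.sample")
    if (!is.null(bits) && bits > 8) {
      warning("16-bit TIFF rescaled to 0-255")
    }
    round(pg * 255)
  })
}

#' Write / read a bead track as CSV with a JSON sidecar
#'
#' The CSV holds one row per frame (`frame`, `t_s`, `x_nm`, `y_nm`,
#' `z_nm`, `amplitude`, `flag` and per-period phase columns); sampling
#' rate, periods, pixel size and the simulation seed go to `<path>.json`.
#' Flagged-missing coordinates are serialized as empty cells and restored
#' as `NA`.
#'
#' @param track A `bead_track`.
#' @param path CSV path (sidecar written to `paste0(path, ".json")`).
#' @param seed Optional seed recorded in the sidecar.
#' @return `write_track` returns `path` invisibly; `read_track` the
#'   restored `bead_track`.
#' @export
write_track <- function(track, path, seed = NULL) {
  stopifnot(inherits(track, "bead_track"))
  utils::write.csv(as.data.frame(track), path, row.names = FALSE,
                   na = "")
  meta <- list(f_s = attr(track, "f_s"),
               periods = attr(track, "periods"),
               pixel_nm = attr(track, "pixel_nm"),
               seed = seed,
               n_frames = nrow(track))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "t_s", "x_nm", "y_nm", "z_nm", "flag")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("track CSV lacks required column(s): ", paste(miss, collapse = ", "))
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    list(f_s = NA_real_, periods = NULL, pixel_nm = NA_real_)
  }
  structure(df, f_s = meta$f_s, periods = meta$periods,
            pixel_nm = meta$pixel_nm, seed = meta$seed,
            class = c("bead_track", "data.frame"))
}

#' Write / read a trajectory CSV (frame, t_s, x_nm, y_nm, z_nm)
#'
#' @param traj A `bead_trajectory`.
#' @param path CSV path.
#' @param f_s Sampling rate override on read (Hz); inferred from `t_s`
#'   when omitted.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   the trajectory.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, f_s = NULL) {
  df <- utils::read.csv(path)
  need <- c("x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV needs columns x_nm, y_nm, z_nm")
  }
  if (is.null(f_s)) {
    f_s <- if ("t_s" %in% names(df) && nrow(df) > 1) {
      1 / stats::median(diff(df$t_s))
    } else NA_real_
  }
  structure(df, f_s = f_s, class = c("bead_trajectory", "data.frame"))
}

#' Serialize / restore a phase calibration as JSON
#'
#' Stores the dense forward tables (height grid, unwrapped phase and
#' amplitude per period) plus metadata; restoring rebuilds a working
#' [calibrate_phase()] object.
#'
#' @param cal A `phase_calibration`.
#' @param path JSON path.
#' @return `write_calibration` returns `path` invisibly;
#'   `read_calibration` the restored object.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "phase_calibration"))
  obj <- list(
    periods = cal$periods, order = cal$order, range = cal$range,
    usable = cal$usable, sigma_res_nm = cal$sigma_res_nm,
    slope_exponent = cal$slope_exponent, c_factor = cal$c_factor,
    z0_nm = cal$z0_nm, amp_median = cal$amp_median,
    grid_z = cal$per_period[[1]]$grid_z,
    grid_phi = lapply(cal$per_period, `[[`, "grid_phi"),
    grid_amp = lapply(cal$per_period, function(pp) {
      if (is.null(pp$grid_amp)) NULL else pp$grid_amp
    }),
    asym_slope = vapply(cal$per_period, `[[`, numeric(1), "asym_slope"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  # per-period vectors come back as a list (ragged) or as a matrix with
  # one row per period (equal lengths)
  pick <- function(x, j) {
    if (is.null(x)) NULL
    else if (is.list(x)) x[[j]]
    else if (is.matrix(x)) x[j, ]
    else x
  }
  per_period <- lapply(seq_along(o$periods), function(j) {
    ga <- pick(o$grid_amp, j)
    list(period = o$periods[j],
         ok = o$usable[j],
         grid_z = o$grid_z,
         grid_phi = pick(o$grid_phi, j),
         grid_amp = if (length(ga)) ga else NULL,
         sigma_res_nm = o$sigma_res_nm[j],
         asym_slope = o$asym_slope[j],
         asym_intercept = NA_real_,
         amp_median = o$amp_median[j])
  })
  structure(
    list(periods = o$periods, order = o$order, range = o$range,
         per_period = per_period, usable = o$usable,
         sigma_res_nm = o$sigma_res_nm,
         slope_exponent = o$slope_exponent, c_factor = o$c_factor,
         z0_nm = o$z0_nm, amp_median = o$amp_median),
    class = "phase_calibration")
}
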