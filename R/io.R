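# Track-file and table export/import.
#
# Track files are plain tab-separated text with '#'-prefixed header lines:
#   # flagbeat-track 1
#   # units: um, s
#   # frame_rate_hz: <rate>
# followed by one row per point with columns
#   frame_index time_s point_index arclength_um x_um y_um z_um
#   axis_x axis_y axis_z
# The head is stored as point_index 0 (arclength NA) carrying the head
# center in x/y/z and the head long axis in axis_*; flagellar points have
# NA axis columns. Unknown extra columns are preserved on read and written
# back verbatim.

TRACK_MAGIC <- "# flagbeat-track 1"

#' Write a beat recording to a track file
#'
#' @param rec [beat_recording]
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_track <- function(rec, path) {
  nf <- n_frames(rec)
  rate <- 1 / frame_dt(rec)
  rows <- vector("list", nf)
  for (i in seq_len(nf)) {
    p <- rec$frames[[i]]$points
    np <- nrow(p)
    rows[[i]] <- data.frame(
      frame_index = i,
      time_s = rec$times[i],
      point_index = c(0L, seq_len(np)),
      arclength_um = c(NA_real_, rec$frames[[i]]$s),
      x_um = c(rec$head_center[i, 1], p[, 1]),
      y_um = c(rec$head_center[i, 2], p[, 2]),
      z_um = c(rec$head_center[i, 3], p[, 3]),
      axis_x = c(rec$head_axis[i, 1], rep(NA_real_, np)),
      axis_y = c(rec$head_axis[i, 2], rep(NA_real_, np)),
      axis_z = c(rec$head_axis[i, 3], rep(NA_real_, np)))
  }
  tab <- do.call(rbind, rows)
  extra <- attr(rec, "extra_columns")
  if (!is.null(extra) && nrow(extra) == nrow(tab)) tab <- cbind(tab, extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(TRACK_MAGIC, "# units: um, s",
               sprintf("# frame_rate_hz: %.10g", rate)), con)
  utils::write.table(format(tab, digits = 12, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a beat recording from a track file
#'
#' Validates the header, per-frame point-index contiguity, frame-index
#' contiguity and coordinate finiteness; parse errors name the offending
#' rows. Unknown columns are kept as the `extra_columns` attribute and a
#' message is emitted.
#'
#' @param path track file written by [write_track()].
#' @return [beat_recording]
#' @export
read_track <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1)
  if (!identical(hdr, TRACK_MAGIC)) {
    stop("malformed header: expected '", TRACK_MAGIC, "'")
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("frame_index", "time_s", "point_index", "arclength_um",
            "x_um", "y_um", "z_um", "axis_x", "axis_y", "axis_z")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  extra_names <- setdiff(names(tab), need)
  bad <- which(!is.finite(tab$x_um) | !is.finite(tab$y_um) |
               !is.finite(tab$z_um))
  if (length(bad)) {
    stop("non-finite coordinates at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  fids <- sort(unique(tab$frame_index))
  if (!identical(fids, seq_along(fids))) {
    gap <- setdiff(seq_len(max(fids)), fids)
    stop("missing frame(s): ", paste(gap, collapse = ", "))
  }
  frames <- vector("list", length(fids))
  times <- numeric(length(fids))
  head_center <- matrix(NA_real_, length(fids), 3)
  head_axis <- matrix(NA_real_, length(fids), 3)
  for (i in fids) {
    sub <- tab[tab$frame_index == i, , drop = FALSE]
    times[i] <- sub$time_s[1]
    hrow <- sub[sub$point_index == 0, , drop = FALSE]
    if (nrow(hrow) != 1) {
      stop("frame ", i, ": expected exactly one head row (point_index 0), ",
           "found ", nrow(hrow))
    }
    head_center[i, ] <- c(hrow$x_um, hrow$y_um, hrow$z_um)
    head_axis[i, ] <- c(hrow$axis_x, hrow$axis_y, hrow$axis_z)
    prow <- sub[sub$point_index > 0, , drop = FALSE]
    prow <- prow[order(prow$point_index), , drop = FALSE]
    if (!identical(as.integer(prow$point_index),
                   seq_len(nrow(prow)))) {
      first_row <- which(tab$frame_index == i)[1]
      stop("frame ", i, " (starting data row ", first_row,
           "): point_index not contiguous")
    }
    frames[[i]] <- structure(
      list(points = as.matrix(prow[, c("x_um", "y_um", "z_um")]),
           s = prow$arclength_um,
           ds = stats::median(diff(prow$arclength_um))),
      class = "flagellar_shape")
    dimnames(frames[[i]]$points) <- NULL
  }
  rec <- beat_recording(frames, times, head_center, head_axis)
  if (length(extra_names)) {
    message("preserving unknown column(s): ",
            paste(extra_names, collapse = ", "))
    attr(rec, "extra_columns") <- tab[, extra_names, drop = FALSE]
  }
  rec
}

#' Export a kymograph as delimited matrices
#'
#' Writes one file per quantity (kappa, tau, valid mask): a tab-separated
#' matrix with the time grid as the header row and the arclength grid as
#' the first column.
#'
#' @param kym [compute_kymographs()] result.
#' @param stem output path stem; files `<stem>_kappa.tsv`,
#'   `<stem>_tau.tsv`, `<stem>_mask.tsv` are written.
#' @return character vector of written paths, invisibly.
#' @export
write_kymograph <- function(kym, stem) {
  wr <- function(M, path) {
    out <- cbind(s_um = kym$s, M)
    colnames(out) <- c("s_um", sprintf("%.9g", kym$t))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  paths <- c(wr(kym$kappa, paste0(stem, "_kappa.tsv")),
             wr(kym$tau, paste0(stem, "_tau.tsv")),
             wr(kym$valid & kym$tau_valid, paste0(stem, "_mask.tsv")))
  invisible(paths)
}

#' Export per-frame gyration frames as a delimited table
#'
#' Columns: time, eigenvector components, eigenvalues, Gamma, roll angle
#' and roll rate.
#'
#' @param rec [beat_recording]
#' @param path output file.
#' @return the table, invisibly.
#' @export
write_frame_table <- function(rec, path) {
  fr <- gyration_frames(rec)
  roll <- rolling_analysis(rec, frames = fr)
  tab <- do.call(rbind, lapply(seq_along(fr), function(i) {
    f <- fr[[i]]
    data.frame(time_s = rec$times[i],
               e1x = f$e1[1], e1y = f$e1[2], e1z = f$e1[3],
               e2x = f$e2[1], e2y = f$e2[2], e2z = f$e2[3],
               e3x = f$e3[1], e3y = f$e3[2], e3z = f$e3[3],
               lambda1 = f$lambda[1], lambda2 = f$lambda[2],
               lambda3 = f$lambda[3], Gamma = f$Gamma,
               roll_angle_rad = roll$roll_angle[i],
               roll_rate_rad_s = roll$roll_rate[i])
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}

#' Export an intensity volume as a multi-page TIFF z-stack
#'
#' 32-bit float pages (one per z-slice) plus a plain-text sidecar with the
#' voxel size and origin. Requires the `tiff` package.
#'
#' @param vol `intensity_volume`
#' @param path output `.tif` path; the sidecar is `<path>.meta`.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export")
  }
  mx <- max(vol$data)
  pages <- lapply(seq_len(dim(vol$data)[3]), function(k) {
    vol$data[, , k] / max(mx, .Machine$double.xmin)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  writeLines(c(sprintf("voxel_um: %.10g", vol$voxel),
               sprintf("origin_um: %.10g %.10g %.10g", vol$origin[1],
                       vol$origin[2], vol$origin[3]),
               sprintf("scale: %.10g", mx)),
             paste0(path, ".meta"))
  invisible(path)
}
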