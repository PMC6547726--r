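#' Read a tab-delimited per-cell intensity table
#'
#' Canonical input is the tab-delimited text export of a flow-cytometry FCS
#' file or a per-ROI microscopy measurement: a header row and one row per
#' cell with numeric donor, raw-FRET and acceptor intensities. Columns may
#' be renamed on read via `columns`; extra columns are passed through. Rows
#' whose required fields fail numeric parsing are dropped with a warning
#' stating the count.
#'
#' @param path Path to a tab-delimited text file with a header row.
#' @param columns Named character vector mapping required names to file
#'   column names, e.g. `c(donor = "FL1", fret = "FL2", acceptor = "FL3")`.
#' @return A tibble with numeric columns `donor`, `fret`, `acceptor` (plus
#'   any extra file columns) and an `id` column if the file has none.
#' @export
read_intensity_table <- function(path,
                                 columns = c(
                                   donor = "donor", fret = "fret",
                                   acceptor = "acceptor"
                                 )) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(unname(columns), names(raw))
  if (length(missing) > 0) {
    stop(
      "Missing required column(s) in ", path, ": ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  for (nm in names(columns)) {
    names(raw)[names(raw) == columns[[nm]]] <- nm
  }
  n0 <- nrow(raw)
  for (nm in names(columns)) {
    if (!is.numeric(raw[[nm]])) {
      raw[[nm]] <- suppressWarnings(as.numeric(raw[[nm]]))
    }
  }
  keep <- stats::complete.cases(raw[, names(columns)])
  if (any(!keep)) {
    warning(
      sum(!keep), " of ", n0,
      " rows dropped: non-numeric donor/fret/acceptor values.",
      call. = FALSE
    )
  }
  out <- raw[keep, , drop = FALSE]
  if (!"id" %in% names(out)) {
    out <- dplyr::mutate(out, id = dplyr::row_number(), .before = 1)
  }
  tibble::as_tibble(out)
}

#' Write a table as tab-delimited text
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_intensity_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

#' Write calibration factors as a flat key-value text file
#'
#' Serializes bleed-through (S1-S4) and calibration (C1, C2, E_ref, G)
#' factors as `key<TAB>value` lines so calibrations can be reused across
#' runs and inspected by eye.
#'
#' @param calibration A `fret_calibration` object from [calibrate()].
#' @param path Output path.
#' @return `calibration`, invisibly.
#' @export
write_calibration <- function(calibration, path) {
  kv <- c(
    s1 = calibration$bleed$s1, s2 = calibration$bleed$s2,
    s3 = calibration$bleed$s3, s4 = calibration$bleed$s4,
    c1 = calibration$cal$c1, c2 = calibration$cal$c2,
    e_ref = calibration$cal$e_ref, g = calibration$cal$g
  )
  writeLines(
    sprintf("%s\t%s", names(kv), formatC(kv, digits = 17, format = "g")),
    path
  )
  invisible(calibration)
}

#' Read calibration factors from a key-value text file
#'
#' @param path Path written by [write_calibration()].
#' @return A `fret_calibration` object.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kv <- stats::setNames(
    vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
    vapply(parts, `[`, character(1), 1)
  )
  need <- c("s1", "s2", "s3", "s4", "c1", "c2", "e_ref", "g")
  if (!all(need %in% names(kv))) {
    stop(
      "Calibration file missing key(s): ",
      paste(setdiff(need, names(kv)), collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      bleed = structure(
        list(s1 = kv[["s1"]], s2 = kv[["s2"]], s3 = kv[["s3"]], s4 = kv[["s4"]]),
        class = "bleedthrough_factors"
      ),
      cal = structure(
        list(
          c1 = kv[["c1"]], c2 = kv[["c2"]], e_ref = kv[["e_ref"]],
          g = kv[["g"]], n_cells = NA_integer_
        ),
        class = "calibration_factors"
      )
    ),
    class = "fret_calibration"
  )
}

#' Read a three-channel TIFF stack
#'
#' Reads a multi-page TIFF (pages = channels, order donor, FRET, acceptor)
#' or three single-channel files into a `height x width x 3` numeric array.
#' Sample values are rescaled from the TIFF unit range back to counts via
#' `scale` (the maximum count the file's range represents).
#'
#' @param path Character vector: one multi-page TIFF path, or three paths in
#'   channel order donor, FRET, acceptor.
#' @param scale Count value corresponding to TIFF sample value 1.0; default
#'   4095 (12-bit data).
#' @return Numeric array `height x width x 3`.
#' @export
read_channel_stack <- function(path, scale = 4095) {
  pages <- if (length(path) == 1) {
    p <- tiff::readTIFF(path, all = TRUE)
    if (is.list(p)) p else list(p)
  } else {
    lapply(path, tiff::readTIFF)
  }
  if (length(pages) != 3) {
    stop("Expected 3 channels (donor, FRET, acceptor); got ", length(pages),
      call. = FALSE
    )
  }
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1) stop("Channel dimensions differ.", call. = FALSE)
  stack <- array(0, dim = c(dims[[1]][1], dims[[1]][2], 3))
  for (i in 1:3) stack[, , i] <- pages[[i]] * scale
  stack
}

#' Write a three-channel stack as a multi-page TIFF
#'
#' @param stack Numeric array `height x width x 3` of counts.
#' @param path Output path.
#' @param scale Count value mapped to TIFF sample value 1.0.
#' @return `path`, invisibly.
#' @export
write_channel_stack <- function(stack, path, scale = 4095) {
  pages <- lapply(1:3, function(i) pmin(pmax(stack[, , i] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Pixelwise DFRET map from a three-channel image stack
#'
#' Applies the full normalization chain per pixel: constant background
#' subtraction per channel, spectral bleed-through correction, FRETc and
#' DFRET. Pixels below the inclusion threshold in the donor or acceptor
#' channel, at or above the detector saturation ceiling in any channel, or
#' with negative DFRET are masked (NA) in the returned map. The data layer
#' is never clamped to the display range; clamping belongs to rendering
#' (see [plot_dfret_map()]).
#'
#' @param stack Numeric array `height x width x 3` (donor, FRET, acceptor).
#' @param calibration A `fret_calibration` object.
#' @param background Length-3 numeric: constant background per channel.
#' @param threshold Inclusion threshold on background-subtracted donor and
#'   acceptor signal.
#' @param ceiling Detector saturation ceiling (counts); default 4095.
#' @return A list with `map` (matrix of DFRET values, NA where masked),
#'   `mask` (logical matrix of retained pixels) and `table` (tibble of the
#'   per-pixel normalized values for retained pixels, with `row`/`col`
#'   coordinates).
#' @export
dfret_map <- function(stack, calibration,
                      background = c(0, 0, 0),
                      threshold = 0,
                      ceiling = 4095) {
  if (length(dim(stack)) != 3 || dim(stack)[3] != 3) {
    stop("`stack` must be a height x width x 3 array.", call. = FALSE)
  }
  if (ceiling <= threshold) {
    stop("`ceiling` must exceed `threshold`.", call. = FALSE)
  }
  h <- dim(stack)[1]
  w <- dim(stack)[2]
  px <- tibble::tibble(
    row = rep(seq_len(h), w),
    col = rep(seq_len(w), each = h),
    donor = as.vector(stack[, , 1]) - background[1],
    fret = as.vector(stack[, , 2]) - background[2],
    acceptor = as.vector(stack[, , 3]) - background[3]
  )
  saturated <- as.vector(stack[, , 1]) >= ceiling |
    as.vector(stack[, , 2]) >= ceiling |
    as.vector(stack[, , 3]) >= ceiling
  norm <- normalize_cells(px, calibration)
  keep <- !saturated &
    norm$donor > threshold & norm$acceptor > threshold &
    is.finite(norm$DFRET) & norm$DFRET >= 0
  map <- matrix(NA_real_, h, w)
  map[cbind(norm$row[keep], norm$col[keep])] <- norm$DFRET[keep]
  mask <- matrix(FALSE, h, w)
  mask[cbind(norm$row[keep], norm$col[keep])] <- TRUE
  list(map = map, mask = mask, table = norm[keep, , drop = FALSE])
}
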