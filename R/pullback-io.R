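#' Read a pullback from disk
#'
#' Reads either a multi-page TIFF file or a directory of equally sized
#' PNG/TIFF images; for a directory, lexicographic filename order defines the
#' frame order. Multi-channel images are converted to grayscale by the
#' unweighted channel mean (IVUS data is natively single-channel, so this is
#' only a fallback). PNG intensities, which the reader delivers in [0, 1],
#' are rescaled to the 8-bit 0-255 range; TIFF intensities are kept as stored.
#'
#' @param path multi-page TIFF file, or a directory containing PNG/TIFF frames.
#' @param spacing optional pixel spacing (mm per pixel) to attach.
#' @param id optional label; defaults to the file or directory name.
#' @return a [Pullback-class].
#' @examples
#' p <- writePullback(pullback(list(matrix(0:3, 2, 2))), tempfile(fileext = ".tif"))
#' length(readPullback(p))
#' @export
readPullback <- function(path, spacing = NA_real_, id = NULL) {
  if (!file.exists(path))
    stop("input path does not exist: ", path, call. = FALSE)
  if (is.null(id)) id <- sub("\\.[^.]+$", "", basename(path))
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    files <- files[order(basename(files))]
    if (length(files) == 0L)
      stop("no PNG/TIFF frames found in directory: ", path, call. = FALSE)
    imgs <- lapply(files, readFrameFile)
  } else {
    # readTIFF normalises every page to [0, 1]; 255 * (k/65535) is exact for
    # all 8-bit counts k stored as 16-bit samples, so integer-valued frames
    # written by writePullback round-trip bit-exactly
    imgs <- tiff::readTIFF(path, all = TRUE)
    if (is.matrix(imgs) || (is.array(imgs) && length(dim(imgs)) == 3L))
      imgs <- list(imgs)
    imgs <- lapply(imgs, function(pg) toGray(pg * 255))
  }
  dims <- vapply(imgs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames have mixed dimensions; all frames must be the same size",
         call. = FALSE)
  pullback(imgs, spacing = spacing, id = id)
}

readFrameFile <- function(f) {
  img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
    png::readPNG(f) * 255
  } else {
    tiff::readTIFF(f) * 255
  }
  toGray(img)
}

toGray <- function(img) {
  if (length(dim(img)) == 3L) {
    # drop a pure-opacity alpha channel, then average the colour channels
    if (dim(img)[3] %in% c(2L, 4L))
      img <- img[, , -dim(img)[3], drop = FALSE]
    img <- apply(img, c(1, 2), mean)
  }
  storage.mode(img) <- "double"
  img
}

#' Write a pullback as a multi-page TIFF
#'
#' One page per frame on the package's canonical 0-255 intensity scale.
#' Integer-valued frames are stored as 16-bit pages (the stored sample is
#' exactly 257 times the 8-bit value, so the round-trip is bit-exact);
#' float-valued frames are stored as 32-bit float pages scaled to [0, 1],
#' preserving values to single precision. Intensities above 255 are not
#' representable and raise an error.
#'
#' @param pb a [Pullback-class].
#' @param path output file path (created or overwritten).
#' @return the path, invisibly.
#' @export
writePullback <- function(pb, path) {
  stopifnot(is(pb, "Pullback"))
  validObject(pb)
  mx <- max(vapply(pb@frames, max, numeric(1)))
  if (mx > 255)
    stop("intensities above 255 cannot be written; rescale the pullback first",
         call. = FALSE)
  integerLike <- all(vapply(pb@frames, function(f) all(f == round(f)),
                            logical(1)))
  scaled <- lapply(pb@frames, function(f) f / 255)
  ok <- tiff::writeTIFF(scaled, path, reduce = FALSE,
                        bits.per.sample = if (integerLike) 16L else 32L)
  if (!isTRUE(ok) && !identical(ok, length(pb@frames)))
    stop("failed to write TIFF: ", path, call. = FALSE)
  invisible(path)
}

#' Write and read frame-pair registration results
#'
#' \code{writeRegistrationResult} stores the match table as CSV (columns
#' \code{index_a, index_b, dissimilarity, angle_deg, tx_px, ty_px, mi_before,
#' mi_after}) plus a sidecar JSON (same path with extension \code{.json})
#' holding the run configuration. \code{readRegistrationResult} reads the CSV
#' back into an identical data frame.
#'
#' @param matches data frame of frame-pair matches as produced by
#'   [registerLongitudinal()] / [registerAxial()].
#' @param path CSV output path.
#' @param config optional named list written to the sidecar JSON.
#' @return the path, invisibly (write); the match data frame (read).
#' @export
writeRegistrationResult <- function(matches, path, config = list()) {
  if (!is.data.frame(matches) || nrow(matches) == 0L)
    stop("'matches' must be a non-empty data frame", call. = FALSE)
  cols <- c("index_a", "index_b", "dissimilarity", "angle_deg", "tx_px",
            "ty_px", "mi_before", "mi_after")
  for (cc in cols) if (is.null(matches[[cc]])) matches[[cc]] <- NA_real_
  utils::write.csv(matches[cols], path, row.names = FALSE)
  sidecar <- sub("\\.[^.]*$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(config, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeRegistrationResult
#' @export
readRegistrationResult <- function(path) {
  utils::read.csv(path)
}
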