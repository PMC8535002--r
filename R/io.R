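#' Read an image stack into a 3-D array
#'
#' Reads an image sequence from one of three layouts, always returning an
#' array whose last axis is the frame (time) axis:
#' \itemize{
#'   \item a multi-page TIFF file (`.tif`/`.tiff`): pages become frames in
#'     page order; integer samples are rescaled to `[0, 1]` by the sample
#'     dtype maximum, float samples are kept as stored;
#'   \item a directory of PNG frames: files are ordered lexicographically by
#'     name; integer samples rescaled to `[0, 1]`;
#'   \item a raw array file (`.bin`/`.raw`): little-endian doubles with a
#'     JSON sidecar `<path>.json` holding `{"dim": [nx, ny, nt]}`.
#' }
#' The applied rescale factor is recorded in the `"rescale"` attribute so
#' [write_stack()] can invert it.
#'
#' @param path File or directory path.
#' @return 3-D numeric array (`nx x ny x nt`).
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) < 3) stop("PNG directory must hold at least 3 frames", call. = FALSE)
    frames <- lapply(files, png::readPNG)
  } else {
    if (!file.exists(path)) stop("cannot read `", path, "`: no such file", call. = FALSE)
    if (grepl("\\.(bin|raw)$", path, ignore.case = TRUE)) {
      sidecar <- paste0(path, ".json")
      if (!file.exists(sidecar))
        stop("raw array file needs a JSON sidecar `", sidecar, "`", call. = FALSE)
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      d <- as.integer(meta$dim)
      vals <- readBin(path, "double", n = prod(d), endian = "little")
      z <- array(vals, d)
      attr(z, "rescale") <- 1
      return(check_sequence(z, min_frames = 3))
    }
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    # affine rescale recorded by write_stack() in a JSON sidecar
    rescale <- NULL
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (isTRUE(meta$jpllk_rescale)) rescale <- meta
    }
  }
  if (length(frames) < 3) stop("stack must hold at least 3 frames", call. = FALSE)
  frames <- lapply(frames, function(f) if (length(dim(f)) == 3) f[, , 1] else f)
  shapes <- vapply(frames, function(f) paste(dim(f), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1)
    stop("inconsistent frame shapes: ", paste(unique(shapes), collapse = ", "),
         call. = FALSE)
  z <- array(unlist(frames), c(dim(frames[[1]]), length(frames)))
  if (exists("rescale", inherits = FALSE) && !is.null(rescale))
    z <- z * rescale$scale + rescale$offset
  attr(z, "rescale") <- 1  # readTIFF/readPNG already map integer dtypes to [0,1]
  check_sequence(z, min_frames = 3)
}

#' Write a 3-D array as an image stack
#'
#' @param z 3-D numeric array, frames along the last axis.
#' @param path Output path. `.tif`/`.tiff` writes a 32-bit float multi-page
#'   TIFF (lossless for values in `[0, 1]`); `.bin`/`.raw` writes
#'   little-endian doubles plus a JSON sidecar with the dimensions (lossless
#'   for any values); a directory path writes numbered 8-bit PNG frames
#'   (values clipped to `[0, 1]`; a preview format, not lossless).
#' @return `path`, invisibly.
#' @export
write_stack <- function(z, path) {
  check_sequence(z)
  if (grepl("\\.(bin|raw)$", path, ignore.case = TRUE)) {
    writeBin(as.double(z), path, endian = "little")
    jsonlite::write_json(list(dim = dim(z)), paste0(path, ".json"),
                         auto_unbox = FALSE, digits = NA)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    # float TIFF storage is defined on [0, 1]; out-of-range stacks are
    # affinely mapped there and the inverse recorded in a JSON sidecar
    lo <- min(z); hi <- max(z)
    if (lo >= 0 && hi <= 1) {
      frames <- lapply(seq_len(dim(z)[3]), function(k) z[, , k])
      tiff::writeTIFF(frames, path, bits.per.sample = 32)
    } else {
      scale <- if (hi > lo) hi - lo else 1
      zz <- (z - lo) / scale
      frames <- lapply(seq_len(dim(z)[3]), function(k) zz[, , k])
      tiff::writeTIFF(frames, path, bits.per.sample = 32)
      jsonlite::write_json(list(jpllk_rescale = TRUE, offset = lo,
                                scale = scale),
                           paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    }
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_len(dim(z)[3])) {
      png::writePNG(pmin(pmax(z[, , k], 0), 1),
                    file.path(path, sprintf("%04d.png", k)))
    }
  }
  invisible(path)
}
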