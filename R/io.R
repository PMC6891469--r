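# Stack and field readers/writers: multi-page TIFF + JSON sidecar.
# Raw stacks are stored as 16-bit unsigned pages (codes / 65535 on disk),
# normalized stacks and fields as 32-bit float pages scaled to [0, 1] with the
# scale recorded in the sidecar; page order matches plan order.

#' Write a low-resolution stack to disk
#'
#' Writes `<path>.tiff` (multi-page) and `<path>.json` (per-page metadata:
#' LED index, exposure, duty cycle, saturation count; plus shape, pitch and
#' the on-disk scale factor).
#'
#' @param stack an [LRStack-class]
#' @param path output path without extension
#' @return invisibly, the two file paths
#' @export
writeStack <- function(stack, path) {
  imgs <- stack@images
  maxVal <- max(1e-12, max(vapply(imgs, max, 0)))
  scale <- if (stack@normalized) maxVal else 65535
  pages <- lapply(imgs, function(m) pmin(pmax(m / scale, 0), 1))
  bits <- if (stack@normalized) 32L else 16L
  tiffPath <- paste0(path, ".tiff")
  jsonPath <- paste0(path, ".json")
  tiff::writeTIFF(pages, tiffPath, bits.per.sample = bits)
  meta <- stack@meta
  meta$saturated_pixels <- vapply(stack@satMask, sum, 0L)
  side <- list(
    shape = dim(imgs[[1]]),
    n_images = length(imgs),
    pixel_pitch_um = stack@pixelPitchUm,
    normalized = stack@normalized,
    scale = scale,
    pages = meta,
    sat_idx = lapply(stack@satMask, which)
  )
  jsonlite::write_json(side, jsonPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(tiffPath, jsonPath))
}

#' Read a low-resolution stack written by [writeStack()]
#'
#' Validates the page count and shape against the sidecar and restores the
#' saturation masks from the recorded pixel indices.
#'
#' @param path path without extension, as passed to [writeStack()]
#' @return an [LRStack-class]
#' @export
readStack <- function(path) {
  tiffPath <- paste0(path, ".tiff")
  jsonPath <- paste0(path, ".json")
  if (!file.exists(tiffPath) || !file.exists(jsonPath))
    stop("expected stack files ", tiffPath, " and ", jsonPath)
  side <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiffPath, all = TRUE)
  if (length(pages) != side$n_images)
    stop("page count ", length(pages), " does not match sidecar (",
         side$n_images, ")")
  imgs <- lapply(pages, function(p) p * side$scale)
  if (!all(dim(imgs[[1]]) == side$shape))
    stop("page shape does not match sidecar")
  meta <- as.data.frame(side$pages)
  masks <- lapply(seq_along(imgs), function(i) {
    m <- matrix(FALSE, nrow(imgs[[i]]), ncol(imgs[[i]]))
    if (!is.null(side$sat_idx) && length(side$sat_idx) >= i)
      m[unlist(side$sat_idx[[i]])] <- TRUE
    m
  })
  new("LRStack", images = imgs, meta = meta, satMask = masks,
      pixelPitchUm = side$pixel_pitch_um, normalized = side$normalized)
}

#' Write a complex field as paired amplitude/phase TIFFs
#'
#' Writes `<path>_amplitude.tiff` and `<path>_phase.tiff` (32-bit float,
#' scaled to [0, 1] on disk) plus `<path>.json` recording the pitch and the
#' scale/offset needed to invert the mapping.
#'
#' @param field a [ComplexField-class]
#' @param path output path without extension
#' @return invisibly, the file paths
#' @export
writeComplexField <- function(field, path) {
  a <- amplitude(field)
  ph <- phaseMap(field)
  aScale <- max(1e-12, max(a))
  tiff::writeTIFF(a / aScale, paste0(path, "_amplitude.tiff"),
                  bits.per.sample = 32L)
  tiff::writeTIFF((ph + pi) / (2 * pi), paste0(path, "_phase.tiff"),
                  bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_pitch_um = field@pixelPitchUm, amplitude_scale = aScale,
         phase_encoding = "(phase + pi) / (2 pi)"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(path, c("_amplitude.tiff", "_phase.tiff", ".json")))
}

#' Read a complex field written by [writeComplexField()]
#' @param path path without extension
#' @return a [ComplexField-class]
#' @export
readComplexField <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  a <- tiff::readTIFF(paste0(path, "_amplitude.tiff")) * side$amplitude_scale
  ph <- tiff::readTIFF(paste0(path, "_phase.tiff")) * 2 * pi - pi
  complexField(a * exp(1i * ph), side$pixel_pitch_um)
}
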