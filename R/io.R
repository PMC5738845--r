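#' Read a multi-page TIFF stack as a 3D grid
#'
#' Pages become z slices (z-major, third array axis). Integer samples (8/16
#' bit) are returned as their raw integer values; 32-bit float samples as
#' doubles. Two-channel stacks stored as interleaved pages are split into a
#' list of two grids of equal shape with `channels = 2`.
#'
#' @param path TIFF file path.
#' @param channels 1 or 2 (interleaved pages).
#' @return a 3D numeric array, or a list of two such arrays.
#' @export
read_stack <- function(path, channels = 1L) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                   info = TRUE),
                    error = function(e) stop("cannot read '", path, "': ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  bps <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bps) && bps == 32L) {
    # float samples: as.is applies an integer rescale, re-read raw
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  scale_back <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- tryCatch(jsonlite::read_json(sidecar), error = function(e) NULL)
    if (!is.null(meta) && identical(meta$format, "levelset3d-float"))
      scale_back <- c(as.numeric(meta$offset), as.numeric(meta$scale))
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] == 1L) p <- p[, , 1] else
        stop("unsupported multi-sample TIFF page in '", path, "'")
    }
    p
  })
  stack <- simplify2array(lapply(pages, function(p) { attributes(p) <- list(dim = dim(p)); p }))
  if (length(dim(stack)) == 2L) dim(stack) <- c(dim(stack), 1L)
  if (!is.null(scale_back)) stack <- stack * scale_back[2] + scale_back[1]
  if (channels == 2L) {
    nz <- dim(stack)[3]
    if (nz %% 2L != 0L) stop("odd page count for a two-channel stack: ", path)
    return(list(stack[, , seq(1L, nz, by = 2L), drop = FALSE],
                stack[, , seq(2L, nz, by = 2L), drop = FALSE]))
  }
  stack
}

#' Write a 3D grid as a multi-page TIFF stack
#'
#' `type = "uint8"`/`"uint16"` store rounded integer values (bit-exact
#' round-trip through [read_stack()]); `"float"` stores 32-bit floats (used
#' for level-set function exports; values round-trip to single precision,
#' with the affine normalisation recorded in a `<path>.json` sidecar).
#' `"auto"` picks uint8/uint16 for integer-valued non-negative data in
#' range, float otherwise.
#'
#' @param grid 3D numeric array.
#' @param path output path.
#' @param type `"auto"`, `"uint8"`, `"uint16"` or `"float"`.
#' @return invisibly, `path`.
#' @export
write_stack <- function(grid, path, type = c("auto", "uint8", "uint16", "float")) {
  assert_grid3d(grid, "grid")
  type <- match.arg(type)
  if (type == "auto") {
    intish <- all(grid == round(grid)) && min(grid) >= 0
    type <- if (intish && max(grid) <= 255) "uint8"
            else if (intish && max(grid) <= 65535) "uint16"
            else "float"
  }
  nz <- dim(grid)[3]
  if (type == "float") {
    # the TIFF writer stores samples in [0, 1]: normalise and record the
    # affine transform in the image description so reading restores values
    # (to single precision)
    off <- min(grid)
    sc <- max(grid) - off
    if (sc == 0) sc <- 1
    norm <- (grid - off) / sc
    pages <- lapply(seq_len(nz), function(k) norm[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(list(format = "levelset3d-float", offset = off,
                              scale = sc),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    mx <- if (type == "uint8") 255 else 65535
    if (min(grid) < 0 || max(grid) > mx)
      stop("values out of range for ", type, " TIFF: ", path)
    pages <- lapply(seq_len(nz), function(k) round(grid[, , k]) / mx)
    tiff::writeTIFF(pages, path,
                    bits.per.sample = if (type == "uint8") 8L else 16L,
                    reduce = FALSE)
  }
  invisible(path)
}
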