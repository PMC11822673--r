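#' Multi-channel image stack
#'
#' The common container for all imaging quantifiers: a numeric voxel grid with
#' physical voxel spacing and named channels. 2-D images are stored with a
#' single z-plane.
#'
#' @param data numeric array, either (x, y, channel) or (x, y, z, channel).
#' @param voxel_size numeric length-3, micrometres per voxel along x, y, z;
#'   all entries must be strictly positive.
#' @param channel_names character, one name per channel.
#' @return An object of class `image_stack`: a list with elements `data`
#'   (always 4-D), `voxel_size` and `channel_names`.
#' @examples
#' a <- array(0, dim = c(8, 8, 2))
#' s <- image_stack(a, voxel_size = c(0.2, 0.2, 0.3),
#'                  channel_names = c("nuclei", "p16"))
#' dim(channel(s, "nuclei"))
#' @export
image_stack <- function(data, voxel_size, channel_names) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3L])
  if (length(dim(data)) != 4L)
    stopf("`data` must be a 3-D (x,y,channel) or 4-D (x,y,z,channel) array")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stopf("`voxel_size` must be 3 strictly positive values (um)")
  if (length(channel_names) != dim(data)[4L])
    stopf("need %d channel names, got %d", dim(data)[4L], length(channel_names))
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 channel_names = as.character(channel_names)),
            class = "image_stack")
}

#' Extract one channel of an image stack as a 3-D array
#'
#' @param stack an [image_stack()].
#' @param name channel name.
#' @export
channel <- function(stack, name) {
  i <- match(name, stack$channel_names)
  if (is.na(i)) stopf("no channel '%s' (have: %s)", name,
                      paste(stack$channel_names, collapse = ", "))
  out <- stack$data[, , , i]
  if (length(dim(out)) != 3L) dim(out) <- dim(stack$data)[1:3]
  out
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d x %d voxels, %d channel(s): %s\n",
              d[1], d[2], d[3], d[4], paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  voxel size (um): %s\n", paste(x$voxel_size, collapse = " x ")))
  invisible(x)
}

#' Write an image stack as multi-page TIFF plus a JSON sidecar
#'
#' One TIFF page per (z, channel) plane, channel-major within each z-plane;
#' channel names, voxel size and dimensions go in `<path>.json` because TIFF
#' tags cannot carry them portably.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  d <- dim(stack$data)
  pages <- vector("list", d[3L] * d[4L])
  k <- 1L
  mx <- max(stack$data, 1e-12)
  for (z in seq_len(d[3L])) for (ch in seq_len(d[4L])) {
    # tiff stores [row, col]; transpose so x stays the first array axis on read
    pages[[k]] <- t(pmin(pmax(stack$data[, , z, ch] / mx, 0), 1))
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(dim = d, voxel_size = stack$voxel_size,
               channel_names = stack$channel_names, intensity_scale = mx)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path (expects `<path>.json` sidecar alongside).
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  a <- array(0, dim = d)
  k <- 1L
  for (z in seq_len(d[3L])) for (ch in seq_len(d[4L])) {
    a[, , z, ch] <- t(pages[[k]]) * meta$intensity_scale
    k <- k + 1L
  }
  image_stack(a, voxel_size = meta$voxel_size, channel_names = meta$channel_names)
}
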