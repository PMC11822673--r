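#' Generate a synthetic voiding-spot-assay image
#'
#' Emulates a UV-imaged filter paper: bright urine spots on a dark
#' background, with a controllable fraction of spots biased into the cage
#' corners (old mice void away from corners, so corner preference is the
#' discriminating metric). Spots are non-overlapping disks.
#'
#' @param n_spots number of spots.
#' @param area_distribution spot areas in cm^2: a numeric vector of length
#'   `n_spots`, or a function `f(n)` returning `n` areas.
#' @param corner_bias probability a spot centroid is placed inside a corner
#'   region (remaining spots are placed with centroid outside the corners).
#' @param cage_dims cage (width, height) in cm.
#' @param px_per_cm pixel calibration.
#' @param corner_fraction each corner region is a
#'   `corner_fraction x width` by `corner_fraction x height` rectangle.
#' @param noise_sd additive background noise SD.
#' @param seed integer seed.
#' @return list with `image` (2-D [image_stack()], channel `uv`), and
#'   `truth`: per-spot data.frame (id, centre in cm, area_cm2, in_corner,
#'   is_large under the >3 cm equivalent-diameter rule), parameters, seed.
#' @export
gen_vsa_image <- function(n_spots,
                          area_distribution = function(n) exp(rnorm(n, log(6), 0.6)),
                          corner_bias = 0.7,
                          cage_dims = c(27, 16),
                          px_per_cm = 10,
                          corner_fraction = 0.25,
                          noise_sd = 0.02,
                          seed = 1L) {
  if (px_per_cm <= 0) stopf("px_per_cm must be positive")
  if (corner_bias < 0 || corner_bias > 1) stopf("corner_bias must be in [0,1]")
  W <- cage_dims[1]; H <- cage_dims[2]
  areas <- if (is.function(area_distribution)) NULL else {
    if (length(area_distribution) != n_spots)
      stopf("area_distribution vector must have length n_spots")
    as.numeric(area_distribution)
  }
  with_seed(seed, {
    if (is.null(areas)) areas <- as.numeric(area_distribution(n_spots))
    if (any(areas <= 0)) stopf("spot areas must be positive")
    radii <- sqrt(areas / pi)
    if (n_spots > 0 && 2 * (max(radii) + 0.4) >= min(W, H))
      stopf("placement failure: spot of %.1f cm2 cannot fit a %gx%g cm cage",
            max(areas), W, H)
    in_corner <- if (n_spots == 0) logical(0) else runif(n_spots) < corner_bias
    cw <- corner_fraction * W; chh <- corner_fraction * H
    ord <- order(radii, decreasing = TRUE)  # large spots first: easier packing
    centers <- NULL
    for (attempt in 1:30) {                # whole-layout retry before failing
      centers <- matrix(NA_real_, n_spots, 2)
      layout_ok <- TRUE
      for (i in ord) {
        r <- radii[i]
        ok <- FALSE
        for (t in 1:4000) {
          p <- c(runif(1, r + 0.2, W - r - 0.2), runif(1, r + 0.2, H - r - 0.2))
          corner_hit <- (p[1] <= cw || p[1] >= W - cw) && (p[2] <= chh || p[2] >= H - chh)
          if (corner_hit != in_corner[i]) next
          prev <- which(!is.na(centers[, 1]))
          if (length(prev) &&
              any((centers[prev, 1] - p[1])^2 + (centers[prev, 2] - p[2])^2 <
                  (radii[prev] + r + 0.3)^2)) next
          ok <- TRUE; break
        }
        if (!ok) { layout_ok <- FALSE; break }
        centers[i, ] <- p
      }
      if (layout_ok) break
      if (attempt == 30)
        stopf("placement failure: could not place %d spots in a %gx%g cm cage",
              n_spots, W, H)
    }
    nx <- as.integer(round(W * px_per_cm)); ny <- as.integer(round(H * px_per_cm))
    dim3 <- c(nx, ny, 1L)
    img <- array(0, dim = dim3)
    for (i in seq_len(n_spots)) {
      rpx <- radii[i] * px_per_cm
      ctr <- c(centers[i, ] * px_per_cm + 0.5, 1)
      img[ellipsoid_voxels(ctr, c(rpx, rpx, 0.5), dim3)] <- 1
    }
    if (noise_sd > 0) img <- pmax(img + rnorm(length(img), 0, noise_sd), 0)
    a <- array(img, dim = c(dim3, 1L))
    image <- image_stack(a, voxel_size = c(1 / px_per_cm, 1 / px_per_cm, 1),
                         channel_names = "uv")
    diam <- 2 * radii
    truth <- data.frame(id = seq_len(n_spots),
                        x_cm = centers[, 1], y_cm = centers[, 2],
                        area_cm2 = areas, in_corner = in_corner,
                        is_large = diam > 3)
    list(image = image,
         truth = list(spots = truth, seed = seed,
                      params = list(n_spots = n_spots, corner_bias = corner_bias,
                                    cage_dims = cage_dims, px_per_cm = px_per_cm,
                                    corner_fraction = corner_fraction,
                                    noise_sd = noise_sd)))
  })
}

#' Detect urine spots in a voiding-spot-assay image
#'
#' Connected bright components with area of at least `min_area_cm2`, areas
#' converted through the pixel calibration squared.
#'
#' @param image 2-D [image_stack()] (first channel is used).
#' @param threshold intensity threshold.
#' @param min_area_cm2 smallest reportable spot.
#' @param px_per_cm pixel calibration (> 0).
#' @param cage_dims cage (width, height) in cm; defaults to the image extent.
#' @return a `spot_set`: list with `spots` (id, n_px, area_cm2, x_cm, y_cm,
#'   in_corner = NA until [assign_corners()]), `px_per_cm`, `cage_dims`.
#' @export
detect_spots <- function(image, threshold = 0.5, min_area_cm2 = 0.1, px_per_cm,
                         cage_dims = NULL) {
  if (px_per_cm <= 0) stopf("px_per_cm must be positive")
  ch <- image$data[, , 1, 1]
  d <- dim(ch)
  if (is.null(cage_dims)) cage_dims <- d / px_per_cm
  lab <- label_components(array(ch > threshold, dim = c(d, 1L)))
  n <- max(lab)
  if (n == 0L) {
    spots <- data.frame(id = integer(0), n_px = integer(0), area_cm2 = numeric(0),
                        x_cm = numeric(0), y_cm = numeric(0), in_corner = logical(0))
    return(structure(list(spots = spots, px_per_cm = px_per_cm, cage_dims = cage_dims),
                     class = "spot_set"))
  }
  idx <- which(lab > 0L)
  labv <- lab[idx]
  x <- ((idx - 1L) %% d[1L]) + 1L
  y <- (((idx - 1L) %/% d[1L]) %% d[2L]) + 1L
  n_px <- tabulate(labv, nbins = n)
  spots <- data.frame(id = seq_len(n), n_px = n_px,
                      area_cm2 = n_px / px_per_cm^2,
                      x_cm = (vapply(split(x, labv), mean, numeric(1)) - 0.5) / px_per_cm,
                      y_cm = (vapply(split(y, labv), mean, numeric(1)) - 0.5) / px_per_cm,
                      in_corner = NA)
  spots <- spots[spots$area_cm2 >= min_area_cm2, , drop = FALSE]
  spots$id <- seq_len(nrow(spots))
  rownames(spots) <- NULL
  structure(list(spots = spots, px_per_cm = px_per_cm, cage_dims = cage_dims),
            class = "spot_set")
}

#' Assign spots to cage-corner regions
#'
#' The four corner regions are rectangles of size
#' `(corner_fraction x W) x (corner_fraction x H)`; a spot is in a corner iff
#' its centroid lies inside one (centroid membership keeps the rule simple
#' and reproducible).
#'
#' @param spot_set a `spot_set` from [detect_spots()].
#' @param corner_fraction fraction of each cage dimension (default 0.25).
#' @return the `spot_set` with `in_corner` filled in and the percent of void
#'   area in corners attached as `percent_area_in_corners` (NA when total
#'   area is zero).
#' @export
assign_corners <- function(spot_set, corner_fraction = 0.25) {
  W <- spot_set$cage_dims[1]; H <- spot_set$cage_dims[2]
  cw <- corner_fraction * W; chh <- corner_fraction * H
  s <- spot_set$spots
  s$in_corner <- (s$x_cm <= cw | s$x_cm >= W - cw) &
                 (s$y_cm <= chh | s$y_cm >= H - chh)
  spot_set$spots <- s
  spot_set$corner_fraction <- corner_fraction
  spot_set$percent_area_in_corners <- if (sum(s$area_cm2) > 0)
    100 * sum(s$area_cm2[s$in_corner]) / sum(s$area_cm2) else NA_real_
  spot_set
}

#' The four voiding-spot-assay metrics
#'
#' Total number of voids, total void area (cm^2), percent of void area in
#' cage corners, and percent of large voids of total voids. "Large" defaults
#' to equivalent-circle diameter above `large_threshold` (3 cm); the
#' area reading (> 3 cm^2) is available via `large_metric = "area"`.
#'
#' @param spot_set a `spot_set` with corners assigned.
#' @param large_threshold threshold for a large void (cm or cm^2).
#' @param large_metric `"diameter"` or `"area"`.
#' @return list: `total_voids`, `total_area_cm2`, `percent_area_in_corners`,
#'   `percent_large_voids` (percents NA when there are no spots), and the
#'   per-spot table with `is_large` filled in.
#' @export
vsa_metrics <- function(spot_set, large_threshold = 3,
                        large_metric = c("diameter", "area")) {
  large_metric <- match.arg(large_metric)
  s <- spot_set$spots
  if (any(is.na(s$in_corner))) stopf("run assign_corners() first")
  size <- if (large_metric == "diameter") 2 * sqrt(s$area_cm2 / pi) else s$area_cm2
  s$is_large <- size > large_threshold
  n <- nrow(s)
  list(total_voids = n,
       total_area_cm2 = sum(s$area_cm2),
       percent_area_in_corners = if (n > 0 && sum(s$area_cm2) > 0)
         100 * sum(s$area_cm2[s$in_corner]) / sum(s$area_cm2) else NA_real_,
       percent_large_voids = if (n > 0) 100 * sum(s$is_large) / n else NA_real_,
       spots = s)
}
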