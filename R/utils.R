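#' @importFrom stats rnorm rbinom rpois runif rnbinom rlnorm quantile mad
#'   pt pf ptukey pwilcox rchisq median sd var complete.cases aggregate
#'   p.adjust setNames
#' @importFrom utils head read.csv write.csv read.delim write.table
NULL

## Internal geometry / image helpers shared by the generators and quantifiers.
## All voxel grids are numeric arrays indexed [x, y, z]; 2-D images use z = 1.

#' Label connected foreground components of a binary mask
#'
#' 6-connectivity in 3D (4-connectivity for single-plane images). Built on an
#' adjacency edge list and `igraph::components`, which keeps the pass
#' vectorised even for large sparse masks.
#'
#' @param mask logical array (x, y, z); `TRUE` is foreground.
#' @return integer array of the same dimension; 0 is background, components
#'   are numbered 1..k in order of their smallest linear index.
#' @keywords internal
label_components <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) d <- c(d, 1L)
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  idx <- which(mask)
  lab <- array(0L, dim = d)
  if (length(idx) == 0L) return(lab)
  pos <- integer(prod(d))
  pos[idx] <- seq_along(idx)
  # voxel coordinates for boundary checks
  x <- ((idx - 1L) %% nx) + 1L
  y <- (((idx - 1L) %/% nx) %% ny) + 1L
  z <- ((idx - 1L) %/% (nx * ny)) + 1L
  ef <- list()
  ok <- x < nx & mask[pmin(idx + 1L, prod(d))]
  ef[[1L]] <- cbind(pos[idx[ok]], pos[idx[ok] + 1L])
  ok <- y < ny & mask[pmin(idx + nx, prod(d))]
  ef[[2L]] <- cbind(pos[idx[ok]], pos[idx[ok] + nx])
  if (nz > 1L) {
    ok <- z < nz & mask[pmin(idx + nx * ny, prod(d))]
    ef[[3L]] <- cbind(pos[idx[ok]], pos[idx[ok] + nx * ny])
  }
  edges <- do.call(rbind, ef)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # renumber components by first occurrence so labels are deterministic
  comp <- match(comp, unique(comp))
  lab[idx] <- comp
  lab
}

#' Separable Gaussian blur of a 3-D intensity array
#'
#' @param a numeric array (x, y, z).
#' @param sigma_px per-axis standard deviation in pixels (length 3); axes with
#'   sigma below 0.05 px are left untouched.
#' @keywords internal
gaussian_blur <- function(a, sigma_px) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_px[ax]
    if (is.na(s) || s < 0.05 || d[ax] == 1L) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    a <- conv_axis(a, k, ax)
  }
  a
}

# zero-padded 1-D convolution along axis `ax` of a 3-D array, by shift-and-sum
# on matrix views (kernels here are a handful of taps, so this beats FFT)
conv_axis <- function(a, k, ax) {
  d <- dim(a)
  r <- (length(k) - 1L) %/% 2L
  n <- d[ax]
  shifts <- lapply(seq_along(k), function(t) {
    o <- t - r - 1L
    src <- seq.int(max(1L, 1L + o), min(n, n + o))
    list(src = src, dst = src - o, w = k[t])
  })
  acc_mat <- function(m) {  # convolve along rows of matrix m
    out <- matrix(0, nrow(m), ncol(m))
    for (s in shifts)
      out[s$dst, ] <- out[s$dst, ] + s$w * m[s$src, ]
    out
  }
  if (ax == 1L) {
    m <- matrix(a, nrow = d[1L])
    array(acc_mat(m), dim = d)
  } else if (ax == 3L) {
    m <- matrix(a, ncol = d[3L])
    array(t(acc_mat(t(m))), dim = d)
  } else {
    for (z in seq_len(d[3L]))
      a[, , z] <- t(acc_mat(t(a[, , z, drop = TRUE])))
    a
  }
}

#' Linear voxel indices of an ellipsoid
#'
#' @param center voxel coordinates (x, y, z), may be fractional.
#' @param radius_px per-axis radius in pixels (length 3).
#' @param dim grid dimension.
#' @keywords internal
ellipsoid_voxels <- function(center, radius_px, dim) {
  lo <- pmax(1L, floor(center - radius_px))
  hi <- pmin(dim, ceiling(center + radius_px))
  if (any(lo > hi)) return(integer(0))
  xs <- lo[1L]:hi[1L]; ys <- lo[2L]:hi[2L]; zs <- lo[3L]:hi[3L]
  dx2 <- ((xs - center[1L]) / radius_px[1L])^2
  dy2 <- ((ys - center[2L]) / radius_px[2L])^2
  dz2 <- ((zs - center[3L]) / radius_px[3L])^2
  g <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  keep <- which(g <= 1)
  if (length(keep) == 0L) return(integer(0))
  co <- arrayInd(keep, .dim = c(length(xs), length(ys), length(zs)))
  (xs[co[, 1L]]) +
    (ys[co[, 2L]] - 1L) * dim[1L] +
    (zs[co[, 3L]] - 1L) * dim[1L] * dim[2L]
}

#' Equivalent diameter of an object from its pixel/voxel count
#'
#' Diameter of the circle (2-D) or sphere (3-D) with the same pixel/voxel
#' count, in pixel units.
#' @keywords internal
equivalent_diameter <- function(n_vox, three_d) {
  if (three_d) 2 * (3 * n_vox / (4 * pi))^(1 / 3) else 2 * sqrt(n_vox / pi)
}

# deterministic child seed derived from a user seed, kept below 2^31
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1299721) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
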