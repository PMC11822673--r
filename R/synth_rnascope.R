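#' Generate a synthetic RNAscope-style 2-D field (nuclei + p16 puncta)
#'
#' Emulates a fluorescence in-situ field in which punctate p16 signal is
#' localised to DAPI-stained nuclei. A controllable fraction of nuclei is
#' positive; each positive nucleus receives in-gate puncta. Debris objects
#' falling outside the puncta diameter gate (too small or too large -- the
#' lipofuscin-like confounders) are scattered outside nuclei so the gate, not
#' location, is what excludes them.
#'
#' @param n_nuclei number of nuclei.
#' @param positive_fraction probability a nucleus is positive.
#' @param puncta_per_positive puncta per positive nucleus: a single count or a
#'   function `f(n)` returning `n` counts (each at least 1).
#' @param nucleus_diam_px nucleus diameter range (px), inside the 10-50 px gate.
#' @param puncta_diam_px puncta diameter range (px), inside the 3-10 px gate;
#'   the lower bound must be at least 1 and the upper bound must not exceed
#'   the nucleus lower bound.
#' @param debris_density number of out-of-gate debris objects in the field.
#' @param noise_sd additive Gaussian noise SD.
#' @param dim optional image dimension (x, y); auto-sized when `NULL`.
#' @param seed integer seed.
#' @return list with `stack` (2-D [image_stack()], channels `nuclei`, `p16`)
#'   and `truth` (per-nucleus record with centre, diameter, positive flag and
#'   puncta count; per-punctum and per-debris records; parameters; seed).
#' @export
gen_rnascope_image <- function(n_nuclei,
                               positive_fraction = 0.1,
                               puncta_per_positive = 5,
                               nucleus_diam_px = c(24, 40),
                               puncta_diam_px = c(3.5, 5.5),
                               debris_density = 10,
                               noise_sd = 0.02,
                               dim = NULL,
                               seed = 1L) {
  if (positive_fraction < 0 || positive_fraction > 1)
    stopf("positive_fraction must be in [0,1]")
  if (puncta_diam_px[1] < 1 || puncta_diam_px[2] < puncta_diam_px[1] ||
      puncta_diam_px[2] > nucleus_diam_px[1])
    stopf("puncta_diam_px must lie within [1, lower nucleus diameter]")
  if (nucleus_diam_px[2] < nucleus_diam_px[1]) stopf("invalid nucleus_diam_px range")
  rmax <- nucleus_diam_px[2] / 2
  if (is.null(dim)) {
    side <- ceiling(sqrt(n_nuclei * (2.6 * rmax)^2)) + 20L
    dim <- c(side, side)
  }
  dim3 <- c(as.integer(dim), 1L)

  with_seed(seed, {
    ## nuclei: non-overlapping disks
    nx <- dim3[1L]; ny <- dim3[2L]
    centers <- matrix(NA_real_, n_nuclei, 2)
    radii <- runif(n_nuclei, nucleus_diam_px[1] / 2, nucleus_diam_px[2] / 2)
    placed <- 0L; tries <- 0L
    while (placed < n_nuclei) {
      tries <- tries + 1L
      if (tries > 4000L * n_nuclei)
        stopf("placement failure: could not place %d nuclei in a %dx%d field",
              n_nuclei, nx, ny)
      r <- radii[placed + 1L]
      p <- runif(2, min = r + 2, max = c(nx, ny) - r - 1)
      if (placed > 0L) {
        d2 <- (centers[1:placed, 1] - p[1])^2 + (centers[1:placed, 2] - p[2])^2
        if (any(d2 < (radii[1:placed] + r + 3)^2)) next
      }
      placed <- placed + 1L
      centers[placed, ] <- p
    }
    positive <- if (positive_fraction >= 1) rep(TRUE, n_nuclei)
                else if (positive_fraction <= 0) rep(FALSE, n_nuclei)
                else runif(n_nuclei) < positive_fraction
    counts <- integer(n_nuclei)
    npos <- sum(positive)
    if (npos > 0) {
      counts[positive] <- if (is.function(puncta_per_positive))
        as.integer(puncta_per_positive(npos)) else rep(as.integer(puncta_per_positive), npos)
      if (any(counts[positive] < 1L))
        stopf("puncta_per_positive must give counts of at least 1")
    }

    ## puncta inside their nucleus, mutually separated so they never merge;
    ## the whole arrangement is retried before declaring placement failure
    puncta <- list()
    for (i in which(positive)) {
      placed_p <- NULL
      for (attempt in 1:40) {
        placed_p <- list()
        ok_all <- TRUE
        for (j in seq_len(counts[i])) {
          dpx <- runif(1, puncta_diam_px[1], puncta_diam_px[2])
          ok <- FALSE
          for (t in 1:400) {
            ang <- runif(1, 0, 2 * pi)
            rad <- (radii[i] - dpx / 2 - 1.5) * sqrt(runif(1))
            p <- centers[i, ] + rad * c(cos(ang), sin(ang))
            ok <- all(vapply(placed_p, function(q)
              sqrt(sum((q$p - p)^2)) >= (q$d + dpx) / 2 + 2, logical(1)))
            if (ok) break
          }
          if (!ok) { ok_all <- FALSE; break }
          placed_p[[j]] <- list(p = p, d = dpx)
        }
        if (ok_all) break
        if (attempt == 40) stopf("placement failure: puncta too dense for nucleus size")
      }
      for (j in seq_along(placed_p))
        puncta[[length(puncta) + 1L]] <- data.frame(
          nucleus = i, cx = placed_p[[j]]$p[1], cy = placed_p[[j]]$p[2],
          diam_px = placed_p[[j]]$d)
    }

    ## debris, outside nuclei, out of gate: half tiny (1-2 px), half large
    debris <- list()
    n_debris <- as.integer(debris_density)
    for (j in seq_len(n_debris)) {
      dpx <- if (j %% 2L == 0L) runif(1, 1, max(1.2, puncta_diam_px[1] - 2))
             else runif(1, 12, 15)
      for (t in 1:2000) {
        p <- runif(2, min = dpx / 2 + 2, max = c(nx, ny) - dpx / 2 - 1)
        d2 <- (centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2
        if (all(d2 > (radii + dpx / 2 + 4)^2)) break
        if (t == 2000) stopf("placement failure: no room for debris objects")
      }
      debris[[j]] <- data.frame(cx = p[1], cy = p[2], diam_px = dpx)
    }

    ## render
    nch <- array(0, dim = dim3); pch <- array(0, dim = dim3)
    for (i in seq_len(n_nuclei))
      nch[ellipsoid_voxels(c(centers[i, ], 1), c(radii[i], radii[i], 0.5), dim3)] <- 0.8
    pdf_ <- if (length(puncta)) do.call(rbind, puncta) else
      data.frame(nucleus = integer(0), cx = numeric(0), cy = numeric(0), diam_px = numeric(0))
    for (k in seq_len(nrow(pdf_)))
      pch[ellipsoid_voxels(c(pdf_$cx[k], pdf_$cy[k], 1),
                           c(pdf_$diam_px[k] / 2, pdf_$diam_px[k] / 2, 0.5), dim3)] <- 1
    ddf <- if (length(debris)) do.call(rbind, debris) else
      data.frame(cx = numeric(0), cy = numeric(0), diam_px = numeric(0))
    for (k in seq_len(nrow(ddf)))
      pch[ellipsoid_voxels(c(ddf$cx[k], ddf$cy[k], 1),
                           c(ddf$diam_px[k] / 2, ddf$diam_px[k] / 2, 0.5), dim3)] <- 0.9
    if (noise_sd > 0) {
      nch <- pmax(nch + rnorm(length(nch), 0, noise_sd), 0)
      pch <- pmax(pch + rnorm(length(pch), 0, noise_sd), 0)
    }
    a <- array(0, dim = c(dim3, 2L))
    a[, , , 1] <- nch; a[, , , 2] <- pch
    stack <- image_stack(a, voxel_size = c(1, 1, 1),
                         channel_names = c("nuclei", "p16"))
    truth <- list(
      nuclei = data.frame(id = seq_len(n_nuclei), cx = centers[, 1], cy = centers[, 2],
                          radius_px = radii, positive = positive, n_puncta = counts),
      puncta = pdf_, debris = ddf, dim = dim3, seed = seed,
      params = list(n_nuclei = n_nuclei, positive_fraction = positive_fraction,
                    nucleus_diam_px = nucleus_diam_px, puncta_diam_px = puncta_diam_px,
                    debris_density = debris_density, noise_sd = noise_sd))
    list(stack = stack, truth = truth)
  })
}

#' Generate a synthetic SA beta-galactosidase-stained section
#'
#' Emulates a brightfield section in which the senescence-associated
#' beta-galactosidase product stains positive cells blue, positivity being
#' restricted to the luminal (surface) urothelial layer. The image carries
#' three colour channels plus a luminal-layer mask channel; luminal cells are
#' a single surface row of disks, non-luminal cells sit beneath and are never
#' positive.
#'
#' @param n_luminal_cells number of luminal (surface) cells.
#' @param n_nonluminal_cells number of underlying cells (never positive).
#' @param positive_fraction_luminal probability a luminal cell is positive.
#' @param cell_radius_px cell radius in px.
#' @param noise_sd additive colour noise SD.
#' @param seed integer seed.
#' @return list with `stack` (2-D [image_stack()], channels `red`, `green`,
#'   `blue`, `luminal_mask`) and `truth` (per-cell record with layer,
#'   positive flag and centre; parameters; seed).
#' @export
gen_sabgal_section <- function(n_luminal_cells,
                               n_nonluminal_cells = 40,
                               positive_fraction_luminal = 0.45,
                               cell_radius_px = 6,
                               noise_sd = 0.02,
                               seed = 1L) {
  if (positive_fraction_luminal < 0 || positive_fraction_luminal > 1)
    stopf("positive_fraction_luminal must be in [0,1]")
  if (n_luminal_cells < 1) stopf("need at least one luminal cell")
  r <- cell_radius_px
  pitch <- 2 * r + 4
  nx <- max(n_luminal_cells, ceiling(n_nonluminal_cells / 3)) * pitch + 2 * pitch
  rows_nl <- if (n_nonluminal_cells > 0) ceiling(n_nonluminal_cells / floor((nx - pitch) / pitch)) else 0
  ny <- (rows_nl + 3) * pitch

  with_seed(seed, {
    positive <- if (positive_fraction_luminal >= 1) rep(TRUE, n_luminal_cells)
                else if (positive_fraction_luminal <= 0) rep(FALSE, n_luminal_cells)
                else runif(n_luminal_cells) < positive_fraction_luminal
    # luminal row along the top of the section
    lum <- data.frame(id = seq_len(n_luminal_cells),
                      cx = pitch + (seq_len(n_luminal_cells) - 1) * pitch +
                        runif(n_luminal_cells, -1.5, 1.5),
                      cy = pitch + runif(n_luminal_cells, -1, 1),
                      layer = "luminal", positive = positive)
    nl <- NULL
    if (n_nonluminal_cells > 0) {
      per_row <- floor((nx - pitch) / pitch)
      ij <- seq_len(n_nonluminal_cells) - 1L
      nl <- data.frame(id = n_luminal_cells + seq_len(n_nonluminal_cells),
                       cx = pitch + (ij %% per_row) * pitch + runif(n_nonluminal_cells, -1.5, 1.5),
                       cy = 2.5 * pitch + (ij %/% per_row) * pitch + runif(n_nonluminal_cells, -1, 1),
                       layer = "nonluminal", positive = FALSE)
    }
    cells <- rbind(lum, nl)
    dim3 <- c(as.integer(nx), as.integer(ny), 1L)
    rch <- array(0, dim = dim3); gch <- array(0, dim = dim3)
    bch <- array(0, dim = dim3); mch <- array(0, dim = dim3)
    # tissue background (pale eosin-like)
    rch[] <- 0.15; gch[] <- 0.12; bch[] <- 0.14
    for (k in seq_len(nrow(cells))) {
      v <- ellipsoid_voxels(c(cells$cx[k], cells$cy[k], 1), c(r, r, 0.5), dim3)
      if (cells$positive[k]) { rch[v] <- 0.15; gch[v] <- 0.30; bch[v] <- 0.85 }
      else { rch[v] <- 0.55; gch[v] <- 0.45; bch[v] <- 0.60 }   # hematoxylin
      if (cells$layer[k] == "luminal") mch[v] <- 1
    }
    if (noise_sd > 0) {
      n <- prod(dim3)
      rch <- pmin(pmax(rch + rnorm(n, 0, noise_sd), 0), 1)
      gch <- pmin(pmax(gch + rnorm(n, 0, noise_sd), 0), 1)
      bch <- pmin(pmax(bch + rnorm(n, 0, noise_sd), 0), 1)
    }
    a <- array(0, dim = c(dim3, 4L))
    a[, , , 1] <- rch; a[, , , 2] <- gch; a[, , , 3] <- bch; a[, , , 4] <- mch
    stack <- image_stack(a, voxel_size = c(1, 1, 1),
                         channel_names = c("red", "green", "blue", "luminal_mask"))
    truth <- list(cells = cells, dim = dim3, seed = seed,
                  params = list(n_luminal_cells = n_luminal_cells,
                                n_nonluminal_cells = n_nonluminal_cells,
                                positive_fraction_luminal = positive_fraction_luminal,
                                cell_radius_px = cell_radius_px, noise_sd = noise_sd))
    list(stack = stack, truth = truth)
  })
}
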