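# Seeded synthetic-data generators. Every generator takes an explicit seed,
# restores the caller's RNG state on exit, and returns machine-readable
# ground truth for each rendered object.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Generate a synthetic 3-D confocal stack with telomere and gamma-H2AX foci
#'
#' Emulates the structure of a telomere-associated-focus (TAF) experiment:
#' a nuclear-stain channel, a telomere channel and a DNA-damage (gamma-H2AX)
#' channel. A controllable fraction of telomere foci is co-placed with a
#' damage focus so their voxel overlap ratio is at least 1 percent (these are
#' the intended TAF pairs); all other telomere/damage foci are kept strictly
#' non-overlapping. Lipofuscin-like autofluorescent droplets are rendered in
#' the cytoplasm and emit in *both* detection channels, mimicking the aging
#' pigment that confounds real quantification. Foci are Gaussian-blurred
#' spheres; the blur stands in for the PSF of the instrument.
#'
#' @param n_nuclei number of nuclei.
#' @param telomere_foci_per_nucleus telomere foci per nucleus.
#' @param gH2AX_foci_per_nucleus *unpaired* damage foci per nucleus (paired
#'   damage foci are created by `taf_fraction` on top of these).
#' @param taf_fraction probability in `[0,1]` that a telomere focus receives a
#'   co-placed damage focus (a true TAF pair).
#' @param lipofuscin_density droplets per 1000 um^3 of stack volume.
#' @param blur_sigma Gaussian blur sigma in um.
#' @param noise_sd additive Gaussian noise SD (intensity units; foci have
#'   amplitude 1).
#' @param voxel_size um per voxel along (x, y, z).
#' @param nucleus_radius_um nucleus radius in um (scaled-down model).
#' @param dim optional grid dimension (x, y, z) in voxels; auto-sized when
#'   `NULL`. Placement that cannot satisfy the non-overlap constraints raises
#'   an explicit placement-failure error rather than silently truncating.
#' @param seed integer seed; identical (seed, parameters) give identical
#'   output.
#' @return list with `stack` (an [image_stack()] with channels
#'   `nuclei`, `telomere`, `gH2AX`) and `truth`, a list holding per-object
#'   records: `nuclei` (id, centre, radius, true TAF-pair count, senescent
#'   flag), `foci` (id, channel, nucleus, centre, radius, voxel count),
#'   `voxels` (named list of linear voxel indices per focus id, noiseless),
#'   `taf_pairs` (telomere id, damage id, nucleus, constructed overlap ratio),
#'   the generator parameters and the seed.
#' @export
gen_confocal_stack <- function(n_nuclei,
                               telomere_foci_per_nucleus = 10,
                               gH2AX_foci_per_nucleus = 3,
                               taf_fraction = 0.1,
                               lipofuscin_density = 0.5,
                               blur_sigma = 0.15,
                               noise_sd = 0.02,
                               voxel_size = c(0.3, 0.3, 0.4),
                               nucleus_radius_um = 3,
                               dim = NULL,
                               seed = 1L) {
  if (taf_fraction < 0 || taf_fraction > 1) stopf("taf_fraction must be in [0,1]")
  if (n_nuclei < 1) stopf("need at least one nucleus")
  r_nuc <- nucleus_radius_um
  r_tel <- 0.3; r_dam <- 0.4; r_lip <- 0.5
  vs <- voxel_size
  r_nuc_px <- r_nuc / vs
  if (is.null(dim)) {
    side <- ceiling(sqrt(n_nuclei * (2.9 * r_nuc_px[1])^2)) + 8L
    dim <- c(side, side, ceiling(2 * r_nuc_px[3]) + 8L)
  }
  dim <- as.integer(dim)

  with_seed(seed, {
    ## --- place nuclei (non-overlapping spheres) ---
    centers <- matrix(NA_real_, n_nuclei, 3)
    margin <- r_nuc_px + 2
    if (any(dim < 2 * margin + 2))
      stopf("placement failure: stack dim %s too small for nuclei", paste(dim, collapse = "x"))
    tries <- 0L; placed <- 0L
    max_tries <- 4000L * n_nuclei
    while (placed < n_nuclei) {
      tries <- tries + 1L
      if (tries > max_tries)
        stopf("placement failure: could not place %d nuclei in a %s stack",
              n_nuclei, paste(dim, collapse = "x"))
      p <- runif(3, min = margin + 1, max = dim - margin)
      if (placed > 0L) {
        d2 <- (centers[1:placed, 1] - p[1])^2 + (centers[1:placed, 2] - p[2])^2 +
          ((centers[1:placed, 3] - p[3]) * r_nuc_px[1] / r_nuc_px[3])^2
        if (any(d2 < (2 * r_nuc_px[1] + 2)^2)) next
      }
      placed <- placed + 1L
      centers[placed, ] <- p
    }

    ## --- place foci inside nuclei, in um offsets from the nucleus centre ---
    sep <- function(r1, r2) r1 + r2 + 2 * blur_sigma + 0.2  # no-contact margin, um
    foci <- list(); voxels <- list(); pairs <- list()
    fid <- 0L
    rand_in_sphere <- function(rmax) {
      v <- rnorm(3); v <- v / sqrt(sum(v^2))
      v * rmax * runif(1)^(1 / 3)
    }
    um_to_px <- function(nuc, off_um) centers[nuc, ] + off_um / vs

    for (nuc in seq_len(n_nuclei)) {
      tel_off <- list(); dam_off <- list()
      # telomere foci, mutually separated
      for (j in seq_len(telomere_foci_per_nucleus)) {
        for (t in 1:600) {
          o <- rand_in_sphere(r_nuc - r_tel - 0.2)
          ok <- all(vapply(tel_off, function(e) sqrt(sum((e - o)^2)) >= sep(r_tel, r_tel),
                           logical(1)))
          if (ok) break
          if (t == 600) stopf("placement failure: telomere foci too dense for nucleus size")
        }
        tel_off[[j]] <- o
      }
      is_taf <- if (taf_fraction >= 1) rep(TRUE, telomere_foci_per_nucleus)
                else if (taf_fraction <= 0) rep(FALSE, telomere_foci_per_nucleus)
                else runif(telomere_foci_per_nucleus) < taf_fraction
      # paired damage foci: co-placed at a small offset from the telomere
      pair_of <- rep(NA_integer_, telomere_foci_per_nucleus)
      for (j in which(is_taf)) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        dam_off[[length(dam_off) + 1L]] <- tel_off[[j]] + u * r_tel
        pair_of[j] <- length(dam_off)
      }
      n_paired <- length(dam_off)
      # unpaired damage foci: clear of every telomere focus and other damage
      for (j in seq_len(gH2AX_foci_per_nucleus)) {
        for (t in 1:800) {
          o <- rand_in_sphere(r_nuc - r_dam - 0.2)
          ok_tel <- all(vapply(tel_off, function(e) sqrt(sum((e - o)^2)) >= sep(r_tel, r_dam),
                               logical(1)))
          ok_dam <- all(vapply(dam_off, function(e) sqrt(sum((e - o)^2)) >= sep(r_dam, r_dam) * 0.7,
                               logical(1)))
          if (ok_tel && ok_dam) break
          if (t == 800) stopf("placement failure: damage foci too dense for nucleus size")
        }
        dam_off[[length(dam_off) + 1L]] <- o
      }
      # rasterise
      tel_ids <- integer(telomere_foci_per_nucleus)
      for (j in seq_along(tel_off)) {
        fid <- fid + 1L; tel_ids[j] <- fid
        ctr <- um_to_px(nuc, tel_off[[j]])
        foci[[fid]] <- list(id = fid, channel = "telomere", nucleus = nuc,
                            cx = ctr[1], cy = ctr[2], cz = ctr[3], r_um = r_tel)
        voxels[[fid]] <- ellipsoid_voxels(ctr, r_tel / vs, dim)
      }
      dam_ids <- integer(length(dam_off))
      for (j in seq_along(dam_off)) {
        fid <- fid + 1L; dam_ids[j] <- fid
        ctr <- um_to_px(nuc, dam_off[[j]])
        foci[[fid]] <- list(id = fid, channel = "gH2AX", nucleus = nuc,
                            cx = ctr[1], cy = ctr[2], cz = ctr[3], r_um = r_dam)
        voxels[[fid]] <- ellipsoid_voxels(ctr, r_dam / vs, dim)
      }
      for (j in which(!is.na(pair_of))) {
        tid <- tel_ids[j]; did <- dam_ids[pair_of[j]]
        a <- voxels[[tid]]
        # guarantee the rasterised overlap: pull the damage focus toward the
        # telomere until the voxel overlap ratio clears the 1% rule with margin
        delta <- dam_off[[pair_of[j]]] - tel_off[[j]]
        repeat {
          b <- voxels[[did]]
          ov <- length(intersect(a, b)) / max(1L, min(length(a), length(b)))
          if (ov >= 0.05 || sqrt(sum(delta^2)) < 1e-3) break
          delta <- delta * 0.6
          ctr <- um_to_px(nuc, tel_off[[j]] + delta)
          foci[[did]]$cx <- ctr[1]; foci[[did]]$cy <- ctr[2]; foci[[did]]$cz <- ctr[3]
          voxels[[did]] <- ellipsoid_voxels(ctr, r_dam / vs, dim)
        }
        pairs[[length(pairs) + 1L]] <- data.frame(
          telomere_id = tid, damage_id = did,
          nucleus = nuc, overlap_ratio = ov)
      }
    }

    ## --- lipofuscin droplets in the cytoplasm, bright in both channels ---
    vol_um3 <- prod(dim) * prod(vs)
    n_lip <- rpois(1, lipofuscin_density * vol_um3 / 1000)
    lip_ids <- integer(0)
    if (n_lip > 0) {
      r_lip_px <- r_lip / vs
      for (j in seq_len(n_lip)) {
        for (t in 1:2000) {
          p <- runif(3, min = r_lip_px + 2, max = dim - r_lip_px - 1)
          d2 <- (centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 +
            ((centers[, 3] - p[3]) * r_nuc_px[1] / r_nuc_px[3])^2
          if (all(d2 > (r_nuc_px[1] + r_lip_px[1] + 2)^2)) break
          if (t == 2000) stopf("placement failure: no cytoplasmic room for lipofuscin")
        }
        fid <- fid + 1L; lip_ids <- c(lip_ids, fid)
        foci[[fid]] <- list(id = fid, channel = "lipofuscin", nucleus = NA_integer_,
                            cx = p[1], cy = p[2], cz = p[3], r_um = r_lip)
        voxels[[fid]] <- ellipsoid_voxels(p, r_lip_px, dim)
      }
    }

    ## --- render ---
    foci_df <- do.call(rbind, lapply(foci, as.data.frame))
    foci_df$n_vox <- vapply(voxels, length, integer(1))
    names(voxels) <- as.character(foci_df$id)
    a <- array(0, dim = c(dim, 3L))
    nch <- array(0, dim = dim)
    for (nuc in seq_len(n_nuclei))
      nch[ellipsoid_voxels(centers[nuc, ], r_nuc_px, dim)] <- 0.6
    tch <- array(0, dim = dim); dch <- array(0, dim = dim)
    for (k in seq_len(nrow(foci_df))) {
      v <- voxels[[k]]
      if (foci_df$channel[k] == "telomere") tch[v] <- 1
      else if (foci_df$channel[k] == "gH2AX") dch[v] <- 1
      else { tch[v] <- pmax(tch[v], 0.9); dch[v] <- pmax(dch[v], 0.9) }
    }
    sig_px <- blur_sigma / vs
    if (blur_sigma > 0) {
      nch <- gaussian_blur(nch, sig_px)
      tch <- gaussian_blur(tch, sig_px)
      dch <- gaussian_blur(dch, sig_px)
    }
    if (noise_sd > 0) {
      nvx <- prod(dim)
      nch <- pmax(nch + rnorm(nvx, 0, noise_sd), 0)
      tch <- pmax(tch + rnorm(nvx, 0, noise_sd), 0)
      dch <- pmax(dch + rnorm(nvx, 0, noise_sd), 0)
    }
    a[, , , 1] <- nch; a[, , , 2] <- tch; a[, , , 3] <- dch
    stack <- image_stack(a, voxel_size = vs,
                         channel_names = c("nuclei", "telomere", "gH2AX"))

    taf_pairs <- if (length(pairs)) do.call(rbind, pairs) else
      data.frame(telomere_id = integer(0), damage_id = integer(0),
                 nucleus = integer(0), overlap_ratio = numeric(0))
    n_pairs <- tabulate(taf_pairs$nucleus, nbins = n_nuclei)
    nuclei_df <- data.frame(id = seq_len(n_nuclei),
                            cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
                            r_um = r_nuc, taf_pairs = n_pairs,
                            senescent = n_pairs >= 2L)
    truth <- list(nuclei = nuclei_df, foci = foci_df, voxels = voxels,
                  taf_pairs = taf_pairs, dim = dim, seed = seed,
                  params = list(n_nuclei = n_nuclei,
                                telomere_foci_per_nucleus = telomere_foci_per_nucleus,
                                gH2AX_foci_per_nucleus = gH2AX_foci_per_nucleus,
                                taf_fraction = taf_fraction,
                                lipofuscin_density = lipofuscin_density,
                                blur_sigma = blur_sigma, noise_sd = noise_sd,
                                voxel_size = vs,
                                nucleus_radius_um = nucleus_radius_um))
    list(stack = stack, truth = truth)
  })
}
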