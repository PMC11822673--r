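#' Configuration for the imaging quantifiers
#'
#' Bundles the thresholds and size gates used across TAF calling and puncta
#' quantification. Defaults follow the instrument settings used in the field:
#' a colocalization is counted when the voxel overlap ratio between a
#' telomere and a damage surface reaches at least 1 percent; a cell is called
#' senescent at 2+ TAFs; p16 puncta are gated at 3-10 px equivalent diameter,
#' nuclei at 10-50 px, actin at 3-50 px; object thresholds derive from the
#' 10th percentile of a parallel positive control.
#'
#' @param overlap_ratio_threshold minimum voxel overlap ratio for a TAF.
#' @param taf_count_threshold TAFs per nucleus required for a senescent call.
#' @param puncta_diam_gate_px inclusive equivalent-diameter gate for puncta (px).
#' @param nucleus_diam_gate_px inclusive gate for nuclei (px).
#' @param actin_diam_gate_px inclusive gate for actin objects (px).
#' @param positive_control_percentile percentile (0-100) of control object
#'   intensities used as the detection threshold.
#' @param autofluorescence_overlap reciprocal overlap fraction above which an
#'   object bright in both detection channels is flagged as autofluorescent.
#' @param overlap_denominator `"min"` (default, the most permissive symmetric
#'   choice) or `"union"`; the instrument definition does not state the
#'   denominator, so it is configurable.
#' @param one_taf_per_telomere if `TRUE` (default) a telomere overlapping
#'   several damage foci still counts as a single TAF.
#' @return a list of class `quant_config`.
#' @export
quant_config <- function(overlap_ratio_threshold = 0.01,
                         taf_count_threshold = 2L,
                         puncta_diam_gate_px = c(3, 10),
                         nucleus_diam_gate_px = c(10, 50),
                         actin_diam_gate_px = c(3, 50),
                         positive_control_percentile = 10,
                         autofluorescence_overlap = 0.7,
                         overlap_denominator = c("min", "union"),
                         one_taf_per_telomere = TRUE) {
  overlap_denominator <- match.arg(overlap_denominator)
  gates <- list(puncta = puncta_diam_gate_px, nucleus = nucleus_diam_gate_px,
                actin = actin_diam_gate_px)
  for (g in names(gates))
    if (length(gates[[g]]) != 2L || gates[[g]][1] > gates[[g]][2] || gates[[g]][1] < 0)
      stopf("%s_diam_gate_px must be an ordered non-negative pair", g)
  if (overlap_ratio_threshold <= 0) stopf("overlap_ratio_threshold must be positive")
  structure(list(overlap_ratio_threshold = overlap_ratio_threshold,
                 taf_count_threshold = as.integer(taf_count_threshold),
                 puncta_diam_gate_px = puncta_diam_gate_px,
                 nucleus_diam_gate_px = nucleus_diam_gate_px,
                 actin_diam_gate_px = actin_diam_gate_px,
                 positive_control_percentile = positive_control_percentile,
                 autofluorescence_overlap = autofluorescence_overlap,
                 overlap_denominator = overlap_denominator,
                 one_taf_per_telomere = one_taf_per_telomere),
            class = "quant_config")
}

#' Detection threshold from a positive-control image
#'
#' Detects objects in the stated channel of the control image and returns the
#' requested percentile of their object-level mean intensities. An empty
#' control is an error -- there is no silent default threshold.
#'
#' @param control_image an [image_stack()].
#' @param channel channel name.
#' @param percentile percentile in `[0,100]` (default 10).
#' @param detect_threshold intensity threshold used to segment control
#'   objects before taking the percentile.
#' @param diam_gate_px optional equivalent-diameter gate applied to control
#'   objects.
#' @return numeric threshold with attributes recording provenance
#'   (`n_objects`, `percentile`, `channel`).
#' @export
threshold_from_positive_control <- function(control_image, channel,
                                            percentile = 10,
                                            detect_threshold = NULL,
                                            diam_gate_px = c(0, Inf)) {
  ch <- uq_channel_checked(control_image, channel)
  if (is.null(detect_threshold)) detect_threshold <- max(ch) / 2
  objs <- detect_objects(control_image, channel, threshold = detect_threshold,
                         diam_gate_px = diam_gate_px)
  if (nrow(objs$objects) == 0L)
    stopf("positive control contains no detectable objects in channel '%s'", channel)
  thr <- as.numeric(quantile(objs$objects$mean_intensity, percentile / 100, type = 7))
  attr(thr, "n_objects") <- nrow(objs$objects)
  attr(thr, "percentile") <- percentile
  attr(thr, "channel") <- channel
  thr
}

uq_channel_checked <- function(stack, name) {
  if (!inherits(stack, "image_stack")) stopf("expected an image_stack")
  channel(stack, name)
}

#' Detect labeled objects in one channel
#'
#' Connected components (6-connectivity in 3-D, 4-connectivity in 2-D) above
#' an intensity threshold, gated inclusively on equivalent diameter (the
#' diameter of the circle/sphere with the object's pixel/voxel count).
#' Sub-gate and supra-gate components are retained in `rejected` with the
#' reason, never silently dropped.
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @param threshold intensity threshold (voxels strictly above are foreground).
#' @param diam_gate_px inclusive `[lo, hi]` equivalent-diameter gate in px.
#' @return an `object_set`: list with `objects` (data.frame: id, n_vox,
#'   volume_um3, eq_diam_px, cx, cy, cz, mean_intensity, autofluorescent),
#'   `voxels` (list of linear voxel indices per object), `rejected`
#'   (data.frame with reasons), `dim`, `voxel_size`, `channel`.
#' @export
detect_objects <- function(stack, channel, threshold, diam_gate_px = c(0, Inf)) {
  ch <- uq_channel_checked(stack, channel)
  d <- dim(ch)
  three_d <- d[3L] > 1L
  lab <- label_components(ch > threshold)
  n <- max(lab)
  empty <- data.frame(id = integer(0), n_vox = integer(0), volume_um3 = numeric(0),
                      eq_diam_px = numeric(0), cx = numeric(0), cy = numeric(0),
                      cz = numeric(0), mean_intensity = numeric(0),
                      autofluorescent = logical(0))
  if (n == 0L)
    return(structure(list(objects = empty, voxels = list(),
                          rejected = cbind(empty, reason = character(0)),
                          dim = d, voxel_size = stack$voxel_size, channel = channel),
                     class = "object_set"))
  idx <- which(lab > 0L)
  labv <- lab[idx]
  ord <- order(labv)
  idx <- idx[ord]; labv <- labv[ord]
  vox <- split(idx, labv)
  n_vox <- lengths(vox)
  co_x <- ((idx - 1L) %% d[1L]) + 1L
  co_y <- (((idx - 1L) %/% d[1L]) %% d[2L]) + 1L
  co_z <- ((idx - 1L) %/% (d[1L] * d[2L])) + 1L
  inten <- ch[idx]
  df <- data.frame(
    id = seq_len(n),
    n_vox = as.integer(n_vox),
    volume_um3 = n_vox * prod(stack$voxel_size[if (three_d) 1:3 else 1:2]),
    eq_diam_px = equivalent_diameter(n_vox, three_d),
    cx = vapply(split(co_x, labv), mean, numeric(1)),
    cy = vapply(split(co_y, labv), mean, numeric(1)),
    cz = vapply(split(co_z, labv), mean, numeric(1)),
    mean_intensity = vapply(split(inten, labv), mean, numeric(1)),
    autofluorescent = FALSE)
  keep <- df$eq_diam_px >= diam_gate_px[1] & df$eq_diam_px <= diam_gate_px[2]
  rejected <- df[!keep, , drop = FALSE]
  rejected$reason <- ifelse(rejected$eq_diam_px < diam_gate_px[1],
                            "below_diameter_gate", "above_diameter_gate")
  objects <- df[keep, , drop = FALSE]
  voxels <- vox[keep]
  objects$id <- seq_len(nrow(objects))
  names(voxels) <- as.character(objects$id)
  rownames(objects) <- NULL; rownames(rejected) <- NULL
  structure(list(objects = objects, voxels = voxels, rejected = rejected,
                 dim = d, voxel_size = stack$voxel_size, channel = channel),
            class = "object_set")
}

#' @export
print.object_set <- function(x, ...) {
  cat(sprintf("<object_set> channel '%s': %d accepted, %d rejected object(s)\n",
              x$channel, nrow(x$objects), nrow(x$rejected)))
  invisible(x)
}

#' Voxel overlap ratio between two objects
#'
#' `|A n B| / min(|A|, |B|)` by default (the most permissive symmetric
#' denominator; `"union"` gives Jaccard). Symmetric and in `[0, 1]`.
#'
#' @param voxA,voxB integer vectors of linear voxel indices on the same grid.
#' @param denominator `"min"` or `"union"`.
#' @export
overlap_ratio <- function(voxA, voxB, denominator = c("min", "union")) {
  denominator <- match.arg(denominator)
  if (length(voxA) == 0L || length(voxB) == 0L) stopf("empty object in overlap_ratio")
  i <- sum(voxA %in% voxB)
  if (denominator == "min") i / min(length(voxA), length(voxB))
  else i / (length(voxA) + length(voxB) - i)
}

# bounding boxes (per axis min/max, voxel coords) for fast pair pre-filtering
object_boxes <- function(set) {
  d <- set$dim
  t(vapply(set$voxels, function(v) {
    x <- ((v - 1L) %% d[1L]) + 1L
    y <- (((v - 1L) %/% d[1L]) %% d[2L]) + 1L
    z <- ((v - 1L) %/% (d[1L] * d[2L])) + 1L
    c(min(x), max(x), min(y), max(y), min(z), max(z))
  }, numeric(6)))
}

boxes_touch <- function(b1, b2) {
  !(b1[2] < b2[1] || b2[2] < b1[1] ||
    b1[4] < b2[3] || b2[4] < b1[3] ||
    b1[6] < b2[5] || b2[6] < b1[5])
}

# all (i, j) pairs whose bounding boxes intersect, vectorised over both sets
box_pair_candidates <- function(bA, bB) {
  sep <- outer(bA[, 2], bB[, 1], `<`) | t(outer(bB[, 2], bA[, 1], `<`)) |
         outer(bA[, 4], bB[, 3], `<`) | t(outer(bB[, 4], bA[, 3], `<`)) |
         outer(bA[, 6], bB[, 5], `<`) | t(outer(bB[, 6], bA[, 5], `<`))
  which(!sep, arr.ind = TRUE)
}

#' Flag autofluorescent objects coincident in two detection channels
#'
#' Lipofuscin, the autofluorescent aging pigment, appears as droplets bright
#' in both the telomere and damage channels at the same location. Any object
#' pair whose voxel overlap fraction is at least `coincidence_overlap` in
#' *both* directions is flagged in both sets; flagged objects are excluded
#' from downstream TAF and puncta counting. A genuine TAF pair (partial,
#' asymmetric overlap) is not flagged.
#'
#' @param fociA,fociB `object_set`s from the same stack.
#' @param coincidence_overlap reciprocal overlap fraction (default 0.7).
#' @return list with the two sets, `autofluorescent` flags updated.
#' @export
flag_autofluorescent <- function(fociA, fociB, coincidence_overlap = 0.7) {
  if (!identical(fociA$dim, fociB$dim)) stopf("object sets are not from the same stack")
  nA <- nrow(fociA$objects); nB <- nrow(fociB$objects)
  if (nA > 0L && nB > 0L) {
    bA <- object_boxes(fociA); bB <- object_boxes(fociB)
    cand <- box_pair_candidates(bA, bB)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1L]; j <- cand[k, 2L]
      a <- fociA$voxels[[i]]; b <- fociB$voxels[[j]]
      ov <- sum(a %in% b)
      if (ov / length(a) >= coincidence_overlap && ov / length(b) >= coincidence_overlap) {
        fociA$objects$autofluorescent[i] <- TRUE
        fociB$objects$autofluorescent[j] <- TRUE
      }
    }
  }
  list(fociA = fociA, fociB = fociB)
}

#' Call telomere-associated foci (TAFs) and senescent nuclei
#'
#' Each unflagged telomere--damage pair whose voxel overlap ratio reaches
#' `config$overlap_ratio_threshold` yields a TAF. A telomere object counts at
#' most once (a telomere in a damage context is one TAF however many damage
#' foci it touches); the partner with the largest overlap wins, ties broken
#' by lower damage id. The TAF is assigned to the nucleus containing its
#' overlap centroid; a centroid outside all nuclei leaves the TAF recorded as
#' unassigned and excluded from per-nucleus counts. A nucleus with
#' `config$taf_count_threshold` (default 2) or more TAFs is flagged
#' senescent.
#'
#' @param telomere,damage `object_set`s with autofluorescent flags already set
#'   (see [flag_autofluorescent()]).
#' @param nuclei an `object_set` of nuclei from the same stack.
#' @param config a [quant_config()].
#' @return list of class `taf_call_result`: `per_nucleus` (nucleus id,
#'   taf_count, senescent), `tafs` (telomere id, damage id, overlap ratio,
#'   nucleus or NA), `n_unassigned`.
#' @export
call_tafs <- function(telomere, damage, nuclei, config = quant_config()) {
  thr <- config$overlap_ratio_threshold
  keepT <- which(!telomere$objects$autofluorescent)
  keepD <- which(!damage$objects$autofluorescent)
  d <- telomere$dim
  # nucleus label lookup
  nlab <- array(0L, dim = d)
  for (i in seq_len(nrow(nuclei$objects)))
    nlab[nuclei$voxels[[i]]] <- nuclei$objects$id[i]
  tafs <- list()
  if (length(keepT) && length(keepD)) {
    bT <- object_boxes(telomere); bD <- object_boxes(damage)
    cand <- box_pair_candidates(bT[keepT, , drop = FALSE], bD[keepD, , drop = FALSE])
    cand_by_tel <- split(keepD[cand[, 2L]], factor(keepT[cand[, 1L]], levels = keepT))
    for (i in keepT) {
      best <- NULL
      for (j in cand_by_tel[[as.character(i)]]) {
        a <- telomere$voxels[[i]]; b <- damage$voxels[[j]]
        inter <- a[a %in% b]
        if (length(inter) == 0L) next
        r <- if (config$overlap_denominator == "min")
          length(inter) / min(length(a), length(b))
        else length(inter) / (length(a) + length(b) - length(inter))
        if (r < thr) next
        rec <- list(telomere_id = telomere$objects$id[i],
                    damage_id = damage$objects$id[j],
                    overlap_ratio = r, inter = inter)
        if (config$one_taf_per_telomere) {
          if (is.null(best) || r > best$overlap_ratio ||
              (r == best$overlap_ratio && rec$damage_id < best$damage_id)) best <- rec
        } else {
          tafs[[length(tafs) + 1L]] <- rec
        }
      }
      if (config$one_taf_per_telomere && !is.null(best))
        tafs[[length(tafs) + 1L]] <- best
    }
  }
  assign_nucleus <- function(inter) {
    cx <- round(mean(((inter - 1L) %% d[1L]) + 1L))
    cy <- round(mean((((inter - 1L) %/% d[1L]) %% d[2L]) + 1L))
    cz <- round(mean(((inter - 1L) %/% (d[1L] * d[2L])) + 1L))
    nlab[cx, cy, cz]
  }
  taf_df <- if (length(tafs)) data.frame(
    telomere_id = vapply(tafs, `[[`, integer(1), "telomere_id"),
    damage_id = vapply(tafs, `[[`, integer(1), "damage_id"),
    overlap_ratio = vapply(tafs, `[[`, numeric(1), "overlap_ratio"),
    nucleus = vapply(tafs, function(t) {
      nid <- assign_nucleus(t$inter)
      if (nid == 0L) NA_integer_ else as.integer(nid)
    }, integer(1))
  ) else data.frame(telomere_id = integer(0), damage_id = integer(0),
                    overlap_ratio = numeric(0), nucleus = integer(0))
  counts <- tabulate(taf_df$nucleus[!is.na(taf_df$nucleus)],
                     nbins = max(nuclei$objects$id, 0L))
  per_nucleus <- data.frame(
    nucleus = nuclei$objects$id,
    taf_count = if (nrow(nuclei$objects)) counts[nuclei$objects$id] else integer(0))
  per_nucleus$senescent <- per_nucleus$taf_count >= config$taf_count_threshold
  structure(list(per_nucleus = per_nucleus, tafs = taf_df,
                 n_unassigned = sum(is.na(taf_df$nucleus))),
            class = "taf_call_result")
}

#' Percent TAF-positive (senescent) cells of total urothelial cells
#'
#' @param result a `taf_call_result` from [call_tafs()].
#' @param total_urothelial_cells denominator; must be at least the number of
#'   senescent-flagged nuclei and positive.
#' @return percentage in `[0, 100]`.
#' @export
percent_taf_positive <- function(result, total_urothelial_cells) {
  ns <- sum(result$per_nucleus$senescent)
  if (total_urothelial_cells <= 0) stopf("total_urothelial_cells must be positive")
  if (total_urothelial_cells < ns)
    stopf("total (%d) smaller than number of senescent nuclei (%d)",
          total_urothelial_cells, ns)
  100 * ns / total_urothelial_cells
}
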