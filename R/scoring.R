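#' Quantify an RNAscope field: puncta per nucleus and positive cells
#'
#' A nucleus is p16-positive iff at least one accepted punctum's centroid
#' falls inside it. Nuclei are gated at `config$nucleus_diam_gate_px`
#' (default 10-50 px), puncta at `config$puncta_diam_gate_px` (3-10 px) which
#' excludes debris and lipofuscin-like objects, actin (when the channel is
#' present) at `config$actin_diam_gate_px` (3-50 px). A cell co-expresses
#' when its p16-positive nucleus overlaps an accepted actin object.
#'
#' @param stack an [image_stack()] with channels `nuclei` and `p16`
#'   (optionally `actin`).
#' @param config a [quant_config()].
#' @param thresholds named list of intensity thresholds per channel; defaults
#'   to half the channel maximum, but use
#'   [threshold_from_positive_control()] for the control-anchored workflow.
#' @return list of class `rnascope_result`: `field` (one-row data.frame with
#'   total_p16_puncta, p16_positive_nuclei, total_nuclei,
#'   percent_p16_positive, actin_positive_cells, coexpressing_cells),
#'   `per_nucleus` (nucleus id, puncta count, positive flag), plus the
#'   detected object sets.
#' @export
rnascope_quantify <- function(stack, config = quant_config(), thresholds = list()) {
  if (!("nuclei" %in% stack$channel_names) || !("p16" %in% stack$channel_names))
    stopf("stack must contain 'nuclei' and 'p16' channels")
  thr <- function(chn) thresholds[[chn]] %||% (max(channel(stack, chn)) / 2)
  nuc <- detect_objects(stack, "nuclei", thr("nuclei"), config$nucleus_diam_gate_px)
  pun <- detect_objects(stack, "p16", thr("p16"), config$puncta_diam_gate_px)
  d <- nuc$dim
  nlab <- array(0L, dim = d)
  for (i in seq_len(nrow(nuc$objects))) nlab[nuc$voxels[[i]]] <- nuc$objects$id[i]
  hit <- integer(0)
  if (nrow(pun$objects) > 0L) {
    cx <- pmin(pmax(round(pun$objects$cx), 1L), d[1L])
    cy <- pmin(pmax(round(pun$objects$cy), 1L), d[2L])
    cz <- pmin(pmax(round(pun$objects$cz), 1L), d[3L])
    hit <- nlab[cbind(cx, cy, cz)]
  }
  n_nuc <- nrow(nuc$objects)
  per_nucleus <- data.frame(nucleus = nuc$objects$id,
                            puncta = if (n_nuc) tabulate(hit[hit > 0L], nbins = n_nuc) else integer(0))
  per_nucleus$positive <- per_nucleus$puncta >= 1L
  actin_pos <- NA_integer_; coexpr <- NA_integer_
  if ("actin" %in% stack$channel_names) {
    act <- detect_objects(stack, "actin", thr("actin"), config$actin_diam_gate_px)
    actin_pos <- nrow(act$objects)
    coexpr <- 0L
    if (actin_pos > 0L && any(per_nucleus$positive)) {
      bN <- object_boxes(nuc); bA <- object_boxes(act)
      pos_ids <- per_nucleus$nucleus[per_nucleus$positive]
      for (i in pos_ids) {
        ov <- FALSE
        for (j in seq_len(actin_pos)) {
          if (!boxes_touch(bN[i, ], bA[j, ])) next
          if (any(nuc$voxels[[i]] %in% act$voxels[[j]])) { ov <- TRUE; break }
        }
        if (ov) coexpr <- coexpr + 1L
      }
    }
  }
  field <- data.frame(
    total_p16_puncta = nrow(pun$objects),
    p16_positive_nuclei = sum(per_nucleus$positive),
    total_nuclei = n_nuc,
    percent_p16_positive = if (n_nuc) 100 * sum(per_nucleus$positive) / n_nuc else NA_real_,
    actin_positive_cells = actin_pos,
    coexpressing_cells = coexpr)
  structure(list(field = field, per_nucleus = per_nucleus,
                 nuclei = nuc, puncta = pun),
            class = "rnascope_result")
}

#' Score an SA beta-galactosidase section field
#'
#' Classifies each cell in the luminal-layer mask as positive when its mean
#' colour is blue-dominant: `mean(blue) > blue_ratio * max(mean(red),
#' mean(green))`. Returns the percentage of positive luminal cells. A field
#' with no luminal cells is an error at this level; [sabgal_aggregate()]
#' excludes such fields with a log entry.
#'
#' @param section an [image_stack()] with channels `red`, `green`, `blue`
#'   and `luminal_mask`.
#' @param blue_ratio blue-dominance ratio (default 1.3).
#' @return list: `percent_positive`, `n_cells`, `n_positive`, `per_cell`.
#' @export
sabgal_score <- function(section, blue_ratio = 1.3) {
  need <- c("red", "green", "blue", "luminal_mask")
  if (!all(need %in% section$channel_names))
    stopf("section must contain channels: %s", paste(need, collapse = ", "))
  mask <- channel(section, "luminal_mask") > 0.5
  if (!any(mask)) stopf("luminal mask is empty")
  lab <- label_components(mask)
  n <- max(lab)
  idx <- which(lab > 0L)
  labv <- lab[idx]
  r <- channel(section, "red")[idx]
  g <- channel(section, "green")[idx]
  b <- channel(section, "blue")[idx]
  mr <- vapply(split(r, labv), mean, numeric(1))
  mg <- vapply(split(g, labv), mean, numeric(1))
  mb <- vapply(split(b, labv), mean, numeric(1))
  pos <- mb > blue_ratio * pmax(mr, mg)
  list(percent_positive = 100 * sum(pos) / n,
       n_cells = n, n_positive = sum(pos),
       per_cell = data.frame(cell = seq_len(n), mean_red = mr, mean_green = mg,
                             mean_blue = mb, positive = as.logical(pos)))
}

#' Aggregate SA beta-gal field scores to section and animal level
#'
#' Fields are averaged within section, sections within animal, mirroring the
#' usual 3-fields-per-section, 3-sections-per-bladder counting scheme. Fields
#' with zero luminal cells (recorded as `NA`) are excluded and listed.
#'
#' @param scores data.frame with columns `animal`, `section`, `field`,
#'   `percent` (NA for unusable fields).
#' @return list: `per_section`, `per_animal`, `excluded_fields`.
#' @export
sabgal_aggregate <- function(scores) {
  need <- c("animal", "section", "field", "percent")
  if (!all(need %in% names(scores))) stopf("scores needs columns: %s", paste(need, collapse = ", "))
  excluded <- scores[is.na(scores$percent), , drop = FALSE]
  ok <- scores[!is.na(scores$percent), , drop = FALSE]
  per_section <- aggregate(percent ~ animal + section, data = ok, FUN = mean)
  per_animal <- aggregate(percent ~ animal, data = per_section, FUN = mean)
  list(per_section = per_section, per_animal = per_animal,
       excluded_fields = excluded)
}
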