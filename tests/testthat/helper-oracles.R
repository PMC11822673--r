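# Independent oracles used across tests. These deliberately use plain loops
# and set operations, not the package's optimised code paths.

# Exhaustive all-pairs voxel-intersection TAF enumeration over detected
# object sets: same semantics as call_tafs (min-denominator overlap ratio,
# one TAF per telomere, overlap-centroid nucleus assignment), brute force.
brute_force_tafs <- function(telomere, damage, nuclei,
                             config = quant_config()) {
  d <- telomere$dim
  keepT <- which(!telomere$objects$autofluorescent)
  keepD <- which(!damage$objects$autofluorescent)
  counts <- rep(0L, nrow(nuclei$objects))
  pairs <- list()
  unassigned <- 0L
  for (i in keepT) {
    best_r <- -1; best_j <- NA_integer_; best_inter <- NULL
    for (j in keepD) {
      a <- telomere$voxels[[i]]; b <- damage$voxels[[j]]
      inter <- intersect(a, b)
      if (length(inter) == 0L) next
      r <- length(inter) / min(length(a), length(b))
      if (r < config$overlap_ratio_threshold) next
      if (r > best_r) { best_r <- r; best_j <- j; best_inter <- inter }
    }
    if (!is.na(best_j)) {
      cx <- round(mean(((best_inter - 1L) %% d[1L]) + 1L))
      cy <- round(mean((((best_inter - 1L) %/% d[1L]) %% d[2L]) + 1L))
      cz <- round(mean(((best_inter - 1L) %/% (d[1L] * d[2L])) + 1L))
      vox <- cx + (cy - 1L) * d[1L] + (cz - 1L) * d[1L] * d[2L]
      nid <- 0L
      for (k in seq_len(nrow(nuclei$objects)))
        if (vox %in% nuclei$voxels[[k]]) { nid <- k; break }
      if (nid > 0L) counts[nid] <- counts[nid] + 1L else unassigned <- unassigned + 1L
      pairs[[length(pairs) + 1L]] <- c(telomere$objects$id[i],
                                       damage$objects$id[best_j])
    }
  }
  list(counts = counts, unassigned = unassigned,
       pairs = if (length(pairs)) do.call(rbind, pairs) else
         matrix(integer(0), 0, 2))
}

# Two-tailed Mann-Whitney p by full enumeration of group relabelings.
mw_enumeration_p <- function(x, y) {
  nx <- length(x)
  all_v <- c(x, y)
  n <- length(all_v)
  r <- rank(all_v)
  u_of <- function(ix) sum(r[ix]) - nx * (nx + 1) / 2
  U_obs <- u_of(seq_len(nx))
  mu <- nx * length(y) / 2
  combs <- utils::combn(n, nx)
  Us <- apply(combs, 2, u_of)
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# Full three-channel TAF pipeline on a generated stack.
run_taf_pipeline <- function(gen, thr_nuc = 0.3, thr_foci = 0.5,
                             config = quant_config()) {
  s <- gen$stack
  nuc <- detect_objects(s, "nuclei", thr_nuc, c(5, 60))
  tel <- detect_objects(s, "telomere", thr_foci, c(0, 20))
  dam <- detect_objects(s, "gH2AX", thr_foci, c(0, 20))
  fl <- flag_autofluorescent(tel, dam, config$autofluorescence_overlap)
  res <- call_tafs(fl$fociA, fl$fociB, nuc, config)
  list(nuclei = nuc, telomere = fl$fociA, damage = fl$fociB, result = res)
}
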