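#' Generate a synthetic RNA-seq count matrix with age- and gavage-structured
#' effects
#'
#' Negative-binomial counts with log-normal library sizes over six groups:
#' young (`Y`), middle-aged (`M`), untreated old (`O`), water-gavaged old
#' (`O_water`), vehicle-gavaged old (`O_vehicle`) and senolytic-treated old
#' (`O_DQ`). Three disjoint gene sets carry effects:
#' \itemize{
#'   \item `aging_gene_set`: shifted in every old group relative to `M`
#'     (and unchanged between `Y` and `M`) -- genuine aging signal;
#'   \item `gavage_gene_set`: shifted in every gavaged group
#'     (`O_water`, `O_vehicle`, `O_DQ`) relative to untreated `O` -- the
#'     technical confounder the filter cascade must remove;
#'   \item `dq_gene_set`: carries the aging-direction shift in old groups
#'     *and* reverts to the middle-aged level under D+Q -- the reversal
#'     signature the senolytic filter looks for. Memberships are disjoint;
#'     effects overlap by design.
#' }
#'
#' @param n_genes number of genes.
#' @param group_n named integer vector of samples per group; all six groups
#'   required, each at least 1.
#' @param aging_gene_set,gavage_gene_set,dq_gene_set disjoint gene index sets.
#' @param effect_log2fc absolute log2 effect size (per-gene signs random).
#' @param dispersion NB dispersion (squared biological CV; 0.01 is the
#'   typical value for genetically identical model organisms).
#' @param libsize_cv coefficient of variation of library-size factors.
#' @param base_log2_mean range of baseline log2 mean counts.
#' @param seed integer seed.
#' @return list: `counts` (genes x samples integer matrix), `samples`
#'   (data.frame sample, group), `lengths` (effective gene lengths, bp, for
#'   TPM), and `truth` (gene sets, per-gene effect signs, library factors,
#'   parameters, seed).
#' @export
gen_counts <- function(n_genes = 2000,
                       group_n = c(Y = 5, M = 5, O = 5,
                                   O_water = 5, O_vehicle = 5, O_DQ = 5),
                       aging_gene_set = integer(0),
                       gavage_gene_set = integer(0),
                       dq_gene_set = integer(0),
                       effect_log2fc = 2,
                       dispersion = 0.01,
                       libsize_cv = 0.2,
                       base_log2_mean = c(8, 13),
                       seed = 1L) {
  need <- c("Y", "M", "O", "O_water", "O_vehicle", "O_DQ")
  if (!all(need %in% names(group_n)))
    stopf("group_n must name all groups: %s", paste(need, collapse = ", "))
  if (any(group_n < 1)) stopf("every group needs at least one sample")
  sets <- list(aging = aging_gene_set, gavage = gavage_gene_set, dq = dq_gene_set)
  all_idx <- unlist(sets)
  if (anyDuplicated(all_idx)) stopf("gene sets must be disjoint")
  if (length(all_idx) && (max(all_idx) > n_genes || min(all_idx) < 1))
    stopf("gene set indices out of range")
  groups <- rep(need, times = group_n[need])
  n_samp <- length(groups)
  old_groups <- c("O", "O_water", "O_vehicle", "O_DQ")
  gavaged <- c("O_water", "O_vehicle", "O_DQ")

  with_seed(seed, {
    base <- runif(n_genes, base_log2_mean[1], base_log2_mean[2])
    sign_of <- function(idx) setNames(sample(c(-1, 1), length(idx), replace = TRUE), idx)
    s_aging <- sign_of(aging_gene_set)
    s_gavage <- sign_of(gavage_gene_set)
    s_dq <- sign_of(dq_gene_set)
    # per-gene, per-group log2 offsets
    off <- matrix(0, n_genes, length(need), dimnames = list(NULL, need))
    off[aging_gene_set, old_groups] <- off[aging_gene_set, old_groups] +
      s_aging * effect_log2fc
    off[gavage_gene_set, gavaged] <- off[gavage_gene_set, gavaged] +
      s_gavage * effect_log2fc
    # dq genes: aging-direction shift in old groups, reverted under D+Q
    off[dq_gene_set, old_groups] <- off[dq_gene_set, old_groups] +
      s_dq * effect_log2fc
    off[dq_gene_set, "O_DQ"] <- 0
    lib <- exp(rnorm(n_samp, 0, sqrt(log(1 + libsize_cv^2))))
    counts <- matrix(0L, n_genes, n_samp)
    for (j in seq_len(n_samp)) {
      mu <- lib[j] * 2^(base + off[, groups[j]])
      counts[, j] <- rnbinom(n_genes, size = 1 / dispersion, mu = mu)
    }
    rownames(counts) <- sprintf("gene%05d", seq_len(n_genes))
    colnames(counts) <- sprintf("%s_%d", groups, stats::ave(seq_len(n_samp),
                                                            groups, FUN = seq_along))
    lengths <- round(exp(runif(n_genes, log(500), log(5000))))
    names(lengths) <- rownames(counts)
    list(counts = counts,
         samples = data.frame(sample = colnames(counts), group = groups),
         lengths = lengths,
         truth = list(aging_gene_set = aging_gene_set,
                      gavage_gene_set = gavage_gene_set,
                      dq_gene_set = dq_gene_set,
                      signs = list(aging = s_aging, gavage = s_gavage, dq = s_dq),
                      lib_factors = lib, seed = seed,
                      params = list(n_genes = n_genes, group_n = group_n,
                                    effect_log2fc = effect_log2fc,
                                    dispersion = dispersion,
                                    libsize_cv = libsize_cv)))
  })
}

#' Generate a synthetic qPCR Ct table from known expression ratios
#'
#' Ct values follow `Ct = Ct0 - log_E(expression)`: a sample expressing a
#' gene at ratio r relative to the calibrator group comes up `log_E(r)`
#' cycles earlier. A per-sample loading shift (common to all genes of that
#' sample) emulates pipetting/input variation -- exactly what geometric
#' averaging of reference genes corrects. Reference genes have true ratio 1
#' in every group.
#'
#' @param true_ratios genes x groups numeric matrix of expression ratios
#'   relative to the calibrator group (rownames = genes, colnames = groups;
#'   must include the calibrator column).
#' @param efficiencies named per-gene amplification efficiencies in (1, 2];
#'   unnamed genes default to 2.
#' @param reference_genes exactly 3 gene names (appended with ratio 1 if not
#'   in `true_ratios`).
#' @param calibrator_group column treated as calibrator (default first).
#' @param n_samples samples per group.
#' @param ct_noise_sd technical Ct noise SD (cycles).
#' @param loading_sd per-sample loading shift SD (cycles).
#' @param base_ct mean calibrator Ct for every gene.
#' @param seed integer seed.
#' @return list: `ct` (long data.frame sample, group, gene, ct),
#'   `efficiencies`, `reference_genes`, `calibrator_group`, and `truth`.
#' @export
gen_qpcr <- function(true_ratios,
                     efficiencies = NULL,
                     reference_genes = c("Rps18", "Ywhaz", "B2m"),
                     calibrator_group = NULL,
                     n_samples = 6,
                     ct_noise_sd = 0.1,
                     loading_sd = 0.3,
                     base_ct = 24,
                     seed = 1L) {
  if (length(reference_genes) != 3L) stopf("exactly 3 reference genes required")
  true_ratios <- as.matrix(true_ratios)
  if (is.null(colnames(true_ratios)) || is.null(rownames(true_ratios)))
    stopf("true_ratios needs row (gene) and column (group) names")
  add_ref <- setdiff(reference_genes, rownames(true_ratios))
  if (length(add_ref)) {
    ref_block <- matrix(1, length(add_ref), ncol(true_ratios),
                        dimnames = list(add_ref, colnames(true_ratios)))
    true_ratios <- rbind(true_ratios, ref_block)
  }
  if (any(true_ratios[reference_genes, ] != 1))
    stopf("reference genes must have true ratio 1 in every group")
  genes <- rownames(true_ratios)
  groups <- colnames(true_ratios)
  if (is.null(calibrator_group)) calibrator_group <- groups[1L]
  if (!calibrator_group %in% groups) stopf("calibrator group not in true_ratios")
  if (any(true_ratios[, calibrator_group] != 1))
    stopf("true ratios must be 1 in the calibrator group")
  E <- setNames(rep(2, length(genes)), genes)
  if (!is.null(efficiencies)) E[names(efficiencies)] <- efficiencies
  if (any(E <= 1 | E > 2)) stopf("efficiencies must be in (1, 2]")

  with_seed(seed, {
    rows <- list()
    for (g in groups) for (s in seq_len(n_samples)) {
      load_shift <- rnorm(1, 0, loading_sd)
      ct <- base_ct - log(true_ratios[, g], base = E) + load_shift +
        rnorm(length(genes), 0, ct_noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("%s_%d", g, s), group = g, gene = genes, ct = ct,
        row.names = NULL)
    }
    list(ct = do.call(rbind, rows),
         efficiencies = E, reference_genes = reference_genes,
         calibrator_group = calibrator_group,
         truth = list(true_ratios = true_ratios, seed = seed,
                      params = list(n_samples = n_samples,
                                    ct_noise_sd = ct_noise_sd,
                                    loading_sd = loading_sd, base_ct = base_ct)))
  })
}
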