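#' Efficiency-corrected relative expression with multiple reference genes
#'
#' The Pfaffl ratio extended to several reference genes by geometric
#' averaging: for each sample,
#' `ratio = E_t^(dCt_t) / geomean_r(E_r^(dCt_r))` where
#' `dCt = mean Ct(calibrator) - Ct(sample)` and the geometric mean runs over
#' the three reference assays. With every efficiency equal to 2 this reduces
#' to the classical 2^-ddCt method with a geometric-mean reference. The
#' calibrator group (young, sex-matched animals in the original design) has
#' mean ratio 1 by construction in the noise-free case.
#'
#' @param ct long-format data.frame with columns `sample`, `group`, `gene`,
#'   `ct`.
#' @param target target gene name (must not be a reference gene).
#' @param efficiencies named per-gene efficiencies in (1, 2]; unnamed genes
#'   default to 2.
#' @param reference_genes exactly 3 reference gene names.
#' @param calibrator_group group label used as calibrator.
#' @return list: `per_sample` (sample, group, ratio; samples with missing Ct
#'   dropped and listed in `dropped`), `group_means` (group, mean_ratio).
#' @export
pfaffl_relative_expression <- function(ct, target, efficiencies = NULL,
                                       reference_genes, calibrator_group) {
  if (length(reference_genes) != 3L) stopf("exactly 3 reference genes required")
  if (target %in% reference_genes) stopf("target must not be a reference gene")
  need <- c(target, reference_genes)
  if (!all(need %in% ct$gene))
    stopf("Ct table lacks gene(s): %s", paste(setdiff(need, ct$gene), collapse = ", "))
  if (!calibrator_group %in% ct$group) stopf("calibrator group absent from Ct table")
  E <- setNames(rep(2, length(need)), need)
  if (!is.null(efficiencies)) {
    common <- intersect(names(efficiencies), need)
    E[common] <- efficiencies[common]
  }
  if (any(E <= 1 | E > 2)) stopf("efficiencies must be in (1, 2]")
  sub <- ct[ct$gene %in% need, c("sample", "group", "gene", "ct")]
  wide <- stats::reshape(sub, idvar = c("sample", "group"), timevar = "gene",
                         direction = "wide")
  names(wide) <- sub("^ct\\.", "", names(wide))
  complete <- complete.cases(wide[, need])
  dropped <- wide$sample[!complete]
  wide <- wide[complete, , drop = FALSE]
  cal <- wide[wide$group == calibrator_group, , drop = FALSE]
  if (nrow(cal) == 0L) stopf("no usable calibrator samples")
  cal_mean <- vapply(need, function(g) mean(cal[[g]]), numeric(1))
  ratio_num <- E[target]^(cal_mean[target] - wide[[target]])
  ref_terms <- vapply(reference_genes, function(g)
    E[g]^(cal_mean[g] - wide[[g]]), numeric(nrow(wide)))
  if (is.null(dim(ref_terms))) ref_terms <- matrix(ref_terms, nrow = 1)
  ref_geo <- exp(rowMeans(log(ref_terms)))
  per_sample <- data.frame(sample = wide$sample, group = wide$group,
                           ratio = as.numeric(ratio_num / ref_geo))
  group_means <- aggregate(ratio ~ group, data = per_sample, FUN = mean)
  names(group_means)[2] <- "mean_ratio"
  list(per_sample = per_sample, group_means = group_means, dropped = dropped)
}

#' Transcripts-per-million normalization
#'
#' `TPM_g = 1e6 * (count_g / length_g) / sum_h(count_h / length_h)` per
#' sample; every column sums to one million.
#'
#' @param counts genes x samples matrix.
#' @param lengths effective gene lengths (same order/names as rows), > 0.
#' @return TPM matrix of the same shape.
#' @export
tpm_normalize <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts)) stopf("one length per gene required")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) stopf("lengths must be positive")
  rate <- counts / lengths
  denom <- colSums(rate)
  if (any(denom == 0)) stopf("sample(s) with all-zero counts: %s",
                             paste(colnames(counts)[denom == 0], collapse = ", "))
  sweep(rate, 2, denom, "/") * 1e6
}

#' Differential expression between two groups (log-CPM Welch engine)
#'
#' Per gene: log2 counts-per-million with a pseudocount, Welch's two-sample
#' t-test between the groups, Benjamini-Hochberg adjustment across genes.
#' The log2 fold change is `mean(log-CPM in group_b) - mean(log-CPM in
#' group_a)`, i.e. the change *from* `group_a` *to* `group_b`. Genes with
#' zero variance in both groups get p = 1 and a `degenerate` flag.
#'
#' @param counts genes x samples matrix.
#' @param groups per-sample group labels (length = ncol).
#' @param group_a,group_b the two groups to compare (each needs >= 2
#'   samples).
#' @param pseudocount added before the log (default 0.5).
#' @return data.frame of class `de_table`: gene, log2fc, t, df, p, adj_p,
#'   degenerate; attribute `comparison`.
#' @export
de_test <- function(counts, groups, group_a, group_b, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  ia <- which(groups == group_a); ib <- which(groups == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stopf("need at least 2 samples per group (%s: %d, %s: %d)",
          group_a, length(ia), group_b, length(ib))
  lib <- colSums(counts)
  logcpm <- log2(sweep(counts + pseudocount, 2, lib + 2 * pseudocount, "/") * 1e6)
  ma <- rowMeans(logcpm[, ia, drop = FALSE]); mb <- rowMeans(logcpm[, ib, drop = FALSE])
  va <- apply(logcpm[, ia, drop = FALSE], 1, var)
  vb <- apply(logcpm[, ib, drop = FALSE], 1, var)
  na <- length(ia); nb <- length(ib)
  se2 <- va / na + vb / nb
  degen <- se2 <= 0
  tstat <- ifelse(degen, 0, (mb - ma) / sqrt(se2))
  df <- ifelse(degen, NA_real_,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)))
  p <- ifelse(degen, 1, 2 * pt(-abs(tstat), df))
  out <- data.frame(gene = rownames(counts) %||% sprintf("gene%05d", seq_len(nrow(counts))),
                    log2fc = mb - ma, t = tstat, df = df, p = p,
                    adj_p = p.adjust(p, method = "BH"),
                    degenerate = degen, row.names = NULL)
  attr(out, "comparison") <- c(group_a, group_b)
  class(out) <- c("de_table", class(out))
  out
}

check_universe <- function(...) {
  tables <- list(...)
  g <- lapply(tables, function(t) t$gene)
  for (i in seq_along(g)[-1]) {
    if (!setequal(g[[1]], g[[i]])) {
      diff <- union(setdiff(g[[1]], g[[i]]), setdiff(g[[i]], g[[1]]))
      stopf("gene universes differ; symmetric difference: %s",
            paste(head(diff, 10), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Aging filter: significant with age, stable before middle age
#'
#' Survivors change significantly (BH-adjusted p < `alpha`) between
#' middle-aged and old, and show minimal change (|log2 fold change| <
#' `stability_bound`) between young and middle-aged -- genuine aging signal
#' rather than maturation. Survivors are ranked by |fold change| in the
#' middle-aged-vs-old comparison; the full audit trail records every gene's
#' pass/fail per criterion.
#'
#' @param de_MvsO [de_test()] table, middle-aged vs old.
#' @param de_YvsM [de_test()] table, young vs middle-aged (same gene
#'   universe).
#' @param alpha FDR level (default 0.05).
#' @param stability_bound |log2 FC| bound for "minimal change" (default 0.2;
#'   a linear-ratio reading of the bound would mean a 5-fold change, which
#'   contradicts "minimal", so the log2 scale is the default and the scale
#'   is explicit in the audit).
#' @param scale `"log2"` or `"linear"` interpretation of `stability_bound`.
#' @return list of class `filter_cascade_result`: `survivors` (ranked gene
#'   ids), `audit` (per-gene criteria values and flags), `params`.
#' @export
aging_gene_filter <- function(de_MvsO, de_YvsM, alpha = 0.05,
                              stability_bound = 0.2,
                              scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  check_universe(de_MvsO, de_YvsM)
  ym <- de_YvsM[match(de_MvsO$gene, de_YvsM$gene), ]
  stable_val <- if (scale == "log2") abs(ym$log2fc) else abs(2^ym$log2fc - 1)
  sig <- de_MvsO$adj_p < alpha
  stable <- stable_val < stability_bound
  audit <- data.frame(gene = de_MvsO$gene,
                      log2fc_MvsO = de_MvsO$log2fc, adj_p_MvsO = de_MvsO$adj_p,
                      pass_significant = sig,
                      stability_value = stable_val, pass_stable = stable,
                      survives = sig & stable)
  audit$failed_criterion <- ifelse(audit$survives, "",
                            ifelse(!sig, "not_significant_MvsO", "unstable_YvsM"))
  surv <- audit[audit$survives, ]
  surv <- surv[order(-abs(surv$log2fc_MvsO), surv$adj_p_MvsO, surv$gene), ]
  structure(list(survivors = surv$gene, audit = audit,
                 params = list(alpha = alpha, stability_bound = stability_bound,
                               scale = scale)),
            class = "filter_cascade_result")
}

#' Senolytic (D+Q) effect filter with gavage-confound exclusion
#'
#' Survivors are genes whose old-vs-D+Q change is significant (adj p <
#' `alpha`) and *reverses* the direction of the middle-aged-vs-old change,
#' while showing minimal change (|log2 FC| < `stability_bound`) in both the
#' water-only and vehicle-only comparisons -- isolating drug effects from
#' gavage/vehicle technique. By default the gene must also be significant in
#' the middle-aged-vs-old comparison (the "top changed with aging, moved
#' back by D+Q" reading); disable with `require_aging_significant = FALSE`.
#' Ranked by |log2 FC(M vs O)| for top-k reporting, ties broken by smaller
#' adjusted p then gene id.
#'
#' @param de_OvsDQ,de_OvsWater,de_OvsVehicle,de_MvsO [de_test()] tables on a
#'   common gene universe (all old-group comparisons are untreated-old vs
#'   treatment).
#' @param alpha FDR level.
#' @param stability_bound |log2 FC| bound for the gavage/vehicle exclusion.
#' @param direction `"reversal_any"` (default), `"reversal_up"` (genes up
#'   with aging, down after D+Q) or `"reversal_down"` (the mirror image).
#' @param require_aging_significant also require adj p(M vs O) < alpha.
#' @param scale as in [aging_gene_filter()].
#' @return a `filter_cascade_result` (see [aging_gene_filter()]).
#' @export
dq_effect_filter <- function(de_OvsDQ, de_OvsWater, de_OvsVehicle, de_MvsO,
                             alpha = 0.05, stability_bound = 0.2,
                             direction = c("reversal_any", "reversal_up",
                                           "reversal_down"),
                             require_aging_significant = TRUE,
                             scale = c("log2", "linear")) {
  direction <- match.arg(direction)
  scale <- match.arg(scale)
  check_universe(de_OvsDQ, de_OvsWater, de_OvsVehicle, de_MvsO)
  g <- de_OvsDQ$gene
  mo <- de_MvsO[match(g, de_MvsO$gene), ]
  wa <- de_OvsWater[match(g, de_OvsWater$gene), ]
  ve <- de_OvsVehicle[match(g, de_OvsVehicle$gene), ]
  stab <- function(x) if (scale == "log2") abs(x) else abs(2^x - 1)
  sig_dq <- de_OvsDQ$adj_p < alpha
  reversal <- switch(direction,
    reversal_any = sign(de_OvsDQ$log2fc) == -sign(mo$log2fc) & mo$log2fc != 0,
    reversal_up = mo$log2fc > 0 & de_OvsDQ$log2fc < 0,
    reversal_down = mo$log2fc < 0 & de_OvsDQ$log2fc > 0)
  clean_water <- stab(wa$log2fc) < stability_bound
  clean_vehicle <- stab(ve$log2fc) < stability_bound
  sig_aging <- if (require_aging_significant) mo$adj_p < alpha else TRUE
  survives <- sig_dq & reversal & clean_water & clean_vehicle & sig_aging
  audit <- data.frame(gene = g,
                      log2fc_MvsO = mo$log2fc, adj_p_MvsO = mo$adj_p,
                      log2fc_OvsDQ = de_OvsDQ$log2fc, adj_p_OvsDQ = de_OvsDQ$adj_p,
                      log2fc_OvsWater = wa$log2fc, log2fc_OvsVehicle = ve$log2fc,
                      pass_sig_dq = sig_dq, pass_reversal = reversal,
                      pass_clean_water = clean_water,
                      pass_clean_vehicle = clean_vehicle,
                      pass_sig_aging = rep(sig_aging, length.out = length(g)),
                      survives = survives)
  audit$failed_criterion <- ifelse(audit$survives, "",
    ifelse(!sig_dq, "not_significant_OvsDQ",
    ifelse(!reversal, "no_reversal",
    ifelse(!clean_water, "gavage_confounded_water",
    ifelse(!clean_vehicle, "gavage_confounded_vehicle", "not_significant_MvsO")))))
  surv <- audit[audit$survives, ]
  surv <- surv[order(-abs(surv$log2fc_MvsO), surv$adj_p_MvsO, surv$gene), ]
  structure(list(survivors = surv$gene, audit = audit,
                 params = list(alpha = alpha, stability_bound = stability_bound,
                               direction = direction,
                               require_aging_significant = require_aging_significant,
                               scale = scale)),
            class = "filter_cascade_result")
}

#' @export
print.filter_cascade_result <- function(x, ...) {
  cat(sprintf("<filter_cascade_result> %d survivor(s) of %d gene(s)\n",
              length(x$survivors), nrow(x$audit)))
  if (length(x$survivors)) cat("  top:", paste(head(x$survivors, 10), collapse = ", "), "\n")
  invisible(x)
}
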