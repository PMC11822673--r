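test_that("Pfaffl relative expression evaluates the efficiency-corrected
           formula with geometric-mean references", {
  mk_ct <- function(tgt_o, refs_o) {
    genes <- c("tgt", "r1", "r2", "r3")
    rbind(data.frame(sample = "y1", group = "Y", gene = genes, ct = 24),
          data.frame(sample = "o1", group = "O", gene = genes,
                     ct = 24 - c(tgt_o, refs_o)))
  }
  # all dCt = 0 -> ratio 1
  pf0 <- pfaffl_relative_expression(mk_ct(0, c(0, 0, 0)), "tgt",
                                    reference_genes = c("r1", "r2", "r3"),
                                    calibrator_group = "Y")
  expect_equal(pf0$group_means$mean_ratio, c(1, 1))
  # E = 2 everywhere, target dCt 3, references dCt 1 -> 8 / 2 = 4
  pf <- pfaffl_relative_expression(mk_ct(3, c(1, 1, 1)), "tgt",
                                   reference_genes = c("r1", "r2", "r3"),
                                   calibrator_group = "Y")
  expect_equal(pf$group_means$mean_ratio[pf$group_means$group == "O"], 4)
  # with all efficiencies 2 the result is the 2^-ddCt method with a
  # geometric-mean reference (closed-form limit check on random Cts)
  set.seed(1)
  ct <- mk_ct(rnorm(1), rnorm(3))
  pf2 <- pfaffl_relative_expression(ct, "tgt",
                                    reference_genes = c("r1", "r2", "r3"),
                                    calibrator_group = "Y")
  o <- ct[ct$sample == "o1", ]; y <- ct[ct$sample == "y1", ]
  ddct <- (o$ct[1] - y$ct[1]) - mean(o$ct[2:4] - y$ct[2:4])
  expect_equal(pf2$group_means$mean_ratio[pf2$group_means$group == "O"],
               2^-ddct)
  # guards
  expect_error(pfaffl_relative_expression(ct, "r1",
                                          reference_genes = c("r1", "r2", "r3"),
                                          calibrator_group = "Y"),
               "reference")
  # a sample with missing Ct is dropped and listed
  ct_na <- ct; ct_na$ct[ct_na$sample == "o1" & ct_na$gene == "r2"] <- NA
  pf3 <- pfaffl_relative_expression(ct_na, "tgt",
                                    reference_genes = c("r1", "r2", "r3"),
                                    calibrator_group = "Y")
  expect_equal(pf3$dropped, "o1")
})

test_that("TPM columns scale to one million and follow length weighting", {
  expect_equal(as.numeric(tpm_normalize(matrix(c(5, 5), 2, 1), c(1, 1))),
               c(5e5, 5e5))
  tp <- tpm_normalize(matrix(c(10, 10), 2, 1), c(1000, 2000))
  expect_equal(as.numeric(tp), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  set.seed(2)
  m <- matrix(rpois(200, 50), 20, 10)
  rownames(m) <- paste0("g", 1:20)
  tpm <- tpm_normalize(m, setNames(runif(20, 200, 2000), rownames(m)))
  expect_equal(unname(colSums(tpm)), rep(1e6, 10), tolerance = 1e-6)
  m0 <- m; m0[, 3] <- 0
  expect_error(tpm_normalize(m0, rep(1000, 20)), "all-zero")
})

test_that("the DE engine controls the null and honours BH structure", {
  g0 <- gen_counts(n_genes = 3000, effect_log2fc = 0, seed = 6)
  de0 <- de_test(g0$counts, g0$samples$group, "M", "O")
  expect_lt(abs(mean(de0$p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 3000) + 0.005)
  expect_lt(mean(de0$adj_p < 0.05), 0.005)
  # BH: adjusted p is a monotone step function of raw-p rank, never below raw
  ord <- order(de0$p)
  expect_true(all(diff(de0$adj_p[ord]) >= -1e-12))
  expect_true(all(de0$adj_p >= de0$p - 1e-12))
  # m = 1 identity
  one <- de_test(matrix(c(10, 12, 30, 31), 1, 4,
                        dimnames = list("g1", NULL)),
                 c("A", "A", "B", "B"), "A", "B")
  expect_equal(one$adj_p, one$p)
  # degenerate variance: p = 1 with flag
  const <- matrix(c(8, 8, 8, 8), 1, 4, dimnames = list("g1", NULL))
  dd <- de_test(const, c("A", "A", "B", "B"), "A", "B")
  expect_true(dd$degenerate)
  expect_equal(dd$p, 1)
  expect_error(de_test(const, c("A", "B", "B", "B"), "A", "B"), "at least 2")
})

test_that("DE engine recovers known effects with correct sign and magnitude", {
  g <- gen_counts(n_genes = 1500, aging_gene_set = 1:50, effect_log2fc = 2,
                  seed = 5)
  de <- de_test(g$counts, g$samples$group, "M", "O")
  expect_equal(median(abs(de$log2fc[1:50])), 2, tolerance = 0.15)
  signs <- g$truth$signs$aging
  expect_true(all(sign(de$log2fc[1:50]) == signs))
})

test_that("aging filter on a hand-checkable toy table", {
  mo <- data.frame(gene = paste0("g", 1:6),
                   log2fc = c(3, -2.5, 1.2, 0.4, 2.0, -1.0),
                   adj_p = c(0.01, 0.02, 0.20, 0.01, 0.03, 0.04))
  ym <- data.frame(gene = paste0("g", 1:6),
                   log2fc = c(0.05, 0.10, 0.02, 0.01, 0.50, -0.30))
  # row-by-row: survivors need adj_p(MvsO) < 0.05 AND |fc(YvsM)| < 0.2:
  # g1 yes, g2 yes, g3 no (p), g4 yes, g5 no (unstable), g6 no (unstable)
  res <- aging_gene_filter(mo, ym)
  expect_setequal(res$survivors, c("g1", "g2", "g4"))
  expect_equal(res$survivors[1:2], c("g1", "g2"))   # ranked by |fc M vs O|
  expect_equal(res$audit$failed_criterion[3], "not_significant_MvsO")
  expect_equal(res$audit$failed_criterion[5], "unstable_YvsM")
  # audit partition: survivors + rejected = universe
  expect_equal(sum(res$audit$survives) + sum(res$audit$failed_criterion != ""),
               6L)
  # alpha = 0 removes everything; infinite bound keeps all significant
  expect_length(aging_gene_filter(mo, ym, alpha = 0)$survivors, 0L)
  expect_setequal(aging_gene_filter(mo, ym, stability_bound = Inf)$survivors,
                  c("g1", "g2", "g4", "g5", "g6"))
  # mismatched universes are reported with the symmetric difference
  expect_error(aging_gene_filter(mo, ym[1:5, ]), "symmetric difference")
})

test_that("senolytic filter isolates reversing genes and drops gavage
           confounds on a toy table", {
  gene <- paste0("g", 1:8)
  mo  <- data.frame(gene, log2fc = c( 2,  2, -2,  2, 0.1,  2,  2, -2),
                    adj_p = c(.01, .01, .01, .01, .8, .01, .3, .01))
  dqt <- data.frame(gene, log2fc = c(-2, -2,  2, -2,  -2,  2, -2,  2),
                    adj_p = c(.01, .01, .01, .01, .01, .01, .01, .2))
  wat <- data.frame(gene, log2fc = c(0, 1.5, 0, 0, 0, 0, 0, 0), adj_p = .5)
  veh <- data.frame(gene, log2fc = c(0, 0, 0, 0.05, 0, 0, 0, 0), adj_p = .5)
  # g1: reverses, clean, aging-significant -> survives
  # g2: reverses but water-confounded -> out
  # g3: reverses (down-up), clean -> survives
  # g4: reverses, clean -> survives
  # g5: no aging signal -> out; g6: same direction -> out
  # g7: not aging-significant -> out; g8: DQ not significant -> out
  res <- dq_effect_filter(dqt, wat, veh, mo)
  expect_setequal(res$survivors, c("g1", "g3", "g4"))
  expect_equal(res$audit$failed_criterion[2], "gavage_confounded_water")
  expect_equal(res$audit$failed_criterion[6], "no_reversal")
  expect_equal(res$audit$failed_criterion[8], "not_significant_OvsDQ")
  # direction restriction
  up <- dq_effect_filter(dqt, wat, veh, mo, direction = "reversal_up")
  expect_setequal(up$survivors, c("g1", "g4"))
  dn <- dq_effect_filter(dqt, wat, veh, mo, direction = "reversal_down")
  expect_setequal(dn$survivors, "g3")
  # every gene gavage-significant: empty set
  wat_all <- wat; wat_all$log2fc <- 2
  expect_length(dq_effect_filter(dqt, wat_all, veh, mo)$survivors, 0L)
})

test_that("filter cascades on generated counts find the right genes", {
  g <- gen_counts(n_genes = 1200, aging_gene_set = 1:40,
                  gavage_gene_set = 41:80, dq_gene_set = 81:120,
                  effect_log2fc = 2, seed = 2)
  de <- function(a, b) de_test(g$counts, g$samples$group, a, b)
  de_mo <- de("M", "O")
  dq <- dq_effect_filter(de("O", "O_DQ"), de("O", "O_water"),
                         de("O", "O_vehicle"), de_mo)
  dqi <- match(dq$survivors, rownames(g$counts))
  expect_gte(sum(dqi %in% 81:120) / 40, 0.8)         # sensitivity
  expect_true(all(head(dqi, 20) %in% 81:120))        # ranked list purity
  ag <- aging_gene_filter(de_mo, de("Y", "M"))
  agi <- match(ag$survivors, rownames(g$counts))
  expect_gte(sum(agi %in% 1:40) / 40, 0.8)
  expect_true(all(head(agi, 20) %in% c(1:40, 81:120)))
  # no gavage-only gene survives the senolytic cascade or either top-20 list
  expect_false(any(dqi %in% 41:80))
  expect_false(any(head(agi, 20) %in% 41:80))
})

test_that("counts and Ct tables round-trip through their file formats", {
  g <- gen_counts(n_genes = 30, seed = 4)
  p <- file.path(tempdir(), "counts.tsv")
  write_counts(g$counts, g$samples, p)
  rt <- read_counts(p)
  expect_equal(rt$counts, g$counts)
  expect_equal(rt$samples, g$samples)
  q <- gen_qpcr(matrix(c(1, 2), 1, 2, dimnames = list("Il6", c("Y", "O"))),
                n_samples = 2, seed = 5)
  pq <- file.path(tempdir(), "ct.csv")
  write_ct_table(q$ct, pq)
  expect_equal(read_ct_table(pq)$ct, q$ct$ct)
  unlink(c(p, paste0(p, ".samples.csv"), pq))
})
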