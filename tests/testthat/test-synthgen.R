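test_that("generators are byte-identical under identical seed and parameters", {
  g1 <- gen_confocal_stack(n_nuclei = 3, taf_fraction = 0.3, seed = 42)
  g2 <- gen_confocal_stack(n_nuclei = 3, taf_fraction = 0.3, seed = 42)
  expect_identical(g1, g2)
  r1 <- gen_rnascope_image(10, seed = 9); r2 <- gen_rnascope_image(10, seed = 9)
  expect_identical(r1, r2)
  c1 <- gen_cmg_trace(n_cycles = 3, seed = 5); c2 <- gen_cmg_trace(n_cycles = 3, seed = 5)
  expect_identical(c1, c2)
  v1 <- gen_vsa_image(5, seed = 2); v2 <- gen_vsa_image(5, seed = 2)
  expect_identical(v1, v2)
  k1 <- gen_counts(n_genes = 100, seed = 3); k2 <- gen_counts(n_genes = 100, seed = 3)
  expect_identical(k1, k2)
  # a different seed changes output
  expect_false(identical(g1$stack$data,
                         gen_confocal_stack(n_nuclei = 3, taf_fraction = 0.3,
                                            seed = 43)$stack$data))
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123); before <- .Random.seed
  invisible(gen_rnascope_image(5, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("confocal ground truth honours the TAF fraction at the extremes", {
  g0 <- gen_confocal_stack(n_nuclei = 3, taf_fraction = 0, seed = 1)
  expect_equal(nrow(g0$truth$taf_pairs), 0L)
  g1 <- gen_confocal_stack(n_nuclei = 3, telomere_foci_per_nucleus = 5,
                           taf_fraction = 1, seed = 1)
  n_tel <- sum(g1$truth$foci$channel == "telomere")
  expect_equal(n_tel, 15L)
  expect_setequal(g1$truth$taf_pairs$telomere_id,
                  g1$truth$foci$id[g1$truth$foci$channel == "telomere"])
})

test_that("intended TAF pairs have >= 1% voxel overlap, verified by explicit
           intersection on the ground-truth voxel sets", {
  g <- gen_confocal_stack(n_nuclei = 20, taf_fraction = 0.3, seed = 7)
  tr <- g$truth
  paired_tel <- tr$taf_pairs$telomere_id
  for (k in seq_len(nrow(tr$taf_pairs))) {
    a <- tr$voxels[[as.character(tr$taf_pairs$telomere_id[k])]]
    b <- tr$voxels[[as.character(tr$taf_pairs$damage_id[k])]]
    ratio <- length(intersect(a, b)) / min(length(a), length(b))
    expect_gte(ratio, 0.01)
  }
  # unpaired telomere foci overlap no damage focus at all
  tel_ids <- tr$foci$id[tr$foci$channel == "telomere"]
  dam_ids <- tr$foci$id[tr$foci$channel == "gH2AX"]
  for (i in setdiff(tel_ids, paired_tel)) {
    for (j in dam_ids)
      expect_equal(length(intersect(tr$voxels[[as.character(i)]],
                                    tr$voxels[[as.character(j)]])), 0L)
  }
  # fraction of telomere foci in pairs ~ Binomial(n_tel, 0.3)
  frac <- nrow(tr$taf_pairs) / length(tel_ids)
  se <- sqrt(0.3 * 0.7 / length(tel_ids))
  expect_lt(abs(frac - 0.3), 4 * se)
})

test_that("every rendered focus is re-detectable on the noiseless stack
           (ground-truth completeness)", {
  g <- gen_confocal_stack(n_nuclei = 4, taf_fraction = 0.2, noise_sd = 0,
                          lipofuscin_density = 0.3, seed = 11)
  tel <- detect_objects(g$stack, "telomere", 0.5, c(0, 30))
  dam <- detect_objects(g$stack, "gH2AX", 0.5, c(0, 30))
  tr <- g$truth$foci
  expect_equal(nrow(tel$objects),
               sum(tr$channel %in% c("telomere", "lipofuscin")))
  expect_equal(nrow(dam$objects),
               sum(tr$channel %in% c("gH2AX", "lipofuscin")))
})

test_that("confocal generator rejects infeasible requests explicitly", {
  expect_error(gen_confocal_stack(n_nuclei = 50, dim = c(40, 40, 16), seed = 1),
               "placement failure")
  expect_error(gen_confocal_stack(n_nuclei = 2, taf_fraction = 1.5, seed = 1),
               "taf_fraction")
})

test_that("RNAscope ground truth matches the requested positivity design", {
  g0 <- gen_rnascope_image(20, positive_fraction = 0, seed = 4)
  expect_false(any(g0$truth$nuclei$positive))
  expect_equal(nrow(g0$truth$puncta), 0L)
  g1 <- gen_rnascope_image(12, positive_fraction = 1, puncta_per_positive = 5,
                           seed = 4)
  expect_true(all(g1$truth$nuclei$positive))
  expect_true(all(g1$truth$nuclei$n_puncta == 5L))
  expect_equal(nrow(g1$truth$puncta), 60L)
  # stochastic positivity count is itself the recorded truth
  g <- gen_rnascope_image(100, positive_fraction = 0.10, seed = 3)
  expect_equal(sum(g$truth$nuclei$positive),
               sum(table(g$truth$puncta$nucleus) > 0))
  expect_error(gen_rnascope_image(10, puncta_diam_px = c(0.5, 30), seed = 1),
               "puncta_diam_px")
})

test_that("SA b-gal generator restricts positivity to the luminal layer", {
  g <- gen_sabgal_section(40, 40, 0.5, seed = 5)
  cells <- g$truth$cells
  expect_false(any(cells$positive[cells$layer == "nonluminal"]))
  npos <- sum(cells$positive[cells$layer == "luminal"])
  expect_lt(abs(npos - 20), 4 * sqrt(40 * 0.25))
  g0 <- gen_sabgal_section(30, 10, 0, seed = 5)
  expect_equal(sum(g0$truth$cells$positive), 0L)
  # luminal-only section: scorer denominator equals n_luminal_cells
  gl <- gen_sabgal_section(25, 0, 0.4, seed = 6)
  expect_equal(sabgal_score(gl$stack)$n_cells, 25L)
})

test_that("CMG volume channel conserves infused volume and steps only at voids", {
  g <- gen_cmg_trace(n_cycles = 4, noise_sd = 0, volume_noise_sd = 0,
                     nvc_rate = 4, nvc_amplitude = 5, seed = 8)
  v <- g$trace$volume
  expect_true(all(diff(v) >= -1e-12))
  # number of step regions equals n_cycles even with NVCs present
  dv <- diff(v)
  runs <- rle(dv > 1e-9)
  expect_equal(sum(runs$values), 4L)
  # conservation: total collected volume = infusion_rate x sum of IVIs
  expect_equal(max(v), 1.5 / 3600 * sum(g$truth$cycles$ivi), tolerance = 1e-10)
  # per-cycle volume matches the printed-magnitude identity 1.5 mL/h x 172.86 s
  expect_equal(g$truth$cycles$voided_volume[1], 1.5 / 3600 * 172.86,
               tolerance = 1e-12)
  expect_error(gen_cmg_trace(landmarks = c(Pbase = 20, Pthresh = 10,
                                           Pmax = 50, Pend = 25), seed = 1),
               "infeasible landmark ordering")
})

test_that("VSA ground truth covers corner bias, emptiness and area arithmetic", {
  gc <- gen_vsa_image(8, corner_bias = 1, seed = 3)
  expect_true(all(gc$truth$spots$in_corner))
  g0 <- gen_vsa_image(0, seed = 3)
  expect_equal(nrow(g0$truth$spots), 0L)
  g <- gen_vsa_image(10, corner_bias = 0.5, seed = 9)
  tr <- g$truth$spots
  pct <- 100 * sum(tr$area_cm2[tr$in_corner]) / sum(tr$area_cm2)
  expect_equal(pct, with(tr, 100 * sum(area_cm2 * in_corner) / sum(area_cm2)))
  expect_error(gen_vsa_image(500, cage_dims = c(10, 10), seed = 1),
               "placement failure")
})

test_that("count generator: aging genes shift between M and O but not Y and M", {
  g <- gen_counts(n_genes = 800, aging_gene_set = 1:40, effect_log2fc = 2,
                  seed = 12)
  de_mo <- de_test(g$counts, g$samples$group, "M", "O")
  de_ym <- de_test(g$counts, g$samples$group, "Y", "M")
  expect_equal(median(abs(de_mo$log2fc[1:40])), 2, tolerance = 0.15)
  expect_lt(median(abs(de_ym$log2fc[1:40])), 0.15)
  expect_error(gen_counts(group_n = c(Y = 0, M = 5, O = 5, O_water = 5,
                                      O_vehicle = 5, O_DQ = 5), seed = 1),
               "at least one sample")
  expect_error(gen_counts(aging_gene_set = 1:10, gavage_gene_set = 5:15,
                          seed = 1), "disjoint")
})

test_that("qPCR generator inverts exactly through the Pfaffl formula", {
  ratios <- matrix(c(1, 1, 4, 0.25), 2, 2,
                   dimnames = list(c("Il6", "Mmp3"), c("Y", "O")))
  q <- gen_qpcr(ratios, n_samples = 4, ct_noise_sd = 0, loading_sd = 0.4,
                seed = 21)
  # a 4-fold ratio at E = 2 is exactly 2 cycles after removing the
  # per-sample loading shift carried by the references
  for (target in c("Il6", "Mmp3")) {
    pf <- pfaffl_relative_expression(q$ct, target, q$efficiencies,
                                     q$reference_genes, "Y")
    expect_equal(pf$group_means$mean_ratio[pf$group_means$group == "O"],
                 ratios[target, "O"], tolerance = 1e-10)
    expect_equal(pf$group_means$mean_ratio[pf$group_means$group == "Y"], 1,
                 tolerance = 1e-10)
  }
  expect_error(gen_qpcr(ratios, efficiencies = c(Il6 = 0.9), seed = 1),
               "efficiencies")
  # noisy estimates are unbiased within Monte-Carlo error
  ests <- vapply(1:30, function(s) {
    q <- gen_qpcr(ratios, n_samples = 8, ct_noise_sd = 0.1, seed = s)
    pf <- pfaffl_relative_expression(q$ct, "Il6", q$efficiencies,
                                     q$reference_genes, "Y")
    pf$group_means$mean_ratio[pf$group_means$group == "O"]
  }, numeric(1))
  expect_lt(abs(mean(ests) - 4), 4 * sd(ests) / sqrt(length(ests)) + 0.02)
})
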