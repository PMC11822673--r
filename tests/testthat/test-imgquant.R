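# helper: build a flat 2-D stack with square objects of given intensities
square_stack <- function(intensities, size = 4, gap = 6) {
  n <- length(intensities)
  nx <- n * (size + gap) + gap
  a <- array(0, dim = c(nx, size + 2 * gap, 1, 1))
  for (i in seq_len(n)) {
    x0 <- gap + (i - 1) * (size + gap)
    a[x0:(x0 + size - 1), gap:(gap + size - 1), 1, 1] <- intensities[i]
  }
  image_stack(a, voxel_size = c(1, 1, 1), channel_names = "ch")
}

test_that("positive-control threshold is the stated percentile of object
           intensities", {
  s <- square_stack(seq(0.1, 1.0, by = 0.1))
  thr <- threshold_from_positive_control(s, "ch", percentile = 10,
                                         detect_threshold = 0.05)
  expect_equal(as.numeric(thr), as.numeric(quantile(seq(0.1, 1, 0.1), 0.1)))
  expect_equal(attr(thr, "n_objects"), 10L)
  thr0 <- threshold_from_positive_control(s, "ch", percentile = 0,
                                          detect_threshold = 0.05)
  expect_equal(as.numeric(thr0), 0.1)
  s1 <- square_stack(0.7)
  for (p in c(0, 10, 50, 100))
    expect_equal(as.numeric(threshold_from_positive_control(
      s1, "ch", p, detect_threshold = 0.05)), 0.7)
  empty <- square_stack(0.0)
  expect_error(threshold_from_positive_control(empty, "ch", 10,
                                               detect_threshold = 0.05),
               "no detectable objects")
})

test_that("detect_objects gates components by equivalent diameter and keeps
           the rejects with reasons", {
  # five in-gate squares (4x4 -> eq diam ~4.5) and three 1-px debris
  a <- array(0, dim = c(80, 30, 1, 1))
  for (i in 0:4) a[(5 + i * 12):(8 + i * 12), 5:8, 1, 1] <- 1
  for (i in 0:2) a[10 + i * 20, 20, 1, 1] <- 1
  s <- image_stack(a, c(1, 1, 1), "ch")
  os <- detect_objects(s, "ch", 0.5, diam_gate_px = c(3, 10))
  expect_equal(nrow(os$objects), 5L)
  expect_equal(nrow(os$rejected), 3L)
  expect_true(all(os$rejected$reason == "below_diameter_gate"))
  # threshold above the global maximum: empty, not an error
  expect_equal(nrow(detect_objects(s, "ch", 2)$objects), 0L)
  # two touching puncta merge into one supra-gate component and are rejected
  b <- array(0, dim = c(40, 40, 1, 1))
  b[5:14, 5:14, 1, 1] <- 1
  b[15:24, 5:14, 1, 1] <- 1   # touching: one 200-px blob, eq diam ~16
  s2 <- image_stack(b, c(1, 1, 1), "ch")
  os2 <- detect_objects(s2, "ch", 0.5, diam_gate_px = c(3, 12))
  expect_equal(nrow(os2$objects), 0L)
  expect_equal(os2$rejected$reason, "above_diameter_gate")
})

test_that("overlap_ratio uses the min denominator, is symmetric and bounded", {
  A <- 1:100; B <- 1:100
  expect_equal(overlap_ratio(A, B), 1)
  expect_equal(overlap_ratio(1:10, 11:20), 0)
  A <- 1:100; B <- c(100L, 200:598)   # |A|=100, |B|=400, |intersection|=1
  expect_equal(overlap_ratio(A, B), 0.01)
  expect_equal(overlap_ratio(A, B), overlap_ratio(B, A))
  expect_gte(overlap_ratio(A, B), 0)
  expect_error(overlap_ratio(integer(0), B), "empty")
  expect_equal(overlap_ratio(A, B, denominator = "union"), 1 / 499)
})

test_that("lipofuscin is flagged in both channels; true TAF pairs are not", {
  g <- gen_confocal_stack(n_nuclei = 4, taf_fraction = 0.5,
                          lipofuscin_density = 3, noise_sd = 0, seed = 31)
  n_lip <- sum(g$truth$foci$channel == "lipofuscin")
  expect_gt(n_lip, 0)
  pip <- run_taf_pipeline(g)
  expect_equal(sum(pip$telomere$objects$autofluorescent), n_lip)
  expect_equal(sum(pip$damage$objects$autofluorescent), n_lip)
  # no true pair lost to the autofluorescence rule: every intended pair called
  expect_equal(nrow(pip$result$tafs), nrow(g$truth$taf_pairs))
  # disjoint sets: zero flags
  tel <- detect_objects(g$stack, "telomere", 0.5, c(0, 20))
  far <- detect_objects(square_stack(0.8), "ch", 0.5)
  far$dim <- tel$dim   # same grid, disjoint voxels
  fl <- flag_autofluorescent(tel, far)
  expect_false(any(fl$fociA$objects$autofluorescent))
})

test_that("call_tafs equals exhaustive all-pairs enumeration on small stacks", {
  for (seed in c(1, 2, 3)) {
    g <- gen_confocal_stack(n_nuclei = 3, taf_fraction = 0.4,
                            lipofuscin_density = 0.5, noise_sd = 0,
                            dim = c(64, 64, 22), seed = seed)
    pip <- run_taf_pipeline(g)
    bf <- brute_force_tafs(pip$telomere, pip$damage, pip$nuclei)
    expect_equal(pip$result$per_nucleus$taf_count, bf$counts)
    expect_equal(pip$result$n_unassigned, bf$unassigned)
    expect_equal(as.matrix(pip$result$tafs[, c("telomere_id", "damage_id")]),
                 bf$pairs, ignore_attr = TRUE)
  }
})

test_that("senescence calls follow the 2+ TAF rule and the zero case", {
  g0 <- gen_confocal_stack(n_nuclei = 4, taf_fraction = 0, noise_sd = 0, seed = 3)
  pip0 <- run_taf_pipeline(g0)
  expect_false(any(pip0$result$per_nucleus$senescent))
  g2 <- gen_confocal_stack(n_nuclei = 6, taf_fraction = 0.5, seed = 17)
  pip2 <- run_taf_pipeline(g2)
  expect_equal(pip2$result$per_nucleus$senescent,
               pip2$result$per_nucleus$taf_count >= 2)
})

test_that("percent TAF-positive arithmetic and guards", {
  g <- gen_confocal_stack(n_nuclei = 6, taf_fraction = 0.5, seed = 17)
  res <- run_taf_pipeline(g)$result
  ns <- sum(res$per_nucleus$senescent)
  expect_equal(percent_taf_positive(res, 50), 100 * ns / 50)
  # 2 senescent of 50 cells is the 4% magnitude reported for umbrella cells
  fake <- res; fake$per_nucleus$senescent <- rep(c(TRUE, FALSE), c(2, 4))
  expect_equal(percent_taf_positive(fake, 50), 4)
  expect_equal(percent_taf_positive(fake, 2), 100)
  fake0 <- res; fake0$per_nucleus$senescent <- rep(FALSE, 6)
  expect_equal(percent_taf_positive(fake0, 10), 0)
  expect_error(percent_taf_positive(res, 0), "positive")
  expect_error(percent_taf_positive(fake, 1), "smaller")
})

test_that("raising the overlap threshold never increases TAF counts;
           widening a gate never shrinks the accepted set", {
  g <- gen_confocal_stack(n_nuclei = 5, taf_fraction = 0.5, seed = 23)
  pip <- run_taf_pipeline(g)
  prev <- Inf
  for (thr in c(0.01, 0.05, 0.2, 0.5, 0.9)) {
    cfg <- quant_config(overlap_ratio_threshold = thr)
    n <- nrow(call_tafs(pip$telomere, pip$damage, pip$nuclei, cfg)$tafs)
    expect_lte(n, prev)
    prev <- n
  }
  prev <- -1
  for (hi in c(4, 8, 16, 32)) {
    n <- nrow(detect_objects(g$stack, "telomere", 0.5, c(0, hi))$objects)
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("consistent channel relabeling leaves all outputs unchanged", {
  g <- gen_confocal_stack(n_nuclei = 4, taf_fraction = 0.4, seed = 29)
  s <- g$stack
  perm <- c(3, 1, 2)
  s2 <- image_stack(s$data[, , , perm], s$voxel_size, s$channel_names[perm])
  for (ch in s$channel_names)
    expect_identical(channel(s, ch), channel(s2, ch))
  r1 <- run_taf_pipeline(list(stack = s))$result
  r2 <- run_taf_pipeline(list(stack = s2))$result
  expect_equal(r1, r2)
})

test_that("RNAscope field quantification recovers the designed positives and
           ignores out-of-gate debris", {
  g <- gen_rnascope_image(100, positive_fraction = 0.10, debris_density = 12,
                          seed = 3)
  r <- rnascope_quantify(g$stack)
  expect_equal(r$field$total_nuclei, 100L)
  expect_equal(r$field$p16_positive_nuclei, sum(g$truth$nuclei$positive))
  expect_equal(r$field$total_p16_puncta, nrow(g$truth$puncta))
  expect_equal(r$field$percent_p16_positive,
               100 * mean(g$truth$nuclei$positive))
  # debris-only field: nothing in gate
  g0 <- gen_rnascope_image(10, positive_fraction = 0, debris_density = 8,
                           seed = 4)
  r0 <- rnascope_quantify(g0$stack)
  expect_equal(r0$field$total_p16_puncta, 0L)
  expect_equal(r0$field$p16_positive_nuclei, 0L)
  expect_error(rnascope_quantify(square_stack(0.5)), "channels")
})

test_that("SA b-gal scoring recovers designed positivity and aggregates
           fields then sections", {
  g <- gen_sabgal_section(40, 30, 0.5, seed = 5)
  sc <- sabgal_score(g$stack)
  truth_pct <- 100 * mean(g$truth$cells$positive[g$truth$cells$layer == "luminal"])
  expect_equal(sc$percent_positive, truth_pct)
  g0 <- gen_sabgal_section(20, 10, 0, seed = 6)
  expect_equal(sabgal_score(g0$stack)$percent_positive, 0)
  # three fields at 30/45/45 average to a 40% section value
  df <- data.frame(animal = "m1", section = c(1, 1, 1), field = 1:3,
                   percent = c(30, 45, 45))
  agg <- sabgal_aggregate(df)
  expect_equal(agg$per_section$percent, 40)
  # unusable fields are excluded and listed
  df2 <- rbind(df, data.frame(animal = "m1", section = 2, field = 1,
                              percent = NA))
  agg2 <- sabgal_aggregate(df2)
  expect_equal(nrow(agg2$excluded_fields), 1L)
  expect_equal(agg2$per_animal$percent, 40)
})
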