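# Generators: determinism, planted effects recoverable by direct oracles,
# and null constructions carrying no signal.

test_that("generators are bit-reproducible given the seed", {
  b1 <- gen_bulk_cohort(n_samples = 40, n_genes = 100, seed = 11)
  b2 <- gen_bulk_cohort(n_samples = 40, n_genes = 100, seed = 11)
  expect_identical(unclass(b1$expr), unclass(b2$expr))
  expect_identical(b1$cohort, b2$cohort)

  s1 <- gen_sc_dataset(n_cells = 60, n_genes = 300,
                       truth = small_truth(n_genes = 300), seed = 4,
                       n_chrom = 3)
  s2 <- gen_sc_dataset(n_cells = 60, n_genes = 300,
                       truth = small_truth(n_genes = 300), seed = 4,
                       n_chrom = 3)
  expect_identical(unclass(s1$counts), unclass(s2$counts))

  d1 <- gen_dilution_assay(0.1, seed = 2)
  d2 <- gen_dilution_assay(0.1, seed = 2)
  expect_identical(d1, d2)

  m1 <- gen_dose_matrix(noise_sd = 2, seed = 9)
  m2 <- gen_dose_matrix(noise_sd = 2, seed = 9)
  expect_identical(m1$inhibition, m2$inhibition)
})

test_that("generator calls do not disturb the caller's RNG state", {
  set.seed(123); before <- .Random.seed
  invisible(gen_dilution_assay(0.2, seed = 77))
  expect_identical(.Random.seed, before)
})

test_that("bulk cohort plants the stated expression effects", {
  # null construction: zero effects, no group difference beyond noise
  tr0 <- small_truth(effects = 0)
  b0 <- gen_bulk_cohort(n_samples = 200, n_genes = 600, truth = tr0,
                        seed = 5, noise_sd = 0.2)
  grp <- b0$cohort$group
  d0 <- rowMeans(as.matrix(b0$expr)[, which(grp == "resistant")]) -
    rowMeans(as.matrix(b0$expr)[, which(grp == "sensitive")])
  se0 <- 0.2 * sqrt(1 / sum(grp == "resistant", na.rm = TRUE) +
                      1 / sum(grp == "sensitive", na.rm = TRUE))
  expect_lt(abs(mean(d0[names(small_truth()$resistance_genes)])), 4 * se0)

  # planted +1.0 log2: group-mean difference within 3 SE of 1.0
  b1 <- gen_bulk_cohort(n_samples = 280, n_genes = 600,
                        truth = small_truth(), seed = 6, noise_sd = 0.2)
  grp <- b1$cohort$group
  i1 <- which(grp == "resistant"); i2 <- which(grp == "sensitive")
  dd <- mean(as.matrix(b1$expr)["MSN", i1]) -
    mean(as.matrix(b1$expr)["MSN", i2])
  se <- 0.2 * sqrt(1 / length(i1) + 1 / length(i2))
  expect_lt(abs(dd - 1.0), 3 * se)

  # group only on dead chemoradiotherapy samples
  lab <- !is.na(b1$cohort$group)
  expect_true(all(b1$cohort$vital_status[lab] == "dead"))
  expect_true(all(b1$cohort$therapy[lab] == "chemoradiotherapy"))
  expect_error(gen_bulk_cohort(n_samples = 4), "n_samples")
})

test_that("cell-line panel couples driver, apoptosis and IC50 as planted", {
  p <- gen_cellline_panel(n_lines = 16, n_genes = 400, n_drugs = 6,
                          truth = small_truth(n_genes = 400), seed = 8,
                          n_sensitive_drugs = 2, ic50_ratio = 4,
                          viability_noise_sd = 0.5)
  # viability at dose 0 anchored near 100%
  v0 <- sapply(p$viability, function(v) mean(v[, "0"]))
  expect_true(all(v0 > 90))

  # planted 4x IC50 ratio recovered within 25% by refitting the curves
  doses <- p$truth$doses
  ratio <- sapply(rownames(p$viability[[1]]), function(l) {
    inhib <- 100 - as.numeric(p$viability[[1]][l, ])
    as.numeric(ic50(fit_loglogistic(doses, clamp_test(inhib))))
  })
  grp <- p$truth$line_group
  est <- exp(mean(log(ratio[grp == "sensitive"])) -
               mean(log(ratio[grp == "resistant"])))
  expect_lt(abs(est - 4) / 4, 0.25)

  # null coupling: zero effects => driver expression independent of
  # apoptosis outcome
  tr0 <- small_truth(n_genes = 400, effects = 0)
  p0 <- gen_cellline_panel(n_lines = 20, n_genes = 400, n_drugs = 2,
                           truth = tr0, seed = 9)
  drv <- as.matrix(p0$expr)["MSN", ]
  apo <- tapply(p0$apoptosis$fraction[p0$apoptosis$condition == "RT"],
                p0$apoptosis$line[p0$apoptosis$condition == "RT"], mean)
  expect_gt(stats::cor.test(drv, apo[names(drv)])$p.value, 0.01)
})

test_that("sc dataset plants segment-level count shifts", {
  tr <- small_truth(n_genes = 600)
  sc <- gen_sc_dataset(n_cells = 300, n_genes = 600, truth = tr, seed = 3,
                       n_chrom = 3, driver_shift = 0)
  seg_genes <- sc$truth$segment_genes[[1]]
  tum <- sc$annotation$cell[sc$annotation$cluster != "ref"]
  ref <- sc$annotation$cell[sc$annotation$cluster == "ref"]
  cnt <- as.matrix(sc$counts)
  ratio <- mean(cnt[seg_genes, tum]) / mean(cnt[seg_genes, ref])
  expect_lt(abs(ratio - 2^0.58), 0.12)

  # no segments: tumor/reference ratio ~= 1 outside planted markers
  tr0 <- synthetic_truth(n_genes = 600,
                         cnv_segments = data.frame(chrom = character(),
                                                   start_idx = integer(),
                                                   end_idx = integer(),
                                                   gain_log2 = numeric()),
                         seed = 1)
  sc0 <- gen_sc_dataset(n_cells = 300, n_genes = 600, truth = tr0,
                        seed = 3, n_chrom = 3, driver_shift = 0)
  plain <- setdiff(rownames(sc0$counts),
                   c(unlist(sc0$truth$marker_genes),
                     names(tr0$resistance_genes)))
  cnt0 <- as.matrix(sc0$counts)
  t0 <- sc0$annotation$cluster != "ref"
  r <- mean(cnt0[plain, t0]) / mean(cnt0[plain, !t0])
  expect_lt(abs(r - 1), 0.05)

  expect_error(gen_sc_dataset(100, 200, truth = synthetic_truth(n_genes = 600)),
               "out of range")
})

test_that("spatial spots are the stated mixtures of cluster profiles", {
  tr <- small_truth(n_genes = 400)
  sc <- gen_sc_dataset(n_cells = 200, n_genes = 400, truth = tr, seed = 2,
                       n_chrom = 2)
  sp <- gen_spatial_dataset(60, sc$truth, seed = 3, dominant_weight = 1,
                            noise_sd = 0.05)
  logp <- log2(sc$truth$cluster_profiles + 1)
  ex <- as.matrix(sp$spatial$expr)
  best <- apply(stats::cor(ex, logp), 1, function(r)
    colnames(logp)[which.max(r)])
  truth_dom <- colnames(sp$truth$spot_mixtures)[
    apply(sp$truth$spot_mixtures, 1, which.max)]
  expect_true(all(best == truth_dom))
  expect_true(all(abs(rowSums(sp$truth$spot_mixtures) - 1) < 1e-12))
})

test_that("dose matrix generator reproduces the Bliss-plus-offset surface", {
  # null: exact Bliss surface of the two curves
  dm0 <- gen_dose_matrix(synergy_magnitude = 0, noise_sd = 0)
  tr <- attr(dm0, "truth")
  expect_equal(dm0$inhibition, clamp_test(tr$bliss * 100),
               ignore_attr = TRUE)
  # planted 0.2: combo cells exceed Bliss by 20 points before clamping
  dm2 <- gen_dose_matrix(synergy_magnitude = 0.2, noise_sd = 0)
  tr2 <- attr(dm2, "truth")
  pos <- outer(dm2$doses_a > 0, dm2$doses_b > 0, `&`)
  expect_equal(unique(round((tr2$surface - tr2$bliss)[pos], 12)), 0.2)
  # default grids give the 5x6 layout
  expect_equal(dim(dm2$inhibition), c(5L, 6L))
  expect_error(gen_dose_matrix(doses_a = c(-1, 0, 4)), "non-negative")
})

test_that("dilution assay follows the single-hit response model", {
  d <- gen_dilution_assay(0.1, seed = 1)
  expect_equal(d$wells_responding[d$cells_per_well == 0], 0)
  d1 <- gen_dilution_assay(1, seed = 1)
  expect_true(all(d1$wells_responding[d1$cells_per_well > 0] ==
                    d1$wells_tested[d1$cells_per_well > 0]))
  # frequency 0.1, dose 10: responding fraction ~= 1 - 0.9^10 = 0.651
  big <- gen_dilution_assay(0.1, doses = 10, n_wells = 4000, seed = 5)
  phat <- big$wells_responding / big$wells_tested
  p0 <- 1 - 0.9^10
  expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / 4000))
  expect_error(gen_dilution_assay(0), "frequency")
  expect_error(gen_dilution_assay(1.2), "frequency")
})
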