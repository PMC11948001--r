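# Signature derivation: stratification rules, differential expression
# against direct oracles, volcano boundaries, intersection, correlation,
# and preranked enrichment.

test_that("survival stratification splits at the median with ties sensitive", {
  cohort <- data.frame(sample = paste0("s", 1:4),
                       survival_time = c(2, 4, 6, 8),
                       vital_status = "dead",
                       therapy = "chemoradiotherapy")
  s <- suppressMessages(stratify_by_survival(cohort))
  expect_equal(s$group[order(s$survival_time)],
               c("resistant", "resistant", "sensitive", "sensitive"))
  expect_equal(attr(s, "cutoff"), 5)

  # a sample exactly at the cutoff goes sensitive
  c2 <- data.frame(sample = paste0("s", 1:3), survival_time = c(2, 5, 9),
                   vital_status = "dead", therapy = "chemoradiotherapy")
  s2 <- suppressMessages(stratify_by_survival(c2))
  expect_equal(s2$group[s2$survival_time == 5], "sensitive")

  alive <- transform(cohort, vital_status = "alive")
  expect_error(suppressMessages(stratify_by_survival(alive)), "fewer than 2")
  flat <- transform(cohort, survival_time = 3)
  expect_error(suppressMessages(stratify_by_survival(flat)), "degenerate")
})

test_that("apoptosis stratification matches a direct t-test oracle", {
  mk <- function(line, ctrl, rt) {
    data.frame(line = line,
               condition = rep(c("control", "RT"), each = length(ctrl)),
               replicate = rep(seq_along(ctrl), 2),
               fraction = c(ctrl, rt))
  }
  # treated identical to control -> resistant
  a <- mk("L1", c(0.05, 0.06, 0.05), c(0.05, 0.06, 0.05))
  expect_equal(stratify_by_apoptosis(a)$label, "resistant")

  # strong increase -> sensitive, p agrees with stats::t.test
  b <- mk("L2", c(0.05, 0.06, 0.04), c(0.58, 0.62, 0.60))
  res <- stratify_by_apoptosis(b)
  expect_equal(res$label, "sensitive")
  oracle <- stats::t.test(c(0.58, 0.62, 0.60), c(0.05, 0.06, 0.04))$p.value
  expect_equal(res$p_RT, oracle)

  # alpha = 0: nothing is significant, every line resistant
  expect_equal(stratify_by_apoptosis(b, alpha = 0)$label, "resistant")

  no_ctrl <- b[b$condition != "control", ]
  expect_error(stratify_by_apoptosis(no_ctrl), "control")
})

test_that("differential expression recovers planted effects and is antisymmetric", {
  tr <- small_truth()
  b <- gen_bulk_cohort(n_samples = 280, n_genes = 600, truth = tr,
                       seed = 21, noise_sd = 0.2)
  grp <- b$cohort$group
  keep <- !is.na(grp)
  labels <- stats::setNames(grp[keep], b$cohort$sample[keep])
  expr <- as.matrix(b$expr)[, names(labels)]
  de <- differential_expression(expr, labels)
  i <- match("MSN", de$gene)
  expect_gt(de$log2fc[i], 0.8)
  expect_lt(de$log2fc[i], 1.2)
  expect_lt(de$fdr[i], 0.05)

  # swapping the labels negates every log2FC exactly
  flipped <- ifelse(labels == "resistant", "sensitive", "resistant")
  names(flipped) <- names(labels)
  de2 <- differential_expression(expr, flipped)
  expect_equal(de2$log2fc, -de$log2fc)

  # moderated variant: identical effect sizes, comparable evidence
  dem <- differential_expression(expr, labels, method = "moderated")
  expect_equal(dem$log2fc, de$log2fc)
  expect_lt(dem$fdr[match("MSN", dem$gene)], 0.05)

  expect_error(differential_expression(expr[, 1:3],
                                       unname(labels[c(1, 2, 3, 4)])),
               "mismatch")
})

test_that("null cohorts carry no differential signal", {
  tr0 <- small_truth(effects = 0)
  b0 <- gen_bulk_cohort(n_samples = 120, n_genes = 500, truth = tr0,
                        seed = 31, noise_sd = 0.3)
  grp <- b0$cohort$group
  keep <- !is.na(grp)
  de <- differential_expression(as.matrix(b0$expr)[, keep], grp[keep])
  expect_lt(mean(de$fdr <= 0.05), 0.02)
  expect_lt(abs(mean(de$log2fc)), 0.05)
})

test_that("volcano filter applies inclusive boundaries", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   log2fc = c(0.5, 0.49, -0.8, 2),
                   p = c(0.05, 0.001, 0.01, 0.2))
  sig <- suppressMessages(volcano_filter(de, lfc_min = 0.5, p_max = 0.05))
  expect_equal(sig$gene, "a")   # boundary gene included; d fails on p
  both <- suppressMessages(volcano_filter(de, 0.5, 0.05, "both"))
  expect_setequal(both$gene, c("a", "c"))
  expect_equal(both$direction[both$gene == "c"], "sensitive-up")
  expect_error(volcano_filter(de, -1, 0.05), "positive")
})

test_that("signature intersection respects direction and set identity", {
  a <- gene_signature(c("x", "y", "z"), "resistant-up", "A")
  b <- gene_signature(c("y", "z", "w"), "resistant-up", "B")
  expect_setequal(intersect_signatures(a, b)$gene, c("y", "z"))

  sub <- gene_signature(c("y"), "resistant-up", "S")
  expect_equal(intersect_signatures(sub, b)$gene, "y")

  dis <- gene_signature(c("q"), "resistant-up", "D")
  expect_warning(out <- intersect_signatures(a, dis), "empty")
  expect_equal(nrow(out), 0)

  conf <- gene_signature(c("y", "z"), c("sensitive-up", "resistant-up"), "C")
  out2 <- suppressMessages(suppressWarnings(intersect_signatures(a, conf)))
  expect_equal(out2$gene, "z")
})

test_that("driver correlation matches closed forms and a Monte-Carlo oracle", {
  n <- 60
  x <- seq_len(n) / 10 + 1
  expr <- rbind(drv = x, same = x, neg = max(x) + 1 - x)
  colnames(expr) <- paste0("s", 1:n)
  res <- correlate_gene(expr, "drv", c("same", "neg"))
  expect_equal(res$r, c(1, -1), tolerance = 1e-12)

  # planted shared latent factor, loading 0.9: observed r within 3 SE of
  # the simulation oracle's mean correlation
  gen_pair <- function(seed) withr::with_seed(seed, {
    f <- stats::rnorm(200)
    a <- 0.9 * f + sqrt(1 - 0.81) * stats::rnorm(200)
    b <- 0.9 * f + sqrt(1 - 0.81) * stats::rnorm(200)
    stats::cor(a, b)
  })
  oracle <- vapply(1:400, gen_pair, numeric(1))
  obs <- gen_pair(9999)
  expect_lt(abs(obs - mean(oracle)), 3 * stats::sd(oracle))

  expr0 <- rbind(drv = rep(1, 5), g = 1:5)
  colnames(expr0) <- paste0("s", 1:5)
  expect_error(correlate_gene(expr0, "drv", "g"), "zero-variance")
})

test_that("preranked enrichment behaves under construction and null", {
  stats_vec <- stats::setNames(seq(5, -5, length.out = 200),
                               paste0("g", 1:200))
  top <- paste0("g", 1:15)
  es_top <- preranked_enrichment(stats_vec, top, n_perm = 200, seed = 1)
  expect_gt(es_top$es, 0)
  expect_lt(es_top$p, 0.01)
  # maximal among random same-size sets
  rnd <- withr::with_seed(42, replicate(50, {
    preranked_enrichment(stats_vec, sample(names(stats_vec), 15),
                         n_perm = 1, seed = 1)$es
  }))
  expect_true(all(es_top$es >= rnd))

  # null ranking: permutation p roughly uniform over repeated draws
  ps <- withr::with_seed(7, vapply(1:120, function(i) {
    sv <- stats::setNames(stats::rnorm(100), paste0("g", 1:100))
    preranked_enrichment(sv, sample(names(sv), 10), n_perm = 99,
                         seed = i)$p
  }, numeric(1)))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.001)

  expect_error(preranked_enrichment(stats_vec, top, n_perm = 0), "n_perm")
  expect_error(preranked_enrichment(stats_vec, "absent", 10), "intersect")
})

test_that("preranked score agrees with fgsea on a fixed ranking", {
  skip_if_not_installed("fgsea")
  sv <- withr::with_seed(5, stats::setNames(stats::rnorm(300),
                                            paste0("g", 1:300)))
  gs <- paste0("g", seq(1, 60, by = 4))
  ours <- preranked_enrichment(sv, gs, n_perm = 10, seed = 1)$es
  ref <- suppressWarnings(
    fgsea::fgsea(list(set = gs), sv, nPermSimple = 101, minSize = 1))$ES
  expect_equal(ours, ref, tolerance = 1e-6)
})
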