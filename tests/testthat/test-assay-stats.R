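# Assay statistics: ELDA against closed forms and a grid-search ML oracle,
# H-score arithmetic, subtype calling, Kaplan-Meier / log-rank against
# hand-rolled oracles, and relative signal.

test_that("single-row ELDA matches the closed-form inversion", {
  t1 <- data.frame(cells_per_well = 10, wells_tested = 16,
                   wells_responding = 8)
  e <- elda_fit(t1)
  expect_equal(e$f_hat, log(2) / 10, tolerance = 1e-6)
  expect_false(e$boundary)
  expect_true(e$lower <= e$f_hat && e$f_hat <= e$upper)
})

test_that("boundary tables are flagged with one-sided bounds", {
  neg <- data.frame(cells_per_well = c(0, 1, 5, 10),
                    wells_tested = 16, wells_responding = 0)
  e0 <- elda_fit(neg)
  expect_true(e0$boundary)
  expect_equal(e0$f_hat, 0)
  expect_gt(e0$upper, 0)

  pos <- data.frame(cells_per_well = c(1, 5, 10), wells_tested = 16,
                    wells_responding = 16)
  e1 <- elda_fit(pos)
  expect_true(e1$boundary)
  expect_gt(e1$lower, 0)

  bad <- data.frame(cells_per_well = 5, wells_tested = 16,
                    wells_responding = 20)
  expect_error(elda_fit(bad), "wells_responding")
  bad0 <- data.frame(cells_per_well = 0, wells_tested = 16,
                     wells_responding = 2)
  expect_error(elda_fit(bad0), "dose-0")
})

test_that("ELDA agrees with a grid-search likelihood oracle", {
  grid <- exp(seq(log(1e-4), log(1), length.out = 10000))
  oracle <- function(tab) {
    tab <- tab[tab$cells_per_well > 0, ]
    ll <- vapply(grid, function(f) {
      p <- pmin(pmax(1 - exp(-f * tab$cells_per_well), 1e-12), 1 - 1e-12)
      sum(tab$wells_responding * log(p) +
            (tab$wells_tested - tab$wells_responding) * log(1 - p))
    }, numeric(1))
    grid[which.max(ll)]
  }
  n_ok <- 0
  withr::with_seed(17, {
    while (n_ok < 30) {
      f <- stats::runif(1, 0.01, 0.5)
      tab <- gen_dilution_assay(f, seed = sample.int(1e6, 1))
      r <- tab$wells_responding[tab$cells_per_well > 0]
      n <- tab$wells_tested[tab$cells_per_well > 0]
      if (all(r == 0) || all(r == n)) next
      n_ok <- n_ok + 1
      est <- elda_fit(tab)$f_hat
      expect_lt(abs(est - oracle(tab)) / oracle(tab), 0.01)
    }
  })
})

test_that("ELDA comparison separates planted frequencies and is symmetric", {
  a <- gen_dilution_assay(0.2, seed = 1)
  b <- gen_dilution_assay(0.02, seed = 2)
  cmp <- elda_compare(a, b)
  expect_lt(cmp$p, 0.001)
  rev <- elda_compare(b, a)
  expect_equal(cmp$chisq, rev$chisq, tolerance = 1e-8)

  same <- elda_compare(a, a)
  expect_lt(same$chisq, 1e-4)
  expect_gt(same$p, 0.99)

  # the planted 10x separation is detected at p < 0.001 across seeds
  ps <- vapply(1:20, function(i)
    elda_compare(gen_dilution_assay(0.2, seed = i),
                 gen_dilution_assay(0.02, seed = i + 1000))$p,
    numeric(1))
  expect_gte(mean(ps < 0.001), 0.95)

  degen <- data.frame(cells_per_well = c(1, 5), wells_tested = 16,
                      wells_responding = 0)
  expect_error(elda_compare(degen, a), "boundary")
})

test_that("H-score follows the weighted-area formula", {
  expect_equal(h_score(0, 0, 1), 300)
  expect_equal(h_score(0, 0, 0, negative = 1), 0)
  expect_equal(h_score(0.5, 0.3, 0.2), 170)  # 50 + 60 + 60
  expect_error(h_score(0.5, 0.5, 0.5, negative = 0), "sum to 1")
  expect_error(h_score(-0.1, 0.6, 0.5), "\\[0, 1\\]")
})

test_that("subtype calling separates marker extremes with PN tie-break", {
  m <- data.frame(CD44 = c(3, 0, 1), YKL40 = c(4, 0, 2),
                  SOX2 = c(0, 3, 2), OLIG2 = c(0, 4, 1))
  out <- call_subtype(m)
  expect_equal(out$subtype[1], "MES")
  expect_equal(out$subtype[2], "PN")

  # exactly balanced z-means tie to PN and are flagged
  tie <- data.frame(CD44 = c(1, 2), YKL40 = c(1, 2),
                    SOX2 = c(1, 2), OLIG2 = c(1, 2))
  tout <- call_subtype(tie)
  expect_true(all(tout$subtype == "PN"))
  expect_true(all(tout$tie))

  zv <- transform(m, CD44 = 1)
  expect_error(call_subtype(zv), "zero-variance")

  # planted two-population panel: >= 95% concordance
  truth_lab <- rep(c("MES", "PN"), each = 50)
  panel <- withr::with_seed(23, {
    shift <- ifelse(truth_lab == "MES", 1.5, -1.5)
    data.frame(CD44 = stats::rnorm(100, shift), YKL40 = stats::rnorm(100, shift),
               SOX2 = stats::rnorm(100, -shift), OLIG2 = stats::rnorm(100, -shift))
  })
  called <- call_subtype(panel)$subtype
  expect_gte(mean(called == truth_lab), 0.95)
})

test_that("log-rank matches hand arithmetic and KM matches a product-limit oracle", {
  # A: deaths at 1, 2 (n = 2); B: deaths at 3, 4 (n = 2)
  km <- km_logrank(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  o_minus_e <- 2 - (2 / 4 + 1 / 3)
  v <- (1 * 3 * 2 * 2) / (16 * 3) + (1 * 2 * 1 * 2) / (9 * 2)
  expect_equal(km$chisq, o_minus_e^2 / v, tolerance = 1e-10)

  # identical groups: chi-square 0, p 1
  km0 <- km_logrank(rep(c(1, 2, 3), 2), rep(1, 6),
                    rep(c("A", "B"), each = 3))
  expect_lt(km0$chisq, 1e-10)
  expect_equal(km0$p, 1)

  # product-limit oracle on random censored datasets
  pl_oracle <- function(time, event) {
    ut <- sort(unique(time[event == 1]))
    s <- 1
    surv <- numeric(length(ut))
    for (k in seq_along(ut)) {
      d <- sum(time == ut[k] & event == 1)
      n <- sum(time >= ut[k])
      s <- s * (1 - d / n)
      surv[k] <- s
    }
    list(time = ut, surv = surv)
  }
  withr::with_seed(29, {
    for (i in 1:25) {
      n <- 30
      tt <- ceiling(stats::rexp(n, 0.2))
      ev <- stats::rbinom(n, 1, 0.7)
      g <- rep(c("A", "B"), length.out = n)
      if (sum(ev[g == "A"]) == 0 || sum(ev[g == "B"]) == 0) next
      km <- km_logrank(tt, ev, g)
      fit <- km$fit
      for (grp_i in 1:2) {
        sel <- if (grp_i == 1) g == "A" else g == "B"
        orc <- pl_oracle(tt[sel], ev[sel])
        idx <- cumsum(fit$strata)
        lo <- if (grp_i == 1) 1 else idx[1] + 1
        hi <- idx[grp_i]
        st <- fit$time[lo:hi]; sv <- fit$surv[lo:hi]
        at_events <- match(orc$time, st)
        expect_equal(sv[at_events], orc$surv, tolerance = 1e-12)
        expect_true(all(diff(sv) <= 1e-12))
      }
    }
  })

  expect_error(km_logrank(1:4, rep(1, 4), rep("A", 4)), "two groups")
  expect_error(km_logrank(1:4, c(0, 0, 1, 1), c("A", "A", "B", "B")),
               "event")
})

test_that("relative signal normalizes to the first measurement", {
  expect_equal(relative_signal(c(100, 200, 400)), c(1, 2, 4))
  expect_equal(relative_signal(rep(7, 4)), rep(1, 4))
  expect_equal(relative_signal(5), 1)
  expect_error(relative_signal(c(0, 1)), "positive")
})
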