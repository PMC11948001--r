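# Pharmacology: four-parameter log-logistic dose-response fitting, IC50
# extraction, differential-IC50 drug screening with a blood-brain-barrier
# filter, and the zero-interaction-potency (ZIP) synergy model with
# optimal-combination selection.

#' Fit a log-logistic dose-response curve
#'
#' Model: inhibition y(d) = L + (U - L) * d^h / (d^h + m^h) with slope
#' h > 0, midpoint m > 0, lower asymptote L (fixed at 0 by default) and
#' upper asymptote U <= `upper_max`. Fitting is bounded least squares
#' (Levenberg-Marquardt) from 5 seeded starts; the best converged fit by
#' RSS wins. Non-convergence and flat (degenerate) inputs return a flagged
#' result rather than an error.
#'
#' @param doses Numeric doses (>= 3 distinct values, including 0).
#' @param inhibitions Inhibition percentages (same length).
#' @param lower_fixed Fixed lower asymptote L (default 0; `NA` frees it).
#' @param upper_max Upper bound on U (default 100).
#' @param n_starts Number of multi-start attempts (default 5).
#' @param seed Seed for start jitter.
#' @return A `dr_curve` list: `h`, `m`, `L`, `U`, `rss`, `converged`,
#'   `degenerate`.
#' @export
fit_loglogistic <- function(doses, inhibitions, lower_fixed = 0,
                            upper_max = 100, n_starts = 5, seed = 1) {
  if (length(doses) != length(inhibitions))
    stop("doses and inhibitions differ in length")
  if (length(unique(doses)) < 3) stop("need >= 3 distinct doses")
  if (!(0 %in% doses)) stop("dose grid must include 0")
  free_L <- is.na(lower_fixed)
  if (stats::sd(inhibitions) < 1e-8) {
    mflat <- mean(inhibitions)
    return(structure(list(h = 1, m = max(doses[doses > 0], 1),
                          L = if (free_L) mflat else lower_fixed, U = mflat,
                          rss = sum((inhibitions - mflat)^2),
                          converged = FALSE, degenerate = TRUE),
                     class = "dr_curve"))
  }
  pred <- function(p, d) {
    L <- if (free_L) p[["L"]] else lower_fixed
    L + (p[["U"]] - L) * ifelse(d > 0, d^p[["h"]] /
                                  (d^p[["h"]] + p[["m"]]^p[["h"]]), 0)
  }
  dpos <- doses[doses > 0]
  u0 <- min(max(inhibitions), upper_max)
  starts <- local_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      s <- list(h = stats::runif(1, 0.5, 3),
                m = exp(stats::runif(1, log(min(dpos)), log(max(dpos)))),
                U = stats::runif(1, 0.6, 1) * max(u0, 10))
      if (free_L) s$L <- stats::runif(1, 0, max(min(inhibitions), 1))
      s
    })
  })
  lower <- c(h = 1e-3, m = 1e-9, U = if (free_L) -Inf else 1e-6)
  upper <- c(h = 50, m = max(dpos) * 1e3, U = upper_max)
  if (free_L) {
    lower <- c(lower, L = -upper_max)
    upper <- c(upper, L = upper_max)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch({
      f <- minpack.lm::nls.lm(
        par = s,
        fn = function(p) inhibitions - pred(p, doses),
        lower = lower[names(s)], upper = upper[names(s)],
        control = minpack.lm::nls.lm.control(maxiter = 200))
      list(par = as.list(stats::coef(f)), rss = sum(f$fvec^2),
           ok = f$info %in% 1:4)
    }, error = function(e) NULL)
    if (!is.null(fit) && fit$ok &&
        (is.null(best) || fit$rss < best$rss)) best <- fit
  }
  if (is.null(best)) {
    s <- starts[[1]]
    return(structure(list(h = s$h, m = s$m,
                          L = if (free_L) s$L else lower_fixed, U = s$U,
                          rss = sum((inhibitions - pred(s, doses))^2),
                          converged = FALSE, degenerate = FALSE),
                     class = "dr_curve"))
  }
  p <- best$par
  structure(list(h = p$h, m = p$m, L = if (free_L) p$L else lower_fixed,
                 U = p$U, rss = best$rss, converged = TRUE,
                 degenerate = FALSE),
            class = "dr_curve")
}

#' Evaluate a dose-response curve
#' @param curve A `dr_curve`.
#' @param d Doses.
#' @return Predicted inhibition at each dose.
#' @export
predict_inhibition <- function(curve, d) {
  curve$L + (curve$U - curve$L) *
    ifelse(d > 0, d^curve$h / (d^curve$h + curve$m^curve$h), 0)
}

#' IC50 of a fitted dose-response curve
#'
#' Smallest dose with 50% inhibition, solved in closed form from the
#' log-logistic parameters. Undefined (NA with attribute
#' `undefined = TRUE`) when the upper asymptote never reaches 50%; 0 when
#' the lower asymptote already exceeds 50%.
#'
#' @param curve A `dr_curve`.
#' @return Dose (numeric), possibly `NA` flagged undefined.
#' @export
ic50 <- function(curve) {
  if (isTRUE(curve$degenerate) || curve$U <= 50)
    return(structure(NA_real_, undefined = TRUE))
  if (curve$L >= 50) return(0)
  q <- (50 - curve$L) / (curve$U - curve$L)
  curve$m * (q / (1 - q))^(1 / curve$h)
}

#' Differential-IC50 drug screen between driver-high and driver-low lines
#'
#' Cell lines are grouped on driver expression with the mean +/- SEM rule
#' (intermediate lines excluded). Per drug: Welch t-test on log10 IC50
#' between groups, log2 fold change (high / low), BH FDR, and a
#' `msn_sensitive` flag = lower IC50 in the driver-high group AND p <
#' `alpha`. Drugs with undefined IC50 in more than half the lines are
#' dropped with a message.
#'
#' @param ic50_table Drugs x lines matrix of IC50 values (NA = undefined).
#' @param driver_expr Named driver expression per line.
#' @param alpha Significance level (default 0.05).
#' @return `data.frame(drug, log2fc, p, fdr, msn_sensitive)` with
#'   attribute `groups`.
#' @export
differential_ic50_screen <- function(ic50_table, driver_expr,
                                     alpha = 0.05) {
  ic50_table <- as.matrix(ic50_table)
  lines <- colnames(ic50_table)
  if (!all(lines %in% names(driver_expr)))
    stop("driver expression missing for some lines")
  grp <- mean_sem_grouping(driver_expr[lines])
  hi <- lines[grp == "high"]; lo <- lines[grp == "low"]
  if (length(hi) < 2 || length(lo) < 2)
    stop("need >= 2 lines per group after mean+/-SEM grouping (",
         length(hi), " high, ", length(lo), " low)")
  rows <- list()
  dropped <- 0
  for (d in rownames(ic50_table)) {
    v <- ic50_table[d, ]
    if (mean(is.na(v)) > 0.5) { dropped <- dropped + 1; next }
    a <- stats::na.omit(log10(v[hi])); b <- stats::na.omit(log10(v[lo]))
    if (length(a) < 2 || length(b) < 2) { dropped <- dropped + 1; next }
    # constant data carry no evidence of a difference
    p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    rows[[d]] <- data.frame(drug = d,
                            log2fc = (mean(a) - mean(b)) / log10(2),
                            p = p, stringsAsFactors = FALSE)
  }
  if (dropped > 0)
    message(dropped, " drug(s) dropped (undefined IC50 in > 50% of lines)")
  if (length(rows) == 0) stop("no testable drug")
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$fdr <- stats::p.adjust(out$p, "BH")
  out$msn_sensitive <- out$log2fc < 0 & out$p < alpha
  attr(out, "groups") <- grp
  out
}

#' Restrict screen hits to blood-brain-barrier-penetrant drugs
#'
#' @param table Screen table from [differential_ic50_screen()].
#' @param bbb_flags Named logical per drug; must cover every drug in the
#'   table.
#' @return Subset of `table` with `msn_sensitive` and `bbb` both true.
#' @export
filter_bbb <- function(table, bbb_flags) {
  if (!all(table$drug %in% names(bbb_flags)))
    stop("missing BBB flag for some drugs")
  table$bbb <- unname(bbb_flags[table$drug])
  table[table$msn_sensitive & table$bbb, , drop = FALSE]
}

#' ZIP synergy scores for a two-agent dose-response matrix
#'
#' Log-logistic curves are fitted to both monotherapy margins (inhibition
#' as fractions); the zero-interaction-potency expectation at doses (a, b)
#' is y_A + y_B - y_A * y_B. With the default `method = "conditional"`
#' the observed side is smoothed as in full ZIP implementations: the
#' response along each positive-dose row (and column) is refitted with the
#' lower asymptote anchored at the fitted monotherapy level of that row
#' (column), the two directions are averaged, and delta = smoothed
#' combination fraction minus the ZIP expectation, in percentage points.
#' Anchoring the conditional fits at the same fitted margins that enter
#' the expectation cancels most margin-fit noise, which keeps the null
#' calibration tight. `method = "simple"` skips the smoothing and uses
#' the raw observed fractions. Delta is defined over strictly positive
#' dose pairs; the summary score is the arithmetic mean delta.
#'
#' @param dm A [dose_matrix()].
#' @param method `"conditional"` (full-ZIP-style smoothing, default) or
#'   `"simple"` (raw observations against margin-fitted expectations).
#' @return A `synergy_result` list: `delta` (matrix over positive dose
#'   pairs), `summary`, `fit_a`, `fit_b`, `flagged`.
#' @export
zip_delta <- function(dm, method = c("conditional", "simple")) {
  method <- match.arg(method)
  da <- dm$doses_a; db <- dm$doses_b
  if (length(da) < 3 || length(db) < 3)
    stop("need >= 3 doses on each monotherapy margin")
  obs <- dm$inhibition / 100
  fa <- fit_loglogistic(da, obs[, 1] * 100, upper_max = 100)
  fb <- fit_loglogistic(db, obs[1, ] * 100, upper_max = 100)
  flagged <- !isTRUE(fa$converged) || !isTRUE(fb$converged)
  ya <- predict_inhibition(fa, da) / 100
  yb <- predict_inhibition(fb, db) / 100
  expectation <- outer(ya, yb, function(a, b) a + b - a * b)
  response <- obs
  if (method == "conditional") {
    # smooth each direction with a conditional fit anchored at the fitted
    # monotherapy level, then average the two directions (full-ZIP style)
    resp_rows <- obs
    for (i in which(da > 0)) {
      fr <- tryCatch(fit_loglogistic(db, obs[i, ] * 100,
                                     lower_fixed = ya[i] * 100),
                     error = function(e) NULL)
      if (!is.null(fr) && fr$converged)
        resp_rows[i, ] <- predict_inhibition(fr, db) / 100
    }
    resp_cols <- obs
    for (j in which(db > 0)) {
      fc <- tryCatch(fit_loglogistic(da, obs[, j] * 100,
                                     lower_fixed = yb[j] * 100),
                     error = function(e) NULL)
      if (!is.null(fc) && fc$converged)
        resp_cols[, j] <- predict_inhibition(fc, da) / 100
    }
    response <- (resp_rows + resp_cols) / 2
  }
  pa <- da > 0; pb <- db > 0
  delta <- (response - expectation)[pa, pb, drop = FALSE] * 100
  dimnames(delta) <- list(format(da[pa], trim = TRUE),
                          format(db[pb], trim = TRUE))
  structure(list(delta = delta, summary = mean(delta),
                 fit_a = fa, fit_b = fb, flagged = flagged,
                 doses_a = da[pa], doses_b = db[pb]),
            class = "synergy_result")
}

#' Select the optimal dose combination from a synergy result
#'
#' Among positive-dose combinations whose observed inhibition meets
#' `min_inhibition`, picks the maximal delta; ties are broken by lower
#' partner-agent (B) dose, then lower primary (A) dose. If no combination
#' meets the constraint the best available is returned with a warning.
#'
#' @param result A `synergy_result`.
#' @param dm The [dose_matrix()] the result came from.
#' @param min_inhibition Minimum observed inhibition %, default 50.
#' @return List with `dose_a`, `dose_b`, `delta`, `inhibition`, `rule`,
#'   `constrained`.
#' @export
select_optimal_combo <- function(result, dm, min_inhibition = 50) {
  da <- result$doses_a; db <- result$doses_b
  inh <- dm$inhibition[match(da, dm$doses_a), match(db, dm$doses_b),
                       drop = FALSE]
  cand <- expand.grid(i = seq_along(da), j = seq_along(db))
  cand$delta <- result$delta[cbind(cand$i, cand$j)]
  cand$inhibition <- inh[cbind(cand$i, cand$j)]
  ok <- cand$inhibition >= min_inhibition
  constrained <- any(ok)
  if (!constrained) {
    warning("no combination reaches ", min_inhibition,
            "% inhibition; returning best available")
    ok <- rep(TRUE, nrow(cand))
  }
  sel <- cand[ok, , drop = FALSE]
  sel <- sel[order(-sel$delta, db[sel$j], da[sel$i]), , drop = FALSE]
  top <- sel[1, ]
  list(dose_a = da[top$i], dose_b = db[top$j], delta = top$delta,
       inhibition = top$inhibition,
       rule = "max delta s.t. inhibition >= min; ties: lower B dose, then lower A dose",
       constrained = constrained)
}
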