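# Assay-level statistics: limiting-dilution (single-hit Poisson) frequency
# estimation and comparison, the immunohistochemistry H-score,
# multiplex-marker subtype calling, Kaplan-Meier / log-rank survival
# comparison, and relative-signal normalization.

#' Estimate active-cell frequency from a limiting-dilution assay
#'
#' Single-hit model: P(well responds | x cells) = 1 - exp(-f * x). The
#' frequency f is estimated by a binomial GLM with complementary log-log
#' link and offset log(x); dose-0 rows are consistency-checked (they must
#' have 0 responders) and excluded. The 95% CI is Wald on log f by default
#' (profile likelihood optional). All-negative or all-positive tables
#' return a one-sided bound with a boundary flag.
#'
#' @param table `data.frame(cells_per_well, wells_tested,
#'   wells_responding)`.
#' @param conf Confidence level (default 0.95).
#' @param ci `"wald"` or `"profile"`.
#' @return A `frequency_estimate` list: `f_hat`, `lower`, `upper`,
#'   `loglik`, `boundary`.
#' @export
elda_fit <- function(table, conf = 0.95, ci = c("wald", "profile")) {
  ci <- match.arg(ci)
  if (nrow(table) == 0) stop("empty dilution table")
  if (any(table$wells_responding > table$wells_tested) ||
      any(table$wells_responding < 0))
    stop("wells_responding must lie in [0, wells_tested]")
  zero <- table$cells_per_well == 0
  if (any(table$wells_responding[zero] > 0))
    stop("dose-0 wells must have 0 responders")
  tab <- table[!zero, , drop = FALSE]
  if (nrow(tab) == 0) stop("need >= 1 row with cells_per_well > 0")
  x <- tab$cells_per_well
  n <- tab$wells_tested
  r <- tab$wells_responding
  alpha <- 1 - conf
  if (all(r == 0)) {
    # no responses anywhere: MLE at the f = 0 boundary; one-sided upper
    # bound from P(all wells negative | f) = alpha
    upper <- -log(alpha) / sum(n * x)
    return(structure(list(f_hat = 0, lower = 0, upper = upper,
                          loglik = 0, boundary = TRUE),
                     class = "frequency_estimate"))
  }
  if (all(r == n)) {
    # every well responded: MLE diverges; one-sided lower bound from
    # P(all wells respond | f) = alpha
    ll_all <- function(f) sum(n * log(pmax(1 - exp(-f * x), 1e-300)))
    lower <- stats::uniroot(function(f) ll_all(f) - log(alpha),
                            c(1e-8, 50), tol = 1e-10)$root
    return(structure(list(f_hat = 1, lower = min(lower, 1), upper = 1,
                          loglik = 0, boundary = TRUE),
                     class = "frequency_estimate"))
  }
  # saturated high-dose rows routinely trip the fitted-probability warning
  fit <- suppressWarnings(
    stats::glm(cbind(r, n - r) ~ 1 + offset(log(x)),
               family = stats::binomial(link = "cloglog")))
  b0 <- stats::coef(fit)[[1]]
  f_hat <- exp(b0)
  z <- stats::qnorm(1 - alpha / 2)
  if (ci == "wald") {
    se <- sqrt(stats::vcov(fit)[1, 1])
    lo <- exp(b0 - z * se); hi <- exp(b0 + z * se)
  } else {
    prof <- suppressMessages(stats::confint(fit, level = conf))
    lo <- exp(prof[[1]]); hi <- exp(prof[[2]])
  }
  # a frequency is a per-cell probability: cap the rate-scale MLE at 1
  boundary <- f_hat > 1
  structure(list(f_hat = min(f_hat, 1), lower = min(lo, 1),
                 upper = min(hi, 1),
                 loglik = as.numeric(stats::logLik(fit)),
                 boundary = boundary),
            class = "frequency_estimate")
}

# Single-hit binomial log-likelihood at frequency f for a dilution table
# (positive-dose rows).
single_hit_loglik <- function(f, x, n, r) {
  p <- clamp(1 - exp(-f * x), 1e-12, 1 - 1e-12)
  sum(r * log(p) + (n - r) * log(1 - p))
}

#' Compare two limiting-dilution assays by likelihood ratio
#'
#' Tests a shared single-hit frequency against group-specific frequencies
#' (1 df). The statistic is symmetric in the two tables.
#'
#' @param a,b Dilution tables (see [elda_fit()]).
#' @return List with `chisq`, `p`, `f_a`, `f_b`, `f_pooled`.
#' @export
elda_compare <- function(a, b) {
  fits <- lapply(list(a, b), elda_fit)
  if (any(vapply(fits, function(f) f$boundary, logical(1))))
    stop("degenerate (boundary) dilution table; cannot compare")
  prep <- function(tab) tab[tab$cells_per_well > 0, , drop = FALSE]
  pa <- prep(a); pb <- prep(b)
  ll <- function(f, tab) single_hit_loglik(f, tab$cells_per_well,
                                           tab$wells_tested,
                                           tab$wells_responding)
  ll_sep <- ll(fits[[1]]$f_hat, pa) + ll(fits[[2]]$f_hat, pb)
  opt <- stats::optimize(function(f) ll(f, pa) + ll(f, pb),
                         c(1e-8, 1), maximum = TRUE, tol = 1e-10)
  chisq <- max(0, 2 * (ll_sep - opt$objective))
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       f_a = fits[[1]]$f_hat, f_b = fits[[2]]$f_hat,
       f_pooled = opt$maximum)
}

#' Immunohistochemistry H-score
#'
#' H-score = 100 * p_weak + 200 * p_moderate + 300 * p_strong, where the
#' p's are area fractions of weak/moderate/strong staining intensity
#' (negative area carries weight 0). Bounded in [0, 300].
#'
#' @param weak,moderate,strong Area fractions in [0, 1] (vectorized).
#' @param negative Negative-area fraction; defaults to the complement.
#' @return Numeric H-score(s).
#' @export
h_score <- function(weak, moderate, strong, negative = NULL) {
  negative <- negative %||% (1 - (weak + moderate + strong))
  comp <- cbind(weak, moderate, strong, negative)
  if (any(comp < -1e-9 | comp > 1 + 1e-9))
    stop("area fractions must lie in [0, 1]")
  if (any(abs(rowSums(comp) - 1) > 1e-9))
    stop("area fractions must sum to 1")
  as.numeric(100 * weak + 200 * moderate + 300 * strong)
}

#' Call MES or PN subtype from multiplex marker values
#'
#' Each marker is z-scored across samples; a sample is mesenchymal (MES)
#' iff the mean z of the MES markers (CD44, YKL40) strictly exceeds the
#' mean z of the proneural markers (SOX2, OLIG2), else proneural (PN).
#' Exact ties go to PN and are flagged.
#'
#' @param markers `data.frame`/matrix, samples x markers, with columns
#'   `CD44`, `YKL40`, `SOX2`, `OLIG2`.
#' @param mes_markers,pn_markers Column names per axis.
#' @return `data.frame(sample, subtype, margin, tie)`.
#' @export
call_subtype <- function(markers, mes_markers = c("CD44", "YKL40"),
                         pn_markers = c("SOX2", "OLIG2")) {
  markers <- as.data.frame(markers)
  need <- c(mes_markers, pn_markers)
  if (!all(need %in% names(markers)))
    stop("missing marker column(s): ",
         paste(setdiff(need, names(markers)), collapse = ", "))
  z <- vapply(need, function(m) {
    v <- markers[[m]]
    s <- stats::sd(v)
    if (s == 0) stop("zero-variance marker: ", m)
    (v - mean(v)) / s
  }, numeric(nrow(markers)))
  mes_z <- rowMeans(z[, mes_markers, drop = FALSE])
  pn_z <- rowMeans(z[, pn_markers, drop = FALSE])
  margin <- mes_z - pn_z
  data.frame(sample = rownames(markers) %||% seq_len(nrow(markers)),
             subtype = ifelse(margin > 0, "MES", "PN"),
             margin = margin, tie = margin == 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Kaplan-Meier curves and log-rank test for two groups
#'
#' Product-limit survival estimates per group and the standard log-rank
#' chi-square (1 df) with simultaneous risk-set handling of tied event
#' times.
#'
#' @param times Survival/follow-up times.
#' @param events Event indicator (1 = event/death, 0 = censored).
#' @param groups Two-level group labels.
#' @return A `survival_comparison` list: `fit` (a
#'   [survival::survfit] object), `chisq`, `p`.
#' @export
km_logrank <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("need exactly two groups")
  if (any(tapply(events, groups, sum) < 1))
    stop("each group needs >= 1 event")
  surv <- survival::Surv(times, events)
  fit <- survival::survfit(surv ~ groups)
  sd <- survival::survdiff(surv ~ groups, rho = 0)
  chisq <- sd$chisq
  structure(list(fit = fit, chisq = chisq,
                 p = stats::pchisq(chisq, df = 1, lower.tail = FALSE)),
            class = "survival_comparison")
}

#' Normalize a signal series to its first measurement
#'
#' @param series Ordered positive measurements; the first value must be
#'   > 0.
#' @return `series / series[1]` (first element 1).
#' @export
relative_signal <- function(series) {
  if (length(series) == 0) stop("empty series")
  if (series[1] <= 0) stop("first measurement must be positive")
  series / series[1]
}
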