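# Derivation of the chemoradiotherapy-resistance signature: survival and
# apoptosis stratification, differential expression with volcano filtering,
# signature intersection, driver-gene correlation, and preranked
# enrichment.

#' Stratify a cohort into resistant and sensitive groups by survival
#'
#' Restricts the cohort to deceased, chemoradiotherapy-treated samples and
#' splits them at a survival-time cutoff (median by default). Shorter
#' survival under full treatment is read as therapy resistance, so
#' `resistant` = survival strictly below the cutoff and `sensitive` =
#' survival at or above it (ties go to sensitive for determinism).
#'
#' @param cohort `data.frame` with columns `sample`, `survival_time`,
#'   `vital_status`, `therapy`.
#' @param rule `"median"` or `"quantile"`.
#' @param q Quantile for `rule = "quantile"`.
#' @return The restricted cohort with a `group` column; counts attached as
#'   attributes `n_restricted`, `n_resistant`, `n_sensitive`, `cutoff`.
#' @export
stratify_by_survival <- function(cohort, rule = c("median", "quantile"),
                                 q = 0.5) {
  rule <- match.arg(rule)
  if (rule == "median") q <- 0.5
  keep <- cohort$vital_status == "dead" &
    cohort$therapy == "chemoradiotherapy"
  sub <- cohort[keep, , drop = FALSE]
  if (nrow(sub) < 2)
    stop("fewer than 2 dead, chemoradiotherapy-treated samples")
  if (length(unique(sub$survival_time)) == 1)
    stop("all survival times identical: degenerate cutoff")
  cutoff <- stats::quantile(sub$survival_time, q, names = FALSE)
  sub$group <- ifelse(sub$survival_time < cutoff, "resistant", "sensitive")
  message(sprintf(
    "survival stratification: %d/%d samples retained; cutoff %.3g; %d resistant, %d sensitive",
    nrow(sub), nrow(cohort), cutoff, sum(sub$group == "resistant"),
    sum(sub$group == "sensitive")))
  attr(sub, "cutoff") <- cutoff
  attr(sub, "n_restricted") <- nrow(sub)
  attr(sub, "n_resistant") <- sum(sub$group == "resistant")
  attr(sub, "n_sensitive") <- sum(sub$group == "sensitive")
  sub
}

#' Label cell lines resistant or sensitive by treatment-induced apoptosis
#'
#' A line is called resistant when no treated condition shows a significant
#' apoptosis increase over its own control (two-sided two-sample t-test at
#' `alpha`, requiring an increase in means), and sensitive otherwise.
#'
#' @param apoptosis `data.frame(line, condition, replicate, fraction)` with
#'   a `control` condition and >= 1 treated condition, >= 2 replicates each.
#' @param alpha Significance level (default 0.05).
#' @return `data.frame(line, label, p_min)` plus one p-value column per
#'   treated condition.
#' @export
stratify_by_apoptosis <- function(apoptosis, alpha = 0.05) {
  lines <- unique(apoptosis$line)
  conds <- setdiff(unique(apoptosis$condition), "control")
  if (length(conds) == 0) stop("no treated condition present")
  out <- lapply(lines, function(ln) {
    d <- apoptosis[apoptosis$line == ln, , drop = FALSE]
    ctrl <- d$fraction[d$condition == "control"]
    if (length(ctrl) == 0) stop("missing control condition for line ", ln)
    if (length(ctrl) < 2) stop("need >= 2 control replicates for line ", ln)
    ps <- vapply(conds, function(cc) {
      trt <- d$fraction[d$condition == cc]
      if (length(trt) < 2)
        stop("need >= 2 replicates of ", cc, " for line ", ln)
      if (stats::sd(trt) == 0 && stats::sd(ctrl) == 0) {
        # identical constant replicates carry no evidence of change
        return(if (mean(trt) == mean(ctrl)) 1 else 0)
      }
      stats::t.test(trt, ctrl)$p.value
    }, numeric(1))
    means <- vapply(conds, function(cc)
      mean(d$fraction[d$condition == cc]), numeric(1))
    increased <- ps < alpha & means > mean(ctrl)
    c(list(line = ln,
           label = if (any(increased)) "sensitive" else "resistant"),
      as.list(stats::setNames(ps, paste0("p_", conds))))
  })
  res <- do.call(rbind, lapply(out, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  pcols <- grep("^p_", names(res), value = TRUE)
  res$p_min <- do.call(pmin, res[pcols])
  res
}

# Vectorized Welch two-sample t-test across matrix rows.
row_welch <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(mean1 = m1, mean2 = m2, t = t, df = df, p = p)
}

#' Differential expression between resistant and sensitive groups
#'
#' Expression is expected on log2 scale; log2 fold change is
#' mean(resistant) - mean(sensitive). P-values come from a per-gene Welch
#' t-test (default) or from a variance-moderated t-test with
#' empirical-Bayes shrinkage of gene variances toward a pooled prior; FDR
#' is Benjamini-Hochberg over all tested genes. Genes with zero variance in
#' both groups are dropped (and counted in attribute `n_dropped`).
#'
#' @param expr Genes x samples log2 matrix.
#' @param labels Character/factor of `"resistant"`/`"sensitive"` per
#'   sample, or named by sample id.
#' @param method `"welch"` or `"moderated"`.
#' @return `data.frame(gene, mean_resistant, mean_sensitive, log2fc, p,
#'   fdr)`.
#' @export
differential_expression <- function(expr, labels,
                                    method = c("welch", "moderated")) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  if (!is.null(names(labels))) {
    if (!all(colnames(expr) %in% names(labels)))
      stop("labels do not cover all samples")
    labels <- labels[colnames(expr)]
  }
  if (length(labels) != ncol(expr))
    stop("label/sample mismatch: ", length(labels), " labels for ",
         ncol(expr), " samples")
  labels <- as.character(labels)
  keep <- labels %in% c("resistant", "sensitive")
  expr <- expr[, keep, drop = FALSE]
  labels <- labels[keep]
  res <- labels == "resistant"
  if (sum(res) < 2 || sum(!res) < 2)
    stop("need >= 2 samples per group")
  x1 <- expr[, res, drop = FALSE]
  x2 <- expr[, !res, drop = FALSE]
  v1 <- apply(x1, 1, stats::var)
  v2 <- apply(x2, 1, stats::var)
  flat <- v1 == 0 & v2 == 0
  if (any(flat)) {
    message(sum(flat), " zero-variance gene(s) dropped")
    x1 <- x1[!flat, , drop = FALSE]
    x2 <- x2[!flat, , drop = FALSE]
  }
  if (method == "welch") {
    w <- row_welch(x1, x2)
    p <- w$p
    m1 <- w$mean1; m2 <- w$mean2
  } else {
    mat <- cbind(x1, x2)
    grp <- factor(rep(c("resistant", "sensitive"), c(ncol(x1), ncol(x2))),
                  levels = c("sensitive", "resistant"))
    fit <- limma::eBayes(limma::lmFit(mat, stats::model.matrix(~grp)))
    p <- fit$p.value[, 2]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  }
  out <- data.frame(gene = rownames(x1), mean_resistant = m1,
                    mean_sensitive = m2, log2fc = m1 - m2, p = p,
                    fdr = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_dropped") <- sum(flat)
  attr(out, "method") <- method
  out
}

#' Construct a gene signature
#' @param gene Character vector of gene ids (unique, non-empty).
#' @param direction `"resistant-up"` or `"sensitive-up"` per gene.
#' @param label Provenance label.
#' @return `data.frame(gene, direction)` of class `gene_signature`.
#' @export
gene_signature <- function(gene, direction, label = "signature") {
  if (length(gene) > 0 && anyDuplicated(gene))
    stop("duplicate gene ids in signature")
  stopifnot(all(direction %in% c("resistant-up", "sensitive-up")))
  structure(data.frame(gene = gene, direction = rep(direction,
                                                    length.out = length(gene)),
                       stringsAsFactors = FALSE),
            label = label, class = c("gene_signature", "data.frame"))
}

#' Volcano filtering of a differential-expression table
#'
#' Keeps genes passing inclusive thresholds on effect size and raw
#' p-value: `log2fc >= lfc_min` for resistant-up genes, `log2fc <=
#' -lfc_min` for sensitive-up genes, with `p <= p_max` in both cases.
#'
#' @param de A differential-expression table from
#'   [differential_expression()].
#' @param lfc_min Minimum |log2 fold change| (default 0.5).
#' @param p_max Maximum raw p-value (default 0.05; use `1e-10` for a
#'   stringent -log10 p > 10 style cut).
#' @param direction `"resistant-up"`, `"sensitive-up"`, or `"both"`.
#' @param label Provenance label for the signature.
#' @return A [gene_signature()].
#' @export
volcano_filter <- function(de, lfc_min = 0.5, p_max = 0.05,
                           direction = c("resistant-up", "sensitive-up",
                                         "both"),
                           label = "volcano") {
  direction <- match.arg(direction)
  if (lfc_min < 0 || p_max < 0) stop("thresholds must be positive")
  up <- de$log2fc >= lfc_min & de$p <= p_max
  down <- de$log2fc <= -lfc_min & de$p <= p_max
  pick <- switch(direction,
                 "resistant-up" = up,
                 "sensitive-up" = down,
                 "both" = up | down)
  dirs <- ifelse(de$log2fc >= 0, "resistant-up", "sensitive-up")[pick]
  message(sprintf("volcano filter: %d/%d genes pass (lfc >= %.3g, p <= %.3g)",
                  sum(pick), nrow(de), lfc_min, p_max))
  gene_signature(de$gene[pick], dirs, label = label)
}

#' Intersect two gene signatures
#'
#' Set intersection on gene ids requiring agreeing direction; genes present
#' in both with conflicting direction are dropped with a message. An empty
#' result triggers a warning, not an error.
#'
#' @param a,b [gene_signature()] objects in the same gene-id namespace.
#' @return A [gene_signature()].
#' @export
intersect_signatures <- function(a, b) {
  m <- merge(as.data.frame(a), as.data.frame(b), by = "gene",
             suffixes = c("_a", "_b"))
  agree <- m$direction_a == m$direction_b
  if (any(!agree))
    message(sum(!agree), " shared gene(s) dropped for direction disagreement")
  out <- gene_signature(m$gene[agree], m$direction_a[agree],
                        label = paste(attr(a, "label"), "&", attr(b, "label")))
  if (nrow(out) == 0) warning("signature intersection is empty")
  out
}

#' Correlate a driver gene with a gene set
#'
#' Two-sided Pearson correlation of one gene's expression against each gene
#' of a set across samples.
#'
#' @param expr Genes x samples matrix.
#' @param gene Driver gene id (must have non-zero variance).
#' @param geneset Character vector of gene ids to correlate against.
#' @return `data.frame(gene, r, p)`; set members absent from the matrix or
#'   with zero variance yield `NA` with a message.
#' @export
correlate_gene <- function(expr, gene, geneset) {
  expr <- as.matrix(expr)
  if (!gene %in% rownames(expr)) stop("gene not in matrix: ", gene)
  if (ncol(expr) < 3) stop("need >= 3 samples")
  x <- expr[gene, ]
  if (stats::sd(x) == 0) stop("zero-variance driver gene")
  res <- lapply(geneset, function(g) {
    if (!g %in% rownames(expr) || stats::sd(expr[g, ]) == 0)
      return(data.frame(gene = g, r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x, expr[g, ], method = "pearson")
    data.frame(gene = g, r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  if (anyNA(out$r))
    message(sum(is.na(out$r)), " gene(s) missing or constant: r = NA")
  rownames(out) <- NULL
  out
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score (weight |stat|).
gsea_es <- function(stats_sorted_abs, hit) {
  wsum <- sum(stats_sorted_abs[hit])
  phit <- if (wsum > 0) cumsum(ifelse(hit, stats_sorted_abs, 0)) / wsum
          else cumsum(hit) / sum(hit)
  pmiss <- cumsum(!hit) / sum(!hit)
  dev <- phit - pmiss
  dev[which.max(abs(dev))]
}

#' Preranked gene-set enrichment with permutation p-value
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic (weights = |ranking
#' stat|) over genes sorted by the ranking metric, with a one-sided
#' permutation p-value from `n_perm` random gene sets of the same size.
#'
#' @param ranked_stats Named numeric vector of finite ranking statistics
#'   over the gene universe.
#' @param geneset Character vector; must intersect the universe.
#' @param n_perm Number of permutations (> 0).
#' @param seed Integer seed for the permutations.
#' @return List with `es`, `p`, `n_hits`, `n_perm`.
#' @export
preranked_enrichment <- function(ranked_stats, geneset, n_perm = 1000,
                                 seed = 1) {
  if (n_perm <= 0) stop("n_perm must be positive")
  if (any(!is.finite(ranked_stats))) stop("ranking statistics must be finite")
  genes <- names(ranked_stats)
  hits <- genes %in% geneset
  if (!any(hits)) stop("geneset does not intersect the gene universe")
  if (all(hits)) stop("geneset covers the whole universe")
  ord <- order(ranked_stats, decreasing = TRUE)
  s <- abs(ranked_stats[ord])
  hit <- hits[ord]
  es <- gsea_es(s, hit)
  k <- sum(hit)
  n <- length(genes)
  perm <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      h <- logical(n)
      h[sample.int(n, k)] <- TRUE
      gsea_es(s, h)
    }, numeric(1))
  })
  # two-sided on the magnitude (the sign of ES is reported separately),
  # which keeps the permutation p uniform under a null ranking
  p <- (1 + sum(abs(perm) >= abs(es))) / (n_perm + 1)
  list(es = unname(es), p = p, n_hits = k, n_perm = n_perm)
}
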