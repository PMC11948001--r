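# Subcluster-level scoring and classification: per-cluster driver
# expression, the mean +/- SEM high/low grouping, signature enrichment
# scores, group intersection, and one-vs-rest marker detection.

#' Per-cluster mean expression of one gene
#'
#' @param expr Genes x cells log-normalized matrix.
#' @param clusters Cluster id per cell (same order as columns, or named by
#'   cell).
#' @param gene Gene id.
#' @return Named numeric vector of per-cluster arithmetic means.
#' @export
cluster_mean_expression <- function(expr, clusters, gene) {
  expr <- as.matrix(expr)
  if (!gene %in% rownames(expr)) stop("unknown gene: ", gene)
  clusters <- align_clusters(clusters, colnames(expr))
  tapply(expr[gene, ], clusters, mean)
}

align_clusters <- function(clusters, cells) {
  if (!is.null(names(clusters))) {
    if (!all(cells %in% names(clusters)))
      stop("cluster labels do not cover all cells")
    clusters <- clusters[cells]
  }
  if (length(clusters) != length(cells))
    stop("cluster labels do not match cell count")
  as.character(clusters)
}

#' Classify values as high, low, or intermediate by mean +/- SEM
#'
#' The mean and SEM (sample SD / sqrt(k)) are computed across the k input
#' values; `high` means strictly above mean + SEM, `low` strictly below
#' mean - SEM, everything else (including boundary values) is
#' `intermediate`.
#'
#' @param values Numeric vector (k >= 2), optionally named.
#' @return Character vector of `"high"`/`"low"`/`"intermediate"` with
#'   attributes `mean` and `sem`.
#' @export
mean_sem_grouping <- function(values) {
  k <- length(values)
  if (k < 2) stop("need >= 2 values (SEM undefined)")
  m <- mean(values)
  sem <- stats::sd(values) / sqrt(k)
  out <- ifelse(values > m + sem, "high",
                ifelse(values < m - sem, "low", "intermediate"))
  names(out) <- names(values)
  attr(out, "mean") <- m
  attr(out, "sem") <- sem
  out
}

#' Score clusters for enrichment of a gene signature
#'
#' Default method `"meanz"`: z-score each signature gene across all cells,
#' average the z-scores per cell, then average within cluster. Method
#' `"preranked"` instead ranks all genes by their cluster-mean z-score
#' (z across clusters) and reports the weighted KS enrichment score of the
#' signature in each cluster's ranking.
#'
#' @param expr Genes x cells log-normalized matrix.
#' @param clusters Cluster id per cell.
#' @param signature A [gene_signature()] or character vector of gene ids.
#' @param method `"meanz"` or `"preranked"`.
#' @return Named per-cluster numeric scores.
#' @export
signature_score_clusters <- function(expr, clusters, signature,
                                     method = c("meanz", "preranked")) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  genes <- if (inherits(signature, "gene_signature")) signature$gene
           else as.character(signature)
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0) stop("no signature gene present in matrix")
  if (length(present) < length(genes))
    message(length(genes) - length(present), " signature gene(s) missing")
  clusters <- align_clusters(clusters, colnames(expr))
  if (method == "meanz") {
    sub <- expr[present, , drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, stats::sd)
    sdv[sdv == 0] <- Inf  # constant genes contribute 0
    z <- (sub - mu) / sdv
    cell_score <- colMeans(z)
    tapply(cell_score, clusters, mean)
  } else {
    cl <- sort(unique(clusters))
    means <- vapply(cl, function(cc)
      rowMeans(expr[, clusters == cc, drop = FALSE]), numeric(nrow(expr)))
    mu <- rowMeans(means)
    sdv <- apply(means, 1, stats::sd)
    sdv[sdv == 0] <- Inf
    z <- (means - mu) / sdv
    scores <- vapply(cl, function(cc) {
      st <- z[, cc]
      ord <- order(st, decreasing = TRUE)
      gsea_es(abs(st[ord]), rownames(z)[ord] %in% present)
    }, numeric(1))
    stats::setNames(scores, cl)
  }
}

#' Intersect driver-expression and resistance-signature groupings
#'
#' @param msn_groups Named `"high"`/`"low"`/`"intermediate"` per cluster
#'   (driver-expression axis).
#' @param resist_groups Same, for the resistance-signature axis (here
#'   `"high"` reads as resistant, `"low"` as sensitive).
#' @param grades Optional named grade label per cluster for the
#'   composition table.
#' @return List with `high_msn_resistant`, `low_msn_sensitive`, `other`
#'   (cluster id vectors) and `composition` (grade x set counts, or NULL).
#' @export
intersect_groups <- function(msn_groups, resist_groups, grades = NULL) {
  u <- sort(names(msn_groups))
  if (!identical(u, sort(names(resist_groups))))
    stop("cluster universes differ between the two groupings")
  dbl_pos <- u[msn_groups[u] == "high" & resist_groups[u] == "high"]
  dbl_neg <- u[msn_groups[u] == "low" & resist_groups[u] == "low"]
  other <- setdiff(u, c(dbl_pos, dbl_neg))
  if (length(dbl_pos) == 0)
    warning("no cluster is both driver-high and signature-resistant")
  composition <- NULL
  if (!is.null(grades)) {
    set <- ifelse(u %in% dbl_pos, "high_msn_resistant",
                  ifelse(u %in% dbl_neg, "low_msn_sensitive", "other"))
    composition <- as.data.frame(table(grade = grades[u], set = set),
                                 stringsAsFactors = FALSE)
  }
  list(high_msn_resistant = dbl_pos, low_msn_sensitive = dbl_neg,
       other = other, composition = composition)
}

#' One-vs-rest cluster marker detection
#'
#' For each cluster with >= 3 cells, compares in-cluster against all other
#' cells: keeps positive markers only, expressed in at least `min_frac` of
#' in-cluster cells with log2 fold change >= `lfc_min`; p-values from the
#' Wilcoxon rank-sum test, BH-adjusted within cluster.
#'
#' @param expr Genes x cells log2-normalized matrix.
#' @param clusters Cluster id per cell.
#' @param min_frac Minimum in-cluster detection fraction (default 0.25).
#' @param lfc_min Minimum log2 fold change (default 0.5).
#' @return `data.frame(cluster, gene, log2fc, fraction, p, fdr)`.
#' @export
find_markers <- function(expr, clusters, min_frac = 0.25, lfc_min = 0.5) {
  expr <- as.matrix(expr)
  clusters <- align_clusters(clusters, colnames(expr))
  cl <- sort(unique(clusters))
  if (length(cl) < 2) stop("need >= 2 clusters")
  out <- list()
  for (cc in cl) {
    inn <- clusters == cc
    if (sum(inn) < 3) {
      message("cluster ", cc, " has < 3 cells; skipped")
      next
    }
    m_in <- rowMeans(expr[, inn, drop = FALSE])
    m_out <- rowMeans(expr[, !inn, drop = FALSE])
    frac <- rowMeans(expr[, inn, drop = FALSE] > 0)
    lfc <- m_in - m_out
    keep <- which(frac >= min_frac & lfc >= lfc_min)
    if (length(keep) == 0) next
    p <- vapply(keep, function(g)
      stats::wilcox.test(expr[g, inn], expr[g, !inn],
                         alternative = "greater", exact = FALSE)$p.value,
      numeric(1))
    out[[cc]] <- data.frame(cluster = cc, gene = rownames(expr)[keep],
                            log2fc = lfc[keep], fraction = frac[keep],
                            p = p, fdr = stats::p.adjust(p, "BH"),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  if (length(out) == 0)
    return(data.frame(cluster = character(), gene = character(),
                      log2fc = numeric(), fraction = numeric(),
                      p = numeric(), fdr = numeric()))
  do.call(rbind, c(out, make.row.names = FALSE))
}
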