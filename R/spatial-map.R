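# Projection of single-cell subcluster identities onto spatial
# transcriptomics clusters. Prediction scores are computed as a
# non-negative least-squares mixture of subcluster centroids over shared
# highly-variable genes, row-normalized to sum to 1, followed by
# anatomical-region enrichment of subcluster groups.

#' Select shared highly-variable genes
#'
#' Ranks genes by dispersion (variance / mean) in the single-cell matrix,
#' restricted to genes present in both datasets; ties are broken by gene id
#' for determinism.
#'
#' @param sc_expr Genes x cells single-cell matrix.
#' @param spatial_expr Genes x spots spatial matrix.
#' @param n_top Number of genes to keep (default 2000; truncated with a
#'   warning when the overlap is smaller).
#' @return Character vector of gene ids.
#' @export
select_shared_hvgs <- function(sc_expr, spatial_expr, n_top = 2000) {
  shared <- intersect(rownames(sc_expr), rownames(spatial_expr))
  if (length(shared) < 50)
    stop("gene-namespace overlap < 50 genes (", length(shared), ")")
  x <- as.matrix(sc_expr)[shared, , drop = FALSE]
  mu <- rowMeans(x)
  v <- apply(x, 1, stats::var)
  disp <- v / pmax(mu, .Machine$double.eps)
  ord <- shared[order(-disp, shared)]
  if (n_top > length(ord)) {
    warning("n_top exceeds overlap; returning all ", length(ord), " genes")
    n_top <- length(ord)
  }
  ord[seq_len(n_top)]
}

#' Prediction scores between spatial clusters and single-cell subclusters
#'
#' Each spatial cluster's centroid (z-scored per gene with single-cell
#' statistics) is decomposed as a non-negative least-squares mixture of the
#' z-scored single-cell subcluster centroids on the shared genes; mixture
#' weights are normalized to sum to 1 per spatial cluster.
#'
#' @param sc_expr Genes x cells single-cell log-normalized matrix.
#' @param sc_clusters Subcluster id per cell.
#' @param spatial A `spatial_dataset` (list with `expr` genes x spots and
#'   `spots` data.frame carrying `spatial_cluster`).
#' @param genes Shared genes to use (e.g. from [select_shared_hvgs()]).
#' @return Matrix (spatial clusters x sc subclusters) of class
#'   `prediction_scores`; rows are non-negative and sum to 1.
#' @export
transfer_scores <- function(sc_expr, sc_clusters, spatial, genes) {
  sc_expr <- as.matrix(sc_expr)
  sc_clusters <- align_clusters(sc_clusters, colnames(sc_expr))
  genes <- intersect(genes, intersect(rownames(sc_expr),
                                      rownames(spatial$expr)))
  if (length(genes) == 0) stop("no shared genes")
  x <- sc_expr[genes, , drop = FALSE]
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  ok <- sdv > 0
  if (!any(ok)) stop("all shared genes constant in single-cell data")
  genes <- genes[ok]; x <- x[ok, , drop = FALSE]
  mu <- mu[ok]; sdv <- sdv[ok]

  cl <- sort(unique(sc_clusters))
  centroids <- vapply(cl, function(cc)
    (rowMeans(x[, sc_clusters == cc, drop = FALSE]) - mu) / sdv,
    numeric(length(genes)))

  sp_expr <- as.matrix(spatial$expr)[genes, , drop = FALSE]
  sp_cl <- spatial$spots$spatial_cluster
  scl <- sort(unique(sp_cl))
  scores <- matrix(0, length(scl), length(cl), dimnames = list(scl, cl))
  for (s in scl) {
    y <- (rowMeans(sp_expr[, sp_cl == s, drop = FALSE]) - mu) / sdv
    w <- tryCatch(pracma::lsqnonneg(centroids, y)$x,
                  error = function(e) stop("NNLS failed for spatial cluster ",
                                           s, ": ", conditionMessage(e)))
    scores[s, ] <- if (sum(w) > 0) w / sum(w) else rep(1 / length(cl),
                                                       length(cl))
  }
  structure(scores, class = c("prediction_scores", class(scores)))
}

#' Anatomical-region enrichment of subcluster groups
#'
#' For each spot, the group score is the summed prediction score of the
#' group's subclusters (taken from the spot's spatial-cluster row); per
#' region the mean spot score is z-normalized across regions.
#'
#' @param scores A `prediction_scores` matrix (spatial clusters x
#'   subclusters).
#' @param spatial A `spatial_dataset` whose `spots` carry `spatial_cluster`
#'   and `region`.
#' @param groups Named list of subcluster-id vectors (e.g.
#'   `list(resistant = ..., sensitive = ...)`).
#' @return `data.frame(group, region, mean_score, z)`; z is 0 when a
#'   group's spot scores are constant.
#' @export
region_enrichment <- function(scores, spatial, groups) {
  spots <- spatial$spots
  if (any(is.na(spots$region)) || is.null(spots$region))
    stop("every spot needs a region label")
  regions <- sort(unique(spots$region))
  if (length(regions) < 2)
    stop("z-normalization undefined with a single region")
  empty <- setdiff(regions, unique(spots$region))
  if (length(empty) > 0) stop("region with zero spots: ", empty[1])
  out <- list()
  for (g in names(groups)) {
    members <- intersect(groups[[g]], colnames(scores))
    if (length(members) == 0) stop("group ", g, " has no known subcluster")
    spot_score <- rowSums(scores[spots$spatial_cluster, members,
                                 drop = FALSE])
    m <- tapply(spot_score, spots$region, mean)[regions]
    sdv <- stats::sd(m)
    z <- if (is.na(sdv) || sdv == 0) rep(0, length(m)) else (m - mean(m)) / sdv
    out[[g]] <- data.frame(group = g, region = regions,
                           mean_score = as.numeric(m), z = as.numeric(z),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
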