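# Single-cell CNV inference from position-ordered expression: reference
# centering, within-chromosome moving-average smoothing, per-cell
# re-standardization with clipping to [-1, 1] and a noise filter, followed
# by the quadratic-summation CNV score and CNV+/- classification.

#' Log-normalize a count matrix
#'
#' Scales each cell to a fixed total count and applies log2(x + 1).
#'
#' @param counts Genes x cells count matrix.
#' @param target_total Per-cell total after scaling (default 1e4).
#' @return Genes x cells log2-normalized matrix.
#' @export
log_normalize <- function(counts, target_total = 1e4) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  log2(sweep(counts, 2, tot, "/") * target_total + 1)
}

# Centered moving average with truncated windows at block edges, via
# cumulative sums (O(n) per row).
running_mean <- function(x, w) {
  n <- length(x)
  half <- (w - 1) %/% 2
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Infer per-cell relative CNV profiles
#'
#' Pipeline: log-normalize counts; filter genes whose mean log-normalized
#' expression does not exceed `cutoff` (the default 0 keeps every expressed
#' gene); order genes by (chromosome, start); center each gene on its
#' reference-cell mean; smooth with a centered moving average of `window`
#' genes strictly within each chromosome; re-standardize each cell by
#' subtracting its median profile value; clip to `[-clip, clip]`; zero out
#' entries with magnitude below `noise_filter`.
#'
#' @param counts Genes x cells count matrix.
#' @param reference_cells Character vector of reference (non-tumor) cell
#'   ids; must be non-empty and leave at least one query cell.
#' @param positions Gene position table (`gene`, `chrom`, `start`, `end`);
#'   every expressed gene must have a position.
#' @param window Moving-average window in genes (default 101); shrunk with
#'   a warning if larger than the smallest chromosome.
#' @param noise_filter Zeroing threshold on |value| (default 0.2).
#' @param clip Clipping bound (default 1).
#' @param cutoff Mean-expression gene filter (default 0).
#' @return Cells x genes matrix of class `cnv_matrix` with attributes
#'   `window`, `noise_filter`, `clip`, `reference_cells`.
#' @export
infer_cnv_profile <- function(counts, reference_cells, positions,
                              window = 101, noise_filter = 0.2, clip = 1,
                              cutoff = 0) {
  counts <- as.matrix(counts)
  if (length(reference_cells) == 0) stop("empty reference cell set")
  if (!all(reference_cells %in% colnames(counts)))
    stop("reference cells missing from count matrix")
  if (length(setdiff(colnames(counts), reference_cells)) == 0)
    stop("no query cells outside the reference set")
  ln <- log_normalize(counts)
  keep <- rowMeans(ln) > cutoff
  if (any(!keep))
    message(sum(!keep), " gene(s) below expression cutoff removed")
  ln <- ln[keep, , drop = FALSE]
  missing <- setdiff(rownames(ln), positions$gene)
  if (length(missing) > 0)
    stop(length(missing), " expressed gene(s) lack positions, e.g. ",
         missing[1])
  pos <- positions[positions$gene %in% rownames(ln), , drop = FALSE]
  pos <- pos[order(chrom_order_key(pos$chrom), pos$start), , drop = FALSE]
  ln <- ln[pos$gene, , drop = FALSE]

  centered <- ln - rowMeans(ln[, reference_cells, drop = FALSE])

  chroms <- unique(pos$chrom)
  min_chrom <- min(table(pos$chrom))
  w <- window
  if (w > min_chrom) {
    w <- max(1, min_chrom - (min_chrom + 1) %% 2)  # largest odd <= min_chrom
    warning("window ", window, " exceeds smallest chromosome (",
            min_chrom, " genes); shrunk to ", w)
  }
  smoothed <- centered
  for (ch in chroms) {
    idx <- which(pos$chrom == ch)
    smoothed[idx, ] <- apply(centered[idx, , drop = FALSE], 2,
                             running_mean, w = w)
  }

  # per-cell re-standardization, then clip and noise-filter
  med <- apply(smoothed, 2, stats::median)
  out <- sweep(smoothed, 2, med, "-")
  out <- clamp(out, -clip, clip)
  out[abs(out) < noise_filter] <- 0

  out <- t(out)  # cells x genes
  structure(out, window = w, noise_filter = noise_filter, clip = clip,
            reference_cells = reference_cells,
            class = c("cnv_matrix", class(out)))
}

#' Quadratic-summation CNV score
#'
#' Per-cell score = sum over genes of the squared smoothed CNV value.
#'
#' @param profiles Cells x genes CNV matrix (e.g. from
#'   [infer_cnv_profile()]).
#' @return Named numeric vector of non-negative per-cell scores.
#' @export
cnv_score <- function(profiles) {
  rowSums(as.matrix(unclass(profiles))^2)
}

#' Classify cells as CNV+ or CNV- from their scores
#'
#' Default rule: CNV+ iff score strictly exceeds the 95th percentile of the
#' reference-cell scores; this requires a non-degenerate reference score
#' distribution. Alternative rule `"cluster2"` runs deterministic 1-D
#' 2-means (initialized at the score range) over all scores and calls the
#' higher-center component CNV+; it does not depend on the reference
#' spread, which matters when very clean reference profiles are zeroed
#' entirely by the noise filter.
#'
#' @param scores Named per-cell scores.
#' @param reference_scores Scores of the reference cells (non-degenerate
#'   for the percentile rule).
#' @param rule `"percentile"` or `"cluster2"`.
#' @param prob Reference percentile for the default rule (0.95).
#' @return `data.frame(cell, cnv_score, cnv_class)` with attributes `rule`
#'   and `threshold` (percentile rule only).
#' @export
classify_cnv <- function(scores, reference_scores,
                         rule = c("percentile", "cluster2"), prob = 0.95) {
  rule <- match.arg(rule)
  if (length(reference_scores) == 0) stop("empty reference scores")
  if (rule == "percentile") {
    if (length(unique(reference_scores)) == 1)
      stop("degenerate (constant) reference score distribution")
    thr <- stats::quantile(reference_scores, prob, names = FALSE)
    cls <- ifelse(scores > thr, "CNV+", "CNV-")
  } else {
    if (length(unique(scores)) == 1)
      stop("all scores identical; cannot split into two components")
    init <- matrix(range(scores), ncol = 1)
    km <- stats::kmeans(matrix(scores, ncol = 1), centers = init)
    hi <- which.max(km$centers)
    cls <- ifelse(km$cluster == hi, "CNV+", "CNV-")
    thr <- NA_real_
  }
  out <- data.frame(cell = names(scores) %||% seq_along(scores),
                    cnv_score = unname(scores), cnv_class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "rule") <- rule
  attr(out, "threshold") <- thr
  out
}
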