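# Synthetic-data generators with planted, recorded ground truth. Every
# downstream stage of the pipeline is exercised against these datasets, so
# each generator returns both the data and a truth record sufficient for
# recovery testing. All generators are bit-reproducible given (params, seed)
# and leave the caller's RNG state untouched.
#
# The generative families are surrogates chosen for desk-scale testing:
# log-normal bulk expression, Weibull/exponential survival, negative
# binomial single-cell counts, mixture-of-profiles spatial spots,
# Bliss-plus-offset dose grids, and single-hit Poisson dilution wells. None
# of them is a claim about the distribution of any real cohort.

#' Assemble a synthetic ground-truth record
#'
#' Collects every planted parameter used by the generators: the resistance
#' gene set with per-gene effect sizes (log2 units), the driver gene, CNV
#' segments, cluster profiles, spot mixtures, the planted Bliss deviation,
#' and stem-cell frequencies.
#'
#' @param n_genes Size of the gene universe (gene ids `g0001`...).
#' @param resistance_genes Named numeric vector of log2 effect sizes. The
#'   default plants 10 genes at +1.0 log2, the first being the driver.
#' @param driver_gene Id of the planted driver (default `"MSN"`, named after
#'   the moesin gene of the motivating biology; it is the first resistance
#'   gene).
#' @param cnv_segments `data.frame(chrom, start_idx, end_idx, gain_log2)`
#'   of contiguous gene-index blocks carrying copy-number shifts in tumor
#'   cells. Defaults to a chr7-style gain and a chr10-style loss of 150
#'   genes each at +/-0.58 log2 (1.5-fold), the classic glioblastoma
#'   arm-level lesions.
#' @param n_clusters Number of single-cell clusters (first is the non-tumor
#'   reference).
#' @param synergy_magnitude Planted Bliss deviation (inhibition fraction).
#' @param stem_frequency Named vector of per-group sphere-forming
#'   frequencies in (0, 1].
#' @param seed Integer seed recorded with the truth.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(n_genes = 1000,
                            resistance_genes = NULL,
                            driver_gene = "MSN",
                            cnv_segments = NULL,
                            n_clusters = 4,
                            synergy_magnitude = 0.2,
                            stem_frequency = c(control = 0.1, treated = 0.02),
                            seed = 1) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (is.null(resistance_genes)) {
    ids <- c(driver_gene, genes[seq_len(9)])
    resistance_genes <- stats::setNames(rep(1.0, 10), ids)
  }
  if (!all(is.finite(resistance_genes))) stop("effect sizes must be finite")
  if (any(stem_frequency <= 0 | stem_frequency > 1))
    stop("stem_frequency must lie in (0, 1]")
  if (is.null(cnv_segments)) {
    cnv_segments <- data.frame(
      chrom = c("chr7", "chr10"),
      start_idx = c(1, 151),
      end_idx = c(150, 300),
      gain_log2 = c(0.58, -0.58))
  }
  structure(list(
    genes = union(names(resistance_genes), genes),
    resistance_genes = resistance_genes,
    driver_gene = driver_gene,
    cnv_segments = cnv_segments,
    n_clusters = n_clusters,
    cluster_profiles = NULL,   # filled by gen_sc_dataset
    spot_mixtures = NULL,      # filled by gen_spatial_dataset
    synergy_magnitude = synergy_magnitude,
    stem_frequency = stem_frequency,
    seed = as.integer(seed)
  ), class = "synthetic_truth")
}

#' Generate a treated patient cohort with survival-linked expression
#'
#' Dead, chemoradiotherapy-treated samples are split into planted resistant
#' and sensitive groups. Survival times follow a group-specific parametric
#' model (Weibull by default, shape 3, medians 6 vs 15 months; exponential
#' optional); resistant samples carry the planted resistance-gene effects
#' (log2 units) on top of log-normal baseline expression. Expression is
#' returned on log2 scale.
#'
#' @param n_samples Total cohort size (>= 8).
#' @param n_genes Gene universe size (>= number of effect genes).
#' @param truth A [synthetic_truth()]; default truth built from `seed`.
#' @param seed Integer seed.
#' @param noise_sd Gaussian SD of log2 expression noise (default 0.3).
#' @param p_crt Fraction receiving chemoradiotherapy.
#' @param p_dead Fraction of treated patients deceased at follow-up.
#' @param survival_model `"weibull"` or `"exponential"`.
#' @param median_resistant,median_sensitive Group median survivals (months).
#' @param weibull_shape Shape parameter for the Weibull model.
#' @return List with `expr` (log2 [expression_matrix()]), `cohort`
#'   (`data.frame` of sample, survival_time, vital_status, therapy, group),
#'   and `truth`.
#' @export
gen_bulk_cohort <- function(n_samples = 280, n_genes = 1000, truth = NULL,
                            seed = 1, noise_sd = 0.3, p_crt = 0.8,
                            p_dead = 0.9,
                            survival_model = c("weibull", "exponential"),
                            median_resistant = 6, median_sensitive = 15,
                            weibull_shape = 3) {
  survival_model <- match.arg(survival_model)
  truth <- truth %||% synthetic_truth(n_genes = n_genes, seed = seed)
  if (n_samples < 8) stop("n_samples must be >= 8")
  effects <- truth$resistance_genes
  genes <- unique(c(names(effects), sprintf("g%04d", seq_len(n_genes))))[seq_len(max(n_genes, length(effects)))]
  if (!all(names(effects) %in% genes))
    stop("effect genes not contained in the gene universe")
  local_seed(seed, {
    samples <- sprintf("s%03d", seq_len(n_samples))
    therapy <- sample(c("chemoradiotherapy", "radiotherapy_only",
                        "chemotherapy_only", "other"),
                      n_samples, replace = TRUE,
                      prob = c(p_crt, (1 - p_crt) / 3, (1 - p_crt) / 3,
                               (1 - p_crt) / 3))
    dead <- stats::rbinom(n_samples, 1, ifelse(therapy == "chemoradiotherapy",
                                               p_dead, 0.7)) == 1
    vital <- ifelse(dead, "dead", "alive")
    eligible <- dead & therapy == "chemoradiotherapy"
    group <- rep(NA_character_, n_samples)
    idx <- which(eligible)
    half <- sample(idx, floor(length(idx) / 2))
    group[half] <- "resistant"
    group[setdiff(idx, half)] <- "sensitive"

    med <- ifelse(!is.na(group) & group == "resistant",
                  median_resistant, median_sensitive)
    surv <- if (survival_model == "weibull") {
      scale <- med / log(2)^(1 / weibull_shape)
      stats::rweibull(n_samples, shape = weibull_shape, scale = scale)
    } else {
      stats::rexp(n_samples, rate = log(2) / med)
    }
    surv <- pmax(surv, 0.1)

    base_mean <- stats::runif(length(genes), 2, 8)
    expr <- matrix(stats::rnorm(length(genes) * n_samples,
                                mean = base_mean, sd = noise_sd),
                   nrow = length(genes), ncol = n_samples,
                   dimnames = list(genes, samples))
    res <- which(!is.na(group) & group == "resistant")
    expr[names(effects), res] <- expr[names(effects), res] + effects
    expr <- pmax(expr, 0)

    cohort <- data.frame(sample = samples, survival_time = surv,
                         vital_status = vital, therapy = therapy,
                         group = group, stringsAsFactors = FALSE)
    list(expr = expression_matrix(expr, scale = "lognorm"),
         cohort = cohort, truth = truth)
  })
}

#' Generate a cell-line panel with apoptosis and drug-viability readouts
#'
#' Half of the lines express the planted driver (and resistance genes)
#' highly and behave therapy-resistant: little treatment-induced apoptosis
#' and lower IC50 for planted driver-sensitive drugs. Viability tables are
#' log-logistic dose responses plus Gaussian noise on a shared dose grid.
#'
#' @param n_lines Number of cell lines (>= 4, split evenly).
#' @param n_genes Gene universe size.
#' @param n_drugs Number of screened drugs.
#' @param truth A [synthetic_truth()] or NULL.
#' @param seed Integer seed.
#' @param noise_sd Log2 expression noise SD.
#' @param apoptosis_reps Replicates per condition (>= 2).
#' @param n_sensitive_drugs Number of planted driver-sensitive drugs
#'   (default 13, of which exactly one is flagged able to cross the
#'   blood-brain barrier, mirroring a screen where a single hit is
#'   brain-penetrant).
#' @param ic50_ratio Fold-change in IC50 between low- and high-driver lines
#'   for driver-sensitive drugs (default 4).
#' @param viability_noise_sd SD of viability noise (percentage points).
#' @param doses Drug dose grid (must include 0).
#' @return List with `expr` (log2 lines panel), `apoptosis`
#'   (`data.frame(line, condition, replicate, fraction)`), `viability`
#'   (named list per drug of lines x doses viability% matrices),
#'   `drug_info` (`data.frame(drug, bbb, driver_sensitive, base_ic50)`),
#'   and `truth`.
#' @export
gen_cellline_panel <- function(n_lines = 20, n_genes = 1000, n_drugs = 30,
                               truth = NULL, seed = 1, noise_sd = 0.3,
                               apoptosis_reps = 3, n_sensitive_drugs = 13,
                               ic50_ratio = 4, viability_noise_sd = 2,
                               doses = c(0, 0.1, 0.3, 1, 3, 10, 30)) {
  truth <- truth %||% synthetic_truth(n_genes = n_genes, seed = seed)
  if (n_lines < 4) stop("need at least 4 cell lines (2 per group)")
  if (apoptosis_reps < 2) stop("need >= 2 apoptosis replicates per condition")
  n_sensitive_drugs <- min(n_sensitive_drugs, n_drugs)
  effects <- truth$resistance_genes
  genes <- unique(c(names(effects), sprintf("g%04d", seq_len(n_genes))))[seq_len(max(n_genes, length(effects)))]
  local_seed(seed, {
    lines <- sprintf("GSC%02d", seq_len(n_lines))
    n_res <- floor(n_lines / 2)
    line_group <- c(rep("resistant", n_res), rep("sensitive", n_lines - n_res))

    base_mean <- stats::runif(length(genes), 2, 8)
    expr <- matrix(stats::rnorm(length(genes) * n_lines, mean = base_mean,
                                sd = noise_sd),
                   nrow = length(genes), dimnames = list(genes, lines))
    res <- which(line_group == "resistant")
    expr[names(effects), res] <- expr[names(effects), res] + effects
    expr <- pmax(expr, 0)

    conds <- c("control", "RT", "TMZ")
    apo <- expand.grid(line = lines, condition = conds,
                       replicate = seq_len(apoptosis_reps),
                       stringsAsFactors = FALSE)
    # resistant lines show no treatment-induced apoptosis (same mean as
    # control); sensitive lines respond strongly
    mu <- ifelse(apo$condition == "control", 0.05,
                 ifelse(line_group[match(apo$line, lines)] == "resistant",
                        0.05, 0.45))
    apo$fraction <- clamp(stats::rnorm(nrow(apo), mu,
                                       ifelse(apo$condition == "control",
                                              0.01, 0.03)), 0, 1)

    drugs <- sprintf("drug%02d", seq_len(n_drugs))
    sens <- seq_len(n_sensitive_drugs)
    bbb <- rep(FALSE, n_drugs)
    if (n_sensitive_drugs >= 1) bbb[sens[1]] <- TRUE
    if (n_drugs > n_sensitive_drugs)
      bbb[-sens] <- stats::runif(n_drugs - n_sensitive_drugs) < 0.3
    base_ic50 <- exp(stats::runif(n_drugs, log(0.5), log(10)))
    hills <- stats::runif(n_drugs, 1, 2.5)

    viability <- vector("list", n_drugs)
    names(viability) <- drugs
    ic50_truth <- matrix(NA_real_, n_drugs, n_lines,
                         dimnames = list(drugs, lines))
    for (d in seq_len(n_drugs)) {
      line_ic50 <- base_ic50[d] * exp(stats::rnorm(n_lines, 0, 0.15))
      if (d %in% sens)
        line_ic50[line_group == "resistant"] <-
          line_ic50[line_group == "resistant"] / ic50_ratio
      ic50_truth[d, ] <- line_ic50
      v <- sapply(doses, function(x)
        100 / (1 + (x / line_ic50)^hills[d]))
      v <- v + matrix(stats::rnorm(length(v), 0, viability_noise_sd),
                      nrow = n_lines)
      v[, doses == 0] <- pmax(v[, doses == 0], 95)  # anchor untreated ~100%
      viability[[d]] <- matrix(clamp(v, 0, 110), nrow = n_lines,
                               dimnames = list(lines, as.character(doses)))
    }
    drug_info <- data.frame(drug = drugs, bbb = bbb,
                            driver_sensitive = seq_len(n_drugs) %in% sens,
                            base_ic50 = base_ic50, hill = hills,
                            stringsAsFactors = FALSE)
    truth$line_group <- stats::setNames(line_group, lines)
    truth$ic50 <- ic50_truth
    truth$doses <- doses
    list(expr = expression_matrix(expr, scale = "lognorm"),
         apoptosis = apo, viability = viability, drug_info = drug_info,
         truth = truth)
  })
}

#' Generate a single-cell count dataset with planted CNV segments
#'
#' Counts are negative binomial around per-cluster mean profiles over a
#' position-ordered gene universe. The first cluster is the non-tumor
#' reference; tumor clusters carry multiplicative expression shifts
#' (2^gain) on the contiguous gene blocks listed in `truth$cnv_segments`.
#' One tumor cluster is additionally planted driver-high and
#' resistance-signature-high (recorded as `truth$resistant_cluster`) and
#' every cluster receives a block of planted marker genes.
#'
#' @param n_cells Total cell count.
#' @param n_genes Gene universe size (split evenly over chromosomes).
#' @param truth A [synthetic_truth()] or NULL.
#' @param seed Integer seed.
#' @param n_chrom Number of chromosomes genes are laid out on.
#' @param dispersion NB size parameter (smaller = noisier). The default
#'   emulates deep full-length (Smart-seq2-style) coverage, under which
#'   smoothed reference profiles fall below the CNV noise filter.
#' @param n_markers Planted marker genes per cluster.
#' @param marker_fc Fold change of planted markers.
#' @param driver_shift Log2 shift of driver/resistance genes in the
#'   resistant tumor cluster.
#' @return List with `counts` (genes x cells [expression_matrix()]),
#'   `annotation` (`data.frame(cell, cluster, is_reference)`), `positions`
#'   (gene position table), and `truth` (with `cluster_profiles`,
#'   `marker_genes`, `resistant_cluster` filled in).
#' @export
gen_sc_dataset <- function(n_cells = 400, n_genes = 1200, truth = NULL,
                           seed = 1, n_chrom = 6, dispersion = 20,
                           n_markers = 20, marker_fc = 4,
                           driver_shift = 1) {
  truth <- truth %||% synthetic_truth(n_genes = n_genes, seed = seed)
  k <- truth$n_clusters
  if (k < 2) stop("need >= 2 clusters (one reference)")
  seg <- truth$cnv_segments
  if (any(seg$start_idx < 1) || any(seg$end_idx > n_genes) ||
      any(seg$start_idx > seg$end_idx))
    stop("cnv segment indices out of range")
  local_seed(seed, {
    # plant driver + resistance genes inside the universe, outside the CNV
    # segments so copy-number gains and driver shifts stay separable
    rg <- names(truth$resistance_genes)
    in_seg <- unlist(Map(seq, seg$start_idx, seg$end_idx))
    free <- setdiff(seq_len(n_genes), in_seg)
    if (length(free) < length(rg)) stop("gene universe too small for planted genes")
    filler <- setdiff(sprintf("g%04d", seq_len(n_genes + length(rg))), rg)
    genes <- character(n_genes)
    genes[free[seq_along(rg)]] <- rg
    genes[genes == ""] <- filler[seq_len(sum(genes == ""))]

    per_chrom <- ceiling(n_genes / n_chrom)
    chrom <- paste0("chr", rep(seq_len(n_chrom), each = per_chrom))[seq_len(n_genes)]
    start <- unlist(lapply(table(chrom)[unique(chrom)],
                           function(n) seq_len(n) * 1000L))
    positions <- data.frame(gene = genes, chrom = chrom,
                            start = as.numeric(start),
                            end = as.numeric(start) + 500,
                            stringsAsFactors = FALSE)

    clusters <- c("ref", paste0("tumor", LETTERS[seq_len(k - 1)]))
    base <- stats::rgamma(n_genes, shape = 2, scale = 15) + 5
    profiles <- matrix(rep(base, k), ncol = k,
                       dimnames = list(genes, clusters))
    marker_genes <- list()
    free2 <- setdiff(free, free[seq_along(rg)])
    for (j in seq_len(k)) {
      mk <- genes[free2[seq_len(n_markers) + (j - 1) * n_markers]]
      profiles[mk, j] <- profiles[mk, j] * marker_fc
      marker_genes[[clusters[j]]] <- mk
    }
    tumor <- clusters[-1]
    for (s in seq_len(nrow(seg))) {
      block <- seq(seg$start_idx[s], seg$end_idx[s])
      profiles[block, tumor] <- profiles[block, tumor] * 2^seg$gain_log2[s]
    }
    resistant_cluster <- tumor[1]
    profiles[rg, resistant_cluster] <-
      profiles[rg, resistant_cluster] * 2^driver_shift

    cluster_of <- sample(rep(clusters, length.out = n_cells))
    mu <- profiles[, cluster_of, drop = FALSE]
    counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = mu,
                                    size = dispersion),
                     nrow = n_genes,
                     dimnames = list(genes, sprintf("c%04d", seq_len(n_cells))))
    annotation <- data.frame(cell = colnames(counts), cluster = cluster_of,
                             is_reference = cluster_of == "ref",
                             stringsAsFactors = FALSE)
    truth$cluster_profiles <- profiles
    truth$marker_genes <- marker_genes
    truth$resistant_cluster <- resistant_cluster
    truth$segment_genes <- lapply(seq_len(nrow(seg)),
                                  function(s) genes[seq(seg$start_idx[s],
                                                        seg$end_idx[s])])
    list(counts = expression_matrix(counts, scale = "counts"),
         annotation = annotation, positions = gene_position_table(positions),
         truth = truth)
  })
}

#' Generate a spatial transcriptomics dataset as mixtures of cell clusters
#'
#' Spots are grouped into spatial clusters, each labeled with an anatomic
#' region (CT, IT, LE, MP, PSEU). Each spot's expression is a weighted
#' mixture of single-cell cluster profiles plus Gaussian noise; mixture
#' weights are recorded in the truth. By default the planted resistant
#' tumor cluster dominates MP and PSEU spots, the other tumor clusters CT
#' and IT, and the reference cluster LE.
#'
#' @param n_spots Number of spots.
#' @param truth A [synthetic_truth()] whose `cluster_profiles` is set
#'   (e.g. by [gen_sc_dataset()]).
#' @param seed Integer seed.
#' @param dominant_weight Mixture weight of the dominant cluster per spot
#'   (1 gives pure spots).
#' @param noise_sd SD of log2-scale expression noise.
#' @return List with `spatial` (a `spatial_dataset`: `expr` spots stored as
#'   genes x spots log2 matrix, `spots` data.frame of spot, x, y,
#'   spatial_cluster, region) and `truth` (with `spot_mixtures`).
#' @export
gen_spatial_dataset <- function(n_spots = 250, truth, seed = 1,
                                dominant_weight = 0.8, noise_sd = 0.2) {
  if (is.null(truth$cluster_profiles))
    stop("truth$cluster_profiles must be set (run gen_sc_dataset first)")
  profiles <- truth$cluster_profiles
  k <- ncol(profiles)
  regions <- c("CT", "IT", "LE", "MP", "PSEU")
  local_seed(seed, {
    clusters <- colnames(profiles)
    tumor <- setdiff(clusters, "ref")
    resistant <- truth$resistant_cluster %||% tumor[1]
    other_tumor <- setdiff(tumor, resistant)
    # dominant sc cluster per region
    dom <- c(CT = other_tumor[1] %||% resistant,
             IT = other_tumor[length(other_tumor)] %||% resistant,
             LE = "ref", MP = resistant, PSEU = resistant)
    region_of <- sample(rep(regions, length.out = n_spots))
    spot_cluster <- paste0("sp_", region_of)
    mix <- matrix(0, n_spots, k, dimnames = list(NULL, clusters))
    for (i in seq_len(n_spots)) {
      w <- rep((1 - dominant_weight) / (k - 1), k)
      w[match(dom[region_of[i]], clusters)] <- dominant_weight
      mix[i, ] <- w / sum(w)
    }
    logp <- log2(profiles + 1)
    expr <- logp %*% t(mix) +
      matrix(stats::rnorm(nrow(profiles) * n_spots, 0, noise_sd),
             ncol = n_spots)
    expr <- pmax(expr, 0)
    colnames(expr) <- sprintf("spot%04d", seq_len(n_spots))
    spots <- data.frame(spot = colnames(expr),
                        x = stats::runif(n_spots, 0, 100),
                        y = stats::runif(n_spots, 0, 100),
                        spatial_cluster = spot_cluster,
                        region = region_of, stringsAsFactors = FALSE)
    rownames(mix) <- colnames(expr)
    truth$spot_mixtures <- mix
    spatial <- structure(list(expr = expression_matrix(expr, scale = "lognorm"),
                              spots = spots),
                         class = "spatial_dataset")
    list(spatial = spatial, truth = truth)
  })
}

#' Generate a two-agent dose-response combination matrix
#'
#' The combination inhibition fraction at doses (a, b) is the Bliss surface
#' of the two monotherapy log-logistic curves plus a planted deviation on
#' cells where both doses are positive, clamped to [0, 1], plus optional
#' Gaussian noise, reported as percentages. The default grids are a 5-dose
#' radiotherapy axis (Gy) crossed with a 6-dose drug axis (uM).
#'
#' @param doses_a,doses_b Dose grids including 0.
#' @param curve_a,curve_b Monotherapy curves as lists with `h`, `m`, `L`,
#'   `U` (inhibition fractions in [0, 1]).
#' @param synergy_magnitude Planted Bliss deviation (fraction).
#' @param noise_sd Gaussian noise SD in percentage points.
#' @param seed Integer seed.
#' @return A [dose_matrix()] with attribute `truth` recording the planted
#'   surface before clamping and noise.
#' @export
gen_dose_matrix <- function(doses_a = c(0, 4, 8, 12, 16),
                            doses_b = c(0, 1, 2, 5, 10, 15),
                            curve_a = list(h = 1.5, m = 8, L = 0, U = 0.9),
                            curve_b = list(h = 1.2, m = 5, L = 0, U = 0.85),
                            synergy_magnitude = 0.2, noise_sd = 0,
                            seed = 1) {
  if (any(doses_a < 0) || any(doses_b < 0)) stop("doses must be non-negative")
  if (!(0 %in% doses_a) || !(0 %in% doses_b)) stop("dose grids must include 0")
  ll <- function(d, c) c$L + (c$U - c$L) * d^c$h / (d^c$h + c$m^c$h)
  ya <- ll(doses_a, curve_a)
  yb <- ll(doses_b, curve_b)
  bliss <- outer(ya, yb, function(a, b) a + b - a * b)
  both <- outer(doses_a > 0, doses_b > 0, `&`)
  surface <- bliss + synergy_magnitude * both
  local_seed(seed, {
    obs <- clamp(surface, 0, 1) * 100 +
      matrix(stats::rnorm(length(surface), 0, noise_sd), nrow = length(doses_a))
    dm <- dose_matrix(doses_a, doses_b, obs)
    attr(dm, "truth") <- list(surface = surface, bliss = bliss,
                              synergy_magnitude = synergy_magnitude)
    dm
  })
}

#' Generate a limiting-dilution assay table
#'
#' Wells seeded with `x` cells respond independently with probability
#' 1 - (1 - frequency)^x, the single-hit model with per-cell activity
#' probability `frequency`.
#'
#' @param frequency Sphere-forming (active-cell) frequency in (0, 1].
#' @param doses Cells-per-well grid (non-negative integers; the default is
#'   the standard 0/1/5/10/20/50 design).
#' @param n_wells Replicate wells per density (default 16).
#' @param seed Integer seed.
#' @return `data.frame(cells_per_well, wells_tested, wells_responding)`.
#' @export
gen_dilution_assay <- function(frequency, doses = c(0, 1, 5, 10, 20, 50),
                               n_wells = 16, seed = 1) {
  if (frequency <= 0 || frequency > 1) stop("frequency must be in (0, 1]")
  if (any(doses < 0) || any(doses != round(doses)))
    stop("doses must be non-negative integers")
  local_seed(seed, {
    p <- 1 - (1 - frequency)^doses
    data.frame(cells_per_well = doses,
               wells_tested = n_wells,
               wells_responding = stats::rbinom(length(doses), n_wells, p))
  })
}
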