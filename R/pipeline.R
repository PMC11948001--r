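# End-to-end orchestration of the discovery pipeline on synthetic inputs:
# cohort + cell-line signature derivation, single-cell CNV scoring and
# subcluster classification, spatial projection, drug screening with ZIP
# synergy, and the supporting assay statistics, collected into a single
# report.

#' Build a pipeline configuration
#'
#' Collects every tunable threshold and problem size with its default;
#' unknown names are rejected. Defaults are the package's reference study
#' conditions.
#'
#' @param seed Master seed (each stage derives its own child seed).
#' @param ... Overrides of the defaults listed below.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # cohort / signature
    n_samples = 280, n_genes = 1000, survival_rule = "median",
    de_method = "welch", lfc_min = 0.5, p_max = 0.05, alpha = 0.05,
    # cell-line panel
    n_lines = 20, n_drugs = 16, n_sensitive_drugs = 4,
    # single cell
    n_cells = 400, n_sc_genes = 1200, window = 101, noise_filter = 0.2,
    clip = 1, cnv_prob = 0.95, min_frac = 0.25, marker_lfc = 0.5,
    # spatial
    n_spots = 250, n_top_hvgs = 500,
    # pharmacology
    min_inhibition = 50, synergy_magnitude = 0.2,
    # assays
    stem_frequency_control = 0.1, stem_frequency_treated = 0.02
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  validate_all(list(
    check(is.finite(cfg$seed), "seed must be set"),
    check(cfg$n_samples >= 8, "n_samples must be >= 8"),
    check(cfg$n_lines >= 4, "n_lines must be >= 4"),
    check(cfg$lfc_min > 0, "lfc_min must be positive"),
    check(cfg$p_max > 0 && cfg$p_max <= 1, "p_max must be in (0, 1]"),
    check(cfg$alpha > 0 && cfg$alpha <= 1, "alpha must be in (0, 1]"),
    check(cfg$noise_filter >= 0 && cfg$noise_filter <= cfg$clip,
          "noise_filter must lie in [0, clip]"),
    check(cfg$clip > 0, "clip must be positive"),
    check(cfg$window >= 1, "window must be >= 1"),
    check(cfg$min_frac >= 0 && cfg$min_frac <= 1,
          "min_frac must be in [0, 1]"),
    check(cfg$cnv_prob > 0 && cfg$cnv_prob < 1,
          "cnv_prob must be in (0, 1)"),
    check(cfg$stem_frequency_control > 0 &&
            cfg$stem_frequency_control <= 1,
          "stem_frequency_control must be in (0, 1]"),
    check(cfg$stem_frequency_treated > 0 &&
            cfg$stem_frequency_treated <= 1,
          "stem_frequency_treated must be in (0, 1]")
  ))
}

#' Run the full pipeline on synthetic inputs
#'
#' Executes signature derivation (patient cohort and cell-line panel, with
#' intersection), single-cell CNV scoring and subcluster classification,
#' spatial projection with region enrichment, the differential-IC50 screen
#' with BBB filter, ZIP synergy with optimal-combination selection, and
#' the assay statistics, all on data generated from `config$seed`. Any
#' stage failure is re-raised with a stage tag; results of completed
#' stages are attached to the error condition.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for the report bundle (TSVs +
#'   `report.json`).
#' @return A named list of stage results (invisible report path attached
#'   as attribute `report` when `output_dir` is given).
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  validate_config(config)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      err <- simpleError(paste0("[stage ", name, "] ", conditionMessage(e)))
      err$partial_results <- results
      stop(err)
    })
  }
  seed <- config$seed
  truth <- synthetic_truth(n_genes = config$n_genes, seed = seed,
                           synergy_magnitude = config$synergy_magnitude)

  # -- signature derivation ------------------------------------------------
  sig <- stage("cohort_signature", {
    bulk <- gen_bulk_cohort(config$n_samples, config$n_genes, truth,
                            seed = derive_seed(seed, "bulk"))
    strat <- stratify_by_survival(bulk$cohort, rule = config$survival_rule)
    labels <- stats::setNames(strat$group, strat$sample)
    de_pat <- differential_expression(
      bulk$expr[, strat$sample, drop = FALSE], labels,
      method = config$de_method)
    sig_pat <- volcano_filter(de_pat, config$lfc_min, config$p_max,
                              "resistant-up", label = "patient")
    panel <- gen_cellline_panel(config$n_lines, config$n_genes,
                                config$n_drugs, truth,
                                seed = derive_seed(seed, "panel"),
                                n_sensitive_drugs = config$n_sensitive_drugs)
    apo <- stratify_by_apoptosis(panel$apoptosis, alpha = config$alpha)
    line_labels <- stats::setNames(apo$label, apo$line)
    de_line <- differential_expression(panel$expr, line_labels,
                                       method = config$de_method)
    sig_line <- volcano_filter(de_line, config$lfc_min, config$p_max,
                               "resistant-up", label = "cellline")
    common <- intersect_signatures(sig_pat, sig_line)
    driver <- if (truth$driver_gene %in% common$gene) truth$driver_gene
              else common$gene[which.max(abs(
                de_pat$log2fc[match(common$gene, de_pat$gene)]))]
    list(de_patient = de_pat, de_cellline = de_line,
         signature_patient = sig_pat, signature_cellline = sig_line,
         signature = common, driver = driver, panel = panel,
         cohort = bulk$cohort, strat = strat,
         driver_recovered = truth$driver_gene %in% common$gene)
  })
  results$signature <- sig

  # -- single-cell CNV + subclusters --------------------------------------
  sc <- stage("sc_cnv", {
    scd <- gen_sc_dataset(config$n_cells, config$n_sc_genes, truth,
                          seed = derive_seed(seed, "sc"))
    refs <- scd$annotation$cell[scd$annotation$is_reference]
    prof <- suppressWarnings(
      infer_cnv_profile(scd$counts, refs, scd$positions,
                        window = config$window,
                        noise_filter = config$noise_filter,
                        clip = config$clip))
    scores <- cnv_score(prof)
    # very clean reference profiles can be zeroed entirely by the noise
    # filter; the percentile rule is then degenerate and the deterministic
    # two-component rule takes over (recorded in the output)
    cls <- if (length(unique(scores[refs])) > 1)
      classify_cnv(scores, scores[refs], prob = config$cnv_prob)
    else classify_cnv(scores, scores[refs], rule = "cluster2")
    list(data = scd, profiles = prof, scores = scores, classes = cls)
  })
  results$sc_cnv <- list(classes = sc$classes)

  sub <- stage("sc_subclusters", {
    scd <- sc$data
    ln <- log_normalize(scd$counts)
    clusters <- stats::setNames(scd$annotation$cluster,
                                scd$annotation$cell)
    driver_means <- cluster_mean_expression(ln, clusters, sig$driver)
    msn_groups <- mean_sem_grouping(driver_means)
    sig_scores <- signature_score_clusters(ln, clusters, sig$signature)
    resist_groups <- mean_sem_grouping(sig_scores)
    groups <- intersect_groups(msn_groups, resist_groups)
    markers <- find_markers(ln, clusters, min_frac = config$min_frac,
                            lfc_min = config$marker_lfc)
    list(driver_means = driver_means, msn_groups = msn_groups,
         sig_scores = sig_scores, resist_groups = resist_groups,
         groups = groups, markers = markers, lognorm = ln,
         clusters = clusters)
  })
  results$subclusters <- sub[c("driver_means", "msn_groups", "sig_scores",
                               "resist_groups", "groups")]

  # -- spatial projection --------------------------------------------------
  spatial <- stage("spatial_map", {
    sp <- gen_spatial_dataset(config$n_spots, sc$data$truth,
                              seed = derive_seed(seed, "spatial"))
    hvgs <- select_shared_hvgs(sub$lognorm, sp$spatial$expr,
                               n_top = config$n_top_hvgs)
    scores <- transfer_scores(sub$lognorm, sub$clusters, sp$spatial, hvgs)
    grp <- list(
      resistant = if (length(sub$groups$high_msn_resistant) > 0)
        sub$groups$high_msn_resistant else sc$data$truth$resistant_cluster,
      sensitive = if (length(sub$groups$low_msn_sensitive) > 0)
        sub$groups$low_msn_sensitive else "ref")
    enrich <- region_enrichment(scores, sp$spatial, grp)
    list(prediction_scores = scores, region_enrichment = enrich,
         dataset = sp)
  })
  results$spatial <- spatial[c("prediction_scores", "region_enrichment")]

  # -- drug screen + synergy ----------------------------------------------
  pharm <- stage("pharm", {
    panel <- sig$panel
    doses <- panel$truth$doses
    ic <- matrix(NA_real_, nrow(panel$drug_info), config$n_lines,
                 dimnames = list(panel$drug_info$drug,
                                 colnames(panel$expr)))
    for (d in panel$drug_info$drug) {
      v <- panel$viability[[d]]
      for (l in rownames(v)) {
        inhib <- 100 - as.numeric(v[l, ]) / mean(v[l, doses == 0]) * 100
        cur <- fit_loglogistic(doses, clamp(inhib, 0, 100),
                               seed = derive_seed(seed, paste0(d, l)))
        ic[d, l] <- as.numeric(ic50(cur))
      }
    }
    driver_expr <- as.matrix(panel$expr)[sig$driver, ]
    screen <- differential_ic50_screen(ic, driver_expr,
                                       alpha = config$alpha)
    bbb <- stats::setNames(panel$drug_info$bbb, panel$drug_info$drug)
    hits <- filter_bbb(screen, bbb)
    dm <- gen_dose_matrix(synergy_magnitude = config$synergy_magnitude,
                          noise_sd = 2,
                          seed = derive_seed(seed, "synergy"))
    syn <- zip_delta(dm)
    combo <- select_optimal_combo(syn, dm,
                                  min_inhibition = config$min_inhibition)
    list(ic50 = ic, screen = screen, bbb_hits = hits, dose_matrix = dm,
         synergy = syn, combo = combo)
  })
  results$pharm <- pharm[c("screen", "bbb_hits", "combo")]
  results$pharm$synergy_summary <- pharm$synergy$summary

  # -- assay statistics ----------------------------------------------------
  assays <- stage("assay_stats", {
    dil_ctrl <- gen_dilution_assay(config$stem_frequency_control,
                                   seed = derive_seed(seed, "dilA"))
    dil_trt <- gen_dilution_assay(config$stem_frequency_treated,
                                  seed = derive_seed(seed, "dilB"))
    f_ctrl <- elda_fit(dil_ctrl)
    f_trt <- elda_fit(dil_trt)
    cmp <- elda_compare(dil_ctrl, dil_trt)
    strat <- sig$strat
    km <- km_logrank(strat$survival_time,
                     rep(1, nrow(strat)), strat$group)
    hs <- local_seed(derive_seed(seed, "ihc"), {
      raw <- matrix(stats::rgamma(4 * 20, shape = 1), ncol = 4)
      comp <- raw / rowSums(raw)
      data.frame(sample = sprintf("tma%02d", seq_len(20)),
                 h_score = h_score(comp[, 1], comp[, 2], comp[, 3],
                                   comp[, 4]))
    })
    list(frequency_control = f_ctrl, frequency_treated = f_trt,
         elda_test = cmp, km = km, h_scores = hs)
  })
  results$assays <- list(
    f_control = assays$frequency_control$f_hat,
    f_treated = assays$frequency_treated$f_hat,
    elda_p = assays$elda_test$p,
    logrank_chisq = assays$km$chisq, logrank_p = assays$km$p)

  report <- list(
    signature_genes = sig$signature$gene,
    driver = sig$driver,
    driver_recovered = sig$driver_recovered,
    n_signature = nrow(sig$signature),
    msn_groups = as.list(results$subclusters$msn_groups),
    resistant_subclusters = sub$groups$high_msn_resistant,
    region_enrichment = spatial$region_enrichment,
    screen = pharm$screen,
    bbb_hits = pharm$bbb_hits$drug,
    synergy_summary = pharm$synergy$summary,
    optimal_combo = pharm$combo[c("dose_a", "dose_b", "delta")],
    assays = results$assays)
  if (!is.null(output_dir)) {
    path <- write_report(report, output_dir, config = unclass(config),
                         seed = config$seed)
    attr(results, "report") <- path
  }
  results$report <- report
  results
}
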