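# Shared fixture builders: small, fast datasets built in code.

small_truth <- function(seed = 1, n_genes = 600, effects = 1.0) {
  ids <- c("MSN", sprintf("g%04d", 1:9))
  synthetic_truth(
    n_genes = n_genes,
    resistance_genes = stats::setNames(rep(effects, 10), ids),
    cnv_segments = data.frame(chrom = "chr1", start_idx = 1, end_idx = 100,
                              gain_log2 = 0.58),
    seed = seed)
}

# tiny log expression matrix with named axes
toy_expr <- function(values, genes = NULL, samples = NULL) {
  m <- matrix(values, nrow = length(genes %||% rownames(values)))
  rownames(m) <- genes
  colnames(m) <- samples
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp_test <- function(x) pmin(pmax(x, 0), 100)
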