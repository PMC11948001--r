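# Readers, writers and validation for the external formats the pipeline
# touches: expression matrices (TSV or MatrixMarket triplet with id
# sidecars), BED-like gene position tables, dose-response CSV grids, and the
# JSON/TSV report bundle. Text dialects are fixed: UTF-8, "." decimal,
# header row mandatory for TSV/CSV tables.

#' Construct a validated expression matrix
#'
#' A thin wrapper around a numeric genes x samples matrix that enforces
#' unique ids on both axes, non-negative values, and a scale tag recording
#' whether values are raw counts or log-normalized.
#'
#' @param values Numeric matrix, genes in rows, samples/cells in columns,
#'   with rownames and colnames set.
#' @param scale Either `"counts"` or `"lognorm"`.
#' @return The matrix with a `scale` attribute and class `expr_matrix`.
#' @export
expression_matrix <- function(values, scale = c("counts", "lognorm")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (any(values < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  structure(values, scale = scale,
            class = c("expr_matrix", class(values)))
}

#' Scale tag of an expression matrix
#' @param x An `expr_matrix` (or plain matrix, which returns `NA`).
#' @return `"counts"`, `"lognorm"`, or `NA_character_`.
#' @export
expr_scale <- function(x) attr(x, "scale") %||% NA_character_

#' Read an expression matrix from TSV or MatrixMarket triplet
#'
#' TSV layout: header row of sample ids, first column gene ids. MTX layout:
#' a MatrixMarket file plus two sidecar files of row (gene) and column
#' (cell) ids, one id per line; absent triplet entries are zeros.
#'
#' @param path File path.
#' @param format `"tsv"` or `"mtx_triplet"`.
#' @param scale Scale tag to attach (`"counts"` or `"lognorm"`).
#' @param genes_file,barcodes_file Sidecar paths for MTX input; default
#'   `<path>.genes.txt` and `<path>.barcodes.txt`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "mtx_triplet"),
                            scale = c("counts", "lognorm"),
                            genes_file = NULL, barcodes_file = NULL) {
  format <- match.arg(format)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("malformed expression TSV: need gene id column plus samples")
    genes <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(vals)) stop("non-numeric expression values in ", path)
    rownames(vals) <- genes
    return(expression_matrix(vals, scale = scale))
  }
  genes_file <- genes_file %||% paste0(path, ".genes.txt")
  barcodes_file <- barcodes_file %||% paste0(path, ".barcodes.txt")
  if (!file.exists(genes_file) || !file.exists(barcodes_file))
    stop("MTX input requires gene and barcode sidecar files")
  m <- Matrix::readMM(path)
  genes <- readLines(genes_file)
  cells <- readLines(barcodes_file)
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    stop("MTX dimensions do not match sidecar id counts")
  vals <- as.matrix(m)
  dimnames(vals) <- list(genes, cells)
  expression_matrix(vals, scale = scale)
}

#' Write an expression matrix as TSV or MatrixMarket triplet
#'
#' @param x Matrix (genes x samples) with dimnames.
#' @param path Output path.
#' @param format `"tsv"` or `"mtx_triplet"` (writes `<path>.genes.txt` and
#'   `<path>.barcodes.txt` sidecars).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "mtx_triplet")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(gene = rownames(x), as.matrix(x), check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(as.matrix(x), sparse = TRUE), "generalMatrix"), "TsparseMatrix"), path)
    writeLines(rownames(x), paste0(path, ".genes.txt"))
    writeLines(colnames(x), paste0(path, ".barcodes.txt"))
  }
  invisible(path)
}

# Natural chromosome ordering: chr1..chr22 numerically, then letters.
chrom_order_key <- function(chrom) {
  stripped <- sub("^chr", "", chrom, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(stripped))
  key <- ifelse(is.na(num), 1000 + match(stripped, sort(unique(stripped))), num)
  key
}

#' Read a BED-like gene position table
#'
#' Expects a header row and at least four columns: chrom, start, end, gene,
#' with 0-based half-open coordinates. Output is sorted by (chromosome,
#' start) using natural chromosome ordering.
#'
#' @param path TSV path.
#' @param chrom_style `"asis"` keeps chromosome labels; `"chr"` forces a
#'   `chr` prefix; `"plain"` strips it.
#' @return `data.frame` with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_positions <- function(path, chrom_style = c("asis", "chr", "plain")) {
  chrom_style <- match.arg(chrom_style)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("position table needs >= 4 columns (chrom, start, end, gene)")
  pos <- data.frame(gene = as.character(tab[[4]]),
                    chrom = as.character(tab[[1]]),
                    start = as.numeric(tab[[2]]),
                    end = as.numeric(tab[[3]]),
                    stringsAsFactors = FALSE)
  gene_position_table(pos, chrom_style = chrom_style)
}

#' Validate and sort a gene position table
#'
#' @param pos `data.frame` with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param chrom_style See [read_positions()].
#' @return Sorted, validated `data.frame`.
#' @export
gene_position_table <- function(pos, chrom_style = c("asis", "chr", "plain")) {
  chrom_style <- match.arg(chrom_style)
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(pos)))
  if (anyDuplicated(pos$gene)) stop("duplicate gene ids in position table")
  if (any(pos$start >= pos$end))
    stop("position table has start >= end (coordinates are 0-based half-open)")
  if (chrom_style == "chr") {
    pos$chrom <- ifelse(grepl("^chr", pos$chrom), pos$chrom,
                        paste0("chr", pos$chrom))
  } else if (chrom_style == "plain") {
    pos$chrom <- sub("^chr", "", pos$chrom)
  }
  pos <- pos[order(chrom_order_key(pos$chrom), pos$start), , drop = FALSE]
  rownames(pos) <- NULL
  pos
}

#' Write a gene position table as BED-like TSV
#' @param pos Position `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_positions <- function(pos, path) {
  utils::write.table(pos[, c("chrom", "start", "end", "gene")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a dose-response matrix
#'
#' Inhibition percentages on a grid of doses for two agents, each dose
#' vector starting at 0 and strictly increasing. Values are clamped to
#' [0, 100] on ingest; the raw grid is preserved.
#'
#' @param doses_a,doses_b Numeric dose vectors including 0.
#' @param inhibition Matrix (length(doses_a) x length(doses_b)) of
#'   inhibition percentages.
#' @return A `dose_matrix` object.
#' @export
dose_matrix <- function(doses_a, doses_b, inhibition) {
  inhibition <- as.matrix(inhibition)
  if (any(doses_a < 0) || any(doses_b < 0)) stop("doses must be non-negative")
  if (!(0 %in% doses_a) || !(0 %in% doses_b))
    stop("each dose grid must include 0")
  oa <- order(doses_a); ob <- order(doses_b)
  doses_a <- doses_a[oa]; doses_b <- doses_b[ob]
  inhibition <- inhibition[oa, ob, drop = FALSE]
  if (anyDuplicated(doses_a) || anyDuplicated(doses_b))
    stop("dose grids must be strictly increasing")
  if (nrow(inhibition) != length(doses_a) || ncol(inhibition) != length(doses_b))
    stop("inhibition grid does not match dose vectors")
  if (any(!is.finite(inhibition))) stop("non-finite inhibition values")
  structure(list(doses_a = doses_a, doses_b = doses_b,
                 inhibition = clamp(inhibition, 0, 100),
                 raw = inhibition),
            class = "dose_matrix")
}

#' Read a dose-response CSV grid
#'
#' First column holds agent-A doses, the header row agent-B doses (the
#' corner cell is a label). Both grids must include 0; shuffled dose
#' orderings are re-sorted ascending.
#'
#' @param path CSV path.
#' @return A [dose_matrix()].
#' @export
read_dose_matrix <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  doses_a <- suppressWarnings(as.numeric(tab[[1]]))
  doses_b <- suppressWarnings(as.numeric(names(tab)[-1]))
  if (any(is.na(doses_a)) || any(is.na(doses_b)))
    stop("non-numeric dose labels in ", path)
  grid <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(grid)) stop("non-numeric inhibition cells in ", path)
  dose_matrix(doses_a, doses_b, grid)
}

#' Write a dose-response matrix as CSV
#' @param dm A `dose_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_matrix <- function(dm, path) {
  tab <- data.frame(dose = dm$doses_a, dm$inhibition, check.names = FALSE)
  names(tab) <- c("dose", format(dm$doses_b, trim = TRUE, digits = 15))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Stable hash of a config list (for report provenance).
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a pipeline report bundle
#'
#' Emits one TSV per tabular result plus a single `report.json` summary
#' embedding the package version, config hash, and seed. The timestamp is
#' stored under its own key so reports are otherwise byte-reproducible
#' given the seed.
#'
#' @param results Named list; `data.frame` elements become TSVs, the rest
#'   go into the JSON summary.
#' @param dir Output directory (created if needed).
#' @param config Pipeline configuration list to embed.
#' @param seed Master seed to embed.
#' @return Path to `report.json`, invisibly.
#' @export
write_report <- function(results, dir, config = list(), seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  is_tab <- vapply(results, is.data.frame, logical(1))
  for (nm in names(results)[is_tab]) {
    utils::write.table(results[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  summary <- list(
    pipeline_version = as.character(utils::packageVersion("gbmresist")),
    config_hash = config_hash(config),
    seed = seed,
    config = config,
    results = results[!is_tab],
    tables = as.list(names(results)[is_tab]),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  out <- file.path(dir, "report.json")
  jsonlite::write_json(summary, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(out)
}
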