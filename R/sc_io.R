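# Count-matrix input (TSV/CSV and Matrix Market triplet directories) and
# single-cell quality control: mitochondrial-fraction and library-complexity
# cell filters, rare-feature removal, per-group activity summaries.

#' Quality-control parameters for single-cell counts
#'
#' Defaults follow the downstream single-cell analysis convention used with
#' these scores: cells with fewer than 100 expressed genes and features
#' expressed in fewer than 10 cells are removed.  The stricter upstream
#' sequencing-QC thresholds (200 genes per cell, 40% mitochondrial UMI cap)
#' are reachable through the same flags.
#'
#' @param min_genes_per_cell minimum expressed (count > 0) genes per cell
#'   (default 100).
#' @param min_cells_per_feature minimum cells expressing a feature
#'   (default 10).
#' @param max_mito_fraction maximum mitochondrial UMI fraction per cell,
#'   computed on raw counts before any removal (default 0.40).
#' @param mito_prefix rowname prefix identifying mitochondrial genes
#'   (default `"MT-"`, the human convention; override for other organisms).
#' @param drop_mito_genes remove mitochondrial genes after the cell-level
#'   mito filter (default TRUE).
#' @return a `qc_params` object.
#' @export
qc_params <- function(min_genes_per_cell = 100L, min_cells_per_feature = 10L,
                      max_mito_fraction = 0.40, mito_prefix = "MT-",
                      drop_mito_genes = TRUE) {
  stopifnot(min_genes_per_cell >= 0, min_cells_per_feature >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  structure(list(min_genes_per_cell = as.integer(min_genes_per_cell),
                 min_cells_per_feature = as.integer(min_cells_per_feature),
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix,
                 drop_mito_genes = isTRUE(drop_mito_genes)),
            class = "qc_params")
}

#' Read a count/expression matrix
#'
#' Supported carriers: delimited text with gene identifiers in the first
#' column (`"tsv"`, `"csv"`) and a Matrix Market triplet directory
#' (`"mtx-dir"`: `matrix.mtx`, `features.tsv`, `barcodes.tsv`, optionally
#' gzipped).  Duplicate feature identifiers are deterministically suffixed
#' `".1"`, `".2"`, ... with a warning.  Non-numeric entries and
#' header/label dimension mismatches are errors.
#'
#' @param path file (tsv/csv) or directory (mtx-dir) path.
#' @param format `"auto"` (from extension / directory-ness), `"tsv"`,
#'   `"csv"` or `"mtx-dir"`.
#' @return numeric matrix (dense for text input, `dgCMatrix` for Matrix
#'   Market) with attribute `is_counts` (TRUE when all values are
#'   non-negative integers).
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx-dir")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx-dir"
      else if (grepl("\\.csv(\\.gz)?$", path)) "csv" else "tsv"
  }
  if (format == "mtx-dir") {
    m <- read_mtx_dir(path)
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.table(path, header = TRUE,
                            sep = if (format == "csv") "," else "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
    ids <- as.character(df[[1L]])
    vals <- df[, -1L, drop = FALSE]
    num <- vapply(vals, is.numeric, logical(1))
    if (!all(num))
      stop("non-numeric entries in column(s): ",
           paste(names(vals)[!num], collapse = ", "))
    m <- as.matrix(vals)
    rownames(m) <- dedupe_ids(ids)
    if (anyNA(m)) stop("missing values in expression matrix")
  }
  attr(m, "is_counts") <- is_count_matrix(m)
  m
}

dedupe_ids <- function(ids) {
  if (anyDuplicated(ids)) {
    warning(sum(duplicated(ids)), " duplicate feature identifier(s) suffixed")
    ids <- make.unique(ids, sep = ".")
  }
  ids
}

# the Matrix Market coordinate header states the number of entries; a
# triplet file with fewer/more data lines is corrupt
check_mtx_entry_count <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "%") & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty Matrix Market file: ", path)
  hdr <- as.numeric(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  if (length(hdr) != 3L || anyNA(hdr))
    stop("malformed Matrix Market size header in ", path)
  n_entries <- length(lines) - 1L
  if (n_entries != hdr[3L])
    stop("Matrix Market header states ", hdr[3L], " entries but ",
         n_entries, " are present in ", path)
  invisible(TRUE)
}

find_triplet_file <- function(dir, stems) {
  for (s in stems) for (ext in c("", ".gz")) {
    f <- file.path(dir, paste0(s, ext))
    if (file.exists(f)) return(f)
  }
  stop("no ", stems[1L], " file found in ", dir)
}

read_mtx_dir <- function(dir) {
  mf <- find_triplet_file(dir, c("matrix.mtx"))
  ff <- find_triplet_file(dir, c("features.tsv", "genes.tsv"))
  bf <- find_triplet_file(dir, c("barcodes.tsv"))
  check_mtx_entry_count(mf)
  m <- Matrix::readMM(mf)
  m <- methods::as(m, "CsparseMatrix")
  feats <- utils::read.delim(ff, header = FALSE, stringsAsFactors = FALSE)
  bcs <- utils::read.delim(bf, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(feats) != nrow(m))
    stop("features file has ", nrow(feats), " rows but matrix header states ",
         nrow(m), " features")
  if (nrow(bcs) != ncol(m))
    stop("barcodes file has ", nrow(bcs), " rows but matrix header states ",
         ncol(m), " cells")
  rownames(m) <- dedupe_ids(as.character(feats[[min(2L, ncol(feats))]]))
  colnames(m) <- as.character(bcs[[1L]])
  m
}

#' Single-cell quality-control filter
#'
#' Applies the QC rules in a fixed, documented order:
#' \enumerate{
#'   \item mitochondrial UMI fraction per cell, computed on the raw counts
#'     before any removal; cells above `max_mito_fraction` dropped;
#'   \item mitochondrial genes (rowname prefix match) removed if
#'     `drop_mito_genes`;
#'   \item cells whose expressed-gene count (features with count > 0, after
#'     step 2) falls below `min_genes_per_cell` dropped;
#'   \item features expressed in fewer than `min_cells_per_feature`
#'     remaining cells dropped.
#' }
#' The order matters (rule 3 counts genes after mito removal; rule 4 counts
#' cells after rules 1-3) and is frozen; the filter is idempotent.
#'
#' @param counts genes x cells count matrix (dense or sparse).
#' @param params a [qc_params()] object.
#' @return list with `counts` (filtered matrix) and `report` (a
#'   `qc_report`: cells/features in and out, per-rule removal counts with
#'   each cell attributed to the first rule it fails, and the mito genes
#'   removed).
#' @export
sc_qc_filter <- function(counts, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts matrix needs rownames (features) and colnames (cells)")
  n_cells_in <- ncol(counts); n_feat_in <- nrow(counts)
  mito <- startsWith(rownames(counts), params$mito_prefix)

  tot <- Matrix::colSums(counts)
  mito_frac <- if (any(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(tot, 1)
  else rep(0, n_cells_in)
  fail_mito <- mito_frac > params$max_mito_fraction

  m <- counts[, !fail_mito, drop = FALSE]
  mito_removed <- character(0)
  if (params$drop_mito_genes && any(mito)) {
    mito_removed <- rownames(counts)[mito]
    m <- m[!mito, , drop = FALSE]
  }
  genes_per_cell <- Matrix::colSums(m > 0)
  fail_complexity <- genes_per_cell < params$min_genes_per_cell
  m <- m[, !fail_complexity, drop = FALSE]

  cells_per_feat <- Matrix::rowSums(m > 0)
  fail_rare <- cells_per_feat < params$min_cells_per_feature
  m <- m[!fail_rare, , drop = FALSE]

  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty matrix after QC")
  report <- structure(list(
    cells_in = n_cells_in, cells_out = ncol(m),
    features_in = n_feat_in, features_out = nrow(m),
    removed = c(high_mito_cells = sum(fail_mito),
                low_complexity_cells = sum(fail_complexity),
                mito_features = length(mito_removed),
                rare_features = sum(fail_rare)),
    mito_genes_removed = mito_removed,
    params = params), class = "qc_report")
  list(counts = m, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: cells %d -> %d, features %d -> %d\n",
              x$cells_in, x$cells_out, x$features_in, x$features_out))
  for (nm in names(x$removed))
    cat(sprintf("  %-22s %d\n", nm, x$removed[[nm]]))
  invisible(x)
}

#' Per-group activity summary (dotplot backing table)
#'
#' Long-format summary behind the usual activity dotplot: per gene set and
#' sample group, the mean activity and the fraction of the group's samples
#' lying above that set's global (all-sample) median.
#'
#' @param activity sets x samples activity matrix.
#' @param labels group label per sample column.
#' @return data.frame with columns `set`, `group`, `mean_activity`,
#'   `frac_above_median`, `n`.
#' @export
group_summary <- function(activity, labels) {
  activity <- as.matrix(activity)
  if (length(labels) != ncol(activity))
    stop("`labels` must cover every sample; unknown or missing labels")
  if (anyNA(labels)) stop("unknown label: NA")
  labels <- as.factor(labels)
  med <- apply(activity, 1L, stats::median)
  out <- do.call(rbind, lapply(levels(labels), function(g) {
    cols <- labels == g
    sub <- activity[, cols, drop = FALSE]
    data.frame(set = rownames(activity), group = g,
               mean_activity = rowMeans(sub),
               frac_above_median = rowMeans(sub > med),
               n = sum(cols), stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}
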