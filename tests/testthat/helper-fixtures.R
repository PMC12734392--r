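# Programmatic fixtures shared across test files.

# Planted single-cell QC fixture: 50 genes x 20 cells.
#  - genes: 3 mitochondrial (MT-*), 42 common, 5 rare
#  - cells 1-2: mito fraction 0.6 (fail rule 1)
#  - cells 3-5: only 5 expressed non-mito genes (fail rule 3 at threshold 10)
#  - rare genes expressed in exactly 2 surviving cells (fail rule 4 at
#    threshold 5)
# Expected survivors with qc_params(10, 5, 0.4): 15 cells, 42 features.
make_qc_fixture <- function() {
  genes <- c(paste0("MT-", c("CO1", "ND1", "ATP6")),
             sprintf("g%02d", 1:42), sprintf("rare%d", 1:5))
  cells <- sprintf("c%02d", 1:20)
  m <- matrix(0L, 50, 20, dimnames = list(genes, cells))
  mito <- 1:3; common <- 4:45; rare <- 46:50
  # normal cells 6..20: all common genes expressed, light mito signal
  for (j in 6:20) {
    m[common, j] <- 1L + (seq_along(common) + j) %% 4
    m[mito, j] <- 2L  # 6 mito counts; fraction well below 0.4
  }
  # high-mito cells 1-2: 60% of counts on mito genes
  for (j in 1:2) {
    m[common, j] <- 1L       # 42 counts
    m[mito, j] <- 21L        # 63 mito counts -> fraction 0.6
  }
  # low-complexity cells 3-5: only 5 expressed (non-mito) genes
  for (j in 3:5) m[common[1:5], j] <- 3L
  # rare genes: expressed only in surviving cells 6 and 7
  m[rare, 6:7] <- 1L
  m
}

qc_fixture_params <- function() {
  qc_params(min_genes_per_cell = 10L, min_cells_per_feature = 5L,
            max_mito_fraction = 0.40, mito_prefix = "MT-",
            drop_mito_genes = TRUE)
}

# small deterministic expression fixture: 8 genes x 3 samples, 2 sets
make_small_expr <- function() {
  set.seed(42)
  X <- matrix(round(rnorm(24, 5, 2), 3), 8, 3,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:3)))
  sets <- list(SETA = c("g1", "g3", "g5"), SETB = c("g2", "g6", "g7", "g8"))
  list(expr = X, sets = sets,
       collection = geneset_collection(sets))
}

write_tmp_gmt <- function(lines) {
  f <- tempfile(fileext = ".gmt")
  writeLines(lines, f)
  f
}
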