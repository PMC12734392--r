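# Gene-set collections: flat (GMT) and hierarchical (MitoCarta-style
# three-level annotation) with size/coverage filtering against an
# expression universe.

#' Construct a gene-set collection
#'
#' A `geneset_collection` is an ordered, named list of gene symbol vectors
#' with optional per-set descriptions and hierarchy paths.  Gene identifiers
#' are case-sensitive exact strings; no alias mapping is attempted.
#'
#' @param sets named list of character vectors (gene symbols). Names must be
#'   unique and non-empty; each set must contain at least one gene.
#'   Duplicate genes within a set are removed, keeping first occurrence.
#' @param descriptions optional character vector parallel to `sets`.
#' @param level_paths optional list of character vectors giving each set's
#'   position in a hierarchy (length 0 for flat sets, up to 3 labels).
#' @param level hierarchy depth of the collection: 0 (flat) or 1-3. Must be
#'   consistent with `level_paths`.
#' @return an object of class `geneset_collection`.
#' @export
geneset_collection <- function(sets, descriptions = NULL, level_paths = NULL,
                               level = 0L) {
  if (!is.list(sets)) stop("`sets` must be a list of character vectors")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) stop("all sets must have non-empty names")
  dup <- nm[duplicated(nm)]
  if (length(dup)) stop("duplicate set names: ", paste(unique(dup), collapse = ", "))
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    g[!duplicated(g) & nzchar(g)]
  })
  if (any(lengths(sets) == 0L) && length(sets) > 0L)
    stop("empty gene set(s): ",
         paste(nm[lengths(sets) == 0L], collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- as.character(descriptions)
  names(descriptions) <- nm
  if (is.null(level_paths)) level_paths <- rep(list(character(0)), length(sets))
  names(level_paths) <- nm
  level <- as.integer(level)
  if (level < 0L || level > 3L) stop("`level` must be 0, 1, 2 or 3")
  pl <- lengths(level_paths)
  if (level == 0L && any(pl != 0L))
    stop("flat collections (level 0) must have empty level paths")
  if (level > 0L && any(pl != level))
    stop("every set in a level-", level, " collection needs a length-",
         level, " path")
  structure(list(sets = sets, descriptions = descriptions,
                 level_paths = level_paths, level = level),
            class = "geneset_collection")
}

#' @export
length.geneset_collection <- function(x) length(x$sets)

#' @export
names.geneset_collection <- function(x) names(x$sets)

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("geneset_collection: %d sets (hierarchy level %d)\n",
              length(x), x$level))
  sz <- lengths(x$sets)
  if (length(x))
    cat(sprintf("  set sizes: min %d, median %g, max %d\n",
                min(sz), stats::median(sz), max(sz)))
  invisible(x)
}

#' @export
`[.geneset_collection` <- function(x, i) {
  geneset_collection(x$sets[i], x$descriptions[i], x$level_paths[i], x$level)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: one set per line, fields are
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.  Line order is preserved;
#' duplicated genes within a line are dropped (first occurrence kept) with a
#' warning.  Duplicate set names or malformed lines are hard errors naming
#' the offending line.
#'
#' @param path path to a GMT file (UTF-8).
#' @return a flat [geneset_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1L],
         " has fewer than 3 tab-separated fields")
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate set name '", nm[duplicated(nm)][1L],
         "' at line ", which(duplicated(nm))[1L])
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(sets, anyDuplicated, integer(1)) > 0L)
  if (ndup > 0L)
    warning(ndup, " set(s) contained duplicated genes; first occurrence kept")
  sets <- lapply(sets, function(g) g[!duplicated(g)])
  names(sets) <- nm
  geneset_collection(sets, descriptions = desc)
}

#' Write a collection to GMT
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(x, f))` reproduces `x`
#' (hierarchy paths are not representable in GMT and are dropped).
#'
#' @param collection a `geneset_collection`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "geneset_collection"))
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(names(collection$sets)[i], collection$descriptions[[i]],
            collection$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Build per-level collections from hierarchical annotation records
#'
#' Takes gene-to-pathway annotation rows of the form
#' (gene, level-1 label, level-2 label, level-3 label) -- the layout of
#' MitoCarta-style hierarchical catalogues -- and returns one collection per
#' hierarchy depth.  The level-k collection has one set per distinct
#' depth-k path; its members are the union of all genes annotated at or
#' below that path.  A gene may belong to several paths.  Set names for
#' depth >= 2 join the path labels with `" > "`.
#'
#' @param records data.frame with columns `gene`, `level1`, `level2`,
#'   `level3` (deeper labels may be blank `""` or `NA`).
#' @return list with components `level1`, `level2`, `level3`, each a
#'   [geneset_collection()] (possibly containing zero sets).
#' @export
build_hierarchy <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("gene", "level1", "level2", "level3")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "))
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    trimws(x)
  }
  g  <- norm(records$gene)
  l1 <- norm(records$level1); l2 <- norm(records$level2); l3 <- norm(records$level3)
  if (any(!nzchar(g))) stop("record ", which(!nzchar(g))[1L], " has a blank gene symbol")
  if (any(!nzchar(l1))) stop("record ", which(!nzchar(l1))[1L], " has a blank level-1 label")
  broken <- !nzchar(l2) & nzchar(l3)
  if (any(broken))
    stop("broken path at record ", which(broken)[1L],
         ": blank level-2 label with non-blank level-3 label")

  collect <- function(keys, genes) {
    keep <- nzchar(keys)
    if (!any(keep)) return(list())
    sp <- split(genes[keep], keys[keep])
    sp <- lapply(sp, function(x) x[!duplicated(x)])
    # preserve first-appearance order of paths
    sp[unique(keys[keep])]
  }
  sep <- " > "
  k1 <- l1
  k2 <- ifelse(nzchar(l2), paste(l1, l2, sep = sep), "")
  k3 <- ifelse(nzchar(l3), paste(l1, l2, l3, sep = sep), "")
  mk <- function(sets, lev) {
    if (!length(sets))
      return(geneset_collection(stats::setNames(list(), character(0)),
                                level_paths = list(), level = lev))
    paths <- strsplit(names(sets), sep, fixed = TRUE)
    geneset_collection(sets, level_paths = paths, level = lev)
  }
  list(level1 = mk(collect(k1, g), 1L),
       level2 = mk(collect(k2, g), 2L),
       level3 = mk(collect(k3, g), 3L))
}

#' Read hierarchical annotations from TSV
#'
#' Expects a UTF-8 tab-separated file with header
#' `gene<TAB>level1<TAB>level2<TAB>level3` and passes the rows to
#' [build_hierarchy()].
#'
#' @param path path to the TSV file.
#' @return list of three collections, as [build_hierarchy()].
#' @export
read_hierarchy_tsv <- function(path) {
  if (!file.exists(path)) stop("hierarchy file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  build_hierarchy(df)
}

#' Restrict a collection to a gene universe
#'
#' Intersects every set with the genes present in an expression matrix and
#' applies size filters; required before scoring so that every enrichment
#' walk is well-defined.  Idempotent for a fixed universe.
#'
#' @param collection a `geneset_collection`.
#' @param universe character vector of available gene identifiers
#'   (typically `rownames(expr)`).
#' @param min_size minimum retained set size (default 3).
#' @param max_size maximum retained set size (default `Inf`).
#' @return list with `collection` (filtered, order preserved) and `report`,
#'   a data.frame with one row per input set: `set`, `original_size`,
#'   `retained_size`, `coverage`, `dropped`, `reason`.
#' @export
restrict_to_matrix <- function(collection, universe, min_size = 3L,
                               max_size = Inf) {
  stopifnot(inherits(collection, "geneset_collection"))
  universe <- as.character(universe)
  if (!length(universe)) stop("`universe` must be non-empty")
  if (min_size < 1L) stop("`min_size` must be >= 1")
  nm <- names(collection$sets)
  inter <- lapply(collection$sets, function(g) g[g %in% universe])
  orig <- lengths(collection$sets)
  kept <- lengths(inter)
  reason <- rep("", length(nm))
  reason[kept < min_size] <- sprintf("retained size %d < min_size %d",
                                     kept[kept < min_size], as.integer(min_size))
  toobig <- kept > max_size & !nzchar(reason)
  reason[toobig] <- sprintf("retained size %d > max_size %g", kept[toobig],
                            max_size)
  dropped <- nzchar(reason)
  report <- data.frame(set = nm, original_size = as.integer(orig),
                       retained_size = as.integer(kept),
                       coverage = ifelse(orig > 0, kept / orig, 0),
                       dropped = dropped, reason = reason,
                       stringsAsFactors = FALSE, row.names = NULL)
  if (all(dropped)) stop("no scorable sets after restriction to universe")
  keep_idx <- which(!dropped)
  out <- geneset_collection(inter[keep_idx],
                            descriptions = collection$descriptions[keep_idx],
                            level_paths = collection$level_paths[keep_idx],
                            level = collection$level)
  list(collection = out, report = report)
}
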