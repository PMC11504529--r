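#' Read an expression table
#'
#' Supports dense TSV/CSV (genes in rows, header row of sample ids, first
#' column gene ids) and MatrixMarket triplet format with companion gene and
#' barcode list files. Duplicate gene rows are rejected rather than silently
#' merged.
#'
#' @param path Path to the table (for `mtx-triplet`, the `.mtx` file).
#' @param format One of `"tsv"`, `"csv"`, `"mtx-triplet"`.
#' @param unit Declared unit of the values (`"counts"`, `"normalized"`,
#'   `"lognorm"`). The unit is declared, never guessed.
#' @param genes_path,cells_path Companion files for `mtx-triplet`: one
#'   gene id / one cell barcode per line. Default to `<stem>.genes.txt` and
#'   `<stem>.cells.txt` next to the `.mtx` file.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "csv", "mtx-triplet"),
                            unit = "normalized",
                            genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = NA)
    if (ncol(df) < 2) stop("expression table needs >= 1 sample column")
    gene_ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in expression table")
    expression_matrix(m, gene_ids, colnames(df)[-1], unit = unit)
  } else {
    stem <- sub("\\.mtx$", "", path)
    if (is.null(genes_path)) genes_path <- paste0(stem, ".genes.txt")
    if (is.null(cells_path)) cells_path <- paste0(stem, ".cells.txt")
    if (!file.exists(genes_path)) stop("gene list not found: ", genes_path)
    if (!file.exists(cells_path)) stop("cell list not found: ", cells_path)
    sp <- Matrix::readMM(path)
    gene_ids <- readLines(genes_path)
    cell_ids <- readLines(cells_path)
    if (nrow(sp) != length(gene_ids)) {
      stop("MTX has ", nrow(sp), " rows but gene list has ", length(gene_ids))
    }
    if (ncol(sp) != length(cell_ids)) {
      stop("MTX has ", ncol(sp), " cols but cell list has ", length(cell_ids))
    }
    expression_matrix(as.matrix(sp), gene_ids, cell_ids, unit = unit)
  }
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]; round-trips exactly for the dense formats
#' and up to dense/sparse representation for MTX.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @param format One of `"tsv"`, `"csv"`, `"mtx-triplet"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "csv", "mtx-triplet")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  format <- match.arg(format)
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(gene_id = x$gene_ids, x$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("gene_id", x$sample_ids)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    stem <- sub("\\.mtx$", "", path)
    sp <- methods::as(methods::as(Matrix::Matrix(x$values, sparse = TRUE),
                                  "CsparseMatrix"), "generalMatrix")
    Matrix::writeMM(sp, path)
    writeLines(x$gene_ids, paste0(stem, ".genes.txt"))
    writeLines(x$sample_ids, paste0(stem, ".cells.txt"))
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then gene symbols, tab-separated.
#' Duplicate genes within a set are deduplicated with a warning; duplicate
#' set names are an error. An empty file yields an empty collection.
#'
#' @param path Path to a `.gmt` file.
#' @return A `GeneSetCollection`: named list of character vectors with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line ", i, " has < 3 fields")
    nm <- f[1]
    if (nm %in% names(sets)) stop("duplicate set name: ", nm)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("set '", nm, "': duplicate genes removed")
      genes <- unique(genes)
    }
    if (!length(genes)) stop("GMT line ", i, " (", nm, ") has no genes")
    sets[[nm]] <- genes
    desc[nm] <- f[2]
  }
  gene_set_collection(sets, desc)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character gene vectors; names unique, sets
#'   nonempty.
#' @param description Optional named character vector of descriptions.
#' @return A `GeneSetCollection` object.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (length(sets) && is.null(names(sets))) stop("sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate set names")
  if (any(!lengths(sets))) stop("empty gene set: ",
                                names(sets)[!lengths(sets)][1])
  sets <- lapply(sets, as.character)
  structure(sets, description = description, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection:", length(x), "sets,",
      length(unique(unlist(x))), "unique genes\n")
  invisible(x)
}

#' Write a gene-set collection to GMT
#' @param sets A `GeneSetCollection` or named list of gene vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical phenotype table
#'
#' TSV with columns `sample_id`, `state` (tumor/control), optional `group`
#' (low/moderate/high), optional `time` (> 0) and `event` (0/1). Column names
#' are configurable.
#'
#' @param path Path to the TSV.
#' @param columns Named character vector mapping canonical names
#'   (`sample_id`, `state`, `group`, `time`, `event`) to the file's headers.
#' @return A validated `data.frame` with canonical column names.
#' @export
read_clinical <- function(path,
                          columns = c(sample_id = "sample_id", state = "state",
                                      group = "group", time = "time",
                                      event = "event")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "state")
  for (cn in need) {
    if (!columns[[cn]] %in% colnames(df)) {
      stop("clinical table lacks required column '", columns[[cn]], "'")
    }
  }
  out <- data.frame(sample_id = as.character(df[[columns[["sample_id"]]]]),
                    state = as.character(df[[columns[["state"]]]]),
                    stringsAsFactors = FALSE)
  for (cn in c("group", "time", "event")) {
    if (columns[[cn]] %in% colnames(df)) out[[cn]] <- df[[columns[[cn]]]]
  }
  validate_clinical(out)
}

#' Validate a clinical table against its invariants
#' @param df Data frame with canonical clinical columns.
#' @return `df`, invisibly validated (returned visibly).
#' @export
validate_clinical <- function(df) {
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  bad_state <- setdiff(unique(df$state), c("tumor", "control"))
  if (length(bad_state)) stop("unknown state value(s): ",
                              paste(bad_state, collapse = ", "))
  if (!is.null(df$group)) {
    bad_g <- setdiff(unique(stats::na.omit(df$group)),
                     c("low", "moderate", "high"))
    if (length(bad_g)) stop("unknown group value(s): ",
                            paste(bad_g, collapse = ", "))
  }
  if (!is.null(df$time)) {
    bad <- which(!is.na(df$time) & df$time <= 0)
    if (length(bad)) stop("nonpositive survival time at row(s): ",
                          paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.null(df$event)) {
    bad <- which(!is.na(df$event) & !(df$event %in% c(0, 1)))
    if (length(bad)) stop("event outside {0,1} at row(s): ",
                          paste(utils::head(bad, 5), collapse = ", "))
  }
  df
}

#' Write a clinical table
#' @param df Canonical clinical data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Central collection of the pipeline's tunable thresholds and
#' hyperparameters, each with its default. Pass overrides as named arguments.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `RunConfig`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # deconvolution
    n_perm = 100L,
    # ssGSEA
    alpha = 0.25,
    ssgsea_normalize = FALSE,
    # immunoactivity grouping
    k_groups = 3L,
    boot_reps = 1000L,
    # differential expression
    lfc_thresh = 1,
    padj_thresh = 0.05,
    # co-expression modules
    soft_powers = c(1:10, 12, 14, 16),
    scale_free_r2 = 0.8,
    default_power = 6L,
    min_module_size = 30L,
    cut_height = 0.8,
    kme_thresh = 0.75,
    trait_cor_flag = 0.85,
    # single-cell QC
    min_cells_per_gene = 100L,
    min_features_create = 300L,
    min_features_filter = 500L,
    max_mito_frac = 0.05,
    mito_prefix = "MT-",
    scale_factor = 10000,
    n_hvg = 2000L,
    clip_z = 10,
    k_neighbors = 20L,
    resolution = 1,
    # phenotype linkage
    lambda = NULL,        # NULL = path search
    alpha_mix = 0.5,
    graph_k = 10L,
    prox_tol = 1e-6,
    prox_max_iter = 2000L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "RunConfig")
}
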