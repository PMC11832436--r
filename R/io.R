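#' @keywords internal
validate_expression <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate gene id(s): ",
         paste(unique(rownames(matrix)[duplicated(rownames(matrix))]), collapse = ", "))
  if (anyDuplicated(colnames(matrix)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(matrix)[duplicated(colnames(matrix))]), collapse = ", "))
  if (anyNA(matrix)) stop("expression matrix contains missing values")
  if (any(matrix < 0)) stop("expression matrix contains negative values")
  invisible(matrix)
}

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a header row of sample identifiers and one row per gene with the
#' gene identifier in the first column; values are linear-scale, non-negative
#' intensities. Lines starting with `#` are comments. Duplicated gene or
#' sample identifiers, missing cells, negative values and ragged rows are
#' errors, not warnings: downstream fold-change arithmetic silently corrupts
#' on any of them.
#'
#' @param path Path to the TSV file.
#' @param alias_map Optional two-column data.frame (`alias`, `gene_id`) applied
#'   to the gene identifiers at load; never applied implicitly.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, alias_map = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) stop("expression TSV needs a header and >= 1 gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  ncol_expected <- length(header)
  width <- lengths(fields[-1L])
  if (any(width != ncol_expected)) {
    bad <- which(width != ncol_expected)[1L] + 1L
    stop("ragged row at line ", bad, ": expected ", ncol_expected,
         " fields, got ", width[bad - 1L])
  }
  genes <- vapply(fields[-1L], `[[`, character(1L), 1L)
  values <- vapply(fields[-1L], function(f) suppressWarnings(as.numeric(f[-1L])),
                   numeric(ncol_expected - 1L))
  mat <- if (is.matrix(values)) t(values) else matrix(values, ncol = ncol_expected - 1L)
  rownames(mat) <- genes
  colnames(mat) <- header[-1L]
  if (!is.null(alias_map)) {
    hit <- match(rownames(mat), alias_map[[1L]])
    rownames(mat)[!is.na(hit)] <- alias_map[[2L]][hit[!is.na(hit)]]
  }
  validate_expression(mat)
  mat
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]; the first column is the gene identifier,
#' the header carries sample identifiers. Optional `#`-prefixed comment lines
#' (e.g. recording the simulation seed) precede the header.
#'
#' @param matrix Expression matrix.
#' @param path Output path.
#' @param comments Character vector of comment lines (without the leading `#`).
#' @export
write_expression <- function(matrix, path, comments = character()) {
  validate_expression(matrix)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(c("gene_id", colnames(matrix)), collapse = "\t"), con)
  body <- apply(matrix, 1L, function(v)
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  invisible(path)
}

metadata_cols <- c("sample_id", "group", "sex", "steatosis",
                   "lobular_inflammation", "ballooning", "nas", "fibrosis",
                   "study_id")

#' Read sample metadata (CSV or TSV)
#'
#' Columns: `sample_id`, `group` (control/patient), `sex` (F/M/unknown),
#' histology scores `steatosis` (0-3), `lobular_inflammation` (0-3),
#' `ballooning` (0-2), `nas` (0-8), `fibrosis` (0-4), and `study_id`. Empty
#' fields are missing values and are never imputed: real biopsy cohorts report
#' per-variable N. When all three NAS components are present, `nas` must equal
#' their sum.
#'
#' @param path Path to a CSV (default) or TSV file.
#' @param sep Field separator, `","` or `"\t"`.
#' @return data.frame with the columns above.
#' @export
read_metadata <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  missing_cols <- setdiff(c("sample_id", "group"), names(df))
  if (length(missing_cols))
    stop("metadata lacks required column(s): ", paste(missing_cols, collapse = ", "))
  for (col in setdiff(metadata_cols, names(df))) df[[col]] <- NA
  validate_metadata(df)
  df[, metadata_cols]
}

#' @keywords internal
validate_metadata <- function(df) {
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(df$group %in% c("control", "patient")))
    stop("group must be 'control' or 'patient'")
  rng <- list(steatosis = 3, lobular_inflammation = 3, ballooning = 2,
              nas = 8, fibrosis = 4)
  for (v in names(rng)) {
    x <- df[[v]]
    if (any(!is.na(x) & (x < 0 | x > rng[[v]])))
      stop(v, " outside 0-", rng[[v]])
  }
  comp <- df$steatosis + df$lobular_inflammation + df$ballooning
  ok <- is.na(comp) | is.na(df$nas) | df$nas == comp
  if (!all(ok)) stop("nas does not equal the sum of its components for sample(s): ",
                     paste(df$sample_id[!ok], collapse = ", "))
  invisible(df)
}

#' Write sample metadata to CSV
#' @param meta Metadata data.frame.
#' @param path Output path.
#' @export
write_metadata <- function(meta, path) {
  validate_metadata(meta)
  utils::write.csv(meta, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then members, tab-separated. Members
#' duplicated within a set are deduplicated with a warning. An empty file
#' yields an empty collection (with a warning); a line with fewer than three
#' fields is a parse error.
#'
#' @param path Path to the GMT file.
#' @param category Category tag for the whole collection: one of `pathway`,
#'   `immune_marker`, `matrisome`, `target_panel`.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors), `descriptions` (named character) and `category`.
#' @export
read_gmt <- function(path, category = c("pathway", "immune_marker",
                                        "matrisome", "target_panel")) {
  category <- match.arg(category)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(list(), character(), category))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    stop("GMT parse error at line ", which(short)[1L], ": fewer than 3 fields")
  nm <- vapply(fields, `[[`, character(1L), 1L)
  desc <- vapply(fields, `[[`, character(1L), 2L)
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    if (anyDuplicated(members))
      warning("duplicated member(s) in set '", f[[1L]], "'; deduplicated")
    unique(members)
  })
  names(sets) <- nm
  names(desc) <- nm
  gene_set_collection(sets, desc, category)
}

#' Construct a gene-set collection
#' @param sets Named list of character vectors (unique names, nonempty sets).
#' @param descriptions Optional named character vector of descriptions.
#' @param category Category tag.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, descriptions = NULL,
                                category = c("pathway", "immune_marker",
                                             "matrisome", "target_panel")) {
  category <- match.arg(category)
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      stop("set names must be present and unique")
    if (any(lengths(sets) == 0L)) stop("empty gene set(s) not allowed")
  }
  if (is.null(descriptions)) {
    descriptions <- rep("", length(sets))
    names(descriptions) <- names(sets)
  }
  structure(list(sets = sets, descriptions = descriptions, category = category),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection [", x$category, "]: ", length(x$sets),
      " set(s)\n", sep = "")
  if (length(x$sets))
    cat("  sizes: ", paste(utils::head(lengths(x$sets), 10L), collapse = ", "),
        if (length(x$sets) > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Write a gene-set collection to GMT
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    desc <- collection$descriptions[[nm]]
    if (!nzchar(desc)) desc <- "na"
    paste(c(nm, desc, collection$sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column evidence/target list (gene id, source tag)
#' @param path TSV path with optional header `gene_id<TAB>source`.
#' @return data.frame with columns `gene_id`, `source`.
#' @export
read_target_list <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("gene_id", "source"))
  if (identical(tolower(df$gene_id[1L]), "gene_id")) df <- df[-1L, , drop = FALSE]
  rownames(df) <- NULL
  df
}
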