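#' Read a 10x-style MatrixMarket count triplet
#'
#' Reads `matrix.mtx` (coordinate integer MatrixMarket), a genes annotation
#' file (one or two tab-separated columns: id, optional symbol) and a
#' one-column barcodes file, returning a sparse gene x cell count matrix.
#' Gzipped files (`.gz`) are accepted for all three parts. MatrixMarket
#' coordinates are 1-based per the standard; any index conversion is confined
#' to this reader.
#'
#' @param matrix_path path to the `.mtx` file.
#' @param genes_path path to `genes.tsv` (id and optional symbol column; the
#'   symbol is used as the row name when present).
#' @param barcodes_path path to `barcodes.tsv`.
#' @param on_duplicate `"error"` (default) or `"suffix"`: duplicated gene
#'   names are rejected, or made unique with numeric suffixes — silent
#'   merging of duplicated symbols would corrupt CV^2 estimates.
#' @return sparse `dgCMatrix`, genes x cells, integer-valued, with a
#'   `gene_table` attribute holding the full annotation.
#' @export
read_counts_mtx <- function(matrix_path, genes_path, barcodes_path,
                            on_duplicate = c("error", "suffix")) {
  on_duplicate <- match.arg(on_duplicate)
  for (f in c(matrix_path, genes_path, barcodes_path))
    if (!file.exists(f)) stop("file not found: ", f)
  m <- Matrix::readMM(maybe_gunzip(matrix_path))
  vals <- m@x
  if (any(vals < 0)) stop("negative entries in count matrix")
  if (any(vals != round(vals))) stop("non-integer entries in count matrix")
  gt <- utils::read.table(maybe_gunzip(genes_path), sep = "\t",
                          header = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  bc <- readLines(maybe_gunzip(barcodes_path))
  bc <- bc[nzchar(bc)]
  if (nrow(gt) != nrow(m))
    stop(sprintf("matrix declares %d genes but genes file has %d lines",
                 nrow(m), nrow(gt)))
  if (length(bc) != ncol(m))
    stop(sprintf("matrix declares %d cells but barcodes file has %d lines",
                 ncol(m), length(bc)))
  gene_names <- if (ncol(gt) >= 2) gt[[2]] else gt[[1]]
  if (anyDuplicated(gene_names)) {
    if (on_duplicate == "error")
      stop("duplicated gene identifiers: ",
           paste(utils::head(unique(gene_names[duplicated(gene_names)]), 5),
                 collapse = ", "))
    gene_names <- make.unique(gene_names, sep = ".")
  }
  if (anyDuplicated(bc)) stop("duplicated cell barcodes")
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(gene_names, bc)
  attr(m, "gene_table") <- gt
  m
}

maybe_gunzip <- function(path) {
  if (!grepl("\\.gz$", path)) return(path)
  tmp <- tempfile()
  con <- gzfile(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = 1e8)
  writeBin(raw, tmp)
  tmp
}

#' Write a count matrix as a 10x-style triplet
#'
#' @param counts gene x cell matrix with dimnames.
#' @param dir output directory (created if needed); files `matrix.mtx`,
#'   `genes.tsv` (id repeated as symbol), `barcodes.tsv` are written.
#' @return invisibly, the directory.
#' @export
write_counts_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(rownames(counts), rownames(counts)),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a dense expression matrix from TSV
#'
#' Tab-separated file with row and column headers. `orientation` declares
#' whether genes are in rows or in columns; the returned matrix is always
#' genes x samples. Non-numeric cells (including `NA`) are rejected with the
#' offending row and column named.
#'
#' @param path TSV path.
#' @param orientation `"genes_in_rows"` (default) or `"genes_in_columns"`.
#' @param integer_counts if `TRUE`, additionally require nonnegative integer
#'   entries (count input).
#' @return numeric matrix, genes x samples.
#' @export
read_dense_matrix <- function(path,
                              orientation = c("genes_in_rows",
                                              "genes_in_columns"),
                              integer_counts = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "#")
  if (length(unique(nf)) > 1)
    stop("ragged rows in ", path, ": rows have ",
         paste(unique(nf), collapse = ", "), " fields")
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "#")
  x <- suppressWarnings(
    matrix(as.numeric(as.matrix(df)), nrow(df), ncol(df),
           dimnames = list(rownames(df), colnames(df))))
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at row '%s', column '%s' in %s",
                 rownames(x)[idx[1]], colnames(x)[idx[2]], path))
  }
  if (orientation == "genes_in_columns") x <- t(x)
  if (integer_counts && (any(x < 0) || any(x != round(x))))
    stop("count input must contain nonnegative integers")
  x
}

#' Write a matrix as TSV with row and column headers
#' @param x matrix with dimnames.
#' @param path output path.
#' @param header_lines optional `#`-prefixed provenance lines.
#' @export
write_dense_matrix <- function(x, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(
    data.frame(gene = rownames(x), x, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines `name<TAB>description<TAB>gene1<TAB>gene2...`; genes
#' repeated within a line are deduplicated; lines with fewer than 3 fields
#' are a format error.
#'
#' @param path GMT path.
#' @return named list of character vectors; set descriptions in the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 0L) < 3
  if (any(short))
    stop("GMT line ", which(short)[1], " has fewer than 3 fields")
  nm <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(nm)) stop("duplicated gene-set names in ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, "", 2), nm)
  sets
}

#' Read a signed regulatory edge list
#'
#' TSV with three columns: source gene, target gene, sign. Sign tokens `+`,
#' `induction`, `activation` normalize to `"induction"`; `-`, `repression`,
#' `inhibition` to `"repression"`; anything else is a format error, as are
#' duplicated (source, target) pairs.
#'
#' @param path TSV path (lines starting with `#` ignored).
#' @return data.frame with columns `source`, `target`, `sign`.
#' @export
read_signed_edges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (ncol(df) < 3) stop("signed edge file needs 3 tab-separated columns")
  sign_map <- c("+" = "induction", "induction" = "induction",
                "activation" = "induction",
                "-" = "repression", "repression" = "repression",
                "inhibition" = "repression")
  tok <- tolower(trimws(df[[3]]))
  tok[df[[3]] == "+"] <- "+"; tok[df[[3]] == "-"] <- "-"
  bad <- !(tok %in% names(sign_map))
  if (any(bad))
    stop("unknown sign token '", df[[3]][which(bad)[1]], "' at line ",
         which(bad)[1])
  out <- data.frame(source = df[[1]], target = df[[2]],
                    sign = unname(sign_map[tok]), stringsAsFactors = FALSE)
  if (anyDuplicated(out[, c("source", "target")]))
    stop("duplicated (source, target) pairs in edge list")
  out
}

#' Write the per-gene statistics table
#'
#' Fixed column order: gene, mean, cv2_obs, cv2_exp, ratio,
#' residual_variability, pvalue, qvalue, is_hvg.
#'
#' @param stats full per-gene table (from [adjust_and_call()] / [sc_hvg()]).
#' @param path output TSV path.
#' @param header_lines optional `#`-prefixed provenance lines.
#' @export
write_gene_stats <- function(stats, path, header_lines = character()) {
  cols <- c("gene", "mean", "cv2_obs", "cv2_exp", "ratio",
            "residual_variability", "pvalue", "qvalue", "is_hvg")
  missing <- setdiff(cols, names(stats))
  if (length(missing))
    stop("stats table lacks columns: ", paste(missing, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(stats[, cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a per-gene statistics table written by [write_gene_stats()]
#' @param path TSV path.
#' @return data.frame in the fixed column order.
#' @export
read_gene_stats <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "#")
}
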