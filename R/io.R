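#' Read a CellRanger-style filtered matrix bundle
#'
#' Reads a directory containing `matrix.mtx`, `features.tsv` (or `genes.tsv`)
#' and `barcodes.tsv`, each optionally gzipped, into a genes x cells integer
#' count matrix. Rows sharing the same gene symbol (distinct transcript IDs)
#' are summed into a single row.
#'
#' @param path directory containing the three sidecar files.
#' @return A sparse `dgCMatrix` (genes x cells) with unique symbol rownames
#'   and barcode colnames.
#' @export
read_mtx_bundle <- function(path) {
  find1 <- function(stems) {
    for (s in stems) for (ext in c("", ".gz")) {
      f <- file.path(path, paste0(s, ext))
      if (file.exists(f)) return(f)
    }
    stop("no file matching ", paste(stems, collapse = "/"), " under ", path)
  }
  mtx  <- find1("matrix.mtx")
  feat <- find1(c("features.tsv", "genes.tsv"))
  bar  <- find1("barcodes.tsv")
  m <- Matrix::readMM(mtx)
  features <- utils::read.table(feat, sep = "\t", header = FALSE,
                                colClasses = "character", quote = "")
  barcodes <- utils::read.table(bar, sep = "\t", header = FALSE,
                                colClasses = "character", quote = "")[[1]]
  if (nrow(features) != nrow(m))
    stop("format error: features file has ", nrow(features),
         " rows but matrix has ", nrow(m))
  if (length(barcodes) != ncol(m))
    stop("format error: barcodes file has ", length(barcodes),
         " entries but matrix has ", ncol(m), " columns")
  # symbol column: CellRanger puts id, symbol[, type]; 1-column files are symbols
  symbols <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  m <- methods::as(m, "CsparseMatrix")
  if (anyDuplicated(symbols)) {
    grp <- factor(symbols, levels = unique(symbols))
    # fac2sparse gives a levels x genes indicator; indicator %*% m sums rows
    agg <- Matrix::fac2sparse(grp) %*% m
    rownames(agg) <- levels(grp)
    m <- methods::as(agg, "CsparseMatrix")
  } else {
    rownames(m) <- symbols
  }
  colnames(m) <- barcodes
  m
}

#' Write a CellRanger-style matrix bundle
#'
#' @param counts genes x cells matrix (dense or sparse).
#' @param path output directory (created if missing).
#' @param gzip compress the three files.
#' @return `path`, invisibly.
#' @export
write_mtx_bundle <- function(counts, path, gzip = FALSE) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "dMatrix"),
                   "CsparseMatrix")
  ext <- if (gzip) ".gz" else ""
  opener <- if (gzip) gzfile else file
  f <- file.path(path, paste0("matrix.mtx", ext))
  if (gzip) {
    tmp <- tempfile(fileext = ".mtx")
    Matrix::writeMM(m, tmp)
    con <- gzfile(f, "wb"); writeLines(readLines(tmp), con); close(con)
    unlink(tmp)
  } else {
    Matrix::writeMM(m, f)
  }
  con <- opener(file.path(path, paste0("features.tsv", ext)), "w")
  writeLines(paste(rownames(counts), rownames(counts), "Gene Expression",
                   sep = "\t"), con)
  close(con)
  con <- opener(file.path(path, paste0("barcodes.tsv", ext)), "w")
  writeLines(colnames(counts), con)
  close(con)
  invisible(path)
}

#' Read a reference class-mean expression table
#'
#' CSV with populations as rows and genes as columns (first column =
#' population name). Optional sidecar columns are not supported; lineage and
#' retain information is supplied separately or via [simulate_reference_profiles()].
#'
#' @param path CSV file.
#' @param lineage optional named character vector population -> lineage.
#' @param retain optional character vector of populations to keep downstream.
#' @return A `ReferenceProfiles` list: `profiles` (populations x genes matrix),
#'   `lineage`, `retain`.
#' @export
read_profile_table <- function(path, lineage = NULL, retain = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE)
  pops <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("format error: non-numeric expression field")
  rownames(mat) <- pops
  if (is.null(lineage)) lineage <- stats::setNames(pops, pops)
  list(profiles = mat, lineage = lineage, retain = retain)
}

#' @rdname read_profile_table
#' @param profiles a `ReferenceProfiles` list.
#' @export
write_profile_table <- function(profiles, path) {
  df <- data.frame(population = rownames(profiles$profiles),
                   profiles$profiles, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bulk RNA-seq count table
#'
#' TSV/CSV with a header row; first column gene symbols, remaining columns
#' samples. Duplicate symbols are summed, mirroring the single-cell reader.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.csv` = comma, otherwise tab).
#' @return genes x samples numeric matrix.
#' @export
read_bulk_counts <- function(path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE, quote = "",
                           check.names = FALSE)
  genes <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("format error: non-numeric count field")
  if (any(mat < 0)) stop("format error: negative count")
  if (anyDuplicated(genes)) {
    mat <- rowsum(mat, group = genes, reorder = FALSE)
  } else {
    rownames(mat) <- genes
  }
  mat
}

#' Read a GMT gene-set library
#'
#' Each line: `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path GMT file.
#' @return Named list of character vectors (unique members, empty members
#'   dropped).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("format error: GMT line with <3 fields")
    unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n)
    paste(c(n, n, sets[[n]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column ortholog mapping table
#'
#' TSV with header; column 1 = source symbol, column 2 = target symbol.
#'
#' @param path TSV file.
#' @return named character vector (source -> target).
#' @export
read_ortholog_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "")
  stats::setNames(tab[[2]], tab[[1]])
}

#' Write per-cell / per-gene annotation tables
#'
#' TSV writers with a stable column order (as given in the data frame);
#' row names are written as a leading `id` column when present.
#'
#' @param table a data.frame.
#' @param path output file.
#' @export
write_cell_table <- function(table, path) {
  df <- table
  if (!is.null(rownames(df)) && !identical(rownames(df), as.character(seq_len(nrow(df)))))
    df <- data.frame(id = rownames(df), df, row.names = NULL, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
write_gene_table <- write_cell_table
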