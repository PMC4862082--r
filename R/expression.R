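#' Construct an expression experiment
#'
#' Expression data live in a [SummarizedExperiment::SummarizedExperiment]
#' whose single assay holds non-negative gene x sample values, whose
#' \code{colData} carries the sample metadata (\code{batch},
#' \code{cell_type}, \code{individual} — any may be absent), and whose
#' \code{metadata()$unit} records the measurement unit (\code{"UMI"},
#' \code{"CPM"}, \code{"RPKM"}, \code{"binary"} or \code{"corrected"}).
#' Duplicate gene ids are collapsed by taking the mean of their rows.
#'
#' @param values numeric matrix, genes x samples, non-negative.
#' @param gene_ids character vector of gene labels (defaults to rownames).
#' @param sample_ids character vector of sample labels (defaults to colnames).
#' @param sample_meta data.frame of per-sample metadata, matched to
#'   \code{sample_ids} by its \code{sample_id} column when present,
#'   otherwise by row order/names. Samples missing from the table get NA.
#' @param unit measurement unit tag.
#' @return a \code{SummarizedExperiment}
#' @export
ExpressionExperiment <- function(values, gene_ids = rownames(values),
                                 sample_ids = colnames(values),
                                 sample_meta = NULL,
                                 unit = c("UMI", "CPM", "RPKM", "binary",
                                          "corrected")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample ids are required")
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("dimension mismatch between matrix and id lists")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative")
  if (unit == "UMI" && any(values != round(values)))
    stop("UMI values must be integer counts")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids")

  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) {
    # collapse duplicate gene rows by their mean value
    values <- rowsum(values, group = gene_ids, reorder = FALSE) /
      as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
    gene_ids <- unique(gene_ids)
  }
  dimnames(values) <- list(gene_ids, sample_ids)

  cd <- S4Vectors::DataFrame(row.names = sample_ids)
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    key <- if ("sample_id" %in% names(sample_meta)) {
      as.character(sample_meta$sample_id)
    } else if (!is.null(rownames(sample_meta)) &&
               !identical(rownames(sample_meta),
                          as.character(seq_len(nrow(sample_meta))))) {
      rownames(sample_meta)
    } else {
      if (nrow(sample_meta) != length(sample_ids))
        stop("sample_meta without sample_id must have one row per sample")
      sample_ids
    }
    idx <- match(sample_ids, key)  # permissive: unmatched samples get NA
    keep <- setdiff(names(sample_meta), "sample_id")
    for (col in keep) cd[[col]] <- sample_meta[[col]][idx]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values), colData = cd)
  S4Vectors::metadata(se)$unit <- unit
  se
}

#' @rdname ExpressionExperiment
#' @param se a \code{SummarizedExperiment} built by this package
#' @export
expressionUnit <- function(se) {
  u <- S4Vectors::metadata(se)$unit
  if (is.null(u)) "UMI" else u
}

`expressionUnit<-` <- function(se, value) {
  S4Vectors::metadata(se)$unit <- value
  se
}

exprValues <- function(se) SummarizedExperiment::assay(se, 1L)

#' Read an expression matrix from disk
#'
#' Dense TSV (gene ids in the first column, sample ids in the header) or a
#' MatrixMarket trio (\code{matrix.mtx} plus \code{genes.tsv} and
#' \code{barcodes.tsv} in the same directory). Duplicate gene rows are
#' collapsed by their mean. Sample metadata, if given, is joined by sample
#' id; samples absent from the table simply get missing metadata.
#'
#' @param path file path (for \code{mtx}, the \code{.mtx} file; companions
#'   are looked up beside it).
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @param sample_meta optional data.frame or path to a TSV with a header and
#'   a \code{sample_id} column.
#' @param unit measurement unit tag for the values on disk.
#' @return a \code{SummarizedExperiment}
#' @export
readExpression <- function(path, format = c("tsv", "mtx"), sample_meta = NULL,
                           unit = "UMI") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(sample_meta))
    sample_meta <- read.delim(sample_meta, check.names = FALSE)
  if (format == "tsv") {
    tab <- read.delim(path, check.names = FALSE)
    genes <- as.character(tab[[1L]])
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(vals)) stop("unparseable expression values in ", path)
    rownames(vals) <- genes
  } else {
    dir <- dirname(path)
    m <- Matrix::readMM(path)
    genes <- read.delim(file.path(dir, "genes.tsv"), header = FALSE)[[1L]]
    cells <- read.delim(file.path(dir, "barcodes.tsv"), header = FALSE)[[1L]]
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop("dimension mismatch between matrix and id lists")
    vals <- as.matrix(m)
    dimnames(vals) <- list(as.character(genes), as.character(cells))
  }
  ExpressionExperiment(vals, sample_meta = sample_meta, unit = unit)
}

#' Write an expression matrix to disk
#'
#' @param se a \code{SummarizedExperiment}
#' @param path output path (TSV) or \code{.mtx} path (the gene and barcode
#'   lists are written beside it).
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @return \code{path}, invisibly
#' @export
writeExpression <- function(se, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  vals <- exprValues(se)
  if (format == "tsv") {
    tab <- data.frame(gene_id = rownames(vals), vals, check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(vals, sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(rownames(vals), file.path(dir, "genes.tsv"))
    writeLines(colnames(vals), file.path(dir, "barcodes.tsv"))
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each GMT line is \code{name<TAB>description<TAB>member...}. All genes
#' named anywhere in the file form the row universe; restriction to a
#' network's gene universe happens later, at annotation filtering.
#'
#' @param path GMT file path.
#' @param exclude_iea drop sets whose description contains the tag
#'   \code{"IEA"} (electronically inferred annotations), as used when
#'   building the semantic-similarity matrix.
#' @return an [AnnotationMatrix-class]
#' @export
readGmt <- function(path, exclude_iea = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1L])
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate set names in GMT: ",
                               ids[duplicated(ids)][1L])
  desc <- vapply(parts, `[[`, "", 2L)
  members <- lapply(parts, function(p) unique(p[-(1:2)]))
  if (exclude_iea) {
    keep <- !grepl("IEA", desc, fixed = TRUE)
    ids <- ids[keep]; members <- members[keep]
  }
  universe <- sort(unique(unlist(members)))
  m <- matrix(0, length(universe), length(ids),
              dimnames = list(universe, ids))
  for (k in seq_along(ids)) m[members[[k]], k] <- 1
  newAnnotation(m)
}

#' Write gene sets to a GMT file
#'
#' @param annotations an [AnnotationMatrix-class] or a named list of
#'   character vectors.
#' @param path output path.
#' @param descriptions optional per-set description column.
#' @return \code{path}, invisibly
#' @export
writeGmt <- function(annotations, path, descriptions = NULL) {
  sets <- if (is(annotations, "AnnotationMatrix")) {
    m <- membership(annotations)
    lapply(setNames(seq_len(ncol(m)), colnames(m)),
           function(k) rownames(m)[m[, k] == 1])
  } else annotations
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, g) paste(c(nm, d, g), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
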