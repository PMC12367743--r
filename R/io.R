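# Readers/writers for the expression matrix, sample metadata, GMT gene sets
# (with an optional per-gene sign sidecar), and clinical/survival tables.
#
# TSV dialect, enforced everywhere: tab-separated, UTF-8, '.' decimal point,
# no quoting, no missing cells. Gene and sample identifiers are opaque
# strings; no symbol mapping is attempted.

#' Validate a log2 expression matrix
#'
#' @param expr numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids), values on the log2 scale.
#' @return `expr`, invisibly, after validation.
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop2("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop2("expression must have gene rownames and sample colnames")
  dup_g <- unique(rownames(expr)[duplicated(rownames(expr))])
  if (length(dup_g))
    stop2("duplicate gene id(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(expr)[duplicated(colnames(expr))])
  if (length(dup_s))
    stop2("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  if (any(!is.finite(expr))) {
    bad <- which(!is.finite(expr), arr.ind = TRUE)[1, ]
    stop2("non-finite expression value at gene '", rownames(expr)[bad[1]],
          "', sample '", colnames(expr)[bad[2]], "'")
  }
  invisible(expr)
}

#' Read a genes x samples log2 expression matrix from TSV
#'
#' First column holds gene ids, header row holds sample ids. Row and column
#' order are preserved as in the file. Duplicate ids, non-numeric cells and
#' ragged rows are rejected with coordinates in the message.
#'
#' @param path path to a TSV file.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2) stop2("expression file needs a header and >= 1 gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  sample_ids <- header[-1]
  n_col <- length(header)
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != n_col)) {
    i <- which(widths != n_col)[1]
    stop2("ragged row ", i + 1, ": expected ", n_col, " fields, found ", widths[i])
  }
  gene_ids <- vapply(body, `[[`, character(1), 1)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(n_col - 1))
  )
  # vapply gives samples in rows; transpose to genes x samples
  m <- if (n_col - 1 == 1) matrix(vals, ncol = 1) else t(vals)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop2("non-numeric cell at gene '", gene_ids[bad[1]],
          "', sample '", sample_ids[bad[2]], "'")
  }
  dimnames(m) <- list(gene_ids, sample_ids)
  validate_expression(m)
  m
}

#' Write an expression matrix as TSV
#'
#' @param expr validated expression matrix.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(expr)), collapse = "\t"), con)
  body <- apply(expr, 1, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE, digits = 15), collapse = "\t"))
  writeLines(paste(rownames(expr), body, sep = "\t"), con)
  invisible(path)
}

#' Validate sample metadata against an expression matrix
#'
#' Required columns: sample_id, patient_id, timepoint (pre/post), arm
#' (BRT/TC), outcome (survivor/deceased), batch. Each patient may have at
#' most one pre and one post sample; every sample_id must be a column of
#' the bound expression matrix when one is supplied.
#'
#' @param meta data.frame of per-sample metadata.
#' @param expr optional expression matrix to bind against.
#' @return `meta`, invisibly.
#' @export
validate_metadata <- function(meta, expr = NULL) {
  need <- c("sample_id", "patient_id", "timepoint", "arm", "outcome", "batch")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop2("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop2("duplicate sample_id in metadata")
  if (!all(meta$timepoint %in% c("pre", "post")))
    stop2("timepoint must be 'pre' or 'post'")
  if (!all(meta$outcome %in% c("survivor", "deceased")))
    stop2("outcome must be 'survivor' or 'deceased'")
  tab <- table(meta$patient_id, meta$timepoint)
  if (any(tab > 1))
    stop2("a patient has more than one sample at a timepoint: ",
          paste(rownames(tab)[apply(tab > 1, 1, any)], collapse = ", "))
  if (!is.null(expr)) {
    absent <- setdiff(meta$sample_id, colnames(expr))
    if (length(absent))
      stop2("metadata sample(s) absent from expression matrix: ",
            paste(absent, collapse = ", "))
  }
  invisible(meta)
}

#' Read sample metadata TSV
#' @param path TSV with columns sample_id, patient_id, timepoint, arm,
#'   outcome, batch.
#' @param expr optional expression matrix to validate against.
#' @return data.frame.
#' @export
read_metadata <- function(path, expr = NULL) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                            fileEncoding = "UTF-8")
  validate_metadata(meta, expr)
  meta
}

#' Write sample metadata TSV
#' @param meta validated metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  validate_metadata(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GMT gene-set collection, with optional sign sidecar
#'
#' Each GMT line is `name TAB description TAB gene1 TAB gene2 ...`. The
#' sidecar is a two-column TSV (gene_id, sign) assigning -1 to genes scored
#' as "low expression"; all other genes default to +1.
#'
#' @param path GMT file path.
#' @param signs_path optional sign sidecar TSV.
#' @return object of class `gene_set_collection`: list with `sets` (named
#'   list of character vectors) and `signs` (named numeric, +1/-1).
#' @export
read_gmt <- function(path, signs_path = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop2("GMT line ", bad[1], " has no genes (need name, description, >= 1 gene)")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop2("duplicate set name in GMT")
  signs <- numeric(0)
  if (!is.null(signs_path)) {
    sg <- utils::read.delim(signs_path, stringsAsFactors = FALSE, quote = "",
                            header = TRUE, fileEncoding = "UTF-8")
    if (ncol(sg) != 2) stop2("sign sidecar must have exactly 2 columns")
    if (!all(sg[[2]] %in% c(-1, 1)))
      stop2("sign values must be +1 or -1; found: ",
            paste(unique(sg[[2]][!sg[[2]] %in% c(-1, 1)]), collapse = ", "))
    signs <- stats::setNames(as.numeric(sg[[2]]), sg[[1]])
  }
  new_gene_set_collection(sets, signs)
}

#' Construct a gene-set collection
#' @param sets named list of character vectors (unique within each set).
#' @param signs named numeric vector of +1/-1 coefficients; genes not named
#'   default to +1.
#' @return object of class `gene_set_collection`.
#' @export
new_gene_set_collection <- function(sets, signs = numeric(0)) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (any(vapply(sets, anyDuplicated, integer(1)) > 0))
    stop2("gene sets must not contain duplicate members")
  if (any(lengths(sets) == 0)) stop2("empty gene set")
  if (length(signs) && !all(signs %in% c(-1, 1)))
    stop2("signs must be +1 or -1")
  structure(list(sets = sets, signs = signs), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets;",
      sum(x$signs == -1), "negative-sign genes\n")
  for (nm in utils::head(names(x$sets), 10))
    cat("  ", nm, " (", length(x$sets[[nm]]), " genes)\n", sep = "")
  invisible(x)
}

#' Look up sign coefficients for a set of genes
#' @param collection a `gene_set_collection`.
#' @param genes character vector of gene ids.
#' @return numeric vector of +1/-1, defaulting to +1.
#' @export
set_signs <- function(collection, genes) {
  s <- rep(1, length(genes))
  hit <- genes %in% names(collection$signs)
  s[hit] <- collection$signs[genes[hit]]
  stats::setNames(s, genes)
}

#' Write a gene-set collection as GMT (+ sign sidecar)
#' @param collection a `gene_set_collection`.
#' @param path output GMT path.
#' @param signs_path optional path for the sign sidecar; written only when
#'   the collection carries any -1 sign.
#' @export
write_gmt <- function(collection, path, signs_path = NULL) {
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, nm, collection$sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path, useBytes = FALSE)
  if (!is.null(signs_path) && length(collection$signs)) {
    utils::write.table(
      data.frame(gene_id = names(collection$signs),
                 sign = as.integer(collection$signs)),
      signs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read survival records TSV
#' @param path TSV with columns patient_id, time_months (> 0), event (0/1),
#'   and optionally a grouping column (e.g. arm).
#' @return data.frame.
#' @export
read_survival <- function(path) {
  sv <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  need <- c("patient_id", "time_months", "event")
  miss <- setdiff(need, names(sv))
  if (length(miss)) stop2("survival table missing column(s): ",
                          paste(miss, collapse = ", "))
  if (any(!is.finite(sv$time_months)) || any(sv$time_months <= 0))
    stop2("time_months must be finite and > 0")
  if (!all(sv$event %in% c(0, 1))) stop2("event must be 0 or 1")
  sv
}

#' Write survival records TSV
#' @param sv survival data.frame.
#' @param path output path.
#' @export
write_survival <- function(sv, path) {
  utils::write.table(sv, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-patient clinical table TSV
#' @param path TSV, one row per patient; first column patient_id.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  cl <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  if (!"patient_id" %in% names(cl)) stop2("clinical table needs patient_id")
  cl
}

#' Write a clinical table TSV
#' @param cl clinical data.frame.
#' @param path output path.
#' @export
write_clinical <- function(cl, path) {
  utils::write.table(cl, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
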