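#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix with unique feature
#' identifiers as row names, unique sample identifiers as column names, no
#' negative values, and a `scale` attribute recording the unit of its entries.
#'
#' @param values numeric matrix, features x samples, with dimnames.
#' @param scale one of `"count"`, `"TPM"`, `"CPM"`, `"abundance"`.
#' @return the validated matrix with the `scale` attribute set.
#' @export
expression_matrix <- function(values, scale = c("count", "TPM", "CPM", "abundance")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  attr(values, "scale") <- scale
  validate_expr_matrix(values)
}

#' @rdname expression_matrix
#' @param x object to validate.
#' @export
validate_expr_matrix <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have feature row names and sample column names",
         call. = FALSE)
  dup_f <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_f) > 0)
    stop("duplicate feature identifiers: ", paste(dup_f, collapse = ", "),
         call. = FALSE)
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s) > 0)
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  neg <- which(x < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative values, e.g. at (", rownames(x)[neg[1, 1]], ", ",
         colnames(x)[neg[1, 2]], ")", call. = FALSE)
  invisible(x)
  x
}

#' Scale of an expression matrix
#' @param x an expression matrix.
#' @return the `scale` attribute, defaulting to `"count"`.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) "count" else s
}

#' Read an expression matrix from delimited text
#'
#' Expects feature identifiers in the first column and sample identifiers in
#' the header. Rejects (rather than coerces) duplicate identifiers, negative
#' values and non-numeric cells, naming the offending coordinates.
#'
#' @param path file path.
#' @param sep field delimiter, default tab.
#' @param scale declared scale of the values (default `"count"`).
#' @return a validated expression matrix.
#' @export
read_matrix <- function(path, sep = "\t", scale = "count") {
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("matrix file needs a feature column plus at least one sample column",
         call. = FALSE)
  feats <- df[[1]]
  dup <- unique(feats[duplicated(feats)])
  if (length(dup) > 0)
    stop("duplicate feature identifiers in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric cell at (", feats[bad[1, 1]], ", ",
         colnames(vals)[bad[1, 2]], "): '", vals[bad[1, 1], bad[1, 2]],
         "'", call. = FALSE)
  dimnames(num) <- list(feats, colnames(vals))
  expression_matrix(num, scale = scale)
}

#' Write an expression matrix as TSV
#' @param x expression matrix.
#' @param path output path.
#' @param feature_col header for the feature column.
#' @export
write_matrix <- function(x, path, feature_col = "feature") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- feature_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' A design table maps each sample to a group label (a cancer subtype or the
#' healthy-control label) and a condition, `"case"` or `"control"`.
#'
#' @param path TSV with columns `sample`, `group`, `condition`.
#' @return a validated data frame.
#' @export
read_design <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  validate_design(df)
}

#' @rdname read_design
#' @param design data frame to validate.
#' @param samples optional sample identifiers that must all be present.
#' @export
validate_design <- function(design, samples = NULL) {
  need <- c("sample", "group", "condition")
  miss <- setdiff(need, colnames(design))
  if (length(miss) > 0)
    stop("design table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dup <- unique(design$sample[duplicated(design$sample)])
  if (length(dup) > 0)
    stop("duplicate samples in design: ", paste(dup, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(design$condition), c("case", "control"))
  if (length(bad) > 0)
    stop("condition must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(samples)) {
    miss <- setdiff(samples, design$sample)
    if (length(miss) > 0)
      stop("samples absent from design: ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  design
}

#' Read a gene-length table
#'
#' Two-column TSV (`feature`, `length` in base pairs). Annotation parsing
#' (GTF/GFF) is deliberately out of scope; lengths come pre-extracted.
#'
#' @param path TSV path.
#' @return named numeric vector of lengths.
#' @export
read_lengths <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("length table needs two columns", call. = FALSE)
  len <- as.numeric(df[[2]])
  if (anyNA(len) || any(len <= 0))
    stop("gene lengths must be positive numbers", call. = FALSE)
  setNames(len, df[[1]])
}

#' Read a qPCR Ct table (wide or long layout, autodetected)
#'
#' Wide layout: first column = feature, remaining columns = samples.
#' Long layout: columns `feature`, `sample`, `ct`. Missing cells are allowed
#' and preserved as `NA`; downstream operations document their missing-data
#' policy.
#'
#' @param path CSV or TSV path (delimiter sniffed from the header line).
#' @return numeric matrix of Ct values, features x samples, `NA` for missing.
#' @export
read_ct_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  cols <- tolower(colnames(df))
  if (all(c("feature", "sample", "ct") %in% cols)) {
    colnames(df) <- cols
    feats <- unique(df$feature); samps <- unique(df$sample)
    key <- paste(df$feature, df$sample)
    if (anyDuplicated(key))
      stop("duplicate (feature, sample) rows in long Ct table", call. = FALSE)
    ct <- matrix(NA_real_, length(feats), length(samps),
                 dimnames = list(feats, samps))
    ct[cbind(match(df$feature, feats), match(df$sample, samps))] <-
      as.numeric(df$ct)
  } else {
    ct <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(ct) <- "double"
    rownames(ct) <- df[[1]]
  }
  if (any(ct[!is.na(ct)] <= 0))
    stop("Ct values must be positive", call. = FALSE)
  ct
}
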