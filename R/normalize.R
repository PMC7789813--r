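#' Transcripts-per-million normalization
#'
#' Per sample, each count is converted to a length-normalized rate
#' (count / length in kilobases) and rates are rescaled to sum to 1e6.
#' Lengths are used in kilobases internally so results are reproducible
#' bit-for-bit across platforms.
#'
#' @param counts expression matrix on the count scale.
#' @param lengths named numeric vector (or two-column data frame) of feature
#'   lengths in base pairs, covering every feature of `counts`.
#' @return expression matrix on the TPM scale; every column sums to 1e6.
#' @export
compute_tpm <- function(counts, lengths) {
  validate_expr_matrix(counts)
  if (is.data.frame(lengths)) lengths <- setNames(lengths[[2]], lengths[[1]])
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss) > 0)
    stop("no length for feature(s): ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stop("feature lengths must be positive", call. = FALSE)
  rate <- counts / (len / 1000)
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("TPM undefined for all-zero sample(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "), call. = FALSE)
  expression_matrix(sweep(rate, 2, tot, "/") * 1e6, scale = "TPM")
}

#' Counts-per-million normalization
#'
#' @param counts expression matrix on the count scale.
#' @return expression matrix on the CPM scale; every column sums to 1e6.
#' @export
compute_cpm <- function(counts) {
  validate_expr_matrix(counts)
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("CPM undefined for all-zero sample(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "), call. = FALSE)
  expression_matrix(sweep(counts, 2, tot, "/") * 1e6, scale = "CPM")
}

#' Elementwise log2(x + 1)
#'
#' @param x expression matrix with nonnegative values.
#' @return matrix of log2(x + 1) values (same dimnames; scale attribute kept).
#' @export
log2p1 <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("log2p1 requires nonnegative values", call. = FALSE)
  out <- log2(x + 1)
  attr(out, "scale") <- expr_scale(x)
  out
}

#' Convert qPCR Ct values to relative abundance
#'
#' Abundance is modeled as 2^-Ct: each additional amplification cycle halves
#' the implied template amount. Missing Ct cells propagate as `NA`.
#'
#' @param ct numeric matrix of Ct values (features x samples), `NA` allowed.
#' @return expression matrix on the abundance scale.
#' @export
ct_to_abundance <- function(ct) {
  if (!is.matrix(ct)) stop("`ct` must be a matrix", call. = FALSE)
  if (any(!is.finite(ct[!is.na(ct)])))
    stop("Ct values must be finite", call. = FALSE)
  ab <- 2^(-ct)
  attr(ab, "scale") <- "abundance"
  ab
}

#' Ct values relative to a control (housekeeping) feature
#'
#' Computes delta-Ct: the Ct of each feature minus the Ct of the control
#' feature in the same sample, so the control's relative values are all zero.
#'
#' @param ct numeric Ct matrix (features x samples).
#' @param control_feature row name of the control feature; it must have a
#'   non-missing Ct in every sample.
#' @return delta-Ct matrix with the same dimensions.
#' @export
relative_ct <- function(ct, control_feature) {
  if (!control_feature %in% rownames(ct))
    stop("control feature '", control_feature, "' not in Ct table", call. = FALSE)
  ctrl <- ct[control_feature, ]
  if (anyNA(ctrl))
    stop("control feature missing in sample(s): ",
         paste(colnames(ct)[is.na(ctrl)], collapse = ", "), call. = FALSE)
  sweep(ct, 2, ctrl, "-")
}
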