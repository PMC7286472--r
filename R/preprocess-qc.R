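#' Quantile normalization
#'
#' Forces every sample (column) to share the same empirical distribution: the
#' across-column mean of order statistics. Ties within a column receive the
#' average of the values they span.
#'
#' @param mat Features x samples numeric matrix, no missing values, >= 2
#'   samples.
#' @return Normalized matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2L) stop("quantile normalization needs >= 2 samples")
  if (anyNA(mat)) stop("missing values are not allowed")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Log2 transformation with offset
#'
#' @param mat Numeric matrix.
#' @param offset Added before taking log2 (default 1).
#' @return `log2(mat + offset)`.
#' @export
log2_transform <- function(mat, offset = 1) {
  if (any(mat + offset <= 0)) stop("values + offset must be positive")
  log2(mat + offset)
}

#' Sample-network quality control
#'
#' Builds the intersample adjacency `A_ij = (1 + cor(i, j)) / 2` (Pearson over
#' features), computes each sample's connectivity `K_i = sum_j A_ij` and
#' weighted clustering coefficient
#' `C_i = sum_{j != k} A_ij A_jk A_ki / (K_i^2 - sum_j A_ij^2)`, standardizes
#' both to Z.K and Z.C (mean 0, sd 1), and flags outliers at `Z.K < zk_cut` or
#' `Z.C > zc_cut`.
#'
#' @param mat Features x samples matrix, >= 4 samples, every sample with
#'   nonzero variance.
#' @param zk_cut Connectivity flag threshold (default -2).
#' @param zc_cut Clustering-coefficient flag threshold (default 2).
#' @return data.frame (class `sample_qc`) with columns sample, K, C, Z.K,
#'   Z.C, outlier.
#' @export
sample_network_qc <- function(mat, zk_cut = -2, zc_cut = 2) {
  stopifnot(is.matrix(mat))
  n <- ncol(mat)
  if (n < 4L) stop("sample network QC needs >= 4 samples")
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "))
  }
  A <- (1 + stats::cor(mat)) / 2
  diag(A) <- 0
  K <- rowSums(A)
  num <- diag(A %*% A %*% A)           # sum over ordered pairs j != k
  den <- K^2 - rowSums(A^2)
  C <- ifelse(den > 1e-12, num / den, NA_real_)
  zstd <- function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x, na.rm = TRUE)) / s
  }
  zk <- zstd(K)
  zc <- zstd(C)
  out <- data.frame(sample = colnames(mat), K = K, C = C,
                    Z.K = zk, Z.C = zc,
                    outlier = zk < zk_cut | zc > zc_cut,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("sample_qc", "data.frame"))
}
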