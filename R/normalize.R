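#' Quantile-normalize an expression matrix
#'
#' Forces every sample column onto the common rank-mean distribution, in
#' four steps: sort each column ascending; average the sorted values across
#' columns at each rank; replace each value by its rank's mean; restore the
#' original row order of each column. Operates on raw linear intensities.
#'
#' Tied values within a column receive the average of the rank-means of the
#' positions they occupy, which makes the output invariant to the arbitrary
#' ordering of ties.
#'
#' @param mat numeric matrix, probes x samples, no missing values.
#' @return matrix of the same shape and dimnames; the multiset of values in
#'   every column equals the vector of rank-means.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 1 || ncol(mat) < 1) {
    stop("need at least one probe and one sample", call. = FALSE)
  }
  if (anyNA(mat)) stop("data error: missing values in expression matrix",
                       call. = FALSE)
  if (ncol(mat) == 1) return(mat)  # rank-mean of one column is itself
  sorted <- apply(mat, 2, sort)
  rank_means <- rowMeans(sorted)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    o <- order(x)
    v <- rank_means
    xs <- x[o]
    # average rank-means over tied positions
    if (anyDuplicated(xs)) {
      v <- stats::ave(v, match(xs, xs), FUN = mean)
    }
    out[o, j] <- v
  }
  out
}
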