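# Classification-accuracy metrics against the generating truth.

#' Pattern-wise classification accuracy (PCA)
#'
#' Fraction of examinees whose full estimated attribute pattern equals the
#' true pattern. Pooled over replications this is the mean over all
#' person-replicates.
#'
#' @param estimated,truth N x K binary matrices.
#' @return A proportion in \[0, 1\].
#' @export
pattern_accuracy <- function(estimated, truth) {
  if (!all(dim(estimated) == dim(truth))) stop("shape mismatch")
  mean(rowSums(estimated == truth) == ncol(truth))
}

#' Attribute-wise classification accuracy (ACA)
#'
#' Fraction of person-attribute cells classified correctly; always at
#' least as large as the pattern-wise accuracy.
#'
#' @inheritParams pattern_accuracy
#' @export
attribute_accuracy <- function(estimated, truth) {
  if (!all(dim(estimated) == dim(truth))) stop("shape mismatch")
  mean(estimated == truth)
}
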