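#' Cohen's kappa for intercoder agreement
#'
#' Unweighted (nominal) kappa between two coders' label sequences:
#' `kappa = (p_o - p_e) / (1 - p_e)` where `p_o` is the observed
#' proportion of agreement and `p_e` the chance agreement from the
#' product of the two coders' marginal label distributions. When both
#' marginals are degenerate on the same single label (`p_e = 1`, which
#' forces perfect agreement) kappa is 1 by convention.
#'
#' @param labels_a,labels_b Equal-length vectors of categorical codes
#'   (character or factor); categories are pooled across both coders.
#' @return A single number in `[-1, 1]`.
#' @export
#' @examples
#' cohens_kappa(c("x", "x", "y"), c("x", "y", "y"))
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("`labels_a` and `labels_b` must have the same length",
         call. = FALSE)
  }
  n <- length(labels_a)
  if (n < 1) stop("label sequences must be non-empty", call. = FALSE)
  levels <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  fa <- factor(as.character(labels_a), levels = levels)
  fb <- factor(as.character(labels_b), levels = levels)
  tab <- table(fa, fb) / n
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (1 - p_e < .Machine$double.eps) {
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}
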