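#' Cliff's delta effect size
#'
#' Nonparametric effect size in [-1, 1] comparing two samples by pairwise
#' dominance: delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (|x| |y|); tied
#' pairs contribute 0. Computed in O((n + m) log m) via sorted dominance
#' counts; identical to brute-force pair enumeration.
#'
#' @param x,y nonempty numeric samples.
#' @return Cliff's delta.
#' @examples
#' cliffs_delta(c(4, 5, 6), c(1, 2, 3))  # 1: complete separation
#' cliffs_delta(c(1, 2), c(2, 3))        # -0.75
#' @export
cliffs_delta <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  cnt <- .dominance_counts(x, sort(y))
  (sum(cnt[, 1]) - sum(cnt[, 2])) / (length(x) * length(y))
}
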