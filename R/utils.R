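#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generator calls do
#' not disturb the global random stream. A NULL seed evaluates in place.
#'
#' @param seed integer seed or NULL.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

#' Draw multivariate normal deviates
#'
#' @param n number of draws.
#' @param Sigma covariance matrix.
#' @return n x ncol(Sigma) matrix.
#' @keywords internal
#' @noRd
rmvnorm_chol <- function(n, Sigma) {
  R <- chol(Sigma)
  Z <- matrix(rnorm(n * ncol(Sigma)), n, ncol(Sigma))
  Z %*% R
}

# stable feature-key string: protein|compartment|measure
feature_key_string <- function(protein, compartment, measure) {
  paste(protein, compartment, measure, sep = "|")
}

parse_feature_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  data.frame(
    protein     = vapply(parts, `[`, "", 1L),
    compartment = vapply(parts, `[`, "", 2L),
    measure     = vapply(parts, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
}

#' Map a compartment label to its localization class
#'
#' Subnodes of the covariation network are grouped by where in the cell the
#' underlying feature was measured: nucleus, cytoplasm (whole-cell measures
#' count as cytoplasmic), the domain/aggregate class of intensely stained
#' regions, or the plasma-membrane ring.
#'
#' @param compartment character vector of compartment labels.
#' @return character vector of localization classes.
#' @export
localization_class <- function(compartment) {
  map <- c(
    nucleus      = "nucleus",
    cytoplasm    = "cytoplasm",
    whole_cell   = "cytoplasm",
    domain       = "domain_aggregate",
    aggregate    = "domain_aggregate",
    pm_aggregate = "domain_aggregate",
    pm           = "pm"
  )
  out <- unname(map[compartment])
  if (anyNA(out)) {
    stop("unknown compartment label(s): ",
         paste(unique(compartment[is.na(out)]), collapse = ", "))
  }
  out
}
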