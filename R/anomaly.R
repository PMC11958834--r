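#' Node-wise block partition of a precision model
#'
#' Permutes feature `i` to the last position of both the precision matrix
#' and its inverse, then extracts the blocks used by the conditional
#' divergence: Lambda = [L l; l' lambda] and Sigma = [W w; w' sigma].
#'
#' @param model a `precision_model`.
#' @param i node index.
#' @return list with `L` ((M-1) x (M-1)), `l` (M-1 vector), `lambda`
#'   (scalar), `W`, `w`, `sigma`, and the permutation used.
#' @export
partition_node <- function(model, i) {
  stopifnot(inherits(model, "precision_model"))
  M <- nrow(model$Lambda)
  if (i < 1 || i > M) stop("node index out of range: ", i)
  perm <- c(seq_len(M)[-i], i)
  Lp <- model$Lambda[perm, perm]
  Sp <- model$Sigma[perm, perm]
  lambda <- Lp[M, M]
  if (lambda <= 0) stop("lambda block is not positive; precision not SPD")
  list(
    L = Lp[-M, -M, drop = FALSE], l = Lp[-M, M], lambda = lambda,
    W = Sp[-M, -M, drop = FALSE], w = Sp[-M, M], sigma = Sp[M, M],
    perm = perm
  )
}

check_same_keys <- function(model_A, model_B) {
  ka <- model_A$keys; kb <- model_B$keys
  if (nrow(model_A$Lambda) != nrow(model_B$Lambda)) {
    stop("models have different numbers of features: ",
         nrow(model_A$Lambda), " vs ", nrow(model_B$Lambda))
  }
  if (!is.null(ka) && !is.null(kb)) {
    sa <- feature_key_string(ka$protein, ka$compartment, ka$measure)
    sb <- feature_key_string(kb$protein, kb$compartment, kb$measure)
    if (!identical(sa, sb)) {
      diff <- union(setdiff(sa, sb), setdiff(sb, sa))
      stop("models have mismatched feature sets",
           if (length(diff)) paste0("; symmetric difference: ",
                                    paste(diff, collapse = ", "))
           else "; same keys in different order")
    }
  }
  invisible(TRUE)
}

#' Directed correlation anomaly divergence for one node
#'
#' The expected Kullback-Leibler divergence, under model A's distribution
#' of the remaining features z, between the two models' Gaussian
#' conditionals of feature i given z:
#' `d_i^AB = w_A' (l_B - l_A) + (l_B' W_A l_B / lambda_B -
#' l_A' W_A l_A / lambda_A) / 2 + (log(lambda_A / lambda_B) +
#' sigma_A (lambda_B - lambda_A)) / 2`.
#' It is nonnegative up to numerical error and zero when the two
#' conditionals coincide.
#'
#' @param model_A,model_B `precision_model`s over the same feature keys in
#'   the same order.
#' @param i node index.
#' @return the divergence d_i^AB (clamped to 0 when within 1e-9 below 0).
#' @export
node_divergence <- function(model_A, model_B, i) {
  check_same_keys(model_A, model_B)
  a <- partition_node(model_A, i)
  b <- partition_node(model_B, i)
  d <- sum(a$w * (b$l - a$l)) +
    0.5 * (drop(crossprod(b$l, a$W %*% b$l)) / b$lambda -
             drop(crossprod(a$l, a$W %*% a$l)) / a$lambda) +
    0.5 * (log(a$lambda / b$lambda) + a$sigma * (b$lambda - a$lambda))
  if (d < 0 && d > -1e-9) d <- 0
  d
}

#' Correlation anomaly scores between two condition models
#'
#' For every node i, computes both directed divergences and the anomaly
#' score `a_i = max(d_i^AB, d_i^BA)`, which is symmetric in the pair and
#' quantifies the change in the connectivity and correlation strength of
#' the node's first neighbors between the two fitted networks.
#'
#' @param model_A,model_B `precision_model`s sharing feature keys.
#' @return object of class `anomaly_result`: list with `d_AB`, `d_BA`,
#'   `a`, `pair`, `keys`.
#' @export
anomaly_score <- function(model_A, model_B) {
  check_same_keys(model_A, model_B)
  M <- nrow(model_A$Lambda)
  d_AB <- vapply(seq_len(M), function(i) node_divergence(model_A, model_B, i), 0)
  d_BA <- vapply(seq_len(M), function(i) node_divergence(model_B, model_A, i), 0)
  a <- pmax(d_AB, d_BA)
  keys <- model_A$keys
  nm <- if (!is.null(keys)) {
    feature_key_string(keys$protein, keys$compartment, keys$measure)
  } else {
    sprintf("F%03d", seq_len(M))
  }
  names(d_AB) <- names(d_BA) <- names(a) <- nm
  structure(list(
    pair = c(A = model_A$condition %||% "A", B = model_B$condition %||% "B"),
    d_AB = d_AB, d_BA = d_BA, a = a, keys = keys
  ), class = "anomaly_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.anomaly_result <- function(x, ...) {
  cat(sprintf("anomaly_result: pair %s vs %s, %d nodes, max a_i = %.4g (%s)\n",
              x$pair[1], x$pair[2], length(x$a), max(x$a),
              names(x$a)[which.max(x$a)]))
  invisible(x)
}

#' Anomaly heatmap matrix over all condition pairs at one penalty
#'
#' Rows are feature keys (sorted by their maximum score, descending);
#' columns are the unordered condition pairs. With exactly three
#' conditions the pair order follows the control / treated / rescued
#' narrative: (1,2), (2,3), (1,3).
#'
#' @param models named list of `precision_model`s, one per condition, all
#'   fitted at the same rho over the same feature keys.
#' @param rho optional consistency check on the models' penalty.
#' @return object of class `anomaly_heatmap`: list with matrix `scores`
#'   (nodes x pairs) and the per-pair `anomaly_result`s.
#' @export
anomaly_heatmap <- function(models, rho = NULL) {
  if (length(models) < 2) stop("need at least 2 condition models")
  if (is.null(names(models))) {
    names(models) <- vapply(models, function(m) m$condition %||% "?", "")
  }
  if (!is.null(rho)) {
    bad <- vapply(models, function(m) !isTRUE(all.equal(m$rho, rho)), TRUE)
    if (any(bad)) {
      stop("model(s) not fitted at rho = ", rho, ": ",
           paste(names(models)[bad], collapse = ", "))
    }
  }
  k <- length(models)
  pairs <- if (k == 3) {
    list(c(1L, 2L), c(2L, 3L), c(1L, 3L))
  } else {
    asplit(combn(k, 2), 2)
  }
  results <- lapply(pairs, function(p) {
    anomaly_score(models[[p[1]]], models[[p[2]]])
  })
  names(results) <- vapply(pairs, function(p) {
    paste(names(models)[p], collapse = " vs ")
  }, "")
  scores <- do.call(cbind, lapply(results, function(r) r$a))
  colnames(scores) <- names(results)
  ord <- order(apply(scores, 1, max), decreasing = TRUE)
  scores <- scores[ord, , drop = FALSE]
  structure(list(scores = scores, results = results,
                 conditions = names(models)),
            class = "anomaly_heatmap")
}

#' Tabulate an anomaly result
#'
#' @param x an `anomaly_result`.
#' @param ... unused.
#' @return data.frame with feature_key, pair, d_AB, d_BA, a.
#' @export
as.data.frame.anomaly_result <- function(x, ...) {
  data.frame(
    feature_key = names(x$a),
    pair = paste(x$pair, collapse = " vs "),
    d_AB = unname(x$d_AB), d_BA = unname(x$d_BA), a = unname(x$a),
    stringsAsFactors = FALSE
  )
}

#' One planted-anomaly recovery replicate through the full pipeline
#'
#' Simulates a two-condition feature table whose second condition carries a
#' neighborhood perturbation at one node, assembles both condition
#' matrices, fits the graphical lasso at a common penalty, scores the
#' anomaly, and reports whether the planted node is the top-scoring node.
#'
#' @param seed replicate seed.
#' @param node planted node index.
#' @param rho penalty for both condition fits (default 0.05, low enough to
#'   retain the moderate partial correlations the generator produces).
#' @param magnitude perturbation size (default 1).
#' @param n_proteins,compartments,time_points_min,wells_per_timepoint,
#'   cells_per_well study dimensions; the defaults give M = 15 features
#'   and N = 200 samples.
#' @return list with `hit` (logical), `rank` of the planted node, and the
#'   score vector.
#' @export
planted_anomaly_replicate <- function(seed, node = 7L, rho = 0.05,
                                      magnitude = 1.0,
                                      n_proteins = 5L,
                                      compartments = c("nucleus", "cytoplasm", "aggregate"),
                                      time_points_min = seq(3, 60, by = 3),
                                      wells_per_timepoint = 10L,
                                      cells_per_well = 200L) {
  spec <- synth_spec(
    n_proteins = n_proteins, compartments_per_protein = compartments,
    n_conditions = 2L, condition_labels = c("A", "B"),
    time_points_min = time_points_min,
    wells_per_timepoint = wells_per_timepoint,
    cells_per_well = cells_per_well,
    anomaly_nodes = as.integer(node), anomaly_magnitude = magnitude,
    perturbed_conditions = 2L, seed = as.integer(seed)
  )
  sim <- simulate_feature_table(spec)
  fit <- function(cond) {
    fm <- assemble_feature_matrix(sim$records, cond)
    graphical_lasso(feature_correlation(fm), rho, keys = fm$keys,
                    condition = cond)
  }
  a <- anomaly_score(fit("A"), fit("B"))$a
  # assembled columns are key-sorted; locate the planted feature by key
  pk <- sim$truth$feature_keys[node, ]
  planted_key <- feature_key_string(pk$protein, pk$compartment, pk$measure)
  if (!planted_key %in% names(a)) {
    stop("planted feature ", planted_key, " missing from assembled matrix")
  }
  list(hit = names(a)[which.max(a)] == planted_key,
       rank = unname(rank(-a)[planted_key]), scores = a,
       planted_key = planted_key)
}

#' Protein-level anomaly scores
#'
#' Collapses subnode scores to proteins by taking each protein's maximum
#' score over its feature keys.
#'
#' @param result an `anomaly_result`.
#' @return named numeric vector, descending.
#' @export
protein_anomaly <- function(result) {
  if (is.null(result$keys)) stop("anomaly result carries no feature keys")
  s <- tapply(result$a, result$keys$protein, max)
  sort(unlist(as.list(s)), decreasing = TRUE)
}
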