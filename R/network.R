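#' Assemble a condition's time x feature matrix from single-cell records
#'
#' Cross-cell values are aggregated (median by default, matching the
#' per-timepoint summary used for the time-course displays) within each
#' (time point, well, feature) group, giving one sample row per
#' (time point, well) and one column per (protein, compartment, measure)
#' feature key. Columns present in fewer than half the rows are dropped
#' with a warning; remaining missing cells are imputed with the column
#' mean; zero-variance columns are dropped. Columns are then standardized
#' to mean 0 and population SD 1, so the cross-product matrix is a
#' correlation matrix.
#'
#' @param records long-format feature records (data.frame/data.table).
#' @param condition condition label to extract; must be present.
#' @param aggregator "median" or "mean".
#' @return object of class `feature_matrix`: list with the standardized
#'   `X` (N x M), `keys` data.frame, `condition`, `dropped` manifest.
#' @export
assemble_feature_matrix <- function(records, condition,
                                    aggregator = c("median", "mean")) {
  aggregator <- match.arg(aggregator)
  cond_label <- condition
  dt <- data.table::as.data.table(records)
  dt <- dt[dt[["condition"]] == cond_label]
  if (nrow(dt) == 0) stop("condition not present in records: ", condition)
  if (length(unique(dt$time_min)) < 3) {
    stop("records must cover at least 3 time points")
  }
  afun <- if (aggregator == "median") stats::median else mean
  agg <- dt[, .(value = afun(value)),
            by = .(time_min, well, protein, compartment, measure)]
  agg[, feature := feature_key_string(protein, compartment, measure)]
  wide <- data.table::dcast(agg, time_min + well ~ feature,
                            value.var = "value")
  sample_ids <- paste(wide$time_min, wide$well, sep = "|")
  X <- as.matrix(wide[, -(1:2)])
  rownames(X) <- sample_ids
  n <- nrow(X)

  dropped <- list(sparse_features = character(), constant_features = character())
  present <- colSums(!is.na(X)) / n
  if (any(present < 0.5)) {
    dropped$sparse_features <- colnames(X)[present < 0.5]
    warning("dropping feature(s) present in <50% of rows: ",
            paste(dropped$sparse_features, collapse = ", "))
    X <- X[, present >= 0.5, drop = FALSE]
  }
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    dropped$constant_features <- colnames(X)[sds == 0]
    message("dropping constant feature(s): ",
            paste(dropped$constant_features, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  # population-SD standardization so that crossprod(X)/N has unit diagonal
  mu <- colMeans(X)
  sd_pop <- apply(X, 2, sd) * sqrt((n - 1) / n)
  X <- sweep(sweep(X, 2, mu), 2, sd_pop, "/")

  keys <- parse_feature_key(colnames(X))
  keys$localization_class <- localization_class(keys$compartment)
  structure(list(condition = condition, X = X, keys = keys,
                 aggregator = aggregator, dropped = dropped),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: condition '%s', N = %d samples, M = %d features (%s-aggregated)\n",
              x$condition, nrow(x$X), ncol(x$X), x$aggregator))
  invisible(x)
}

#' Empirical correlation matrix of a standardized feature matrix
#'
#' Computed as crossprod(X) / N on the standardized columns, then
#' symmetrized with unit diagonal and entries clipped to [-1, 1].
#'
#' @param fm a [assemble_feature_matrix()] result, or a standardized matrix.
#' @return M x M correlation matrix.
#' @export
feature_correlation <- function(fm) {
  X <- if (inherits(fm, "feature_matrix")) fm$X else as.matrix(fm)
  if (nrow(X) < 3) stop("need at least 3 samples")
  S <- crossprod(X) / nrow(X)
  S <- (S + t(S)) / 2
  S[S > 1] <- 1; S[S < -1] <- -1
  diag(S) <- 1
  S
}

#' Sparse precision estimation by the graphical lasso
#'
#' Maximizes `log det(Lambda) - tr(S Lambda) - rho * sum_{i != j}
#' |Lambda_ij|` by block coordinate descent over columns, each column
#' solved as an L1-penalized regression (coordinate descent in compiled
#' code). Convergence is declared when the duality gap
#' `tr(S Lambda) + rho * ||Lambda||_1,off - M` falls below `tol`.
#' The returned partial correlations are
#' `r_ij = -Lambda_ij / sqrt(Lambda_ii Lambda_jj)`.
#'
#' @param S symmetric correlation matrix with unit diagonal.
#' @param rho L1 penalty on off-diagonal precision entries (>= 0).
#' @param tol duality-gap convergence tolerance (default 1e-4).
#' @param maxit maximum number of full column sweeps.
#' @param keys optional feature-key data.frame attached to the model.
#' @param condition optional condition label.
#' @param warm optional warm start: list with `W` and `B` from a previous
#'   solution on the same S (used by [glasso_sweep()]).
#' @return object of class `precision_model`: list with `Lambda`, `Sigma`
#'   (its inverse), `partials`, `rho`, `keys`, `condition`, `gap`.
#' @export
graphical_lasso <- function(S, rho, tol = 1e-4, maxit = 200,
                            keys = NULL, condition = NULL, warm = NULL) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), rho >= 0)
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  M <- nrow(S)
  if (rho == 0) {
    rc <- rcond(S)
    if (!is.finite(rc) || rc < 1e-12) {
      stop("S is singular or ill-conditioned at rho = 0; use rho > 0")
    }
    Lambda <- solve(S)
    Lambda <- (Lambda + t(Lambda)) / 2
    return(new_precision_model(Lambda, rho, keys, condition, gap = 0))
  }

  W <- if (!is.null(warm)) warm$W else S
  B <- if (!is.null(warm)) warm$B else matrix(0, M - 1, M)
  diag(W) <- diag(S)  # off-diagonal-only penalty: diagonal unpenalized
  gap <- Inf
  Lambda <- NULL
  for (sweep_i in seq_len(maxit)) {
    for (j in seq_len(M)) {
      idx <- seq_len(M)[-j]
      beta <- .lasso_cd(W[idx, idx, drop = FALSE], S[idx, j], rho, B[, j])
      B[, j] <- beta
      w12 <- W[idx, idx, drop = FALSE] %*% beta
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    # each lasso column keeps |w12 - s12|_inf <= rho and diag(W) = diag(S),
    # so W is dual feasible and the exact-inverse gap is a true duality gap
    Lambda <- chol2inv(chol((W + t(W)) / 2))
    gap <- sum(S * Lambda) +
      rho * (sum(abs(Lambda)) - sum(abs(diag(Lambda)))) - M
    if (is.finite(gap) && gap < tol) break
  }
  if (!is.finite(gap) || gap >= tol) {
    stop(sprintf("graphical lasso did not converge at rho = %g (gap %.3g after %d sweeps)",
                 rho, gap, maxit))
  }
  # harden the support: the column regressions carry the exact zero pattern
  support <- matrix(FALSE, M, M)
  for (j in seq_len(M)) {
    support[seq_len(M)[-j], j] <- B[, j] != 0
  }
  support <- support | t(support)
  Lambda[!support & !diag(M)] <- 0
  Lambda <- (Lambda + t(Lambda)) / 2
  model <- new_precision_model(Lambda, rho, keys, condition, gap = gap)
  model$warm <- list(W = W, B = B)
  model
}

new_precision_model <- function(Lambda, rho, keys, condition, gap = NA_real_) {
  ev <- min(eigen(Lambda, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("estimated precision matrix is not positive definite")
  Sigma <- solve(Lambda)
  Sigma <- (Sigma + t(Sigma)) / 2
  d <- sqrt(diag(Lambda))
  partials <- -Lambda / outer(d, d)
  diag(partials) <- 1
  structure(list(condition = condition, rho = rho, Lambda = Lambda,
                 Sigma = Sigma, partials = partials, keys = keys,
                 gap = gap),
            class = "precision_model")
}

#' @export
print.precision_model <- function(x, ...) {
  M <- nrow(x$Lambda)
  ne <- sum(abs(x$partials[upper.tri(x$partials)]) > 1e-8)
  cat(sprintf("precision_model: %s M = %d, rho = %g, %d edge(s)\n",
              if (is.null(x$condition)) "" else paste0("condition '", x$condition, "', "),
              M, x$rho, ne))
  invisible(x)
}

#' Number of edges (nonzero off-diagonal partial correlations) of a model
#'
#' @param model a `precision_model`.
#' @param floor numeric floor distinguishing solver zeros (default 1e-8).
#' @return edge count.
#' @export
edge_count <- function(model, floor = 1e-8) {
  sum(abs(model$partials[upper.tri(model$partials)]) > floor)
}

#' Graphical-lasso solutions along a penalty path
#'
#' Fits one model per penalty value, warm-starting each fit from the
#' previous solution along the (ascending) path.
#'
#' @param S correlation matrix.
#' @param rhos penalty values, sorted ascending.
#' @param ... passed to [graphical_lasso()].
#' @return named list of `precision_model`s (names = rho values), each
#'   with an `edges` attribute; per-rho failures are re-signalled with the
#'   offending rho named.
#' @export
glasso_sweep <- function(S, rhos, ...) {
  if (is.unsorted(rhos)) stop("rhos must be sorted ascending")
  out <- vector("list", length(rhos))
  warm <- NULL
  for (k in seq_along(rhos)) {
    out[[k]] <- tryCatch(
      graphical_lasso(S, rhos[k], warm = warm, ...),
      error = function(e) {
        stop("sweep failed at rho = ", rhos[k], ": ", conditionMessage(e))
      }
    )
    warm <- out[[k]]$warm
  }
  names(out) <- format(rhos)
  out
}

#' Build a covariation network from a precision model
#'
#' One subnode per feature key, grouped under its protein node; one edge
#' per nonzero partial correlation (absolute value above the numeric
#' floor), weighted by the partial correlation. Subnodes carry their
#' localization class (nucleus / cytoplasm / domain-aggregate / PM).
#'
#' @param model a `precision_model` with feature keys attached.
#' @param floor edge floor distinguishing solver zeros (default 1e-8).
#' @return object of class `covariation_network`: list with the igraph
#'   `graph`, `rho`, `condition`, `keys`.
#' @export
build_network <- function(model, floor = 1e-8) {
  stopifnot(inherits(model, "precision_model"))
  M <- nrow(model$partials)
  keys <- model$keys
  if (is.null(keys)) {
    keys <- data.frame(protein = sprintf("F%03d", seq_len(M)),
                       compartment = "cytoplasm",
                       measure = "value", stringsAsFactors = FALSE)
    keys$localization_class <- "cytoplasm"
  }
  if (is.null(keys$localization_class)) {
    keys$localization_class <- localization_class(keys$compartment)
  }
  A <- model$partials
  diag(A) <- 0
  A[abs(A) <= floor] <- 0
  vname <- feature_key_string(keys$protein, keys$compartment, keys$measure)
  dimnames(A) <- list(vname, vname)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$protein <- keys$protein[match(igraph::V(g)$name, vname)]
  igraph::V(g)$compartment <- keys$compartment[match(igraph::V(g)$name, vname)]
  igraph::V(g)$measure <- keys$measure[match(igraph::V(g)$name, vname)]
  igraph::V(g)$localization_class <-
    keys$localization_class[match(igraph::V(g)$name, vname)]
  structure(list(graph = g, rho = model$rho, condition = model$condition,
                 keys = keys),
            class = "covariation_network")
}

#' @export
print.covariation_network <- function(x, ...) {
  cat(sprintf("covariation_network: %s%d subnodes, %d edges, rho = %g\n",
              if (is.null(x$condition)) "" else paste0("condition '", x$condition, "', "),
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$rho))
  invisible(x)
}

#' Protein degrees of a covariation network
#'
#' A protein node's degree is the number of edges incident to any of its
#' subnodes.
#'
#' @param network a `covariation_network`.
#' @return named integer vector, descending.
#' @export
protein_degree <- function(network) {
  g <- network$graph
  el <- igraph::as_edgelist(g)
  pa <- igraph::V(g)$protein[match(el[, 1], igraph::V(g)$name)]
  pb <- igraph::V(g)$protein[match(el[, 2], igraph::V(g)$name)]
  counts <- table(c(pa, pb))
  # count each edge once per incident protein (an intra-protein edge
  # touches its protein twice but is one incident edge)
  intra <- pa == pb
  if (any(intra)) {
    dec <- table(pa[intra])
    counts[names(dec)] <- counts[names(dec)] - dec
  }
  sort(unlist(as.list(counts)), decreasing = TRUE)
}

#' Collapse a covariation network to a protein-level simple graph
#'
#' Any subnode edge implies a protein edge; the maximum absolute partial
#' correlation over implying subnode pairs is retained as the protein-edge
#' weight. Intra-protein edges are dropped.
#'
#' @param network a `covariation_network`.
#' @return igraph undirected simple graph on protein symbols.
#' @export
collapse_to_proteins <- function(network) {
  g <- network$graph
  el <- igraph::as_edgelist(g)
  w <- abs(igraph::E(g)$weight)
  pa <- igraph::V(g)$protein[match(el[, 1], igraph::V(g)$name)]
  pb <- igraph::V(g)$protein[match(el[, 2], igraph::V(g)$name)]
  keep <- pa != pb
  proteins <- unique(igraph::V(g)$protein)
  if (!any(keep)) {
    return(igraph::make_empty_graph(directed = FALSE) +
             igraph::vertices(proteins))
  }
  df <- data.frame(a = pmin(pa[keep], pb[keep]),
                   b = pmax(pa[keep], pb[keep]), w = w[keep])
  agg <- aggregate(w ~ a + b, df, max)
  gp <- igraph::graph_from_data_frame(agg, directed = FALSE,
                                      vertices = proteins)
  igraph::E(gp)$weight <- agg$w
  gp
}

#' Export a covariation network to GraphML and a TSV edge list
#'
#' @param network a `covariation_network`.
#' @param graphml_path,edges_path output paths (NULL to skip either).
#' @export
export_network <- function(network, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    el <- igraph::as_edgelist(network$graph)
    out <- data.frame(from = el[, 1], to = el[, 2],
                      weight = igraph::E(network$graph)$weight)
    utils::write.table(out, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(network)
}
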