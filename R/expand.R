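#' Overlapping link communities of a protein network
#'
#' Clusters the edges of an undirected graph: the similarity of two edges
#' sharing a node k is the Jaccard index of the inclusive neighborhoods
#' (neighbors plus self) of their non-shared endpoints; non-adjacent edge
#' pairs have similarity 0. Edges are grouped by single-linkage
#' hierarchical clustering and the dendrogram is cut at the height
#' maximizing partition density (ties broken toward the lowest such cut).
#' Edge sets partition the edge set; vertex sets may overlap.
#'
#' @param graph igraph undirected graph (a protein-collapsed covariation
#'   network) or a `covariation_network` (collapsed automatically).
#' @return object of class `cluster_set`: list with `graph`, `edge_sets`
#'   (list of edge-index vectors), `vertex_sets`, `mean_degree`,
#'   `graph_mean_degree`, `selected` (filled by [select_dense_clusters()]),
#'   `partition_density`, `cut_height`.
#' @export
link_communities <- function(graph) {
  if (inherits(graph, "covariation_network")) {
    graph <- collapse_to_proteins(graph)
  }
  stopifnot(igraph::is_igraph(graph))
  g <- igraph::simplify(igraph::as_undirected(graph))
  m <- igraph::ecount(g)
  if (m == 0) {
    return(structure(list(graph = g, edge_sets = list(),
                          vertex_sets = list(), mean_degree = numeric(),
                          graph_mean_degree = NA_real_,
                          selected = logical(),
                          partition_density = NA_real_,
                          cut_height = NA_real_),
                     class = "cluster_set"))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  nv <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g)
  inc_nbhd <- lapply(seq_len(nv), function(v) c(v, as.integer(adj[[v]])))

  if (m == 1) {
    edge_sets <- list(1L)
    cut_h <- 0
  } else {
    sim <- matrix(0, m, m)
    inc_edges <- igraph::as_adj_edge_list(g)
    for (k in seq_len(nv)) {
      ids <- as.integer(inc_edges[[k]])
      if (length(ids) < 2) next
      for (ai in seq_len(length(ids) - 1)) {
        for (bi in (ai + 1):length(ids)) {
          e1 <- ids[ai]; e2 <- ids[bi]
          i <- setdiff(el[e1, ], k); j <- setdiff(el[e2, ], k)
          if (length(i) == 0) i <- k  # self-loop guard (simplified away)
          s <- length(intersect(inc_nbhd[[i]], inc_nbhd[[j]])) /
            length(union(inc_nbhd[[i]], inc_nbhd[[j]]))
          sim[e1, e2] <- max(sim[e1, e2], s)
          sim[e2, e1] <- sim[e1, e2]
        }
      }
    }
    hc <- hclust(as.dist(1 - sim), method = "single")
    heights <- sort(unique(c(0, hc$height)))
    best <- NULL
    for (h in heights) {
      memb <- cutree(hc, h = h)
      pd <- partition_density(el, memb, m)
      if (is.null(best) || pd > best$pd + 1e-12) {
        best <- list(pd = pd, h = h, memb = memb)
      }
    }
    edge_sets <- unname(split(seq_len(m), best$memb))
    cut_h <- best$h
  }
  vertex_sets <- lapply(edge_sets, function(es) {
    sort(unique(as.vector(el[es, , drop = FALSE])))
  })
  mean_degree <- vapply(seq_along(edge_sets), function(ci) {
    2 * length(edge_sets[[ci]]) / length(vertex_sets[[ci]])
  }, 0)
  vnames <- igraph::V(g)$name
  vertex_sets <- lapply(vertex_sets, function(vs) {
    if (is.null(vnames)) vs else vnames[vs]
  })
  structure(list(
    graph = g, edge_sets = edge_sets, vertex_sets = vertex_sets,
    mean_degree = mean_degree,
    graph_mean_degree = 2 * m / nv,
    selected = rep(NA, length(edge_sets)),
    partition_density = if (m == 1) 0 else best$pd,
    cut_height = cut_h
  ), class = "cluster_set")
}

# link-community partition density over an edge membership vector
partition_density <- function(el, memb, m) {
  contrib <- vapply(split(seq_len(m), memb), function(es) {
    mc <- length(es)
    nc <- length(unique(as.vector(el[es, , drop = FALSE])))
    if (nc <= 2) return(0)
    mc * (mc - nc + 1) / ((nc - 2) * (nc - 1) / 2) / 2
  }, 0)
  # D = (2/m) * sum_c m_c * (m_c - n_c + 1) / ((n_c - 1)(n_c - 2))
  sum(contrib) * 2 / m
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d cluster(s) over %d edges / %d vertices (graph mean degree %.3g)\n",
              length(x$edge_sets), igraph::ecount(x$graph),
              igraph::vcount(x$graph), x$graph_mean_degree))
  for (i in seq_along(x$edge_sets)) {
    cat(sprintf("  cluster %d: |E| = %d, |V| = %d, mean degree %.3g%s\n",
                i, length(x$edge_sets[[i]]), length(x$vertex_sets[[i]]),
                x$mean_degree[i],
                if (isTRUE(x$selected[i])) " [selected]" else ""))
  }
  invisible(x)
}

#' Select dense clusters by the mean-degree rule
#'
#' A cluster is selected iff its mean degree 2|E_i|/|V_i| strictly exceeds
#' the whole-graph mean degree 2|E|/|V|; a cluster equal to the whole
#' graph is therefore never selected.
#'
#' @param clusters a `cluster_set`.
#' @return the `cluster_set` with its `selected` flags set.
#' @export
select_dense_clusters <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  clusters$selected <- clusters$mean_degree > clusters$graph_mean_degree
  clusters
}

#' GO term over-representation in a protein cluster
#'
#' One-sided hypergeometric test per GO term held by at least two cluster
#' proteins, with Benjamini-Hochberg adjustment across the tested terms;
#' enrichment is declared at q <= `q_threshold`. Proteins absent from the
#' annotation map are counted as term-free.
#'
#' @param cluster_proteins protein symbols of the cluster (subset of
#'   `background`).
#' @param go_map named list mapping protein symbol to GO id vector.
#' @param background background protein universe (nonempty).
#' @param q_threshold BH-adjusted significance threshold (default 0.05).
#' @param min_k minimum cluster count for a term to be tested (default 2).
#' @return data.frame with term, k, K, n, N, p, q, enriched.
#' @export
go_enrichment <- function(cluster_proteins, go_map, background,
                          q_threshold = 0.05, min_k = 2) {
  if (!length(background)) stop("background protein set is empty")
  if (!all(cluster_proteins %in% background)) {
    stop("cluster proteins must be a subset of the background")
  }
  n <- length(cluster_proteins)
  N <- length(background)
  terms_of <- function(p) unique(go_map[[p]] %||% character())
  cl_terms <- table(unlist(lapply(cluster_proteins, terms_of)))
  cl_terms <- cl_terms[cl_terms >= min_k]
  if (!length(cl_terms)) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), enriched = logical()))
  }
  bg_terms <- table(unlist(lapply(background, terms_of)))
  out <- data.frame(
    term = names(cl_terms),
    k = as.integer(cl_terms),
    K = as.integer(bg_terms[names(cl_terms)]),
    n = n, N = N, stringsAsFactors = FALSE
  )
  out$p <- phyper(out$k - 1, out$K, out$N - out$K, out$n, lower.tail = FALSE)
  out$q <- p.adjust(out$p, method = "BH")
  out$enriched <- out$q <= q_threshold
  out[order(out$p), ]
}

#' High-anomaly proteins within a cluster
#'
#' Protein-level anomaly scores (maximum over the protein's feature keys)
#' are thresholded at the given quantile within the cluster; proteins at
#' or above the within-cluster quantile are flagged high.
#'
#' @param anomaly protein-level scores: named numeric vector (e.g. from
#'   [protein_anomaly()]).
#' @param cluster_proteins proteins of the cluster.
#' @param high_quantile within-cluster quantile defining "high" (default 0.8).
#' @return character vector of high-anomaly proteins.
#' @export
high_anomaly_proteins <- function(anomaly, cluster_proteins,
                                  high_quantile = 0.8) {
  s <- anomaly[intersect(names(anomaly), cluster_proteins)]
  if (!length(s)) return(character())
  thr <- quantile(s, high_quantile, names = FALSE, type = 7)
  names(s)[s >= thr]
}

#' Evaluate PPI expansion candidates for one cluster at one penalty
#'
#' The candidate pool is the PPI first neighbors of the cluster's proteins
#' minus the cluster itself. Each candidate is scored against two filters:
#' GO sharing (its annotation intersects the cluster-enriched term set)
#' and anomaly adjacency (PPI edges to strictly more than `link_threshold`
#' of the cluster's high-anomaly proteins). Candidates are sorted by
#' anomaly link fraction (descending), ties broken by PPI degree then
#' symbol.
#'
#' @param cluster_proteins proteins of the selected cluster.
#' @param high_anomaly high-anomaly proteins of the cluster (e.g. from
#'   [high_anomaly_proteins()]).
#' @param ppi igraph PPI graph on official symbols.
#' @param enriched_terms GO ids enriched in the cluster.
#' @param go_map named list mapping protein to GO ids.
#' @param link_threshold anomaly-adjacency fraction that must be strictly
#'   exceeded (default 0.5).
#' @return data.frame with protein, go_pass, anomaly_link_fraction,
#'   anomaly_pass, pass (= both).
#' @export
expand_cluster <- function(cluster_proteins, high_anomaly, ppi,
                           enriched_terms, go_map, link_threshold = 0.5) {
  stopifnot(igraph::is_igraph(ppi))
  sym <- igraph::V(ppi)$name
  known <- intersect(cluster_proteins, sym)
  missing <- setdiff(cluster_proteins, sym)
  if (length(missing)) {
    message("cluster protein(s) absent from the PPI graph, skipped: ",
            paste(missing, collapse = ", "))
  }
  if (!length(known)) {
    return(empty_candidates())
  }
  nb <- unique(unlist(lapply(known, function(p) {
    igraph::neighbors(ppi, p)$name
  })))
  pool <- setdiff(nb, cluster_proteins)
  if (!length(pool)) return(empty_candidates())

  high_known <- intersect(high_anomaly, sym)
  frac <- vapply(pool, function(cand) {
    if (!length(high_known)) return(0)
    nbc <- igraph::neighbors(ppi, cand)$name
    length(intersect(nbc, high_known)) / length(high_known)
  }, 0)
  go_pass <- vapply(pool, function(cand) {
    length(intersect(go_map[[cand]] %||% character(), enriched_terms)) > 0
  }, TRUE)
  anomaly_pass <- frac > link_threshold
  deg <- igraph::degree(ppi)[pool]
  out <- data.frame(
    protein = pool,
    go_pass = unname(go_pass),
    anomaly_link_fraction = unname(frac),
    anomaly_pass = unname(anomaly_pass),
    pass = unname(go_pass & anomaly_pass),
    degree = unname(deg),
    stringsAsFactors = FALSE
  )
  out[order(-out$anomaly_link_fraction, -out$degree, out$protein), ]
}

empty_candidates <- function() {
  data.frame(protein = character(), go_pass = logical(),
             anomaly_link_fraction = numeric(), anomaly_pass = logical(),
             pass = logical(), degree = numeric(),
             stringsAsFactors = FALSE)
}

#' Combine per-penalty candidate tables into robust nominations
#'
#' A candidate is nominated when it passes both the GO and anomaly filters
#' at a minimum number of penalty values (robustness across the
#' regularization path, default 2).
#'
#' @param candidate_tables named list (by rho) of [expand_cluster()]
#'   outputs.
#' @param min_rho_support minimum number of penalties at which a
#'   candidate must pass (default 2).
#' @return data.frame of candidates with rho_support, robust_pass and
#'   `nominated` (pass at every listed criterion), sorted like
#'   [expand_cluster()].
#' @export
nominate_targets <- function(candidate_tables, min_rho_support = 2) {
  if (length(candidate_tables) < min_rho_support) {
    stop("need candidate tables at >= ", min_rho_support, " rho values")
  }
  all_prot <- unique(unlist(lapply(candidate_tables, `[[`, "protein")))
  if (!length(all_prot)) return(cbind(empty_candidates(),
                                      rho_support = integer(),
                                      robust_pass = logical(),
                                      nominated = logical()))
  support <- vapply(all_prot, function(p) {
    sum(vapply(candidate_tables, function(tab) {
      any(tab$protein == p & tab$pass)
    }, TRUE))
  }, 0L)
  # report each candidate with its best (max link fraction) evidence row
  rows <- lapply(all_prot, function(p) {
    recs <- do.call(rbind, lapply(candidate_tables, function(tab) {
      tab[tab$protein == p, , drop = FALSE]
    }))
    recs[which.max(recs$anomaly_link_fraction), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  out$rho_support <- as.integer(support[out$protein])
  out$robust_pass <- out$rho_support >= min_rho_support
  out$nominated <- out$go_pass & out$anomaly_pass & out$robust_pass
  out <- out[order(-out$nominated, -out$anomaly_link_fraction,
                   -out$degree, out$protein), ]
  rownames(out) <- NULL
  out
}
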