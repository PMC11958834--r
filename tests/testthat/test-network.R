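test_that("assembly yields one standardized row per (time, well)", {
  sim <- small_study(seed = 2)
  fm <- assemble_feature_matrix(sim$records, "A")
  # 9 default time points x 2 wells
  expect_equal(nrow(fm$X), 18)
  expect_equal(ncol(fm$X), 8)
  expect_true(all(abs(colMeans(fm$X)) < 1e-9))
  n <- nrow(fm$X)
  sd_pop <- apply(fm$X, 2, sd) * sqrt((n - 1) / n)
  expect_true(all(abs(sd_pop - 1) < 1e-9))

  expect_error(assemble_feature_matrix(sim$records, "no-such"),
               "condition not present")
})

test_that("constant features are dropped and the median aggregator is robust", {
  sim <- small_study(seed = 3)
  rec <- sim$records
  const <- rec[rec$protein == "P01" & rec$compartment == "nucleus", ]
  const$value <- 5
  const$protein <- "PXX"
  rec2 <- rbind(rec, const)
  expect_message(fm <- assemble_feature_matrix(rec2, "A"), "constant")
  expect_false(any(grepl("PXX", colnames(fm$X))))

  # median of {1, 2, 100} is 2 before standardization
  toy <- data.frame(
    condition = "c", time_min = rep(c(5, 10, 15), each = 6),
    well = "w1", cell_id = sprintf("c%d", 1:3),
    protein = rep(c("P1", "P2"), each = 3), compartment = "nucleus",
    measure = "mean_intensity",
    value = c(1, 2, 100, 0, 1, 2, 3, 4, 5, 1, 1, 1, 6, 7, 8, 2, 2, 3)
  )
  dt <- data.table::as.data.table(toy)
  agg <- dt[, .(value = median(value)),
            by = .(time_min, well, protein, compartment, measure)]
  expect_equal(agg$value[agg$time_min == 5 & agg$protein == "P1"], 2)
  fm2 <- assemble_feature_matrix(toy, "c")
  expect_equal(nrow(fm2$X), 3)
})

test_that("the empirical correlation matrix behaves like one", {
  sim <- small_study(seed = 4)
  fm <- assemble_feature_matrix(sim$records, "A")
  S <- feature_correlation(fm)
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, ncol(S)))
  expect_true(all(abs(S) <= 1 + 1e-12))

  # duplicated column pair gives correlation 1
  X <- cbind(fm$X, dup = fm$X[, 1])
  S2 <- feature_correlation(X)
  expect_equal(S2[1, ncol(S2)], 1, tolerance = 1e-9)

  # opposite two-point columns give correlation -1
  X3 <- cbind(a = c(1, -1), b = c(-1, 1), c = c(1, -1))
  X3 <- scale(X3) * sqrt(2 / 1)
  expect_error(feature_correlation(X3[1:2, ]), "at least 3")

  # independent columns at large N have small off-diagonal correlations
  set.seed(10)
  Xi <- scale(matrix(rnorm(1000 * 8), 1000)) * sqrt(1000 / 999)
  Si <- feature_correlation(Xi)
  expect_lt(max(abs(Si[upper.tri(Si)])), 0.12)
})

test_that("graphical lasso honors its closed-form contracts", {
  set.seed(5)
  L <- generate_precision(8, 0.3, seed = 33)
  S <- cov2cor(solve(L))

  # unpenalized fit equals the inverse correlation
  m0 <- graphical_lasso(S, 0)
  expect_lt(max(abs(m0$Lambda - solve(S))), 1e-4)

  # full penalty: diagonal precision, zero edges
  rho_max <- max(abs(S[upper.tri(S)]))
  mfull <- graphical_lasso(S, rho_max + 0.01)
  expect_equal(edge_count(mfull), 0)
  expect_equal(unname(diag(mfull$Lambda)), 1 / diag(S), tolerance = 1e-8)

  # model invariants
  m <- graphical_lasso(S, 0.05)
  expect_equal(m$Lambda, t(m$Lambda))
  expect_lt(max(abs(m$Sigma %*% m$Lambda - diag(8))), 1e-6)
  expect_true(all(abs(m$partials) <= 1 + 1e-9))
  expect_equal(unname(diag(m$partials)), rep(1, 8))

  # singular input without penalty is refused with guidance
  Xs <- matrix(rnorm(4 * 8), 4)
  Ss <- crossprod(scale(Xs) * sqrt(4 / 3)) / 4
  diag(Ss) <- 1
  expect_error(graphical_lasso(Ss, 0), "rho > 0")
})

test_that("partial correlations match the textbook three-variable identity", {
  # Gaussian chain X - Y - Z with known marginal correlations
  r_xy <- 0.6; r_yz <- 0.5
  S <- diag(3)
  S[1, 2] <- S[2, 1] <- r_xy
  S[2, 3] <- S[3, 2] <- r_yz
  S[1, 3] <- S[3, 1] <- r_xy * r_yz  # chain-induced marginal
  m <- graphical_lasso(S, 0)
  textbook <- function(rxz, rxy, ryz) {
    (rxz - rxy * ryz) / sqrt((1 - rxy^2) * (1 - ryz^2))
  }
  expect_equal(m$partials[1, 3], textbook(S[1, 3], r_xy, r_yz),
               tolerance = 1e-6)
  expect_equal(m$partials[1, 3], 0, tolerance = 1e-6)
  expect_gt(m$partials[1, 2], 0)
})

test_that("planted support is recovered with F1 >= 0.8 on a tuned path", {
  f1 <- function(seed, m = 10, N = 200, grid = seq(0.02, 0.5, by = 0.04)) {
    L <- generate_precision(m, 0.3, seed = seed)
    true_sup <- abs(L[upper.tri(L)]) > 0
    withr::with_seed(seed + 1, {
      X <- matrix(rnorm(N * m), N) %*% chol(solve(L))
    })
    X <- scale(X) * sqrt(N / (N - 1))
    S <- crossprod(X) / N
    diag(S) <- 1
    best <- 0
    for (mod in glasso_sweep(S, grid)) {
      est <- abs(mod$partials[upper.tri(mod$partials)]) > 1e-8
      tp <- sum(est & true_sup)
      f <- if (tp == 0) 0 else 2 * tp / (2 * tp + sum(est & !true_sup) +
                                           sum(!est & true_sup))
      best <- max(best, f)
    }
    best
  }
  scores <- vapply(1:20, f1, 0)
  expect_gte(mean(scores), 0.8)
})

test_that("sweeps warm-start consistently and sparsify with rising penalty", {
  set.seed(6)
  L <- generate_precision(10, 0.3, seed = 12)
  S <- cov2cor(solve(L))
  sw <- glasso_sweep(S, c(0.05, 0.2))
  direct <- graphical_lasso(S, 0.2)
  expect_equal(sw[[2]]$Lambda, direct$Lambda, tolerance = 1e-3)
  expect_lte(edge_count(sw[[2]]), edge_count(sw[[1]]))

  single <- glasso_sweep(S, 0.1)
  expect_equal(single[[1]]$Lambda, graphical_lasso(S, 0.1)$Lambda)

  expect_error(glasso_sweep(S, c(0.3, 0.1)), "ascending")

  # empirical path monotonicity across random inputs
  mono <- 0
  for (s in 1:25) {
    withr::with_seed(600 + s, {
      X <- matrix(rnorm(30 * 8), 30)
    })
    X <- scale(X) * sqrt(30 / 29)
    Sr <- crossprod(X) / 30
    diag(Sr) <- 1
    sw <- glasso_sweep(Sr, c(0.5, 0.92))
    mono <- mono + (edge_count(sw[[2]]) <= edge_count(sw[[1]]))
  }
  expect_gte(mono / 25, 0.95)
})

test_that("permuting features permutes the fitted model identically", {
  set.seed(7)
  L <- generate_precision(6, 0.4, seed = 21)
  S <- cov2cor(solve(L))
  perm <- sample(6)
  m1 <- graphical_lasso(S, 0.08, tol = 1e-9, maxit = 1000)
  m2 <- graphical_lasso(S[perm, perm], 0.08, tol = 1e-9, maxit = 1000)
  expect_lt(max(abs(m2$Lambda - m1$Lambda[perm, perm])), 1e-6)
  expect_lt(max(abs(m2$partials - m1$partials[perm, perm])), 1e-6)
})

test_that("networks inherit structure from the precision model", {
  # diagonal precision: no edges
  mdiag <- model_from_precision(diag(2, 4))
  expect_equal(igraph::ecount(build_network(mdiag)$graph), 0)

  # chain X - Y - Z: only adjacent pairs connected
  Lc <- matrix(c(2, -1, 0, -1, 2, -1, 0, -1, 2), 3, 3)
  keys <- data.frame(protein = c("X", "Y", "Z"), compartment = "cytoplasm",
                     measure = "mean_intensity", stringsAsFactors = FALSE)
  mc <- covanet:::new_precision_model(Lc, 0, keys, "c")
  net <- build_network(mc)
  el <- apply(igraph::as_edgelist(net$graph), 1, function(r) {
    paste(sort(sub("\\|.*", "", r)), collapse = "-")
  })
  expect_setequal(el, c("X-Y", "Y-Z"))

  # hub model: the hub has maximal protein degree
  m <- 6
  Lh <- diag(1, m)
  Lh[1, 2:m] <- Lh[2:m, 1] <- -0.3
  diag(Lh) <- rowSums(abs(Lh)) + 1 - diag(Lh)
  keysh <- data.frame(protein = paste0("H", 1:m), compartment = "cytoplasm",
                      measure = "mean_intensity", stringsAsFactors = FALSE)
  mh <- covanet:::new_precision_model(Lh, 0, keysh, "c")
  deg <- protein_degree(build_network(mh))
  expect_equal(names(deg)[1], "H1")

  # edge weights are the partial correlations
  w <- igraph::E(net$graph)$weight
  expect_true(all(abs(w) <= 1))
})

test_that("network exports round-trip through GraphML and TSV", {
  sim <- small_study(seed = 8)
  fm <- assemble_feature_matrix(sim$records, "A")
  mod <- graphical_lasso(feature_correlation(fm), 0.1, keys = fm$keys,
                         condition = "A")
  net <- build_network(mod)
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, gml, tsv)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(net$graph))
  edges <- read.delim(tsv)
  expect_equal(nrow(edges), igraph::ecount(net$graph))
  expect_true(all(c("from", "to", "weight") %in% names(edges)))
})
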