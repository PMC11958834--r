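# Independent oracles used across the suite.

# Monte-Carlo estimate of the expected conditional Gaussian KL divergence
# E_{z ~ p_A}[KL(p_A(x_i | z) || p_B(x_i | z))], via the Gaussian KL
# identity per draw. `E` optionally supplies shared standard normal draws
# (n x >= M-1); returns the estimate and its standard error.
mc_divergence <- function(model_A, model_B, i, n = 2e5, E = NULL) {
  pa <- partition_node(model_A, i)
  pb <- partition_node(model_B, i)
  k <- length(pa$l)
  Z <- if (is.null(E)) {
    matrix(rnorm(n * k), n) %*% chol(pa$W)
  } else {
    E[, seq_len(k), drop = FALSE] %*% chol(pa$W)
  }
  m1 <- -(Z %*% pa$l) / pa$lambda
  m2 <- -(Z %*% pb$l) / pb$lambda
  v1 <- 1 / pa$lambda
  v2 <- 1 / pb$lambda
  kl <- 0.5 * log(v2 / v1) + (v1 + (m1 - m2)^2) / (2 * v2) - 0.5
  list(estimate = mean(kl), se = sd(kl) / sqrt(nrow(Z)))
}

# O(nm) brute-force Cliff's delta by full pair enumeration
cliffs_delta_brute <- function(x, y) {
  gt <- 0; lt <- 0
  for (xi in x) {
    gt <- gt + sum(xi > y)
    lt <- lt + sum(xi < y)
  }
  (gt - lt) / (length(x) * length(y))
}

# precision model without estimation, for oracle tests
model_from_precision <- function(Lambda, condition = NULL) {
  covanet:::new_precision_model(Lambda, rho = 0, keys = NULL,
                                condition = condition)
}

# binary disk mask centred in a square frame
disk_mask <- function(radius, size = 2 * radius + 21) {
  xs <- matrix(rep(seq_len(size), each = size), size)
  ys <- t(xs)
  c0 <- (size + 1) / 2
  (xs - c0)^2 + (ys - c0)^2 <= radius^2
}

# small two-condition study used by several network tests
small_study <- function(seed = 1, ...) {
  spec <- synth_spec(n_proteins = 4,
                     compartments_per_protein = c("nucleus", "cytoplasm"),
                     n_conditions = 2, condition_labels = c("A", "B"),
                     cells_per_well = 20, wells_per_timepoint = 2,
                     seed = seed, ...)
  simulate_feature_table(spec)
}
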