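#' Specification for a synthetic covariation study
#'
#' Describes a three-condition, nine-timepoint immunofluorescence time course
#' of the kind the pipeline consumes: a panel of proteins each measured in
#' several compartments, hundreds of cells per well, and a per-condition
#' latent Gaussian with known sparse precision structure. Condition 1 is the
#' untreated control; by default condition 2 carries the planted neighborhood
#' anomaly (drug response) and condition 3 reverts to the control structure
#' (rescue), so condition pairs mirror a control / treated / rescued design.
#'
#' @param n_proteins number of stained proteins (default 35, a typical
#'   curated antibody panel size).
#' @param compartments_per_protein compartment labels measured per protein.
#' @param n_conditions number of treatment conditions (default 3).
#' @param time_points_min fixation times in minutes, strictly increasing
#'   (default `c(5, 10, 15, 20, 25, 30, 40, 50, 60)`).
#' @param cells_per_well cells imaged per well (default 200).
#' @param wells_per_timepoint replicate wells per (condition, time) (default 2).
#' @param sparsity fraction of nonzero off-diagonal precision entries,
#'   in (0, 1) (default 0.3).
#' @param anomaly_nodes feature indices whose precision-row neighborhoods
#'   differ in the perturbed condition (default feature 1).
#' @param anomaly_magnitude relative perturbation size (default 1.0).
#' @param noise_sd cell-level measurement noise SD (default 1.0).
#' @param trend_amplitude SD of the random low-order polynomial time trend
#'   added per feature, in latent-SD units (default 0.5).
#' @param trend_degree polynomial degree of the time trend (default 2).
#' @param step_time optional response-onset time (minutes) at which a step
#'   of size `step_size` is added to each feature trend; NULL for no step.
#' @param step_size step amplitude used when `step_time` is set.
#' @param perturbed_conditions which conditions carry the planted anomaly
#'   (default condition 2 only).
#' @param condition_labels labels for the conditions.
#' @param seed RNG seed governing every random draw made from this spec.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_proteins = 35,
                       compartments_per_protein = c("nucleus", "cytoplasm", "aggregate"),
                       n_conditions = 3L,
                       time_points_min = c(5, 10, 15, 20, 25, 30, 40, 50, 60),
                       cells_per_well = 200L,
                       wells_per_timepoint = 2L,
                       sparsity = 0.3,
                       anomaly_nodes = 1L,
                       anomaly_magnitude = 1.0,
                       noise_sd = 1.0,
                       trend_amplitude = 0.5,
                       trend_degree = 2L,
                       step_time = NULL,
                       step_size = 0,
                       perturbed_conditions = 2L,
                       condition_labels = NULL,
                       seed = 1L) {
  stopifnot(
    n_proteins >= 1, length(compartments_per_protein) >= 1,
    n_conditions >= 1, cells_per_well >= 1, wells_per_timepoint >= 1,
    sparsity > 0, sparsity < 1,
    anomaly_magnitude > 0, noise_sd >= 0
  )
  if (is.unsorted(time_points_min, strictly = TRUE)) {
    stop("time_points_min must be strictly increasing")
  }
  if (is.null(condition_labels)) {
    condition_labels <- if (n_conditions == 3L) {
      c("control", "treated", "rescued")
    } else {
      paste0("condition", seq_len(n_conditions))
    }
  }
  stopifnot(length(condition_labels) == n_conditions)
  m <- n_proteins * length(compartments_per_protein)
  if (length(anomaly_nodes) && any(anomaly_nodes < 1 | anomaly_nodes > m)) {
    stop("anomaly_nodes out of range 1..", m)
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    compartments_per_protein = compartments_per_protein,
    n_conditions = as.integer(n_conditions),
    time_points_min = time_points_min,
    cells_per_well = as.integer(cells_per_well),
    wells_per_timepoint = as.integer(wells_per_timepoint),
    sparsity = sparsity,
    anomaly_nodes = as.integer(anomaly_nodes),
    anomaly_magnitude = anomaly_magnitude,
    noise_sd = noise_sd,
    trend_amplitude = trend_amplitude,
    trend_degree = as.integer(trend_degree),
    step_time = step_time,
    step_size = step_size,
    perturbed_conditions = as.integer(perturbed_conditions),
    condition_labels = condition_labels,
    m_features = as.integer(m),
    seed = as.integer(seed)
  ), class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat("Synthetic covariation study spec\n")
  cat(sprintf("  %d proteins x %d compartments = %d features\n",
              x$n_proteins, length(x$compartments_per_protein), x$m_features))
  cat(sprintf("  %d conditions (%s), %d time points, %d wells x %d cells\n",
              x$n_conditions, paste(x$condition_labels, collapse = ", "),
              length(x$time_points_min), x$wells_per_timepoint,
              x$cells_per_well))
  cat(sprintf("  sparsity %.2f, anomaly at node(s) %s (magnitude %.2f), seed %d\n",
              x$sparsity, paste(x$anomaly_nodes, collapse = ","),
              x$anomaly_magnitude, x$seed))
  invisible(x)
}

#' Generate a random sparse symmetric positive-definite precision matrix
#'
#' Off-diagonal support is drawn uniformly over upper-triangle positions at
#' the requested fraction; nonzero entries are uniform in magnitude 0.2-0.8
#' with random sign. Positive definiteness is guaranteed by diagonal
#' dominance: each diagonal entry is set to the absolute row sum of its
#' off-diagonals plus a fixed margin of 1.0.
#'
#' @param m number of features (>= 2).
#' @param sparsity requested fraction of nonzero off-diagonal entries in
#'   [0, 1); the realized count is `round(sparsity * m * (m - 1) / 2)`.
#' @param seed RNG seed; NULL uses the current stream.
#' @param margin diagonal-dominance margin (default 1.0).
#' @return m x m precision matrix.
#' @export
generate_precision <- function(m, sparsity, seed = NULL, margin = 1.0) {
  stopifnot(m >= 2, sparsity >= 0, sparsity < 1, margin > 0)
  with_seed(seed, {
    n_pairs <- m * (m - 1L) / 2L
    k <- round(sparsity * n_pairs)
    Lambda <- matrix(0, m, m)
    if (k > 0) {
      pos <- sample.int(n_pairs, k)
      vals <- runif(k, 0.2, 0.8) * sample(c(-1, 1), k, replace = TRUE)
      ut <- which(upper.tri(Lambda))
      Lambda[ut[pos]] <- vals
      Lambda <- Lambda + t(Lambda)
    }
    diag(Lambda) <- rowSums(abs(Lambda)) + margin
    ev <- min(eigen(Lambda, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) stop("internal error: constructed precision not positive definite")
    Lambda
  })
}

#' Perturb the precision-matrix neighborhood of one node
#'
#' Models a between-condition change in the connectivity and correlation
#' strength of a node's first neighbors: every nonzero off-diagonal entry
#' in the node's row/column is re-signed and rescaled by `1 + magnitude`
#' (at magnitude 1 each neighbor coupling reverses sign and doubles).
#' Diagonal entries of affected rows are repaired to preserve their
#' original dominance margin, keeping the result positive definite; all
#' other off-diagonal entries are untouched. The perturbation is
#' deterministic; `seed` is accepted for interface symmetry with the other
#' generators but unused.
#'
#' @param precision symmetric positive-definite precision matrix.
#' @param node index of the perturbed node.
#' @param magnitude relative perturbation size (>= 0; 0 returns the input).
#' @param seed ignored (deterministic operation).
#' @return perturbed positive-definite precision matrix.
#' @export
perturb_neighborhood <- function(precision, node, magnitude, seed = NULL) {
  m <- nrow(precision)
  stopifnot(is.matrix(precision), m == ncol(precision),
            node >= 1, node <= m, magnitude >= 0)
  if (magnitude == 0) return(precision)
  old_diag <- diag(precision)
  old_rowsum <- rowSums(abs(precision)) - abs(old_diag)
  margin <- old_diag - old_rowsum
  out <- precision
  off <- out[node, -node]
  nz <- which(off != 0)
  if (length(nz)) {
    off[nz] <- -off[nz] * (1 + magnitude)
    out[node, -node] <- off
    out[-node, node] <- off
  }
  touched <- unique(c(node, setdiff(seq_len(m), node)[nz]))
  new_rowsum <- rowSums(abs(out)) - abs(diag(out))
  for (j in touched) {
    diag(out)[j] <- new_rowsum[j] + margin[j]
  }
  if (any(diag(out)[touched] > 10 * old_diag[touched])) {
    stop("diagonal repair exceeds 10x the original diagonal; ",
         "reduce the perturbation magnitude")
  }
  ev <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("internal error: repaired precision not positive definite")
  out
}

# condition -> true precision matrices implied by a spec
condition_precisions <- function(spec) {
  base <- generate_precision(spec$m_features, spec$sparsity,
                             seed = spec$seed)
  lapply(seq_len(spec$n_conditions), function(ci) {
    if (!(ci %in% spec$perturbed_conditions)) return(base)
    P <- base
    for (k in seq_along(spec$anomaly_nodes)) {
      P <- perturb_neighborhood(P, spec$anomaly_nodes[k],
                                spec$anomaly_magnitude,
                                seed = spec$seed + 1000L * ci + k)
    }
    P
  })
}

# feature-key table for a spec: protein x compartment, mean_intensity measure
spec_feature_keys <- function(spec) {
  proteins <- sprintf("P%02d", seq_len(spec$n_proteins))
  keys <- expand.grid(
    compartment = spec$compartments_per_protein,
    protein = proteins,
    stringsAsFactors = FALSE
  )[, c("protein", "compartment")]
  keys$measure <- "mean_intensity"
  keys
}

#' Simulate a long-format single-cell feature table with known ground truth
#'
#' Emulates the pipeline's input data: for every condition, each
#' (time point, well) receives one latent feature vector drawn from a
#' zero-mean Gaussian with that condition's true covariance (the inverse of
#' its sparse precision matrix), plus a smooth per-feature time trend. Each
#' cell in the well then reports the latent value plus independent Gaussian
#' noise. Because each protein is stained in separate wells, cross-feature
#' structure exists only at the (time point, well) level, which is exactly
#' what the downstream aggregation recovers.
#'
#' @param spec a [synth_spec()].
#' @return list with `records` (a data.table with columns condition,
#'   time_min, well, cell_id, protein, compartment, measure, value) and
#'   `truth` (per-condition precision matrices, planted anomaly nodes,
#'   latent draws, trend coefficients, feature keys).
#' @export
simulate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  keys <- spec_feature_keys(spec)
  m <- spec$m_features
  precisions <- condition_precisions(spec)
  tt <- spec$time_points_min
  n_t <- length(tt)
  n_w <- spec$wells_per_timepoint
  n_cells <- spec$cells_per_well
  t01 <- (tt - min(tt)) / max(1e-12, diff(range(tt)))

  with_seed(spec$seed + 1L, {
    # per-feature polynomial trend (+ optional onset step), shared across
    # conditions so trends cancel in between-condition comparisons
    coef <- matrix(rnorm(m * (spec$trend_degree + 1L), sd = spec$trend_amplitude),
                   nrow = spec$trend_degree + 1L)
    basis <- vapply(0:spec$trend_degree, function(d) t01^d, numeric(n_t))
    trend <- basis %*% coef  # n_t x m
    if (!is.null(spec$step_time)) {
      trend <- trend + outer(as.numeric(tt >= spec$step_time),
                             rep(spec$step_size, m))
    }

    out <- vector("list", spec$n_conditions)
    latents <- vector("list", spec$n_conditions)
    for (ci in seq_len(spec$n_conditions)) {
      Sigma <- solve(precisions[[ci]])
      lat <- rmvnorm_chol(n_t * n_w, Sigma)  # rows: (time, well)
      latents[[ci]] <- lat
      grid <- data.table::CJ(ti = seq_len(n_t), wi = seq_len(n_w),
                             sorted = FALSE)
      rows <- vector("list", nrow(grid))
      for (g in seq_len(nrow(grid))) {
        ti <- grid$ti[g]; wi <- grid$wi[g]
        latent_row <- lat[(ti - 1L) * n_w + wi, ] + trend[ti, ]
        vals <- rep(latent_row, each = n_cells) +
          rnorm(n_cells * m, sd = spec$noise_sd)
        rows[[g]] <- data.table::data.table(
          condition = spec$condition_labels[ci],
          time_min = tt[ti],
          well = sprintf("t%02d_w%d", ti, wi),
          cell_id = rep(sprintf("c%04d", seq_len(n_cells)), times = m),
          protein = rep(keys$protein, each = n_cells),
          compartment = rep(keys$compartment, each = n_cells),
          measure = rep(keys$measure, each = n_cells),
          value = vals
        )
      }
      out[[ci]] <- data.table::rbindlist(rows)
    }
    records <- data.table::rbindlist(out)

    truth <- list(
      precisions = setNames(precisions, spec$condition_labels),
      anomaly_nodes = spec$anomaly_nodes,
      perturbed_conditions = spec$perturbed_conditions,
      feature_keys = keys,
      latents = setNames(latents, spec$condition_labels),
      trend = trend,
      spec = spec
    )
    list(records = records, truth = truth)
  })
}

#' Write a feature table to tab-delimited text
#'
#' @param records data.frame/data.table of single-cell feature records.
#' @param path output path.
#' @export
write_feature_table <- function(records, path) {
  data.table::fwrite(records, path, sep = "\t")
  invisible(path)
}

#' Read a long-format feature table
#'
#' @param path tab-delimited file with columns condition, time_min, well,
#'   cell_id, protein, compartment, measure, value.
#' @return data.table of records.
#' @export
read_feature_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("condition", "time_min", "well", "cell_id", "protein",
            "compartment", "measure", "value")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("feature table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  dt
}
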