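test_that("generate_precision plants the requested support and stays SPD", {
  # requested support fraction realized exactly (round(0.4 * 10) = 4)
  L <- generate_precision(5, 0.4, seed = 1)
  expect_equal(sum(L[upper.tri(L)] != 0), 4)
  expect_equal(L, t(L))

  # vanishing sparsity gives a diagonal matrix with zero partial correlation
  L0 <- generate_precision(2, 0, seed = 1)
  expect_true(all(L0[upper.tri(L0)] == 0))

  # construction guarantee across seeds: min eigenvalue positive
  for (s in 1:20) {
    Ls <- generate_precision(sample(2:12, 1), runif(1, 0.05, 0.9), seed = s)
    expect_gt(min(eigen(Ls, symmetric = TRUE, only.values = TRUE)$values),
              1e-9)
  }

  # identical seeds give identical matrices
  expect_identical(generate_precision(8, 0.3, seed = 7),
                   generate_precision(8, 0.3, seed = 7))
})

test_that("perturb_neighborhood is local, magnitude-0 neutral, and SPD", {
  # chain precision: nodes coupled along 1-2-3-4-5
  m <- 5
  L <- diag(3, m)
  for (j in 1:(m - 1)) L[j, j + 1] <- L[j + 1, j] <- -1
  expect_identical(perturb_neighborhood(L, 3, 0), L)

  Lp <- perturb_neighborhood(L, 3, 1.0)
  off_changed <- which(L != Lp, arr.ind = TRUE)
  off_changed <- off_changed[off_changed[, 1] != off_changed[, 2], ,
                             drop = FALSE]
  # only row/column 3 off-diagonals differ
  expect_true(all(off_changed[, 1] == 3 | off_changed[, 2] == 3))
  expect_gt(min(eigen(Lp, symmetric = TRUE, only.values = TRUE)$values), 0)

  # magnitude-1 re-sign + rescale on the perturbed row
  expect_equal(Lp[3, 2], -L[3, 2] * 2)
  expect_equal(Lp[3, 4], -L[3, 4] * 2)
})

test_that("simulated feature tables have the promised cardinality and determinism", {
  spec <- synth_spec(n_proteins = 2,
                     compartments_per_protein = c("nucleus", "cytoplasm"),
                     n_conditions = 3, cells_per_well = 5,
                     wells_per_timepoint = 2, seed = 3)
  sim <- simulate_feature_table(spec)
  # 3 conditions x 9 times x 2 wells x 5 cells x 4 features
  expect_equal(nrow(sim$records), 3 * 9 * 2 * 5 * 4)
  expect_equal(length(sim$truth$precisions), 3)

  sim2 <- simulate_feature_table(spec)
  expect_identical(sim$records, sim2$records)
})

test_that("zero noise and flat trends reproduce the latent draws at the medians", {
  spec <- synth_spec(n_proteins = 2,
                     compartments_per_protein = c("nucleus", "cytoplasm"),
                     n_conditions = 1, condition_labels = "only",
                     cells_per_well = 7, wells_per_timepoint = 1,
                     noise_sd = 0, trend_amplitude = 0, seed = 5)
  sim <- simulate_feature_table(spec)
  rec <- sim$records
  lat <- sim$truth$latents[["only"]]
  keys <- sim$truth$feature_keys
  for (ti in c(1, 5, 9)) {
    t_min <- spec$time_points_min[ti]
    for (j in c(1, 4)) {
      vals <- rec$value[rec$time_min == t_min & rec$protein == keys$protein[j] &
                          rec$compartment == keys$compartment[j]]
      expect_equal(median(vals), lat[ti, j], tolerance = 1e-12)
    }
  }
})

test_that("strongly coupled feature pairs covary more than independent pairs", {
  # replicate-averaged check against ground truth: the pair with the
  # strongest true coupling shows larger empirical time-course correlation
  # than the pair with the weakest true marginal correlation
  r_strong <- r_weak <- numeric()
  for (s in 1:20) {
    spec <- synth_spec(n_proteins = 3,
                       compartments_per_protein = c("nucleus", "cytoplasm"),
                       n_conditions = 1, condition_labels = "only",
                       cells_per_well = 10, wells_per_timepoint = 4,
                       trend_amplitude = 0, seed = 100 + s)
    sim <- simulate_feature_table(spec)
    L <- sim$truth$precisions[[1]]
    Struth <- cov2cor(solve(L))
    P <- -cov2cor(L)
    diag(P) <- 0
    diag(Struth) <- 0
    strong <- which(abs(P) == max(abs(P)), arr.ind = TRUE)[1, ]
    ut <- which(upper.tri(P) & P == 0, arr.ind = TRUE)
    if (!nrow(ut)) next
    weak <- ut[which.min(abs(Struth[ut])), ]
    fm <- assemble_feature_matrix(sim$records, "only")
    S <- feature_correlation(fm)
    keys <- sim$truth$feature_keys
    kstr <- paste(keys$protein, keys$compartment, keys$measure, sep = "|")
    col_of <- match(kstr, colnames(S))
    r_strong <- c(r_strong, abs(S[col_of[strong[1]], col_of[strong[2]]]))
    r_weak <- c(r_weak, abs(S[col_of[weak[1]], col_of[weak[2]]]))
  }
  expect_gt(mean(r_strong), mean(r_weak))
})

test_that("rendered fields carry a faithful ground-truth inventory", {
  img <- render_images(n_cells = 5, seed = 2)
  expect_equal(nrow(img$truth$nucleus_centers), 5)
  expect_equal(dim(img$channels$nucleus), c(256, 256, 3))

  # identical seeds give byte-identical stacks
  img2 <- render_images(n_cells = 5, seed = 2)
  expect_identical(img$channels, img2$channels)

  # every planted punctum lies inside exactly one cell polygon
  tp <- img$truth$puncta
  for (i in seq_len(nrow(tp))) {
    inside <- vapply(img$truth$cell_polygons, function(poly) {
      covanet:::point_in_polygon(matrix(tp$x[i]), matrix(tp$y[i]), poly)[1]
    }, TRUE)
    expect_equal(sum(inside), 1)
  }

  # domain-class puncta meet the downstream area split
  expect_true(all(tp$area_px[tp$class == "domain"] >= 50))
  expect_true(all(tp$area_px[tp$class == "aggregate"] < 50))
})

test_that("a punctum-free protein channel yields zero detections", {
  img <- render_images(n_cells = 4, n_aggregates_per_cell = 0,
                       n_domains_per_cell = 0, seed = 9)
  pro <- project_max(img$channels$protein)
  nl <- segment_nuclei(project_max(img$channels$nucleus))
  cl <- segment_cells(project_max(img$channels$cell), nl)
  pn <- detect_puncta(pro, make_compartments(nl, cl))
  expect_equal(nrow(pn$table), 0)
})

test_that("image stacks round-trip through multi-page TIFF", {
  img <- render_images(n_cells = 3, seed = 13)
  p <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(img$channels, p)
  back <- read_image_stack(p, n_z = 3)
  expect_named(back, c("nucleus", "cell", "protein"))
  expect_equal(dim(back$protein), dim(img$channels$protein))
  # 16-bit rescaling preserves structure (channel written scaled to [0, 1])
  expect_gt(cor(as.vector(back$protein), as.vector(img$channels$protein)),
            0.99)
})

test_that("PPI/GO fixtures round-trip exactly with planted filter structure", {
  cluster <- paste0("CL", 1:6)
  fx <- make_expansion_fixture(cluster, high_anomaly_proteins = cluster[1:4],
                               seed = 5)
  ppi_path <- withr::local_tempfile(fileext = ".txt")
  gaf_path <- withr::local_tempfile(fileext = ".gaf")
  write_fixtures(fx, ppi_path, gaf_path)

  ppi <- read_biogrid_tab3(ppi_path)
  go <- read_gaf(gaf_path)

  # round trip: parsed graph equals the intended graph exactly
  g0 <- igraph::simplify(igraph::graph_from_data_frame(fx$ppi_edges,
                                                       directed = FALSE))
  expect_setequal(igraph::V(g0)$name, igraph::V(ppi)$name)
  expect_equal(igraph::ecount(igraph::difference(g0, ppi)), 0)
  expect_equal(igraph::ecount(igraph::difference(ppi, g0)), 0)

  # planted candidate touches 3 of the 4 high-anomaly proteins
  expect_equal(length(intersect(igraph::neighbors(ppi, fx$candidate)$name,
                                fx$high_anomaly_proteins)), 3)
  # low-link decoy touches 1 of 4 (fraction 0.25 < 0.5)
  expect_equal(length(intersect(igraph::neighbors(ppi, fx$decoys[1])$name,
                                fx$high_anomaly_proteins)), 1)
  # GO structure: candidate shares the enriched term, the no-GO decoy not
  expect_true(fx$enriched_term %in% go[[fx$candidate]])
  expect_false(fx$enriched_term %in% go[[fx$decoys[2]]])

  # determinism of the fixture writer
  fx2 <- make_expansion_fixture(cluster, high_anomaly_proteins = cluster[1:4],
                                seed = 5)
  expect_identical(fx, fx2)
})
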