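#' Default pipeline run configuration
#'
#' Settings orchestrating a full synthetic run: simulate feature records,
#' build per-condition networks along a penalty grid, score anomalies for
#' every condition pair, and expand selected clusters through a PPI/GO
#' fixture. The penalty grid brackets the representative value 0.92 used
#' for the headline networks. The single `seed` governs every stochastic
#' stage.
#'
#' @param out_dir output directory of the run.
#' @param seed master RNG seed.
#' @param rhos penalty grid (in (0, 1]); must be non-empty.
#' @param aggregator cross-cell aggregator ("median" or "mean").
#' @param high_quantile within-cluster quantile defining high anomaly.
#' @param q_threshold GO enrichment significance threshold.
#' @param min_rho_support penalties a candidate must pass at.
#' @param pm_width,area_threshold,h_factor feature-extraction parameters
#'   (recorded for provenance; image stages use them when run).
#' @param synth arguments overriding [synth_spec()] defaults; the default
#'   trims the panel to 13 proteins (M = 39 features) for a desk-scale run.
#' @param ppi_path,gaf_path optional external PPI/GO files; when NULL the
#'   run writes and uses a planted synthetic fixture.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = "covanet_run",
                       seed = 1L,
                       rhos = c(0.80, 0.86, 0.92, 0.96),
                       aggregator = "median",
                       high_quantile = 0.8,
                       q_threshold = 0.05,
                       min_rho_support = 2,
                       pm_width = 3,
                       area_threshold = 50,
                       h_factor = 3,
                       synth = list(n_proteins = 13),
                       ppi_path = NULL,
                       gaf_path = NULL) {
  if (!length(rhos) || any(rhos <= 0 | rhos > 1)) {
    stop("rhos must be a non-empty grid with values in (0, 1]")
  }
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), rhos = sort(rhos),
              aggregator = aggregator, high_quantile = high_quantile,
              q_threshold = q_threshold,
              min_rho_support = min_rho_support, pm_width = pm_width,
              area_threshold = area_threshold, h_factor = h_factor,
              synth = synth, ppi_path = ppi_path, gaf_path = gaf_path)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' The configuration round-trips losslessly through its file form.
#'
#' @param path YAML file path.
#' @param config a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path)
  invisible(path)
}

# md5 of a TSV with rows canonicalized (sorted) so cosmetic order changes
# cannot break idempotence checks
canonical_checksum <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 1) lines <- c(lines[1], sort(lines[-1]))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic covariation pipeline
#'
#' Executes, in dependency order: data simulation (feature records plus a
#' planted PPI/GO fixture), per-condition network estimation along the
#' penalty grid, anomaly scoring for every condition pair, and cluster
#' expansion with candidate nomination. Stage outputs are tab-delimited
#' files under `config$out_dir`; a JSON manifest records the
#' configuration, per-output canonical checksums, dropped features,
#' warnings, and timings. Re-running with an identical configuration
#' reuses up-to-date stage outputs.
#'
#' @param config a [run_config()] (or a path to its YAML form).
#' @param force re-run all stages even when outputs are up to date.
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config(), force = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (length(config$ppi_path) && !file.exists(config$ppi_path)) {
    stop("configured PPI file does not exist: ", config$ppi_path)
  }
  if (length(config$gaf_path) && !file.exists(config$gaf_path)) {
    stop("configured GO annotation file does not exist: ", config$gaf_path)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  prev <- if (!force && file.exists(manifest_path)) {
    tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
  } else NULL
  cfg_tmp <- tempfile(); on.exit(unlink(cfg_tmp))
  write_run_config(config, cfg_tmp)
  cfg_hash <- unname(tools::md5sum(cfg_tmp))
  if (!is.null(prev) && !identical(prev$config_hash, cfg_hash)) prev <- NULL

  # fully up-to-date run: every previously recorded output still matches
  if (!is.null(prev) && length(prev$checksums)) {
    all_files <- file.path(config$out_dir, names(prev$checksums))
    if (all(file.exists(all_files)) &&
        all(vapply(all_files, function(f) {
          identical(prev$checksums[[basename(f)]], canonical_checksum(f))
        }, TRUE))) {
      prev$stages <- lapply(prev$stages, function(s) "up-to-date")
      writeLines(jsonlite::toJSON(prev, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE, null = "null"),
                 manifest_path)
      return(invisible(prev))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("covanet")),
    config_hash = cfg_hash,
    config = unclass(config),
    stages = list(), checksums = list(), warnings = list(),
    dropped_features = list(), timing = list()
  )
  log_stage <- function(name, t0, outputs, skipped = FALSE) {
    manifest$stages[[name]] <<- if (skipped) "up-to-date" else "run"
    manifest$timing[[name]] <<- round(as.numeric(Sys.time()) - t0, 3)
    for (f in outputs) {
      manifest$checksums[[basename(f)]] <<- canonical_checksum(f)
    }
  }
  up_to_date <- function(outputs) {
    !is.null(prev) && all(file.exists(outputs)) &&
      all(vapply(outputs, function(f) {
        identical(prev$checksums[[basename(f)]], canonical_checksum(f))
      }, TRUE))
  }

  # --- stage: simulate --------------------------------------------------
  spec <- do.call(synth_spec, c(config$synth, list(seed = config$seed)))
  feat_path <- file.path(config$out_dir, "features.tsv")
  ppi_path <- config$ppi_path %||% file.path(config$out_dir, "synthetic_ppi.tab3.txt")
  gaf_path <- config$gaf_path %||% file.path(config$out_dir, "synthetic_go.gaf")
  truth_path <- file.path(config$out_dir, "truth.rds")
  sim_out <- c(feat_path)
  t0 <- as.numeric(Sys.time())
  if (up_to_date(sim_out) && file.exists(truth_path)) {
    truth <- readRDS(truth_path)
    records <- read_feature_table(feat_path)
    log_stage("simulate", t0, sim_out, skipped = TRUE)
  } else {
    sim <- simulate_feature_table(spec)
    records <- sim$records
    truth <- sim$truth
    write_feature_table(records, feat_path)
    saveRDS(truth, truth_path)
    log_stage("simulate", t0, sim_out)
  }

  # --- stage: network ---------------------------------------------------
  t0 <- as.numeric(Sys.time())
  conditions <- spec$condition_labels
  models <- list(); networks <- list()
  net_files <- character()
  for (cond in conditions) {
    wrn <- character()
    fm <- withCallingHandlers(
      assemble_feature_matrix(records, cond, aggregator = config$aggregator),
      warning = function(w) {
        wrn <<- c(wrn, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    if (length(wrn)) manifest$warnings[[cond]] <- wrn
    manifest$dropped_features[[cond]] <- fm$dropped
    S <- feature_correlation(fm)
    sw <- glasso_sweep(S, config$rhos, keys = fm$keys, condition = cond)
    models[[cond]] <- sw
    networks[[cond]] <- lapply(sw, build_network)
    for (r in names(sw)) {
      net <- networks[[cond]][[r]]
      base <- file.path(config$out_dir,
                        sprintf("network_%s_rho%s", cond, gsub("\\s", "", r)))
      export_network(net, paste0(base, ".graphml"), paste0(base, "_edges.tsv"))
      net_files <- c(net_files, paste0(base, "_edges.tsv"))
    }
  }
  log_stage("network", t0, net_files)

  # --- stage: anomaly ---------------------------------------------------
  t0 <- as.numeric(Sys.time())
  anomaly_files <- character()
  heatmaps <- list()
  for (r in names(models[[1]])) {
    hm <- anomaly_heatmap(lapply(models, `[[`, r))
    heatmaps[[r]] <- hm
    tab <- do.call(rbind, lapply(hm$results, as.data.frame))
    f <- file.path(config$out_dir,
                   sprintf("anomaly_rho%s.tsv", gsub("\\s", "", r)))
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    anomaly_files <- c(anomaly_files, f)
  }
  log_stage("anomaly", t0, anomaly_files)

  # --- stage: expand ----------------------------------------------------
  t0 <- as.numeric(Sys.time())
  drug_cond <- if (length(spec$perturbed_conditions)) {
    conditions[spec$perturbed_conditions[1]]
  } else conditions[min(2, length(conditions))]
  pair_idx <- vapply(heatmaps[[1]]$results, function(res) {
    drug_cond %in% res$pair
  }, TRUE)
  candidate_tables <- list()
  cluster_rows <- list()
  fixture <- NULL
  for (r in names(models[[1]])) {
    net <- networks[[drug_cond]][[r]]
    gp <- collapse_to_proteins(net)
    cs <- select_dense_clusters(link_communities(gp))
    sel <- which(cs$selected)
    if (!length(sel)) next
    # largest selected cluster, as the expansion focus
    ci <- sel[which.max(vapply(cs$vertex_sets[sel], length, 0L))]
    cluster_proteins <- cs$vertex_sets[[ci]]
    cluster_rows[[r]] <- data.frame(
      rho = r, cluster = ci, protein = cluster_proteins,
      mean_degree = cs$mean_degree[ci], stringsAsFactors = FALSE)
    res <- heatmaps[[r]]$results[[which(pair_idx)[1]]]
    pa <- protein_anomaly(res)
    high <- high_anomaly_proteins(pa, cluster_proteins,
                                  config$high_quantile)
    if (is.null(fixture)) {
      if (is.null(config$ppi_path)) {
        fixture <- make_expansion_fixture(cluster_proteins,
                                          high_anomaly_proteins = head(high, 4),
                                          seed = config$seed + 7L)
        write_fixtures(fixture, ppi_path, gaf_path)
      }
      ppi <- read_biogrid_tab3(ppi_path)
      go_map <- read_gaf(gaf_path)
    }
    enr <- go_enrichment(intersect(cluster_proteins, names(go_map)), go_map,
                         union(names(go_map), cluster_proteins),
                         q_threshold = config$q_threshold)
    enriched_terms <- enr$term[enr$enriched]
    candidate_tables[[r]] <- expand_cluster(cluster_proteins, high, ppi,
                                            enriched_terms, go_map)
  }
  expand_files <- character()
  if (length(cluster_rows)) {
    f <- file.path(config$out_dir, "clusters.tsv")
    utils::write.table(do.call(rbind, cluster_rows), f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    expand_files <- c(expand_files, f)
  }
  if (length(candidate_tables) >= config$min_rho_support) {
    nom <- nominate_targets(candidate_tables, config$min_rho_support)
    f <- file.path(config$out_dir, "candidates.tsv")
    utils::write.table(nom, f, sep = "\t", quote = FALSE, row.names = FALSE)
    expand_files <- c(expand_files, f)
  }
  log_stage("expand", t0, expand_files)

  manifest_json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                    pretty = TRUE, null = "null")
  writeLines(manifest_json, manifest_path)
  invisible(manifest)
}

#' Render report figures and summaries for a completed run
#'
#' Emits per-penalty network diagrams (subnodes colored by localization
#' class: blue nucleus, pink cytoplasm, orange domains/aggregates, green
#' PM), an anomaly heatmap per penalty, per-feature time-course plots
#' (median line with interquartile band) for the highest-anomaly
#' features, and the candidate table. Missing stage outputs produce a
#' partial report with warnings.
#'
#' @param run_dir directory of a [run_pipeline()] run.
#' @param n_timecourse number of top-anomaly features to plot.
#' @return invisible character vector of files written.
#' @export
report_pipeline <- function(run_dir, n_timecourse = 4) {
  written <- character()
  loc_palette <- c(nucleus = "#4477CC", cytoplasm = "#EE88AA",
                   domain_aggregate = "#EE9933", pm = "#44AA77")
  edge_files <- list.files(run_dir, "^network_.*_edges\\.tsv$",
                           full.names = TRUE)
  if (!length(edge_files)) warning("no network outputs found in ", run_dir)
  for (f in edge_files) {
    gml <- sub("_edges\\.tsv$", ".graphml", f)
    if (!file.exists(gml)) next
    g <- igraph::read_graph(gml, format = "graphml")
    png_path <- sub("_edges\\.tsv$", ".png", f)
    grDevices::png(png_path, width = 900, height = 900, type = "cairo")
    cols <- loc_palette[igraph::V(g)$localization_class]
    cols[is.na(cols)] <- "grey70"
    w <- abs(igraph::E(g)$weight %||% numeric())
    plot(g, vertex.color = cols, vertex.size = 4, vertex.label = NA,
         edge.width = 1 + 2 * w,
         layout = igraph::layout_with_fr(g, weights = w + 1e-6))
    graphics::legend("topleft", legend = names(loc_palette),
                     pt.bg = loc_palette, pch = 21, bty = "n")
    grDevices::dev.off()
    written <- c(written, png_path)
  }
  anomaly_files <- list.files(run_dir, "^anomaly_rho.*\\.tsv$",
                              full.names = TRUE)
  if (!length(anomaly_files)) warning("no anomaly outputs found in ", run_dir)
  top_features <- character()
  for (f in anomaly_files) {
    tab <- utils::read.delim(f)
    scores <- do.call(cbind, lapply(split(tab, tab$pair),
                                    function(d) setNames(d$a, d$feature_key)))
    ord <- order(apply(scores, 1, max), decreasing = TRUE)
    scores <- scores[ord, , drop = FALSE]
    top_features <- unique(c(top_features, rownames(scores)[seq_len(
      min(n_timecourse, nrow(scores)))]))
    png_path <- sub("\\.tsv$", ".png", f)
    grDevices::png(png_path, width = 700,
                   height = max(400, 12 * nrow(scores)), type = "cairo")
    graphics::par(mar = c(8, 10, 2, 2))
    graphics::image(t(scores[rev(seq_len(nrow(scores))), , drop = FALSE]),
                    axes = FALSE, col = grDevices::hcl.colors(64, "YlOrRd",
                                                              rev = TRUE))
    graphics::axis(1, at = seq(0, 1, length.out = ncol(scores)),
                   labels = colnames(scores), las = 2, cex.axis = 0.8)
    graphics::axis(2, at = seq(0, 1, length.out = min(nrow(scores), 40)),
                   labels = rev(rownames(scores))[round(seq(1, nrow(scores),
                                                            length.out = min(nrow(scores), 40)))],
                   las = 2, cex.axis = 0.5)
    grDevices::dev.off()
    written <- c(written, png_path)
  }
  feat_path <- file.path(run_dir, "features.tsv")
  if (file.exists(feat_path) && length(top_features)) {
    records <- read_feature_table(feat_path)
    records[, feature := feature_key_string(protein, compartment, measure)]
    sub <- records[records$feature %in% top_features]
    qs <- sub[, .(med = stats::median(value),
                  lo = stats::quantile(value, 0.25),
                  hi = stats::quantile(value, 0.75)),
              by = .(condition, time_min, feature)]
    png_path <- file.path(run_dir, "timecourses.png")
    grDevices::png(png_path, width = 1000, height = 300 * length(top_features),
                   type = "cairo")
    graphics::par(mfrow = c(length(top_features), 1), mar = c(4, 4, 2, 1))
    for (tf in top_features) {
      d <- qs[qs$feature == tf]
      conds <- unique(d$condition)
      cols <- grDevices::hcl.colors(length(conds), "Dark 3")
      plot(NA, xlim = range(d$time_min), ylim = range(c(d$lo, d$hi)),
           xlab = "time (min)", ylab = "feature value", main = tf)
      for (k in seq_along(conds)) {
        dc <- d[d$condition == conds[k]][order(time_min)]
        graphics::polygon(c(dc$time_min, rev(dc$time_min)),
                          c(dc$lo, rev(dc$hi)),
                          col = grDevices::adjustcolor(cols[k], 0.2),
                          border = NA)
        graphics::lines(dc$time_min, dc$med, col = cols[k], lwd = 2)
      }
      graphics::legend("topright", legend = conds, col = cols, lwd = 2,
                       bty = "n")
    }
    grDevices::dev.off()
    written <- c(written, png_path)
  } else if (!file.exists(feat_path)) {
    warning("feature table missing; time-course plots skipped")
  }
  invisible(written)
}
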