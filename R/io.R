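#' Read a BioGRID TAB3-dialect interaction file into an undirected graph
#'
#' Requires the `Official Symbol Interactor A` and `Official Symbol
#' Interactor B` columns; a leading `#` on the header line is tolerated.
#' Self-loops and duplicate/reciprocal rows are collapsed to a simple
#' undirected graph on official symbols.
#'
#' @param path tab-delimited interaction file.
#' @return igraph undirected simple graph.
#' @export
read_biogrid_tab3 <- function(path) {
  if (!file.exists(path)) stop("PPI file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  names(dt) <- sub("^#\\s*", "", names(dt))
  need <- c("Official Symbol Interactor A", "Official Symbol Interactor B")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("PPI file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(dt) == 0) stop("PPI file ", path, " contains no interaction rows")
  edges <- unique(dt[, need, with = FALSE])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read a GAF 2.2-dialect annotation file into a protein -> GO term map
#'
#' Comment lines prefixed `!` (including the version pragma) are skipped;
#' rows whose qualifier contains `NOT` are excluded per GAF semantics.
#' Symbols are taken from the DB Object Symbol column, terms from GO ID.
#'
#' @param path GAF file.
#' @return named list mapping protein symbol to character vector of GO ids.
#' @export
read_gaf <- function(path) {
  if (!file.exists(path)) stop("GO annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!")]
  if (!length(lines)) stop("GAF file ", path, " contains no annotation rows")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol_ok <- vapply(parts, length, 0L) >= 5L
  if (!any(ncol_ok)) stop("GAF file ", path, " contains no parseable rows")
  parts <- parts[ncol_ok]
  sym <- vapply(parts, `[`, "", 3L)
  qual <- vapply(parts, `[`, "", 4L)
  term <- vapply(parts, `[`, "", 5L)
  keep <- !grepl("\\bNOT\\b", qual)
  sym <- sym[keep]; term <- term[keep]
  if (!length(sym)) stop("GAF file ", path, " has no usable (non-NOT) rows")
  split(term, sym) |> lapply(unique)
}

#' Write interactions as a BioGRID TAB3-dialect file
#'
#' @param edges two-column data.frame/matrix of interactor symbols.
#' @param path output path.
#' @export
write_ppi_fixture <- function(edges, path) {
  edges <- as.data.frame(edges)
  stopifnot(ncol(edges) >= 2)
  out <- data.frame(
    `#BioGRID Interaction ID` = seq_len(nrow(edges)),
    `Official Symbol Interactor A` = edges[[1]],
    `Official Symbol Interactor B` = edges[[2]],
    `Experimental System` = "Two-hybrid",
    `Experimental System Type` = "physical",
    `Organism ID Interactor A` = 9606L,
    `Organism ID Interactor B` = 9606L,
    check.names = FALSE
  )
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write PPI fixture to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Write a protein -> GO term map as a GAF 2.2-dialect file
#'
#' @param go_map named list mapping protein symbol to GO id vector.
#' @param path output path.
#' @export
write_gaf_fixture <- function(go_map, path) {
  sym <- rep(names(go_map), lengths(go_map))
  term <- unlist(go_map, use.names = FALSE)
  rows <- vapply(seq_along(sym), function(i) {
    paste(c("SYNTHDB", paste0("ID:", sym[i]), sym[i], "enables", term[i],
            "SYNTH:0000001", "IDA", "", "P", sym[i], "", "protein",
            "taxon:9606", "20260101", "SYNTHDB", "", ""),
          collapse = "\t")
  }, "")
  ok <- tryCatch({
    writeLines(c("!gaf-version: 2.2", rows), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write GAF fixture to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Build a planted PPI/GO expansion fixture
#'
#' Constructs a PPI graph and GO annotation map around a cluster of network
#' proteins so the expansion filters have a known right answer: one planted
#' candidate is PPI-adjacent to a stated fraction (default 3 of 4) of the
#' cluster's high-anomaly proteins and shares the cluster-enriched GO term;
#' one decoy has too few anomaly links (1 of 4) and one decoy has the links
#' but no shared GO term. Background proteins dilute the GO term so the
#' cluster enrichment is real.
#'
#' @param cluster_proteins proteins of the extracted cluster.
#' @param high_anomaly_proteins subset of `cluster_proteins` flagged as
#'   high-anomaly (default: the first 4).
#' @param candidate,decoy_low_links,decoy_no_go symbols for the planted
#'   candidate and the two decoy classes.
#' @param enriched_term GO id planted as cluster-enriched.
#' @param n_background number of background proteins in the PPI/GO universe.
#' @param candidate_links how many high-anomaly proteins the candidate
#'   touches (default 3).
#' @param decoy_links how many the low-link decoy touches (default 1).
#' @param seed RNG seed for background wiring.
#' @return list with `ppi_edges` (two-column data.frame), `go_map` (named
#'   list), and the planted identities.
#' @export
make_expansion_fixture <- function(cluster_proteins,
                                   high_anomaly_proteins = head(cluster_proteins, 4),
                                   candidate = "CAND1",
                                   decoy_low_links = "DECOY_LOWLINK",
                                   decoy_no_go = "DECOY_NOGO",
                                   enriched_term = "GO:0001111",
                                   n_background = 60,
                                   candidate_links = NULL,
                                   decoy_links = NULL,
                                   seed = 1L) {
  stopifnot(length(high_anomaly_proteins) >= 1,
            all(high_anomaly_proteins %in% cluster_proteins))
  # defaults: candidate clearly above the 50% rule, decoy clearly below
  if (is.null(candidate_links)) {
    candidate_links <- max(1, ceiling(0.75 * length(high_anomaly_proteins)))
  }
  if (is.null(decoy_links)) {
    decoy_links <- max(1, floor(0.25 * length(high_anomaly_proteins)))
  }
  stopifnot(candidate_links <= length(high_anomaly_proteins),
            decoy_links <= length(high_anomaly_proteins))
  with_seed(seed, {
    bg <- sprintf("BG%03d", seq_len(n_background))
    # intra-cluster ring so every cluster protein (and hence every
    # high-anomaly protein) is present in the PPI universe
    ring <- data.frame(a = cluster_proteins,
                       b = cluster_proteins[c(2:length(cluster_proteins), 1)])
    edges <- rbind(
      ring,
      data.frame(a = candidate,
                 b = high_anomaly_proteins[seq_len(candidate_links)]),
      data.frame(a = decoy_low_links,
                 b = high_anomaly_proteins[seq_len(decoy_links)]),
      data.frame(a = decoy_no_go,
                 b = high_anomaly_proteins[seq_len(min(candidate_links,
                                                       length(high_anomaly_proteins)))])
    )
    # random background scaffolding that avoids the high-anomaly set so it
    # cannot create accidental candidates
    n_scaffold <- max(2 * n_background, 40)
    scaffold <- data.frame(
      a = sample(bg, n_scaffold, replace = TRUE),
      b = sample(c(bg, setdiff(cluster_proteins, high_anomaly_proteins)),
                 n_scaffold, replace = TRUE)
    )
    scaffold <- scaffold[scaffold$a != scaffold$b, ]
    edges <- unique(rbind(edges, scaffold))

    go_map <- c(
      setNames(lapply(cluster_proteins, function(p) enriched_term),
               cluster_proteins),
      setNames(list(c(enriched_term, "GO:0009999")), candidate),
      setNames(list(c(enriched_term, "GO:0008888")), decoy_low_links),
      setNames(list("GO:0007777"), decoy_no_go),
      setNames(lapply(bg, function(p) {
        if (runif(1) < 0.05) c(enriched_term, "GO:0006666") else "GO:0006666"
      }), bg)
    )
    list(
      ppi_edges = edges,
      go_map = go_map,
      candidate = candidate,
      decoys = c(decoy_low_links, decoy_no_go),
      enriched_term = enriched_term,
      cluster_proteins = cluster_proteins,
      high_anomaly_proteins = high_anomaly_proteins,
      background = bg
    )
  })
}

#' Write a planted expansion fixture to PPI and GAF files
#'
#' @param fixture list from [make_expansion_fixture()].
#' @param ppi_path,gaf_path output paths.
#' @export
write_fixtures <- function(fixture, ppi_path, gaf_path) {
  write_ppi_fixture(fixture$ppi_edges, ppi_path)
  write_gaf_fixture(fixture$go_map, gaf_path)
  invisible(list(ppi = ppi_path, gaf = gaf_path))
}
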