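#' Maximum intensity projection of a z-stack
#'
#' @param zstack 3D array in (y, x, z) order with at least one plane, or a
#'   2D matrix (returned as is).
#' @return 2D matrix of per-pixel maxima over z.
#' @export
project_max <- function(zstack) {
  if (is.matrix(zstack)) return(zstack)
  d <- dim(zstack)
  if (is.null(d) || length(d) != 3 || d[3] < 1) {
    stop("zstack must be a (y, x, z) array with at least one plane")
  }
  out <- zstack[, , 1]
  if (d[3] > 1) {
    for (z in 2:d[3]) out <- pmax(out, zstack[, , z])
  }
  out
}

# normalize to [0,1]; constant images map to all-zero
norm01 <- function(img) {
  rng <- range(img)
  if (diff(rng) <= 0) return(matrix(0, nrow(img), ncol(img)))
  (img - rng[1]) / diff(rng)
}

#' Segment nuclei from a nuclear-marker image
#'
#' Global Otsu threshold, watershed splitting of touching blobs seeded at
#' distance-transform maxima, and removal of regions below `min_area`.
#'
#' @param nuclear_image 2D grayscale matrix.
#' @param min_area minimum region area in px^2.
#' @return integer label matrix (0 = background); blank images give zero
#'   labels.
#' @export
segment_nuclei <- function(nuclear_image, min_area = 40) {
  stopifnot(is.matrix(nuclear_image))
  imgn <- norm01(nuclear_image)
  if (all(imgn == 0)) return(matrix(0L, nrow(imgn), ncol(imgn)))
  th <- EBImage::otsu(EBImage::Image(imgn))
  bw <- imgn > th
  if (!any(bw)) return(matrix(0L, nrow(imgn), ncol(imgn)))
  dm <- EBImage::distmap(EBImage::Image(bw * 1))
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes < min_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  relabel_sequential(lab)
}

# compact label ids to 1..k
relabel_sequential <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(matrix(0L, nrow(lab), ncol(lab)))
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (k in seq_along(ids)) out[lab == ids[k]] <- k
  out
}

#' Segment cells from a cell-body marker image, seeded at nuclei
#'
#' Voronoi-style propagation of nucleus seeds over the thresholded
#' cell-marker foreground, so cells tile the foreground and each cell
#' contains its seed nucleus (one cell per nucleus). A nucleus falling
#' outside the foreground receives its own 2 px-dilated nucleus as cell
#' area, with a warning.
#'
#' @param cell_marker_image 2D grayscale matrix.
#' @param nuclei integer label matrix from [segment_nuclei()].
#' @return integer label matrix with the same label ids as `nuclei`.
#' @export
segment_cells <- function(cell_marker_image, nuclei) {
  stopifnot(is.matrix(cell_marker_image),
            all(dim(cell_marker_image) == dim(nuclei)))
  if (!any(nuclei > 0)) return(matrix(0L, nrow(nuclei), ncol(nuclei)))
  imgn <- norm01(cell_marker_image)
  th <- if (all(imgn == 0)) 1 else EBImage::otsu(EBImage::Image(imgn))
  fg <- imgn > th
  ids <- sort(unique(nuclei[nuclei > 0]))
  outside <- vapply(ids, function(k) !any(fg[nuclei == k]), TRUE)
  if (any(outside)) {
    warning(sum(outside), " nucleus/nuclei outside the cell-marker ",
            "foreground; using dilated nuclei as their cell areas")
  }
  mask <- fg | nuclei > 0
  lab <- EBImage::propagate(EBImage::Image(imgn), seeds = nuclei,
                            mask = mask)
  lab <- EBImage::imageData(lab)
  if (any(outside)) {
    brush <- EBImage::makeBrush(5, "disc")
    for (k in ids[outside]) {
      dil <- EBImage::imageData(
        EBImage::dilate(EBImage::Image((nuclei == k) * 1), brush)) > 0.5
      lab[dil & lab == 0] <- k
    }
  }
  storage.mode(lab) <- "integer"
  lab
}

#' Build per-cell compartment masks
#'
#' The cytoplasm of a cell is its cell area minus its nucleus (pixel-exact
#' set difference), and the plasma-membrane (PM) ring is the band of cell
#' pixels within `pm_width` of the cell boundary (inner-erosion
#' difference). A `pm_width` of 0 gives empty rings; a ring that would
#' swallow the whole cell is capped at the cytoplasm with a warning.
#'
#' @param nuclei,cells aligned integer label matrices sharing label ids.
#' @param pm_width ring width in px (default 3).
#' @return object of class `compartment_masks`: list with label matrices
#'   `nuclei`, `cells`, `cytoplasm`, `pm` and the vector of cell ids.
#' @export
make_compartments <- function(nuclei, cells, pm_width = 3) {
  stopifnot(all(dim(nuclei) == dim(cells)), pm_width >= 0)
  ids <- sort(unique(cells[cells > 0]))
  cyt <- cells
  cyt[nuclei > 0] <- 0L
  pm <- matrix(0L, nrow(cells), ncol(cells))
  if (pm_width > 0 && length(ids)) {
    brush <- EBImage::makeBrush(2 * round(pm_width) + 1, "disc")
    capped <- FALSE
    for (k in ids) {
      own <- cells == k
      er <- EBImage::imageData(
        EBImage::erode(EBImage::Image(own * 1), brush)) > 0.5
      ring <- own & !er
      if (!any(er)) {  # ring would cover the entire cell
        ring <- own & cyt == k
        capped <- TRUE
      }
      pm[ring] <- k
    }
    if (capped) {
      warning("pm_width >= cell radius for some cell(s); PM ring capped ",
              "at the cytoplasm")
    }
  }
  structure(list(nuclei = nuclei, cells = cells, cytoplasm = cyt,
                 pm = pm, cell_ids = ids),
            class = "compartment_masks")
}

#' Detect puncta (domains and aggregates) in a protein channel
#'
#' Regional maxima are found by the h-maxima transform (grayscale
#' reconstruction of `image - h` under `image`) on a lightly smoothed
#' copy, and each maximum is grown to its half-maximum extent over the
#' local cell background (the connected region above halfway between the
#' peak and the cell's median level). Regions with area at least
#' `area_threshold` are classed as domains, smaller ones as aggregates;
#' aggregates touching the PM ring are additionally recorded as
#' PM-associated. Detections outside any cell are discarded.
#'
#' @param protein_image 2D grayscale matrix.
#' @param masks a [make_compartments()] result.
#' @param h intensity prominence; default `h_factor` times the robust SD
#'   (median absolute deviation) of the smoothed image.
#' @param h_factor multiplier for the default prominence (default 3).
#' @param area_threshold domain/aggregate area split in px^2 (default 50).
#' @param smooth_sigma Gaussian pre-smoothing SD in px (default 1; 0
#'   disables), suppressing shot-noise maxima before detection.
#' @param min_height_factor detections whose peak does not rise above the
#'   image median by this many robust SDs are discarded (default 5),
#'   rejecting residual noise maxima.
#' @return object of class `puncta_set`: list with label matrices `domain`,
#'   `aggregate`, `pm_aggregate` and a data.frame `table` (label, cell,
#'   class, area, pm_associated).
#' @export
detect_puncta <- function(protein_image, masks, h = NULL, h_factor = 3,
                          area_threshold = 50, smooth_sigma = 1,
                          min_height_factor = 5) {
  stopifnot(inherits(masks, "compartment_masks"),
            all(dim(protein_image) == dim(masks$cells)))
  img <- if (smooth_sigma > 0) {
    EBImage::imageData(EBImage::gblur(EBImage::Image(protein_image),
                                      sigma = smooth_sigma))
  } else protein_image
  rsd <- max(mad(img), 1e-6)
  if (is.null(h)) h <- h_factor * rsd
  floor_level <- median(img) + min_height_factor * rsd
  recon <- .grey_reconstruct(img - h, img)
  resid <- img - recon                  # in [0, h]
  seeds <- resid >= h - 1e-9            # strict h-maxima plateaus
  empty <- matrix(0L, nrow(protein_image), ncol(protein_image))
  if (!any(seeds)) {
    return(structure(list(domain = empty, aggregate = empty,
                          pm_aggregate = empty,
                          table = empty_puncta_table()),
                     class = "puncta_set"))
  }
  seed_lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(seeds * 1)))
  # per-cell background level: median of the (mostly punctum-free) cell area
  cell_bg <- vapply(masks$cell_ids, function(k) {
    stats::median(img[masks$cells == k])
  }, 0)
  names(cell_bg) <- masks$cell_ids
  lab <- empty
  next_id <- 0L
  for (sk in sort(unique(seed_lab[seed_lab > 0]))) {
    comp <- seed_lab == sk
    p <- max(img[comp])
    if (p < floor_level) next           # noise maximum
    cv <- masks$cells[comp]; cv <- cv[cv > 0]
    if (!length(cv)) next               # seed outside all cells
    cellk <- as.integer(names(which.max(table(cv))))
    bg <- cell_bg[[as.character(cellk)]]
    thr <- (p + bg) / 2                 # half-maximum above local background
    above <- EBImage::imageData(
      EBImage::bwlabel(EBImage::Image((img >= thr) * 1)))
    region_id <- unique(above[comp])
    region_id <- region_id[region_id > 0][1]
    px <- above == region_id
    if (any(lab[px] > 0)) next          # already claimed by a nearby seed
    next_id <- next_id + 1L
    lab[px] <- next_id
  }
  keep <- seq_len(next_id)
  if (!length(keep)) {
    return(structure(list(domain = empty, aggregate = empty,
                          pm_aggregate = empty,
                          table = empty_puncta_table()),
                     class = "puncta_set"))
  }

  domain <- empty; aggregate <- empty; pm_agg <- empty
  rows <- list()
  for (k in keep) {
    px <- lab == k
    cell_votes <- masks$cells[px]
    cell_votes <- cell_votes[cell_votes > 0]
    if (!length(cell_votes)) next  # outside all cells
    cell <- as.integer(names(which.max(table(cell_votes))))
    area <- sum(px)
    if (area >= area_threshold) {
      domain[px] <- cell
      cls <- "domain"
      pm_hit <- FALSE
    } else {
      aggregate[px] <- cell
      cls <- "aggregate"
      pm_hit <- any(masks$pm[px] > 0)
      if (pm_hit) pm_agg[px] <- cell
    }
    rows[[length(rows) + 1L]] <- data.frame(
      label = k, cell = cell, class = cls, area = area,
      pm_associated = pm_hit, stringsAsFactors = FALSE
    )
  }
  tab <- if (length(rows)) do.call(rbind, rows) else empty_puncta_table()
  structure(list(domain = domain, aggregate = aggregate,
                 pm_aggregate = pm_agg, table = tab),
            class = "puncta_set")
}

empty_puncta_table <- function() {
  data.frame(label = integer(), cell = integer(), class = character(),
             area = integer(), pm_associated = logical(),
             stringsAsFactors = FALSE)
}

#' Quantify per-cell, per-compartment feature records
#'
#' For every cell and compartment, reports the mean pixel intensity of the
#' protein channel, the compartment area in pixels, and its circularity
#' (4*pi*A / P^2 with the perimeter measured along the boundary-pixel
#' chain). Per well, the formation rate is the fraction of cells containing
#' at least one aggregate (and, separately, at least one domain); these
#' rows carry an empty cell id. Empty compartments yield a missing (NA)
#' mean intensity, never zero.
#'
#' @param protein_image 2D protein-channel matrix.
#' @param masks a [make_compartments()] result.
#' @param puncta a [detect_puncta()] result (optional).
#' @param condition,time_min,well,protein metadata stamped on each record.
#' @return data.frame of single-cell feature records.
#' @export
quantify_features <- function(protein_image, masks, puncta = NULL,
                              condition = "control", time_min = 0,
                              well = "w1", protein = "P01") {
  stopifnot(inherits(masks, "compartment_masks"))
  ids <- masks$cell_ids
  comps <- list(
    whole_cell = masks$cells,
    nucleus = masks$nuclei,
    cytoplasm = masks$cytoplasm,
    pm = masks$pm
  )
  if (!is.null(puncta)) {
    comps$domain <- puncta$domain
    comps$aggregate <- puncta$aggregate
    comps$pm_aggregate <- puncta$pm_aggregate
  }
  rows <- list()
  for (k in ids) {
    cid <- sprintf("c%04d", k)
    for (cn in names(comps)) {
      px <- comps[[cn]] == k
      area <- sum(px)
      mi <- if (area > 0) mean(protein_image[px]) else NA_real_
      circ <- if (area > 0) mask_circularity(px) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        condition = condition, time_min = time_min, well = well,
        cell_id = cid, protein = protein, compartment = cn,
        measure = c("mean_intensity", "total_area", "circularity"),
        value = c(mi, area, circ), stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(puncta) && length(ids)) {
    has_agg <- vapply(ids, function(k) any(puncta$aggregate == k), TRUE)
    has_dom <- vapply(ids, function(k) any(puncta$domain == k), TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = condition, time_min = time_min, well = well,
      cell_id = "", protein = protein,
      compartment = c("aggregate", "domain"),
      measure = "formation_rate",
      value = c(mean(has_agg), mean(has_dom)), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Circularity of a binary mask
#'
#' 4*pi*A / P^2 with the perimeter measured by tracing each connected
#' component's outer boundary chain (orthogonal steps count 1, diagonal
#' steps sqrt(2)). Interior holes are not traced, so an annulus scores by
#' its outer boundary.
#'
#' @param mask logical matrix.
#' @return circularity value; 1 for an ideal disk up to discretization.
#' @export
mask_circularity <- function(mask) {
  area <- sum(mask)
  if (area == 0) return(NA_real_)
  if (area <= 2) return(1)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  per <- 0
  for (k in sort(unique(lab[lab > 0]))) {
    per <- per + trace_perimeter(lab == k)
  }
  if (per <= 0) return(1)
  4 * pi * area / per^2
}

# Moore-neighbour boundary trace; returns chain length (1 per orthogonal
# step, sqrt(2) per diagonal step) of the outer boundary cycle
trace_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  # first foreground pixel in column-major order: leftmost column, topmost
  # row within it, so its W/NW/N neighbours are background
  start <- which(mask)[1]
  si <- (start - 1L) %% nr + 1L
  sj <- (start - 1L) %/% nr + 1L
  # 0-based directions clockwise: W, NW, N, NE, E, SE, S, SW
  di <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dj <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  steplen <- ifelse(di != 0L & dj != 0L, sqrt(2), 1)
  inside <- function(i, j) i >= 1 && i <= nr && j >= 1 && j <= nc && mask[i, j]
  if (!any(vapply(1:8, function(k) inside(si + di[k], sj + dj[k]), TRUE))) {
    return(4)  # isolated pixel: perimeter of the unit square
  }
  per <- 0
  ci <- si; cj <- sj
  scan_from <- 0L  # 0-based direction to start the clockwise scan
  first_dir <- NA_integer_
  steps <- 0L
  max_steps <- 4L * nr * nc
  repeat {
    moved <- FALSE
    for (s in 0:7) {
      d <- (scan_from + s) %% 8L
      ni <- ci + di[d + 1L]; nj <- cj + dj[d + 1L]
      if (inside(ni, nj)) {
        # Jacob's criterion: back at the start, repeating the first move
        if (ci == si && cj == sj) {
          if (is.na(first_dir)) first_dir <- d
          else if (d == first_dir) return(per)
        }
        per <- per + steplen[d + 1L]
        ci <- ni; cj <- nj
        scan_from <- (d + 6L) %% 8L
        moved <- TRUE
        break
      }
    }
    if (!moved) return(per + 4)
    steps <- steps + 1L
    if (steps > max_steps) return(per)
  }
}
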