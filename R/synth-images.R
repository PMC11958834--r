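#' Render a synthetic three-channel immunofluorescence field
#'
#' Produces a multi-channel z-stack emulating a confocal field: a nuclear
#' marker channel (Gaussian blobs at known centers), a cell-body marker
#' channel (filled polygons covering the nuclei), and a protein channel
#' (uniform background plus planted puncta of two size classes and an
#' optional membrane rim). Signal is spread over z planes with a Gaussian
#' focal profile and corrupted with Poisson shot noise plus additive
#' Gaussian read noise. The returned ground truth inventories every object.
#'
#' Nuclei are placed on a jittered grid; if two nuclei come closer than the
#' stated separation the field is regenerated with new jitter (at most 10
#' attempts).
#'
#' @param n_cells number of cells in the field.
#' @param width,height image size in pixels (>= 128).
#' @param n_z number of z planes.
#' @param n_aggregates_per_cell small puncta planted per cell (scalar or
#'   per-cell vector, recycled).
#' @param n_domains_per_cell large puncta planted per cell (scalar or
#'   per-cell vector, recycled).
#' @param aggregate_radius,domain_radius punctum radii in px; the defaults
#'   put aggregates well below and domains well above a 50 px^2 area split.
#' @param nucleus_radius_range,cell_radius_range object size ranges (px).
#' @param membrane_rim logical; add a bright rim along each cell boundary.
#' @param background,punctum_intensity,nucleus_intensity,cell_intensity
#'   photon-scale intensities.
#' @param read_noise_sd additive Gaussian read noise SD.
#' @param min_separation minimum nucleus center separation; defaults to
#'   2.5x the maximum nucleus radius.
#' @param seed RNG seed.
#' @return list with `channels` (named list nucleus/cell/protein, each a
#'   width x height x n_z array in (y, x, z) order) and `truth` (nucleus
#'   centers and radii, cell polygons, punctum inventory with size class).
#' @export
render_images <- function(n_cells = 5,
                          width = 256, height = 256, n_z = 3,
                          n_aggregates_per_cell = 3,
                          n_domains_per_cell = 1,
                          aggregate_radius = 2.5,
                          domain_radius = 6,
                          nucleus_radius_range = c(7, 9),
                          cell_radius_range = c(20, 26),
                          membrane_rim = FALSE,
                          background = 20,
                          punctum_intensity = 150,
                          nucleus_intensity = 200,
                          cell_intensity = 120,
                          read_noise_sd = 2,
                          min_separation = NULL,
                          seed = 1L) {
  stopifnot(width >= 128, height >= 128, n_z >= 1, n_cells >= 1)
  if (is.null(min_separation)) min_separation <- 2.5 * max(nucleus_radius_range)

  with_seed(seed, {
    # grid spacing chosen so neighbouring cell polygons cannot overlap
    spacing <- 2 * max(cell_radius_range) + 6
    margin <- max(cell_radius_range) + 2
    gx <- seq(margin, width - margin, by = spacing)
    gy <- seq(margin, height - margin, by = spacing)
    if (length(gx) * length(gy) < n_cells) {
      stop("objects do not fit in frame: at most ", length(gx) * length(gy),
           " cells of this size fit in ", width, "x", height)
    }
    centers <- NULL
    for (attempt in 1:10) {
      slots <- expand.grid(x = gx, y = gy)
      slots <- slots[sample.int(nrow(slots), n_cells), , drop = FALSE]
      jit <- spacing / 20
      cand <- cbind(slots$x + runif(n_cells, -jit, jit),
                    slots$y + runif(n_cells, -jit, jit))
      dmin <- if (n_cells > 1) min(stats::dist(cand)) else Inf
      if (dmin >= min_separation) { centers <- cand; break }
    }
    if (is.null(centers)) {
      stop("failed to place non-overlapping nuclei after 10 attempts")
    }

    nuc_r <- runif(n_cells, nucleus_radius_range[1], nucleus_radius_range[2])
    polys <- vector("list", n_cells)
    inradii <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      nv <- sample(8:12, 1)
      ang <- 2 * pi * (seq_len(nv) - 1) / nv + runif(nv, 0, pi / nv)
      rad <- runif(nv, cell_radius_range[1], cell_radius_range[2])
      polys[[i]] <- cbind(x = centers[i, 1] + rad * cos(ang),
                          y = centers[i, 2] + rad * sin(ang))
      inradii[i] <- poly_inradius(centers[i, ], polys[[i]])
    }

    xs <- matrix(rep(seq_len(width), each = height), height, width)
    ys <- matrix(rep(seq_len(height), times = width), height, width)

    nuc_plane <- matrix(0, height, width)
    for (i in seq_len(n_cells)) {
      s <- nuc_r[i] / 2
      d2 <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2
      nuc_plane <- nuc_plane + nucleus_intensity * exp(-d2 / (2 * s^2))
    }

    cell_plane <- matrix(0, height, width)
    cell_owner <- matrix(0L, height, width)
    for (i in seq_len(n_cells)) {
      inside <- point_in_polygon(xs, ys, polys[[i]])
      cell_plane[inside] <- cell_intensity
      cell_owner[inside] <- i
    }

    # puncta placed inside the cell's inner disc so each lies in exactly
    # one cell polygon
    n_agg <- rep(n_aggregates_per_cell, length.out = n_cells)
    n_dom <- rep(n_domains_per_cell, length.out = n_cells)
    puncta <- list()
    prot_plane <- matrix(background, height, width)
    for (i in seq_len(n_cells)) {
      np <- n_agg[i] + n_dom[i]
      if (np == 0) next
      classes <- c(rep("aggregate", n_agg[i]), rep("domain", n_dom[i]))
      radii <- c(rep(aggregate_radius, n_agg[i]),
                 rep(domain_radius, n_dom[i]))
      placed <- matrix(numeric(0), 0, 3)  # x, y, radius
      for (p in seq_len(np)) {
        inner <- max(inradii[i] - radii[p] - 2, 1)
        px <- py <- NA_real_
        for (try in 1:50) {
          a <- runif(1, 0, 2 * pi)
          r <- sqrt(runif(1)) * inner
          cx <- centers[i, 1] + r * cos(a)
          cy <- centers[i, 2] + r * sin(a)
          # keep same-cell puncta from merging into one detection
          if (nrow(placed) == 0 ||
              all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
                  placed[, 3] + radii[p] + 2)) {
            px <- cx; py <- cy
            break
          }
        }
        if (is.na(px)) { px <- cx; py <- cy }  # dense cell: accept overlap
        placed <- rbind(placed, c(px, py, radii[p]))
        d2 <- (xs - px)^2 + (ys - py)^2
        disc <- d2 <= radii[p]^2
        prot_plane[disc] <- prot_plane[disc] + punctum_intensity
        puncta[[length(puncta) + 1L]] <- data.frame(
          cell = i, x = px, y = py, radius = radii[p],
          area_px = sum(disc), class = classes[p],
          stringsAsFactors = FALSE
        )
      }
    }
    if (membrane_rim) {
      for (i in seq_len(n_cells)) {
        own <- cell_owner == i
        er <- EBImage::erode(EBImage::Image(own * 1),
                             EBImage::makeBrush(5, "disc"))
        rim <- own & !(er@.Data > 0.5)
        prot_plane[rim] <- prot_plane[rim] + punctum_intensity / 2
      }
    }

    # distribute over z with per-object focal planes, then add noise
    spread_z <- function(plane, base) {
      z0 <- sample.int(n_z, 1)
      arr <- array(0, dim = c(height, width, n_z))
      for (z in seq_len(n_z)) {
        wz <- exp(-((z - z0)^2) / 2)
        arr[, , z] <- base + (plane - base) * wz
      }
      arr
    }
    noisy <- function(arr) {
      shot <- array(rpois(length(arr), lambda = pmax(arr, 0)), dim = dim(arr))
      shot + array(rnorm(length(arr), sd = read_noise_sd), dim = dim(arr))
    }
    channels <- list(
      nucleus = noisy(spread_z(nuc_plane, 0)),
      cell = noisy(spread_z(cell_plane, 0)),
      protein = noisy(spread_z(prot_plane, background))
    )
    truth <- list(
      nucleus_centers = centers,
      nucleus_radii = nuc_r,
      cell_polygons = polys,
      cell_owner = cell_owner,
      puncta = if (length(puncta)) do.call(rbind, puncta) else
        data.frame(cell = integer(), x = numeric(), y = numeric(),
                   radius = numeric(), area_px = integer(),
                   class = character())
    )
    list(channels = channels, truth = truth)
  })
}

# minimum distance from an interior point to the polygon boundary
poly_inradius <- function(center, poly) {
  n <- nrow(poly)
  d <- numeric(n)
  j <- n
  for (i in seq_len(n)) {
    a <- poly[j, ]; b <- poly[i, ]
    ab <- b - a
    t <- sum((center - a) * ab) / max(sum(ab^2), 1e-12)
    t <- min(max(t, 0), 1)
    proj <- a + t * ab
    d[i] <- sqrt(sum((center - proj)^2))
    j <- i
  }
  min(d)
}

# even-odd crossing test, vectorized over pixel coordinate matrices
point_in_polygon <- function(xs, ys, poly) {
  n <- nrow(poly)
  inside <- matrix(FALSE, nrow(xs), ncol(xs))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > ys) != (yj > ys)) &
      (xs < (xj - xi) * (ys - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Write a multi-channel z-stack to a multi-page TIFF
#'
#' Pages are ordered channel-major (all z planes of the nucleus channel,
#' then the cell channel, then the protein channel). Intensities are scaled
#' to 16-bit.
#'
#' @param channels named list of (y, x, z) arrays as from [render_images()].
#' @param path output TIFF path.
#' @export
write_image_stack <- function(channels, path) {
  stopifnot(all(c("nucleus", "cell", "protein") %in% names(channels)))
  pages <- list()
  for (ch in c("nucleus", "cell", "protein")) {
    arr <- channels[[ch]]
    hi <- max(arr, 1)
    for (z in seq_len(dim(arr)[3])) {
      pages[[length(pages) + 1L]] <- pmin(pmax(arr[, , z] / hi, 0), 1)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a channel-major multi-page TIFF into named channel stacks
#'
#' @param path TIFF written by [write_image_stack()].
#' @param n_z number of z planes per channel.
#' @return named list of (y, x, z) arrays.
#' @export
read_image_stack <- function(path, n_z) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) == 3 * n_z)
  out <- list()
  k <- 1L
  for (ch in c("nucleus", "cell", "protein")) {
    arr <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2], n_z))
    for (z in seq_len(n_z)) {
      arr[, , z] <- pages[[k]]
      k <- k + 1L
    }
    out[[ch]] <- arr
  }
  out
}
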