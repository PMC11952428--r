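# 3D immunofluorescence quantification: per-ROI median filtering of the DAPI
# channel, intensity thresholding and size filtering to segment mitotic
# chromosomes, a dilation shell to estimate cytoplasmic signal, and the
# chromosome/cytoplasm intensity ratio per cell, compared across groups with
# Welch t-tests. Arrays are indexed (y, x, z); all operations are 3D.

reflect_index <- function(i, n) {
  i <- ifelse(i < 1L, 2L - i, i)
  ifelse(i > n, 2L * n - i, i)
}

#' 3D median filter with reflection padding
#'
#' Replaces each voxel by the median of its `kernel` neighborhood (default
#' 7 x 7 x 3 in (y, x, z)); edges are handled by reflecting the volume.
#'
#' @param vol numeric 3D array (y, x, z).
#' @param kernel odd integer kernel dimensions, `(y, x, z)`.
#' @return filtered array of the same shape.
#' @export
median_filter_3d <- function(vol, kernel = c(7L, 7L, 3L)) {
  stopifnot(length(dim(vol)) == 3L, length(kernel) == 3L)
  if (any(kernel %% 2L != 1L)) stop("kernel dimensions must be odd")
  d <- dim(vol)
  if (any(kernel > d)) stop("kernel larger than image in some dimension")
  h <- (kernel - 1L) %/% 2L
  offs <- as.matrix(expand.grid(dy = -h[1]:h[1], dx = -h[2]:h[2], dz = -h[3]:h[3]))
  n <- prod(d)
  yy <- rep.int(seq_len(d[1]), d[2] * d[3])
  xx <- rep.int(rep(seq_len(d[2]), each = d[1]), d[3])
  zz <- rep(seq_len(d[3]), each = d[1] * d[2])
  M <- matrix(0, n, nrow(offs))
  for (j in seq_len(nrow(offs))) {
    M[, j] <- vol[cbind(reflect_index(yy + offs[j, 1L], d[1]),
                        reflect_index(xx + offs[j, 2L], d[2]),
                        reflect_index(zz + offs[j, 3L], d[3]))]
  }
  array(apply(M, 1L, stats::median), d)
}

#' Otsu threshold of a numeric volume
#'
#' Maximizes between-class variance on a 256-bin histogram; used as the
#' default intensity threshold for chromosome segmentation.
#'
#' @param v numeric vector or array.
#' @param nbins histogram bins (default 256).
#' @return threshold value on the intensity scale of `v`.
#' @export
otsu_threshold <- function(v, nbins = 256L) {
  v <- as.numeric(v)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1L])
  h <- graphics::hist(v, breaks = seq(rng[1L], rng[2L], length.out = nbins + 1L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  omega <- cumsum(p)
  mu <- cumsum(p * h$mids)
  mt <- mu[length(mu)]
  sb <- (mt * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  h$mids[which.max(sb)]
}

# 26-connected component labeling via a pairwise-adjacency graph
label_components_3d <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(array(0L, d))
  lin <- array(0L, d); lin[idx] <- seq_along(idx)
  co <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  offs <- offs[seq_len(13L), , drop = FALSE]  # half neighborhood
  from <- integer(0); to <- integer(0)
  for (j in seq_len(nrow(offs))) {
    nb <- sweep(co, 2L, offs[j, ], `+`)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
    nb_id <- lin[nb[ok, , drop = FALSE]]
    here <- which(ok)[nb_id > 0L]
    from <- c(from, here); to <- c(to, nb_id[nb_id > 0L])
  }
  comp <- seq_along(idx)  # union-find with path halving
  find <- function(i) {
    while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }
    i
  }
  for (e in seq_along(from)) {
    a <- find(from[e]); b <- find(to[e])
    if (a != b) comp[a] <- b
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  lab <- array(0L, d)
  lab[idx] <- as.integer(factor(roots))
  lab
}

#' Segment mitotic chromosomes in a filtered DAPI volume
#'
#' Global intensity threshold (Otsu by default, overridable), 26-connected
#' component labeling, and removal of components below `min_size` voxels.
#'
#' @param filtered_dapi median-filtered DAPI volume.
#' @param min_size minimum component size in voxels.
#' @param threshold manual intensity threshold; `NULL` uses Otsu.
#' @return integer label array (0 = background); the threshold used is
#'   attached as attribute `threshold`.
#' @export
segment_chromosomes <- function(filtered_dapi, min_size = 100L,
                                threshold = NULL) {
  stopifnot(length(dim(filtered_dapi)) == 3L)
  thr <- if (is.null(threshold)) otsu_threshold(filtered_dapi) else threshold
  lab <- label_components_3d(filtered_dapi > thr)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  if (length(keep) == 0L) {
    warning("no component survives the size filter")
    out <- array(0L, dim(filtered_dapi))
  } else {
    out <- array(0L, dim(filtered_dapi))
    for (i in seq_along(keep)) out[lab == keep[i]] <- i
  }
  attr(out, "threshold") <- thr
  out
}

ball_offsets <- function(r) {
  g <- as.matrix(expand.grid(dy = -r:r, dx = -r:r, dz = -r:r))
  g[rowSums(g^2) <= r^2, , drop = FALSE]
}

dilate_3d <- function(mask, r) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (j in seq_len(nrow(offs <- ball_offsets(r)))) {
    dy <- offs[j, 1L]; dx <- offs[j, 2L]; dz <- offs[j, 3L]
    ys <- max(1L, 1L + dy):min(d[1L], d[1L] + dy)
    xs <- max(1L, 1L + dx):min(d[2L], d[2L] + dx)
    zs <- max(1L, 1L + dz):min(d[3L], d[3L] + dz)
    out[ys - dy, xs - dx, zs - dz] <-
      out[ys - dy, xs - dx, zs - dz] | mask[ys, xs, zs]
  }
  out
}

#' Cytoplasm shell around a chromosome mask
#'
#' Morphological dilation of the mask by a radius-`radius` ball (isotropic
#' in voxel units) minus the mask: a rind of at most `radius` voxels,
#' disjoint from the mask by construction and clipped at the volume border.
#'
#' @param mask logical 3D array (or integer labels; nonzero = mask).
#' @param radius dilation radius in voxels (default 2).
#' @return logical 3D array of shell voxels.
#' @export
shell_mask <- function(mask, radius = 2L) {
  if (!is.logical(mask)) mask <- mask > 0L
  if (!any(mask)) stop("mask is empty")
  shell <- dilate_3d(mask, radius) & !mask
  if (!any(shell))
    stop("insufficient context: mask fills the ROI, shell is empty")
  shell
}

#' Chromosome/cytoplasm intensity measurement for one cell
#'
#' Mean target-channel intensity over the chromosome mask and over the
#' cytoplasm shell, and their ratio. The ratio is invariant to rescaling
#' the channel.
#'
#' @param ctcf target-channel 3D volume.
#' @param mask logical chromosome mask.
#' @param shell logical cytoplasm shell (disjoint from mask).
#' @param cell_id,group identifiers carried into the result.
#' @return data.frame (`cell_measurement`) with `cell_id`, `group`,
#'   `chromosome_mean`, `shell_mean`, `ratio`, `mask_voxels`,
#'   `shell_voxels`.
#' @export
measure_cell <- function(ctcf, mask, shell, cell_id = "cell", group = NA_character_) {
  stopifnot(any(mask), any(shell))
  if (any(mask & shell)) stop("mask and shell overlap")
  cm <- mean(ctcf[mask]); sm <- mean(ctcf[shell])
  if (sm == 0) stop("undefined ratio: shell mean is zero")
  data.frame(cell_id = cell_id, group = group, chromosome_mean = cm,
             shell_mean = sm, ratio = cm / sm,
             mask_voxels = sum(mask), shell_voxels = sum(shell),
             stringsAsFactors = FALSE)
}

#' Full per-cell quantification pipeline
#'
#' Median-filters the DAPI channel (7 x 7 x 3), segments chromosomes
#' (Otsu + size filter), builds the radius-2 cytoplasm shell, and measures
#' the target-channel ratio. Shell voxels whose raw DAPI exceeds the
#' segmentation threshold are excluded from the cytoplasm estimate:
#' chromatin bleeding past the mask boundary must not be counted as
#' cytoplasm.
#'
#' @param dapi,ctcf 3D volumes (y, x, z) for the segmentation and target
#'   channels of one ROI.
#' @param cell_id,group identifiers.
#' @param min_size,threshold,shell_radius segmentation/shell parameters.
#' @param exclude_dapi_positive apply the DAPI exclusion in the shell
#'   (default `TRUE`).
#' @return a `cell_measurement` data.frame row.
#' @export
quantify_cell <- function(dapi, ctcf, cell_id = "cell", group = NA_character_,
                          min_size = 100L, threshold = NULL,
                          shell_radius = 2L, exclude_dapi_positive = TRUE) {
  filt <- median_filter_3d(dapi)
  lab <- segment_chromosomes(filt, min_size = min_size, threshold = threshold)
  if (!any(lab > 0L)) stop("no chromosome mask found for cell ", cell_id)
  mask <- lab > 0L
  shell <- shell_mask(mask, shell_radius)
  if (exclude_dapi_positive) {
    shell2 <- shell & (dapi <= attr(lab, "threshold"))
    if (any(shell2)) shell <- shell2
  }
  measure_cell(ctcf, mask, shell, cell_id = cell_id, group = group)
}

#' Compare measured ratios between groups
#'
#' Two-sided Welch (unequal-variance) two-sample t-test of per-cell ratios,
#' each group against the reference group; no multiple-testing correction
#' (per-group reporting).
#'
#' @param measurements data.frame with `group` and `ratio` columns
#'   (rbind of [measure_cell()]/[quantify_cell()] rows).
#' @param reference reference group label (e.g. a secondary-only control).
#' @return data.frame with one row per non-reference group: `group`, `n`,
#'   `mean_ratio`, `t`, `df`, `p_value`, and a `flagged` column for
#'   degenerate-variance cases at n = 2.
#' @export
compare_groups <- function(measurements, reference) {
  stopifnot(all(c("group", "ratio") %in% names(measurements)))
  ref <- measurements$ratio[measurements$group == reference]
  if (length(ref) < 2L) stop("reference group needs >= 2 cells")
  groups <- setdiff(unique(measurements$group), reference)
  out <- lapply(groups, function(g) {
    x <- measurements$ratio[measurements$group == g]
    if (length(x) < 2L) stop("group '", g, "' needs >= 2 cells")
    flagged <- (length(x) == 2L && stats::sd(x) == 0) ||
      (length(ref) == 2L && stats::sd(ref) == 0)
    tt <- stats::t.test(x, ref, var.equal = FALSE)
    data.frame(group = g, n = length(x), mean_ratio = mean(x),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "reference") <- reference
  attr(res, "reference_mean") <- mean(ref)
  res
}

#' Simulate two-channel confocal ROIs of mitotic cells
#'
#' Each cell is a random ellipsoid chromosome mass: bright DAPI inside,
#' target channel at `ratio * cytoplasm_level` inside and
#' `cytoplasm_level` outside, plus Gaussian noise (`noise_sd` as a fraction
#' of the local level) on both channels; intensities are clamped at zero.
#' Deterministic under `seed`.
#'
#' @param groups data.frame with columns `group`, `true_ratio`,
#'   `cytoplasm_level`, `noise_sd`, `n_cells`.
#' @param dims ROI dimensions (y, x, z).
#' @param seed integer seed.
#' @return list of cells, each `list(dapi, ctcf, group, true_ratio,
#'   cell_id)`.
#' @export
simulate_cells <- function(groups, dims = c(48L, 48L, 20L), seed = 1L) {
  stopifnot(all(c("group", "true_ratio", "cytoplasm_level", "noise_sd",
                  "n_cells") %in% names(groups)))
  set.seed(seed)
  cells <- list()
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    for (ci in seq_len(g$n_cells)) {
      ctr <- c(dims[1] / 2, dims[2] / 2, dims[3] / 2) +
        stats::runif(3, -2, 2)
      radii <- c(stats::runif(1, 9, 12), stats::runif(1, 8, 10),
                 stats::runif(1, 4, 6))
      yy <- rep.int(seq_len(dims[1]), dims[2] * dims[3])
      xx <- rep.int(rep(seq_len(dims[2]), each = dims[1]), dims[3])
      zz <- rep(seq_len(dims[3]), each = dims[1] * dims[2])
      inside <- ((yy - ctr[1]) / radii[1])^2 + ((xx - ctr[2]) / radii[2])^2 +
        ((zz - ctr[3]) / radii[3])^2 <= 1
      B <- array(inside, dims)
      dapi_level <- 2 * g$cytoplasm_level
      dapi <- array(0, dims); dapi[B] <- dapi_level
      ctcf <- array(g$cytoplasm_level, dims)
      ctcf[B] <- g$true_ratio * g$cytoplasm_level
      if (g$noise_sd > 0) {
        dapi <- dapi + stats::rnorm(length(dapi), 0, g$noise_sd * dapi_level)
        ctcf <- ctcf + stats::rnorm(length(ctcf), 0,
                                    g$noise_sd * g$cytoplasm_level)
      }
      cells[[length(cells) + 1L]] <- list(
        dapi = pmax(dapi, 0), ctcf = pmax(ctcf, 0), group = g$group,
        true_ratio = g$true_ratio,
        cell_id = sprintf("%s_cell%02d", g$group, ci))
    }
  }
  cells
}

#' Quantify a simulated or loaded cohort
#' @param cells list of cells as returned by [simulate_cells()].
#' @param ... passed to [quantify_cell()].
#' @return data.frame of per-cell measurements.
#' @export
quantify_cohort <- function(cells, ...) {
  do.call(rbind, lapply(cells, function(cl)
    quantify_cell(cl$dapi, cl$ctcf, cell_id = cl$cell_id, group = cl$group, ...)))
}

#' Read a single-channel multi-page TIFF as a (y, x, z) array
#' @param path TIFF path (one z-slice per page).
#' @return numeric 3D array.
#' @export
read_channel_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF input")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), c(dim(pages[[1L]])[1:2], length(pages)))
}

#' Write a (y, x, z) array as a multi-page TIFF
#' @param vol numeric 3D array; rescaled to the unit range for storage.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(vol, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF output")
  rng <- range(vol)
  sc <- if (diff(rng) > 0) (vol - rng[1L]) / diff(rng) else vol * 0
  tiff::writeTIFF(lapply(seq_len(dim(vol)[3L]), function(z) sc[, , z]), path)
  invisible(path)
}
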