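#' Volume grids, masks and beta series
#'
#' A volume grid is an isotropic-or-not voxel lattice with voxel size in mm
#' and a world-space origin. A beta series holds one coefficient per
#' (stimulus, in-mask voxel) for one subject.
#'
#' @param dim integer length-3 grid dimensions
#' @param voxdim_mm voxel size per axis in mm (default 3 mm isotropic)
#' @param origin_mm world coordinate of voxel (1,1,1)
#' @return object of class `volume_grid`
#' @export
volume_grid <- function(dim, voxdim_mm = c(3, 3, 3), origin_mm = c(0, 0, 0)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim > 0L), all(voxdim_mm > 0))
  structure(list(dim = dim, voxdim_mm = as.numeric(voxdim_mm),
                 origin_mm = as.numeric(origin_mm)), class = "volume_grid")
}

#' @rdname volume_grid
#' @param subject_id subject identifier
#' @param grid a [volume_grid()]
#' @param labels stimulus labels (length = rows of `data`)
#' @param data stimuli x in-mask-voxel matrix (columns follow `which(mask)`)
#' @param mask logical 3-D array on `grid`
#' @export
beta_series <- function(subject_id, grid, labels, data, mask) {
  stopifnot(inherits(grid, "volume_grid"), identical(dim(mask), grid$dim),
            sum(mask) >= 1L)
  data <- as.matrix(data)
  if (ncol(data) != sum(mask))
    stop("data has ", ncol(data), " columns but mask has ", sum(mask), " voxels")
  if (nrow(data) != length(labels)) stop("labels do not match data rows")
  if (any(!is.finite(data))) stop("beta values must be finite")
  rownames(data) <- labels
  structure(list(subject_id = subject_id, grid = grid,
                 labels = as.character(labels), data = data,
                 mask = mask), class = "beta_series")
}

#' Integer offsets of a voxel sphere
#'
#' All lattice offsets (i, j, k) with i^2 + j^2 + k^2 <= radius^2,
#' including (0, 0, 0). A radius of 3 gives the standard 123-voxel sphere.
#'
#' @param radius radius in voxels (>= 0)
#' @return integer matrix, one offset per row
#' @export
sphere_offsets <- function(radius) {
  stopifnot(radius >= 0)
  r <- floor(radius)
  g <- as.matrix(expand.grid(i = -r:r, j = -r:r, k = -r:r))
  out <- g[rowSums(g^2) <= radius^2, , drop = FALSE]
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}

#' Searchlight configuration
#'
#' @param radius sphere radius in voxels (default 3)
#' @param min_occupancy_frac minimum in-mask fraction of the full sphere for
#'   a center to be evaluated (default 0.5; edge-truncated spheres above it
#'   are retained)
#' @param method "spearman" or "partial_spearman"
#' @return object of class `searchlight_config`
#' @export
searchlight_config <- function(radius = 3, min_occupancy_frac = 0.5,
                               method = c("spearman", "partial_spearman")) {
  method <- match.arg(method)
  stopifnot(radius >= 0, min_occupancy_frac >= 0, min_occupancy_frac <= 1)
  structure(list(radius = radius, min_occupancy_frac = min_occupancy_frac,
                 method = method), class = "searchlight_config")
}

mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE) - 1L  # 0-based for the C++ kernel
}

mask_lookup <- function(mask) {
  lk <- integer(length(mask))
  lk[] <- -1L
  lk[which(mask)] <- seq_len(sum(mask)) - 1L
  lk
}

#' Neural RDM of one searchlight sphere
#'
#' Correlation-distance RDM over stimulus patterns restricted to the
#' in-mask voxels of the sphere centred at `center` (voxel indices,
#' 1-based). Spheres are truncated at mask and volume edges.
#'
#' @param bs a [beta_series()]
#' @param center integer length-3 voxel coordinate (1-based)
#' @param offsets from [sphere_offsets()]
#' @param min_occupancy_frac centers with fewer in-mask voxels are refused
#' @return an [rdm()]
#' @export
neural_rdm <- function(bs, center, offsets, min_occupancy_frac = 0.5) {
  dims <- bs$grid$dim
  pts <- sweep(offsets, 2L, as.integer(center), `+`)
  ok <- pts[, 1] >= 1 & pts[, 2] >= 1 & pts[, 3] >= 1 &
    pts[, 1] <= dims[1] & pts[, 2] <= dims[2] & pts[, 3] <= dims[3]
  pts <- pts[ok, , drop = FALSE]
  lin <- pts[, 1] + dims[1] * (pts[, 2] - 1L) + dims[1] * dims[2] * (pts[, 3] - 1L)
  lin <- lin[bs$mask[lin]]
  need <- max(2L, ceiling(min_occupancy_frac * nrow(offsets)))
  if (length(lin) < need)
    stop("sphere at (", paste(center, collapse = ","), ") has ", length(lin),
         " in-mask voxels (minimum ", need, ")")
  cols <- mask_lookup(bs$mask)[lin] + 1L
  compute_rdm(bs$data[, cols, drop = FALSE])
}

#' Searchlight correlation map(s)
#'
#' For every in-mask center voxel, builds the sphere's neural RDM and
#' compares it with each requested model RDM by rank-based (partial)
#' second-order correlation, assigning rho to the center. Centers whose
#' sphere occupancy falls below the configured minimum are left NA.
#'
#' `searchlight_multi()` evaluates several analyses in one sweep (the
#' per-sphere neural RDM and its ranks are shared); `searchlight_map()` is
#' the single-analysis wrapper.
#'
#' @param bs a [beta_series()]
#' @param analyses named list; each element is `list(model = rdm, control =
#'   rdm or NULL)` (a NULL control requests the plain Spearman comparison)
#' @param config a [searchlight_config()]
#' @param centers optional integer vector of mask-voxel indices (into
#'   `which(mask)`) to evaluate; default all
#' @return named list of 3-D arrays (NA outside evaluated centers), plus
#'   attribute `n_skipped`
#' @export
searchlight_multi <- function(bs, analyses, config = searchlight_config(),
                              centers = NULL) {
  stopifnot(length(analyses) >= 1L)
  offsets <- sphere_offsets(config$radius)
  labs <- bs$labels
  ranks <- do.call(cbind, lapply(analyses, function(a) {
    if (!identical(rownames(a$model), labs))
      stop("model RDM labels do not match beta-series stimuli")
    rank(upper_tri_vec(a$model))
  }))
  ctrl_ranks <- lapply(analyses, function(a) {
    if (is.null(a$control)) return(NULL)
    if (!identical(rownames(a$control), labs))
      stop("control RDM labels do not match beta-series stimuli")
    rank(upper_tri_vec(a$control))
  })
  # model_ranks columns: one per analysis, controls appended after
  mr <- ranks
  control_of <- rep(-1L, length(analyses))
  for (i in seq_along(analyses)) {
    if (!is.null(ctrl_ranks[[i]])) {
      mr <- cbind(mr, ctrl_ranks[[i]])
      control_of[i] <- ncol(mr) - 1L  # 0-based column
    }
  }
  co <- mask_coords(bs$mask)
  if (is.null(centers)) centers <- seq_len(sum(bs$mask))
  res <- cpp_searchlight(bs$data * 1.0, co[, 1], co[, 2], co[, 3],
                         mask_lookup(bs$mask), bs$grid$dim[1], bs$grid$dim[2],
                         bs$grid$dim[3], offsets, as.integer(centers - 1L),
                         as.matrix(mr) * 1.0,
                         c(control_of, rep(-1L, ncol(mr) - length(analyses))),
                         2L, config$min_occupancy_frac)
  rho <- res$rho[, seq_along(analyses), drop = FALSE]
  rho[is.nan(rho)] <- NA_real_
  lin <- which(bs$mask)[centers]
  out <- lapply(seq_along(analyses), function(m) {
    a <- array(NA_real_, bs$grid$dim)
    a[lin] <- rho[, m]
    a
  })
  names(out) <- names(analyses)
  attr(out, "n_skipped") <- sum(is.na(rho[, 1L]))
  out
}

#' @rdname searchlight_multi
#' @param model model [rdm()]
#' @param control control [rdm()] for the partial comparison (required iff
#'   `config$method == "partial_spearman"`)
#' @return `searchlight_map`: a 3-D array of rho (class `searchlight_map`)
#' @export
searchlight_map <- function(bs, model, config = searchlight_config(),
                            control = NULL, centers = NULL) {
  if (config$method == "partial_spearman" && is.null(control))
    stop("partial_spearman requires a control RDM")
  if (config$method == "spearman") control <- NULL
  maps <- searchlight_multi(bs, list(map = list(model = model, control = control)),
                            config, centers)
  structure(maps$map, class = c("searchlight_map", "array"),
            n_skipped = attr(maps, "n_skipped"))
}

gaussian_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) exp(-((i - j)^2) / (2 * sigma_vox^2)))
  # normalize by the untruncated kernel mass so edge rows lose mass; the
  # mask-aware denominator restores it
  K / sum(exp(-((-(4 * ceiling(sigma_vox) + 1):(4 * ceiling(sigma_vox) + 1))^2) /
                (2 * sigma_vox^2)))
}

conv_axis <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  m <- K %*% m
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

#' Gaussian smoothing of a statistic map
#'
#' Separable Gaussian convolution with sigma = FWHM / (2 sqrt(2 ln 2)) per
#' axis (in mm, converted to voxels), renormalized against the smoothed
#' mask so values near mask and volume edges are proper weighted averages
#' of in-mask data. FWHM 0 is the identity.
#'
#' @param map 3-D array (values outside `mask` ignored)
#' @param fwhm_mm kernel full width at half maximum in mm
#' @param grid a [volume_grid()]
#' @param mask logical 3-D array
#' @return 3-D array, NA outside the mask
#' @export
smooth_map <- function(map, fwhm_mm, grid, mask) {
  stopifnot(fwhm_mm >= 0, identical(dim(map), grid$dim))
  out <- map
  out[!mask] <- NA_real_
  if (fwhm_mm == 0) return(out)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  num <- map
  num[!mask | !is.finite(num)] <- 0
  den <- array(0, grid$dim)
  den[mask & is.finite(map)] <- 1
  num <- num * den
  for (axis in 1:3) {
    K <- gaussian_kernel_matrix(grid$dim[axis], sigma_mm / grid$voxdim_mm[axis])
    num <- conv_axis(num, K, axis)
    den <- conv_axis(den, K, axis)
  }
  res <- array(NA_real_, grid$dim)
  ok <- mask & den > 1e-12
  res[ok] <- num[ok] / den[ok]
  res
}

#' Group inference configuration
#'
#' @param fwhm_mm smoothing kernel FWHM (default 6 mm)
#' @param voxel_p voxelwise p threshold (default 0.001)
#' @param cluster_extent_mm3 minimum cluster volume (default 234.9 mm^3)
#' @param connectivity 6, 18 (default, faces+edges) or 26
#' @param fisher_z apply atanh to (smoothed) subject maps before the t test
#' @param two_sided threshold |t| (default) rather than t only
#' @return object of class `group_inference_config`
#' @export
group_inference_config <- function(fwhm_mm = 6, voxel_p = 0.001,
                                   cluster_extent_mm3 = 234.9,
                                   connectivity = 18L, fisher_z = TRUE,
                                   two_sided = TRUE) {
  stopifnot(fwhm_mm >= 0, voxel_p > 0, voxel_p < 1, cluster_extent_mm3 >= 0,
            connectivity %in% c(6L, 18L, 26L))
  structure(list(fwhm_mm = fwhm_mm, voxel_p = voxel_p,
                 cluster_extent_mm3 = cluster_extent_mm3,
                 connectivity = as.integer(connectivity),
                 fisher_z = fisher_z, two_sided = two_sided),
            class = "group_inference_config")
}

#' Label connected components of a binary volume
#' @param bin logical 3-D array
#' @param connectivity 6, 18 or 26
#' @return integer array of component labels (0 = background)
#' @export
label_clusters <- function(bin, connectivity = 18L) {
  d <- dim(bin)
  lab <- cpp_label_clusters(as.logical(bin), d[1], d[2], d[3],
                            as.integer(connectivity))
  array(lab, d)
}

#' Group-level inference on subject searchlight maps
#'
#' Each subject map is smoothed (mask-aware), Fisher-transformed
#' (atanh, with |rho| clipped at 1 - 1e-7), and a per-voxel one-sample t
#' test against 0 is computed across subjects. Voxels with zero
#' across-subject variance are flagged NA. The t map is thresholded at the
#' voxelwise p (two-sided by default); positive suprathreshold voxels are
#' grouped into connected components and components smaller than the
#' cluster extent are discarded.
#'
#' @param maps list of per-subject 3-D rho arrays (>= 2 subjects)
#' @param grid a [volume_grid()]
#' @param mask logical 3-D array
#' @param config a [group_inference_config()]
#' @return list: `t_map` (3-D array), `df`, `threshold`, `cluster_map`
#'   (labels after extent thresholding), `clusters` (data.frame: cluster,
#'   n_voxels, volume_mm3, peak_t, peak_x_mm, peak_y_mm, peak_z_mm)
#' @export
group_inference <- function(maps, grid, mask, config = group_inference_config()) {
  n <- length(maps)
  stopifnot(n >= 2L)
  for (m in maps) stopifnot(identical(dim(m), grid$dim))
  sm <- lapply(maps, smooth_map, fwhm_mm = config$fwhm_mm, grid = grid,
               mask = mask)
  if (config$fisher_z) {
    clip <- 1 - 1e-7
    sm <- lapply(sm, function(m) {
      over <- is.finite(m) & abs(m) > clip
      if (any(over)) {
        warning(sum(over), " |rho| value(s) >= 1 clipped before Fisher z")
        m[over] <- sign(m[over]) * clip
      }
      atanh(m)
    })
  }
  stack <- simplify2array(sm)            # x,y,z,subject
  mu <- apply(stack, 1:3, mean)
  s <- apply(stack, 1:3, sd)
  t_map <- array(NA_real_, grid$dim)
  ok <- mask & is.finite(mu) & is.finite(s) & s > 0
  t_map[ok] <- mu[ok] / (s[ok] / sqrt(n))
  df <- n - 1L
  p <- config$voxel_p
  thr <- if (config$two_sided) qt(1 - p / 2, df) else qt(1 - p, df)
  supra <- !is.na(t_map) & t_map > thr   # positive-only cluster reporting
  lab <- label_clusters(supra, config$connectivity)
  vox_mm3 <- prod(grid$voxdim_mm)
  keep <- integer()
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes * vox_mm3 >= config$cluster_extent_mm3)
  }
  cluster_map <- array(0L, grid$dim)
  rows <- list()
  for (i in seq_along(keep)) {
    vox <- which(lab == keep[i])
    cluster_map[vox] <- i
    pk <- vox[which.max(t_map[vox])]
    co <- arrayInd(pk, grid$dim)
    rows[[i]] <- data.frame(
      cluster = i, n_voxels = length(vox),
      volume_mm3 = length(vox) * vox_mm3,
      peak_t = t_map[pk],
      peak_x_mm = grid$origin_mm[1] + (co[1] - 1) * grid$voxdim_mm[1],
      peak_y_mm = grid$origin_mm[2] + (co[2] - 1) * grid$voxdim_mm[2],
      peak_z_mm = grid$origin_mm[3] + (co[3] - 1) * grid$voxdim_mm[3])
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), n_voxels = integer(),
               volume_mm3 = numeric(), peak_t = numeric(),
               peak_x_mm = numeric(), peak_y_mm = numeric(),
               peak_z_mm = numeric())
  if (nrow(clusters)) {
    ord <- order(-clusters$n_voxels)
    clusters <- clusters[ord, ]
    relabel <- array(0L, grid$dim)
    for (k in seq_along(ord)) relabel[cluster_map == clusters$cluster[ord[k]]] <- k
    cluster_map <- relabel
    clusters$cluster <- seq_len(nrow(clusters))
    rownames(clusters) <- NULL
  }
  list(t_map = t_map, df = df, threshold = thr, cluster_map = cluster_map,
       clusters = clusters)
}
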