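test_that("sphere offsets match brute-force lattice enumeration", {
  expect_equal(nrow(sphere_offsets(0)), 1L)
  expect_equal(nrow(sphere_offsets(1)), 7L)
  expect_equal(nrow(sphere_offsets(3)), 123L)
  for (r in 0:4) {
    count <- 0L
    for (i in -r:r) for (j in -r:r) for (k in -r:r)
      if (i^2 + j^2 + k^2 <= r^2) count <- count + 1L
    expect_equal(nrow(sphere_offsets(r)), count)
    expect_true(any(rowSums(abs(sphere_offsets(r))) == 0))
  }
})

make_toy_betas <- function(n_stim = 8, dims = c(6L, 6L, 6L), seed = 5,
                           mask = NULL) {
  grid <- volume_grid(dims)
  if (is.null(mask)) mask <- array(TRUE, dims)
  dat <- withr::with_seed(seed,
    matrix(rnorm(n_stim * sum(mask)), n_stim, sum(mask)))
  beta_series("sub-01", grid, paste0("s", seq_len(n_stim)), dat, mask)
}

test_that("neural RDM delegates to compute_rdm on the extracted sphere", {
  bs <- make_toy_betas()
  off <- sphere_offsets(2)
  got <- neural_rdm(bs, c(3, 3, 3), off, min_occupancy_frac = 0.5)
  pts <- sweep(off, 2, c(3L, 3L, 3L), `+`)
  keep <- apply(pts, 1, function(p) all(p >= 1 & p <= 6))
  lin <- apply(pts[keep, ], 1, function(p) p[1] + 6 * (p[2] - 1) + 36 * (p[3] - 1))
  cols <- match(lin, which(bs$mask))
  expect_equal(unclass(got), unclass(compute_rdm(bs$data[, cols])),
               ignore_attr = TRUE)

  # identical patterns give zero distance
  bs2 <- bs
  bs2$data[2, ] <- bs2$data[1, ]
  got2 <- neural_rdm(bs2, c(3, 3, 3), off)
  expect_equal(got2[1, 2], 0, tolerance = 1e-12)

  # single-voxel sphere is degenerate
  expect_error(neural_rdm(bs, c(3, 3, 3), sphere_offsets(0)), "in-mask voxels")
})

test_that("searchlight map matches a per-voxel loop oracle on a 6^3 volume", {
  dims <- c(6L, 6L, 6L)
  mask <- array(FALSE, dims)
  mask[2:5, 2:5, 2:5] <- TRUE
  bs <- make_toy_betas(n_stim = 8, dims = dims, seed = 31, mask = mask)
  model <- rand_rdm(8, seed = 77)
  control <- rand_rdm(8, seed = 78)
  cfg <- searchlight_config(radius = 2, min_occupancy_frac = 0.5)
  got_plain <- searchlight_map(bs, model, cfg)
  got_part <- searchlight_map(bs, model,
                              searchlight_config(radius = 2,
                                                 min_occupancy_frac = 0.5,
                                                 method = "partial_spearman"),
                              control = control)
  off <- sphere_offsets(2)
  thr <- max(2L, ceiling(0.5 * nrow(off)))
  for (lin in which(mask)) {
    center <- arrayInd(lin, dims)
    nr <- tryCatch(neural_rdm(bs, center, off, 0.5), error = function(e) NULL)
    if (is.null(nr)) {
      expect_true(is.na(got_plain[lin]))
      next
    }
    expect_equal(got_plain[lin], rdm_spearman(nr, model)$rho, tolerance = 1e-12)
    expect_equal(got_part[lin], rdm_partial_spearman(nr, model, control)$rho,
                 tolerance = 1e-12)
  }
  expect_true(all(is.na(got_plain[!mask])))
})

test_that("searchlight is invariant to simultaneous stimulus permutation", {
  bs <- make_toy_betas(n_stim = 7, seed = 41)
  model <- rand_rdm(7, seed = 42)
  rownames(model) <- colnames(model) <- bs$labels
  m1 <- searchlight_map(bs, model, searchlight_config(radius = 1,
                                                      min_occupancy_frac = 0))
  perm <- withr::with_seed(43, sample(7))
  bs2 <- beta_series("sub-01", bs$grid, bs$labels[perm], bs$data[perm, ], bs$mask)
  model2 <- rdm(unclass(model)[perm, perm])
  m2 <- searchlight_map(bs2, model2, searchlight_config(radius = 1,
                                                        min_occupancy_frac = 0))
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("a mask-covering sphere yields rho 1 against its own geometry", {
  # mask so small that every sphere covers it entirely: every center sees
  # the same voxel set, so the neural RDM is constant and equals the model
  dims <- c(6L, 6L, 6L)
  mask <- array(FALSE, dims)
  mask[3:4, 3:4, 3] <- TRUE
  feats <- rand_features(6, sum(mask), seed = 55)
  bs <- beta_series("s", volume_grid(dims), rownames(feats), feats, mask)
  model <- compute_rdm(feats)
  m <- searchlight_map(bs, model, searchlight_config(radius = 3,
                                                     min_occupancy_frac = 0))
  expect_equal(unname(m[mask]), rep(1, sum(mask)), tolerance = 1e-12)
})

test_that("pure-noise searchlight rho is centred on zero", {
  bs <- make_toy_betas(n_stim = 12, dims = c(7L, 7L, 7L), seed = 91)
  model <- rand_rdm(12, seed = 92)
  rownames(model) <- colnames(model) <- bs$labels
  m <- searchlight_map(bs, model, searchlight_config(radius = 2,
                                                     min_occupancy_frac = 0.5))
  v <- m[!is.na(m)]
  expect_gt(length(v), 50)
  expect_lt(abs(mean(v)), 3 * sd(v) / sqrt(length(v) / 10))  # ~10x overlap
})

test_that("smoothing is identity at FWHM 0, flat on constants, right width", {
  grid <- volume_grid(c(24L, 24L, 24L))
  mask <- array(TRUE, grid$dim)
  mask[1, , ] <- FALSE  # a mask edge
  m <- array(withr::with_seed(8, rnorm(prod(grid$dim))), grid$dim)
  s0 <- smooth_map(m, 0, grid, mask)
  expect_equal(s0[mask], m[mask])
  expect_true(all(is.na(s0[!mask])))

  const <- array(3.7, grid$dim)
  sc <- smooth_map(const, 6, grid, mask)
  expect_equal(sc[mask], rep(3.7, sum(mask)), tolerance = 1e-10)

  imp <- array(0, grid$dim)
  imp[12, 12, 12] <- 1
  si <- smooth_map(imp, 9, grid, array(TRUE, grid$dim))
  prof <- si[, 12, 12] / si[12, 12, 12]
  half <- approx(prof[12:24], 12:24, xout = 0.5)$y
  fwhm_vox <- 2 * (half - 12)
  expect_lt(abs(fwhm_vox * 3 - 9) / 9, 0.05)
})

test_that("group t map matches the closed form and flags degenerate voxels", {
  grid <- volume_grid(c(4L, 4L, 4L))
  mask <- array(TRUE, grid$dim)
  n <- 18
  vals <- withr::with_seed(3, rnorm(n, 0.3, 0.1))
  maps <- lapply(seq_len(n), function(i) {
    m <- array(0.2, grid$dim)
    m[2, 2, 2] <- vals[i]
    m
  })
  cfg <- group_inference_config(fwhm_mm = 0, fisher_z = FALSE)
  gi <- group_inference(maps, grid, mask, cfg)
  expect_equal(gi$df, 17L)
  expect_equal(gi$t_map[2, 2, 2],
               mean(vals) / (sd(vals) / sqrt(n)), tolerance = 1e-10)
  # all-identical voxels have zero variance: flagged NA
  expect_true(is.na(gi$t_map[1, 1, 1]))

  # fisher path applies atanh after smoothing
  gz <- group_inference(maps, grid, mask,
                        group_inference_config(fwhm_mm = 0, fisher_z = TRUE))
  expect_equal(gz$t_map[2, 2, 2],
               mean(atanh(vals)) / (sd(atanh(vals)) / sqrt(n)),
               tolerance = 1e-10)
})

test_that("cluster extent thresholding keeps only large-enough components", {
  grid <- volume_grid(c(4L, 4L, 4L))  # 27 mm3 voxels
  mask <- array(TRUE, grid$dim)
  n <- 6
  base <- array(0, grid$dim)
  big <- rbind(c(1, 1, 1), c(2, 1, 1), c(1, 2, 1), c(1, 1, 2), c(2, 2, 1))
  small <- rbind(c(4, 4, 4), c(4, 4, 3))
  maps <- lapply(seq_len(n), function(i) {
    m <- base + withr::with_seed(100 + i, array(rnorm(64, 0, 1e-3), dim(base)))
    for (r in seq_len(nrow(big)))
      m[big[r, 1], big[r, 2], big[r, 3]] <- 0.9 + m[big[r, 1], big[r, 2], big[r, 3]]
    for (r in seq_len(nrow(small)))
      m[small[r, 1], small[r, 2], small[r, 3]] <- 0.9 + m[small[r, 1], small[r, 2], small[r, 3]]
    m
  })
  gi <- group_inference(maps, grid, mask,
                        group_inference_config(fwhm_mm = 0, fisher_z = FALSE,
                                               cluster_extent_mm3 = 135))
  expect_equal(nrow(gi$clusters), 1L)
  expect_equal(gi$clusters$n_voxels, 5L)
  expect_equal(gi$clusters$volume_mm3, 135)
  expect_true(all(gi$cluster_map[gi$cluster_map > 0] == 1))
})

test_that("cluster labeling agrees with a flood-fill oracle", {
  for (s in 1:5) {
    bin <- withr::with_seed(s, array(runif(5^3) < 0.35, c(5L, 5L, 5L)))
    for (conn in c(6L, 18L, 26L)) {
      got <- label_clusters(bin, conn)
      want <- flood_fill_oracle(bin, conn)
      expect_true(same_partition(got, want))
    }
  }
})

test_that("NIfTI volumes and beta series round trip", {
  f <- withr::local_tempfile(fileext = ".nii")
  vol <- array(withr::with_seed(6, rnorm(10 * 8 * 6)), c(10L, 8L, 6L))
  write_nifti(vol, f, voxdim_mm = c(3, 3, 3), origin_mm = c(-15, -12, -9))
  got <- read_nifti(f)
  expect_equal(got$data, vol, tolerance = 1e-6)   # float32 storage
  expect_equal(got$voxdim_mm, c(3, 3, 3))
  expect_equal(got$origin_mm, c(-15, -12, -9))

  write_nifti(vol, f, datatype = "float64")
  expect_identical(read_nifti(f)$data, vol)       # lossless at float64

  vol4 <- array(withr::with_seed(7, rnorm(4 * 4 * 4 * 5)), c(4L, 4L, 4L, 5L))
  write_nifti(vol4, f)
  expect_equal(dim(read_nifti(f)$data), c(4L, 4L, 4L, 5L))

  grid <- volume_grid(c(6L, 6L, 6L))
  mask <- array(FALSE, grid$dim); mask[2:5, 2:5, 2:5] <- TRUE
  bs <- make_toy_betas(5, grid$dim, seed = 10, mask = mask)
  pre <- file.path(withr::local_tempdir(), "sub-01_beta")
  write_beta_series(bs, pre)
  bs2 <- read_beta_series(pre, mask, "sub-01")
  expect_equal(bs2$data, bs$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(bs2$labels, bs$labels)

  # grid mismatch
  expect_error(read_beta_series(pre, array(TRUE, c(5L, 5L, 5L))), "grid")
  # sidecar mismatch
  writeLines(c("stimulus", "s1", "s2"), paste0(pre, "_labels.tsv"))
  expect_error(read_beta_series(pre, mask), "labels but volume")
})
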