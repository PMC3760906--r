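test_that("rasterised sphere has the analytic volume and is deterministic", {
  nuc <- make_sphere(r = 5)
  expect_s3_class(nuc$mask, "nucleus_mask")
  expect_lt(abs(mask_volume(nuc$mask) - 4 / 3 * pi * 125) / (4 / 3 * pi * 125),
            0.02)
  nuc2 <- make_sphere(r = 5)
  expect_identical(nuc$mask$idx, nuc2$mask$idx)
  expect_identical(nuc$truth$quaternion, nuc2$truth$quaternion)
})

test_that("true flattening is the ratio of longest to shortest semi-axis", {
  cfg <- simulation_config(seed = 3, semi_axes_mean = c(8, 6, 2.4),
                           semi_axes_cv = 0,
                           condition_scale = list(A = c(1, 1, 1)))
  nuc <- simulate_nucleus(cfg, "A", seed = 3)
  expect_equal(nuc$truth$semi_axes[1] / nuc$truth$semi_axes[3], 8 / 2.4,
               tolerance = 1e-12)
})

test_that("a fixed grid too small for the ellipsoid names the offending axis", {
  cfg <- simulation_config(seed = 1, semi_axes_mean = c(8, 6, 3),
                           semi_axes_cv = 0,
                           condition_scale = list(A = c(1, 1, 1)),
                           grid_dim = c(5, 200, 200))
  expect_error(simulate_nucleus(cfg, "A", seed = 1), "axis z")
})

test_that("sampled spots always lie inside the mask with consistent true shells", {
  for (seed in 1:3) {
    cfg <- simulation_config(seed = seed, semi_axes_mean = c(6, 5, 3),
                             semi_axes_cv = 0.1,
                             condition_scale = list(A = c(1, 1, 1)))
    nuc <- simulate_nucleus(cfg, "A", seed = seed)
    sp <- sample_spots(nuc, c(0.3, 0.3, 0.2, 0.1, 0.1), 40, seed = seed + 10)
    arr <- logical(prod(nuc$mask$dim)); arr[nuc$mask$idx] <- TRUE
    tt <- nuc$truth
    for (i in seq_len(nrow(sp))) {
      p <- as.numeric(sp[i, c("z_um", "y_um", "x_um")])
      ijk <- round(p / nuc$mask$spacing) + 1
      lin <- ijk[1] + nuc$mask$dim[1] *
        ((ijk[2] - 1) + nuc$mask$dim[2] * (ijk[3] - 1))
      expect_true(arr[lin])
      s <- sqrt(sum((as.numeric((p - tt$center) %*% tt$axes) /
                       tt$semi_axes)^2))
      expect_lte(s, 1)
      expect_equal(sp$shell[i], min(5L, floor(s^3 * 5) + 1L))
    }
  }
})

test_that("degenerate shell probabilities confine spots to the right band", {
  nuc <- make_sphere(r = 5)
  inner <- sample_spots(nuc, c(1, 0, 0, 0, 0), 30, seed = 2)
  expect_true(all(inner$shell == 1L))
  outer <- sample_spots(nuc, c(0, 0, 0, 0, 1), 30, seed = 3)
  expect_true(all(outer$shell == 5L))
  # normalized radius of inner spots below the innermost volume-quintile cut
  tt <- nuc$truth
  s <- apply(inner[c("z_um", "y_um", "x_um")], 1, function(p)
    sqrt(sum((as.numeric((p - tt$center) %*% tt$axes) / tt$semi_axes)^2)))
  expect_true(all(s <= (1 / 5)^(1 / 3) + 1e-9))
})

test_that("empirical shell frequencies recover a printed generating row", {
  # one large nucleus, 5000 spots, 3-sigma binomial bands per shell
  p <- c(19.77, 31.40, 30.23, 9.30, 9.30)
  p <- p / sum(p)
  nuc <- make_sphere(r = 6, spacing = c(0.4, 0.25, 0.25))
  sp <- sample_spots(nuc, p, 5000, seed = 7)
  emp <- tabulate(sp$shell, 5) / 5000
  expect_true(all(abs(emp - p) < 3 * sqrt(p * (1 - p) / 5000)))
})

test_that("zero-noise zero-PSF rendering puts probe signal only at spot voxels", {
  cfg <- sphere_config(r = 4)
  nuc <- simulate_nucleus(cfg, "A", seed = 5)
  sp <- sample_spots(nuc, rep(0.2, 5), 2, seed = 6)
  st <- render_stack(nuc, sp, cfg)
  hot <- which(st$channels$fish > 1e-6 * cfg$amp_spot)
  # trilinear deposit touches at most 8 voxels per spot
  expect_lte(length(hot), 16)
  d <- st$dim
  hz <- ((hot - 1) %% d[1]) * st$spacing[1]
  expect_true(all(vapply(hz, function(z)
    any(abs(z - sp$z_um) < 2 * st$spacing[1]), TRUE)))
})

test_that("PSF convolution conserves total probe signal before noise", {
  cfg <- sphere_config(r = 4, psf = c(0.4, 0.13, 0.13))
  nuc <- simulate_nucleus(cfg, "A", seed = 5)
  sp <- sample_spots(nuc, rep(0.2, 5), 2, seed = 6)
  st <- render_stack(nuc, sp, cfg)
  expect_equal(sum(st$channels$fish), 2 * cfg$amp_spot,
               tolerance = 0.01)
})

test_that("identical config and seed give bit-identical simulations", {
  cfg <- default_config(seed = 77, n = 1)
  a <- simulate_fish_experiment(cfg)
  b <- simulate_fish_experiment(cfg)
  expect_identical(a$nuclei, b$nuclei)
  expect_identical(a$spots, b$spots)
  expect_identical(a$fields[[1]]$stack$channels, b$fields[[1]]$stack$channels)
})

test_that("myocyte-scaled nuclei are smaller and flatter (truth-level)", {
  # anisotropic condition scaling; Mann-Whitney on true morphometry
  ps <- sapply(101:103, function(seed) {
    cfg <- simulation_config(seed = seed, n_nuclei_per_condition = 50)
    ex <- simulate_fish_experiment(cfg, render = FALSE)
    v <- split(ex$nuclei$volume_um3, ex$nuclei$condition)
    f <- split(ex$nuclei$flattening, ex$nuclei$condition)
    c(mann_whitney_u(v$Mb24h, v$Mc7d)$p_value,
      mann_whitney_u(f$Mb24h, f$Mc7d)$p_value,
      median(v$Mc7d) < median(v$Mb24h),
      median(f$Mc7d) > median(f$Mb24h))
  })
  expect_true(all(ps[1, ] < 0.01))
  expect_true(all(ps[2, ] < 0.01))
  expect_true(all(ps[3, ] == 1) && all(ps[4, ] == 1))
})

test_that("expression generator is deterministic and records truth", {
  a <- simulate_expression(200, 3, 0.1, 2, seed = 5)
  b <- simulate_expression(200, 3, 0.1, 2, seed = 5)
  expect_identical(a$matrix, b$matrix)
  expect_equal(dim(a$matrix), c(200L, 6L))
  expect_equal(sum(a$truth$spiked), 20)
  expect_true(all(abs(a$truth$true_lfc[a$truth$spiked]) == 2))
  expect_true(all(a$truth$true_lfc[!a$truth$spiked] == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(shell_probs = list(p = c(0.5, 0.6))),
               "sum to 1")
  expect_error(simulation_config(shell_probs = list(p = c(-0.1, 1.1, 0, 0, 0))),
               "non-negative")
  expect_error(simulation_config(semi_axes_mean = c(3, 6, 8)), "descending")
})
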