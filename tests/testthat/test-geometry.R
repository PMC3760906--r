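test_that("ellipsoid fit recovers a digital sphere", {
  nuc <- make_sphere(r = 5)
  fit <- fit_ellipsoid(nuc$mask)
  expect_true(all(abs(fit$semi_axes - 5) / 5 < 0.03))
  expect_gte(fit$flattening, 1)
  expect_lt(fit$flattening, 1.05)
  expect_equal(fit$volume,
               length(nuc$mask$idx) * prod(nuc$mask$spacing))  # exact
})

test_that("ellipsoid fit recovers a randomly rotated 8/6/2.4 ellipsoid", {
  cfg <- simulation_config(seed = 4, semi_axes_mean = c(8, 6, 2.4),
                           semi_axes_cv = 0,
                           condition_scale = list(A = c(1, 1, 1)))
  for (seed in 41:43) {
    nuc <- simulate_nucleus(cfg, "A", seed = seed)
    fit <- fit_ellipsoid(nuc$mask)
    expect_true(all(abs(fit$semi_axes - c(8, 6, 2.4)) / c(8, 6, 2.4) < 0.05))
    expect_lt(abs(fit$flattening - 8 / 2.4) / (8 / 2.4), 0.05)
  }
})

test_that("degenerate voxel sets are rejected", {
  m <- new_nucleus_mask(1L, idx = 1:10, dim = c(10L, 3L, 3L),
                        spacing = c(0.5, 0.2, 0.2))
  expect_error(fit_ellipsoid(m), "degenerate")
})

test_that("the two radial metrics agree on a sphere", {
  nuc <- make_sphere(r = 5)
  redt <- radial_coordinate(nuc$mask, "edt")
  rell <- radial_coordinate(nuc$mask, "ellipsoid")
  expect_gt(cor(redt, rell, method = "spearman"), 0.99)
  # centre voxel near 0, border voxel maximal
  expect_lt(min(redt), 0.05)
  co <- voxel_coords_um(nuc$mask)
  rphys <- sqrt(colSums((t(co) - nuc$truth$center)^2))
  expect_gt(cor(redt, rphys, method = "spearman"), 0.99)
  # the geometrically outermost voxel carries the maximal edt coordinate
  # (many border voxels tie at the maximum)
  expect_equal(redt[which.max(rphys)], max(redt), tolerance = 1e-12)
})

test_that("equal-volume contract holds for arbitrary masks and K", {
  cfg <- simulation_config(seed = 6, semi_axes_mean = c(6, 5, 2.5),
                           semi_axes_cv = 0.1,
                           condition_scale = list(A = c(1, 1, 1)))
  for (seed in 61:62) {
    nuc <- simulate_nucleus(cfg, "A", seed = seed)
    for (K in c(1L, 3L, 5L, 7L)) {
      part <- equal_volume_shells(nuc$mask, K)
      expect_equal(sort(unique(part$shell)), seq_len(K))
      voxvol <- prod(nuc$mask$spacing)
      expect_lte(max(abs(part$shell_volumes - mask_volume(nuc$mask) / K)),
                 K * voxvol)
      if (K == 1L) expect_length(part$boundaries, 0)
      else expect_true(all(diff(part$boundaries) > 0))
    }
  }
})

test_that("innermost shell boundary of a digital sphere matches the analytic radius", {
  # equal-volume radii of a sphere: r_k = (k/5)^(1/3) R
  nuc <- make_sphere(r = 5, spacing = c(0.25, 0.25, 0.25))
  for (mode in c("edt", "ellipsoid")) {
    part <- equal_volume_shells(nuc$mask, 5, mode = mode)
    co <- voxel_coords_um(nuc$mask)
    rphys <- sqrt(colSums((t(co) - nuc$truth$center)^2))
    r1 <- max(rphys[part$shell == 1])
    expect_lt(abs(r1 - (1 / 5)^(1 / 3) * 5) / ((1 / 5)^(1 / 3) * 5), 0.03)
  }
})

test_that("uniform random spots give uniform shell counts (chi-square GOF)", {
  nuc <- make_sphere(r = 5)
  part <- equal_volume_shells(nuc$mask, 5)
  set.seed(99)
  pvals <- replicate(100, {
    vox <- sample(seq_along(nuc$mask$idx), 400, replace = TRUE)
    suppressWarnings(chisq.test(tabulate(part$shell[vox], 5),
                                p = rep(0.2, 5))$p.value)
  })
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("shell index is non-decreasing from the centre out along rays", {
  cfg <- simulation_config(seed = 8, semi_axes_mean = c(6, 5, 3),
                           semi_axes_cv = 0,
                           condition_scale = list(A = c(1, 1, 1)))
  nuc <- simulate_nucleus(cfg, "A", seed = 8)
  part <- equal_volume_shells(nuc$mask, 5, mode = "ellipsoid")
  fit <- part$fit
  set.seed(7)
  for (rep in 1:20) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    s_seq <- seq(0.02, 0.999, length.out = 60)
    sh <- vapply(s_seq, function(s) {
      p <- fit$center + as.vector(fit$axes %*% (s * d * fit$semi_axes))
      point_shell(part, p)
    }, 1L)
    sh <- sh[!is.na(sh)]
    expect_true(all(diff(sh) >= 0))
  }
})

test_that("edt and ellipsoid partitions agree on near-spherical masks", {
  # isotropic sampling so grid anisotropy does not dominate the boundary bands
  nuc <- make_sphere(r = 5, spacing = c(0.25, 0.25, 0.25))
  pe <- equal_volume_shells(nuc$mask, 5, mode = "edt")
  pl <- equal_volume_shells(nuc$mask, 5, mode = "ellipsoid")
  agree <- mean(pe$shell == pl$shell)
  expect_gte(agree, 0.95)
  # disagreements confined to adjacent shells (boundary bands)
  expect_true(all(abs(pe$shell - pl$shell) <= 1))
})

test_that("axis-aligned 90-degree rotation permutes nothing in the distribution", {
  cfg <- sphere_config(r = 4, spacing = c(0.25, 0.25, 0.25))
  nuc <- simulate_nucleus(cfg, "A", seed = 9)
  sp <- sample_spots(nuc, c(0.2, 0.4, 0.2, 0.1, 0.1), 30, seed = 10)
  count_shells <- function(mask, spots) {
    part <- equal_volume_shells(mask, 5, mode = "edt")
    spots$nucleus_label <- 1L; spots$probe <- "p"; spots$condition <- "A"
    shell_counts(assign_spots(spots, list(`1` = part)))[1, ]
  }
  base <- count_shells(nuc$mask, sp)
  # rotate mask and spots 90 degrees about z: (z, y, x) -> (z, x, Ny - y)
  arr <- array(FALSE, nuc$mask$dim); arr[nuc$mask$idx] <- TRUE
  rot <- aperm(arr, c(1, 3, 2))[, , rev(seq_len(dim(arr)[2]))]
  m2 <- new_nucleus_mask(1L, which(rot), dim(rot), nuc$mask$spacing)
  ny <- nuc$mask$dim[2]
  sp2 <- data.frame(z_um = sp$z_um, y_um = sp$x_um,
                    x_um = (ny - 1) * nuc$mask$spacing[2] - sp$y_um)
  expect_identical(unname(count_shells(m2, sp2)), unname(base))
})

test_that("spots at the centre and periphery land in shells 1 and K", {
  nuc <- make_sphere(r = 5)
  part <- equal_volume_shells(nuc$mask, 5)
  expect_equal(point_shell(part, nuc$truth$center), 1L)
  # noiseless path in the metric the spots were generated in
  pell <- equal_volume_shells(nuc$mask, 5, mode = "ellipsoid")
  sp5 <- sample_spots(nuc, c(0, 0, 0, 0, 1), 20, seed = 13)
  sp5$nucleus_label <- 1L; sp5$probe <- "p"; sp5$condition <- "A"
  d <- assign_spots(sp5, list(`1` = pell))
  expect_equal(unname(shell_counts(d)[1, 5]), 20L)
})

test_that("off-mask centroids snap within one voxel, farther ones are discarded", {
  nuc <- make_sphere(r = 5)
  part <- equal_volume_shells(nuc$mask, 5)
  co <- voxel_coords_um(nuc$mask)
  border <- co[which.max(radial_coordinate(nuc$mask)), ]
  out_dir <- border - nuc$truth$center
  out_dir <- out_dir / sqrt(sum(out_dir^2))
  near <- border + out_dir * nuc$mask$spacing * 0.9
  far <- border + out_dir * 5
  sp <- data.frame(z_um = c(near[1], far[1]), y_um = c(near[2], far[2]),
                   x_um = c(near[3], far[3]),
                   nucleus_label = 1L, probe = "p", condition = "A")
  d <- assign_spots(sp, list(`1` = part))
  expect_equal(attr(d, "discarded"), 1L)
  expect_equal(sum(shell_counts(d)), 1)
})

test_that("morphometry table separates the two generator conditions end to end", {
  cfg <- default_config(seed = 55, n = 6)
  ex <- simulate_fish_experiment(cfg)
  masks <- lapply(ex$fields, function(f) {
    m <- segment_nuclei(f$stack, condition = f$condition)[[1]]
    m$label <- f$id
    m
  })
  mt <- morphometry_table(masks)
  expect_true(all(c("volume_um3", "flattening") %in% names(mt)))
  expect_lt(median(mt$volume_um3[mt$condition == "Mc7d"]),
            median(mt$volume_um3[mt$condition == "Mb24h"]))
  expect_gt(median(mt$flattening[mt$condition == "Mc7d"]),
            median(mt$flattening[mt$condition == "Mb24h"]))
  expect_identical(morphometry_table(list()),
                   data.frame(nucleus = integer(), condition = character(),
                              volume_um3 = numeric(), flattening = numeric()))
})
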