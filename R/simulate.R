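#' Configuration for the synthetic 3D-FISH experiment generator
#'
#' Bundles and validates every knob of the generator: nucleus geometry per
#' condition, voxel grid, per-probe shell probabilities used to place
#' centromere spots, the imaging point-spread function and the noise model.
#' The defaults emulate a myoblast / myotube comparison: myoblast-like
#' nuclei with semi-axes (8, 6, 3) um, and myotube-like nuclei scaled
#' anisotropically (more along z) to (7, 6, 2) um, i.e. smaller and more
#' flattened after differentiation.
#'
#' @param seed master seed; every stage derives its own substream from it.
#' @param n_nuclei_per_condition nuclei to simulate per condition.
#' @param voxel_spacing voxel size in um, order (z, y, x).
#' @param semi_axes_mean mean ellipsoid semi-axes in um, sorted a >= b >= c.
#' @param semi_axes_cv coefficient of variation of the per-nucleus
#'   log-normal-ish jitter applied to each semi-axis.
#' @param condition_scale named list, one numeric length-3 multiplier
#'   (applied to \code{semi_axes_mean} in (a, b, c) order) per condition.
#' @param shell_probs named list of per-probe probability vectors over the
#'   K shells (innermost first); each must be non-negative and sum to 1.
#'   A probe entry may itself be a named list with one vector per
#'   condition, so the generating radial distribution can differ between
#'   conditions (the repositioning scenario).
#' @param spots_per_nucleus FISH signals per nucleus (2 for a diploid
#'   autosome probe; exposed because X-probe counts differ by sex and
#'   overlapping homolog signals may merge).
#' @param psf_sigma Gaussian PSF standard deviation in um, (z, y, x).
#' @param noise_model list with elements \code{photon} (logical: apply
#'   Poisson photon-count noise), \code{background} (mean background photon
#'   level added before the Poisson draw) and \code{read_sd} (additive
#'   Gaussian read-noise SD applied after).
#' @param amp_nucleus counterstain photon amplitude inside the nucleus.
#' @param amp_spot total photons deposited per FISH spot.
#' @param grid_dim optional fixed grid dimension (nz, ny, nx); when NULL the
#'   grid is sized to hold the ellipsoid plus a PSF margin.
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(seed = 1L,
                              n_nuclei_per_condition = 50L,
                              voxel_spacing = c(0.4, 0.2, 0.2),
                              semi_axes_mean = c(8, 6, 3),
                              semi_axes_cv = 0.08,
                              condition_scale = list(
                                Mb24h = c(1, 1, 1),
                                Mc7d = c(7 / 8, 1, 2 / 3)
                              ),
                              shell_probs = list(probe = rep(0.2, 5)),
                              spots_per_nucleus = 2L,
                              psf_sigma = c(0.4, 0.13, 0.13),
                              noise_model = list(photon = TRUE,
                                                 background = 10,
                                                 read_sd = 2),
                              amp_nucleus = 100,
                              amp_spot = 2000,
                              grid_dim = NULL) {
  stopifnot(length(voxel_spacing) == 3, all(voxel_spacing > 0),
            length(semi_axes_mean) == 3, all(semi_axes_mean > 0),
            length(psf_sigma) == 3, all(psf_sigma >= 0),
            semi_axes_cv >= 0, spots_per_nucleus >= 1,
            n_nuclei_per_condition >= 1)
  if (is.unsorted(rev(semi_axes_mean)))
    stop("semi_axes_mean must be sorted descending (a >= b >= c)")
  if (is.null(names(condition_scale)) || anyDuplicated(names(condition_scale)))
    stop("condition_scale must be a uniquely named list")
  for (cs in condition_scale)
    stopifnot(length(cs) == 3, all(cs > 0))
  if (is.null(names(shell_probs)) || anyDuplicated(names(shell_probs)))
    stop("shell_probs must be a uniquely named list")
  leaves <- unlist(lapply(shell_probs, function(p)
    if (is.list(p)) p else list(p)), recursive = FALSE)
  K <- unique(vapply(leaves, length, 1L))
  if (length(K) != 1L)
    stop("all shell_probs vectors must have the same length K")
  for (p in leaves) {
    if (any(p < 0)) stop("shell probabilities must be non-negative")
    if (abs(sum(p) - 1) > 1e-9)
      stop("each shell_probs vector must sum to 1 (tolerance 1e-9)")
  }
  structure(list(seed = as.integer(seed),
                 n_nuclei_per_condition = as.integer(n_nuclei_per_condition),
                 voxel_spacing = as.numeric(voxel_spacing),
                 semi_axes_mean = as.numeric(semi_axes_mean),
                 semi_axes_cv = semi_axes_cv,
                 condition_scale = condition_scale,
                 shell_probs = shell_probs,
                 K = K,
                 spots_per_nucleus = as.integer(spots_per_nucleus),
                 psf_sigma = as.numeric(psf_sigma),
                 noise_model = noise_model,
                 amp_nucleus = amp_nucleus,
                 amp_spot = amp_spot,
                 grid_dim = grid_dim),
            class = "simulation_config")
}

# Haar-uniform random rotation matrix (QR of a Gaussian matrix with the
# sign convention fixed, determinant forced to +1).
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# unit quaternion (w, x, y, z) of a rotation matrix, for ground-truth export
rotation_quaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

#' Simulate one voxelized ellipsoidal nucleus
#'
#' Draws per-nucleus semi-axes (mean scaled by the condition multiplier,
#' jittered by \code{semi_axes_cv}) and a uniformly random orientation, then
#' rasterises the ellipsoid: a voxel belongs to the nucleus iff its centre
#' satisfies the ellipsoid inequality. The grid is sized to contain the
#' ellipsoid plus a PSF margin unless \code{config$grid_dim} is fixed.
#'
#' @param config a [simulation_config()].
#' @param condition name of an entry of \code{config$condition_scale}.
#' @param seed optional integer; when given, seeds the draw (otherwise the
#'   current RNG state is used).
#' @return list with \code{mask} (a \code{nucleus_mask}) and \code{truth}
#'   (centre, semi-axes, orientation matrix and quaternion, condition).
#' @export
simulate_nucleus <- function(config, condition, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!condition %in% names(config$condition_scale))
    stop("unknown condition: ", condition)
  if (!is.null(seed)) set.seed(seed)
  scale <- config$condition_scale[[condition]]
  semi <- config$semi_axes_mean * scale *
    pmax(0.2, 1 + config$semi_axes_cv * rnorm(3))
  semi <- sort(semi, decreasing = TRUE)
  R <- random_rotation()
  sp <- config$voxel_spacing
  margin <- 3 * max(config$psf_sigma) + 0.6
  if (is.null(config$grid_dim)) {
    # half-extent of the rotated ellipsoid along grid axis i is
    # sqrt(sum_j (R[i,j] * semi[j])^2); rows of the world<-body matrix
    ext <- sqrt(rowSums((R %*% diag(semi))^2))
    dim3 <- as.integer(ceiling(2 * (ext + margin) / sp) + 1L)
  } else {
    dim3 <- as.integer(config$grid_dim)
    ext <- sqrt(rowSums((R %*% diag(semi))^2))
    need <- 2 * (ext + margin)
    have <- (dim3 - 1) * sp
    if (any(need > have)) {
      ax <- c("z", "y", "x")[which(need > have)[1]]
      stop("ellipsoid exceeds grid bounds along axis ", ax,
           " (needs ", sprintf("%.1f", need[which(need > have)[1]]),
           " um)")
    }
  }
  center <- (dim3 - 1) / 2 * sp
  cz <- ((seq_len(dim3[1]) - 1) * sp[1] - center[1])
  cy <- ((seq_len(dim3[2]) - 1) * sp[2] - center[2])
  cx <- ((seq_len(dim3[3]) - 1) * sp[3] - center[3])
  # body-frame coordinates: b = t(R) %*% (x - c); accumulate s^2 axis-wise
  s2 <- array(0, dim3)
  for (j in 1:3) {
    bj <- outer(outer(cz * R[1, j], cy * R[2, j], `+`), cx * R[3, j], `+`)
    s2 <- s2 + (bj / semi[j])^2
  }
  inside <- s2 <= 1
  mask <- new_nucleus_mask(label = 1L, idx = which(inside), dim = dim3,
                           spacing = sp, condition = condition)
  truth <- list(center = center, semi_axes = semi, axes = R,
                quaternion = rotation_quaternion(R), condition = condition)
  list(mask = mask, truth = truth)
}

# volume-quantile shell of ellipsoid-metric radius s (fraction inside a
# scaled surface s is s^3)
true_shell_of <- function(s, K) pmin(K, floor(pmin(s, 1 - 1e-12)^3 * K) + 1L)

#' Place FISH spots inside a simulated nucleus with known radial structure
#'
#' Each spot is drawn by sampling a shell index from \code{shell_probs} and
#' then a position uniformly over that shell of the true ellipsoid (radius
#' from the volume-quantile band, direction uniform). Positions falling in a
#' voxel outside the rasterised mask (possible right at the surface) are
#' resampled, so every spot lies strictly inside the mask.
#'
#' @param nucleus result of [simulate_nucleus()].
#' @param shell_probs probability vector over the K shells, innermost first.
#' @param n_spots number of spots.
#' @param seed optional integer seed.
#' @return data.frame with columns z_um, y_um, x_um, shell (true shell).
#' @export
sample_spots <- function(nucleus, shell_probs, n_spots, seed = NULL) {
  stopifnot(n_spots >= 1, all(shell_probs >= 0),
            abs(sum(shell_probs) - 1) < 1e-9)
  if (!is.null(seed)) set.seed(seed)
  K <- length(shell_probs)
  mask <- nucleus$mask
  truth <- nucleus$truth
  # validate geometry: every shell with mass must own at least one voxel
  vox <- voxel_coords_um(mask)
  b <- sweep(vox, 2, truth$center) %*% truth$axes
  svox <- sqrt(rowSums(sweep(b, 2, truth$semi_axes, `/`)^2))
  have <- unique(true_shell_of(svox, K))
  needed <- which(shell_probs > 0)
  if (!all(needed %in% have))
    stop("degenerate geometry: shell ", setdiff(needed, have)[1],
         " has positive probability but zero voxels")
  arr <- logical(prod(mask$dim)); arr[mask$idx] <- TRUE
  out <- matrix(NA_real_, n_spots, 3)
  shell <- integer(n_spots)
  for (i in seq_len(n_spots)) {
    k <- sample.int(K, 1, prob = shell_probs)
    for (try in 1:1000) {
      u <- runif(1, (k - 1) / K, k / K)
      s <- u^(1 / 3)
      d <- rnorm(3); d <- d / sqrt(sum(d^2))
      p <- truth$center + as.vector(truth$axes %*% (s * d * truth$semi_axes))
      ijk <- round(p / mask$spacing) + 1
      if (all(ijk >= 1) && all(ijk <= mask$dim)) {
        lin <- ijk[1] + mask$dim[1] * ((ijk[2] - 1) + mask$dim[2] * (ijk[3] - 1))
        if (arr[lin]) { out[i, ] <- p; shell[i] <- k; break }
      }
    }
    if (is.na(out[i, 1]))
      stop("degenerate geometry: could not place a spot in shell ", k)
  }
  data.frame(z_um = out[, 1], y_um = out[, 2], x_um = out[, 3], shell = shell)
}

# wrapped separable Gaussian kernel values for an axis of length n
gauss1d_wrapped <- function(n, sigma_vox) {
  k <- numeric(n)
  if (sigma_vox <= 0) { k[1] <- 1; return(k) }
  d <- pmin(0:(n - 1), n - (0:(n - 1)))
  k <- exp(-0.5 * (d / sigma_vox)^2)
  k / sum(k)
}

# circular FFT convolution with a separable kernel given per-axis 1-D parts
conv_separable_fft <- function(arr, kz, ky, kx) {
  kern <- kz %o% ky %o% kx
  Re(stats::fft(stats::fft(arr) * stats::fft(kern), inverse = TRUE)) /
    length(arr)
}

gaussian_blur_3d <- function(arr, sigma_um, spacing) {
  sv <- sigma_um / spacing
  if (all(sv <= 0)) return(arr)
  d <- dim(arr)
  conv_separable_fft(arr, gauss1d_wrapped(d[1], sv[1]),
                     gauss1d_wrapped(d[2], sv[2]),
                     gauss1d_wrapped(d[3], sv[3]))
}

#' Render a two-channel confocal stack for one simulated nucleus
#'
#' Channel 1 (counterstain) is the binary nucleus mask times
#' \code{amp_nucleus}; channel 2 (FISH probe) deposits \code{amp_spot}
#' photons per spot by trilinear interpolation. Both channels are convolved
#' with the anisotropic Gaussian PSF, then Poisson photon noise (on signal
#' plus mean background) and additive Gaussian read noise are applied;
#' intensities are clamped at zero.
#'
#' @param nucleus result of [simulate_nucleus()].
#' @param spots data.frame from [sample_spots()] (may have zero rows).
#' @param config a [simulation_config()].
#' @param seed optional integer seed for the noise draws.
#' @return an [image_stack()] with channels \code{"dna"} and \code{"fish"}.
#' @export
render_stack <- function(nucleus, spots, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mask <- nucleus$mask
  d <- mask$dim; sp <- mask$spacing
  ch1 <- array(0, d); ch1[mask$idx] <- config$amp_nucleus
  ch2 <- array(0, d)
  if (nrow(spots)) {
    for (i in seq_len(nrow(spots))) {
      p <- as.numeric(spots[i, c("z_um", "y_um", "x_um")]) / sp  # 0-based
      i0 <- floor(p); f <- p - i0
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        w <- prod(ifelse(c(dz, dy, dx) == 1, f, 1 - f))
        ijk <- i0 + c(dz, dy, dx) + 1
        if (all(ijk >= 1) && all(ijk <= d))
          ch2[ijk[1], ijk[2], ijk[3]] <-
            ch2[ijk[1], ijk[2], ijk[3]] + w * config$amp_spot
      }
    }
  }
  ch1 <- gaussian_blur_3d(ch1, config$psf_sigma, sp)
  ch2 <- gaussian_blur_3d(ch2, config$psf_sigma, sp)
  nm <- config$noise_model
  addnoise <- function(a) {
    a <- pmax(a, 0)
    if (isTRUE(nm$photon))
      a <- array(rpois(length(a), a + nm$background), dim(a))
    else a <- a + nm$background
    if ((nm$read_sd %||% 0) > 0)
      a <- a + array(rnorm(length(a), 0, nm$read_sd), dim(a))
    pmax(a, 0)
  }
  image_stack(list(dna = addnoise(ch1), fish = addnoise(ch2)), spacing = sp)
}

#' Simulate a full two-condition 3D-FISH experiment with ground truth
#'
#' For every condition and probe, simulates \code{n_nuclei_per_condition}
#' nuclei, places spots according to the probe's shell probabilities and
#' (optionally) renders the noisy two-channel stacks. All randomness flows
#' from \code{config$seed} through per-stage substreams, so identical
#' configurations give bit-identical results.
#'
#' @param config a [simulation_config()].
#' @param probes which entries of \code{config$shell_probs} to simulate.
#' @param render if FALSE, skip stack rendering (geometry and truth only).
#' @return object of class \code{fish_simulation}: list with \code{fields}
#'   (one record per nucleus: mask, truth, spots, stack or NULL) and tidy
#'   truth tables \code{nuclei} and \code{spots}.
#' @export
simulate_fish_experiment <- function(config,
                                     probes = names(config$shell_probs),
                                     render = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  fields <- list()
  nrec <- list(); srec <- list()
  id <- 0L
  for (cond in names(config$condition_scale)) {
    for (probe in probes) {
      pr <- config$shell_probs[[probe]]
      if (is.list(pr)) {
        if (is.null(pr[[cond]]))
          stop("shell_probs for probe ", probe, " has no entry for ",
               "condition ", cond)
        pr <- pr[[cond]]
      }
      for (i in seq_len(config$n_nuclei_per_condition)) {
        id <- id + 1L
        tag <- paste(cond, probe, i, sep = "/")
        nuc <- simulate_nucleus(config, cond,
                                seed = stage_seed(config$seed,
                                                  paste0("nucleus/", tag)))
        spots <- sample_spots(nuc, pr, config$spots_per_nucleus,
                              seed = stage_seed(config$seed,
                                                paste0("spots/", tag)))
        stack <- if (render)
          render_stack(nuc, spots, config,
                       seed = stage_seed(config$seed,
                                         paste0("render/", tag)))
        fields[[id]] <- list(id = id, condition = cond, probe = probe,
                             mask = nuc$mask, truth = nuc$truth,
                             spots = spots, stack = stack)
        nrec[[id]] <- data.frame(nucleus = id, condition = cond,
                                 probe = probe,
                                 volume_um3 = 4 / 3 * pi *
                                   prod(nuc$truth$semi_axes),
                                 flattening = nuc$truth$semi_axes[1] /
                                   nuc$truth$semi_axes[3],
                                 t(setNames(nuc$truth$quaternion,
                                            paste0("q", 1:4))))
        srec[[id]] <- cbind(nucleus = id, condition = cond, probe = probe,
                            spots)
      }
    }
  }
  structure(list(config = config, fields = fields,
                 nuclei = do.call(rbind, nrec),
                 spots = do.call(rbind, srec)),
            class = "fish_simulation")
}

#' @export
print.fish_simulation <- function(x, ...) {
  cat("fish_simulation:", length(x$fields), "fields,",
      nrow(x$spots), "spots;",
      "conditions:", paste(unique(x$nuclei$condition), collapse = ", "),
      "; probes:", paste(unique(x$nuclei$probe), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a two-group log2 expression matrix with spiked fold changes
#'
#' Genes get i.i.d. Gaussian noise around a per-gene baseline; a random
#' subset is shifted by \code{+/- effect_log2fc} in group 2. Emulates a
#' triplicate-per-group microarray comparison on the log2 scale.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (>= 2).
#' @param spike_fraction fraction of genes with a true effect.
#' @param effect_log2fc absolute log2 fold change of spiked genes.
#' @param noise_sd residual SD on the log2 scale.
#' @param seed optional integer seed.
#' @return list with \code{matrix} (genes x samples), \code{groups}
#'   (factor), and \code{truth} (gene, spiked, true_lfc).
#' @export
simulate_expression <- function(n_genes, n_per_group, spike_fraction = 0.05,
                                effect_log2fc = 3, noise_sd = 0.25,
                                seed = NULL) {
  stopifnot(n_per_group >= 2, n_genes >= 1,
            spike_fraction >= 0, spike_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  baseline <- rnorm(n_genes, mean = 8, sd = 1.5)
  nspike <- round(spike_fraction * n_genes)
  spiked <- sort(sample.int(n_genes, nspike))
  lfc <- numeric(n_genes)
  if (nspike)
    lfc[spiked] <- effect_log2fc * sample(c(-1, 1), nspike, replace = TRUE)
  ns <- 2 * n_per_group
  m <- matrix(rnorm(n_genes * ns, sd = noise_sd), n_genes, ns) + baseline
  g2 <- (n_per_group + 1):ns
  m[, g2] <- m[, g2] + lfc
  genes <- sprintf("gene%05d", seq_len(n_genes))
  rownames(m) <- genes
  colnames(m) <- c(paste0("A", seq_len(n_per_group)),
                   paste0("B", seq_len(n_per_group)))
  list(matrix = m,
       groups = factor(rep(c("A", "B"), each = n_per_group)),
       truth = data.frame(gene = genes, spiked = seq_len(n_genes) %in% spiked,
                          true_lfc = lfc))
}
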