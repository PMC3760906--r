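#' Fit an inertia-equivalent ellipsoid to a nucleus mask
#'
#' The centre is the voxel centroid (um); orientation and semi-axes come
#' from the principal axes of the second-moment (covariance) matrix of the
#' voxel coordinates, with semi-axis i equal to \code{sqrt(5 * lambda_i)}
#' so that a uniform solid ellipsoid with those axes has the same inertia.
#' Volume is voxel count times voxel volume; flattening is the ratio of the
#' longest to the shortest semi-axis (a/c, always >= 1).
#'
#' @param mask a \code{nucleus_mask}.
#' @return object of class \code{ellipsoid_fit} with fields center,
#'   semi_axes (a >= b >= c), axes (columns = principal directions),
#'   volume, flattening.
#' @export
fit_ellipsoid <- function(mask) {
  stopifnot(inherits(mask, "nucleus_mask"))
  co <- voxel_coords_um(mask)
  center <- colMeans(co)
  cv <- stats::cov(co) * (nrow(co) - 1) / nrow(co)
  if (nrow(co) < 4 ||
      min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values) < 1e-12)
    stop("degenerate geometry: voxel set is planar or linear")
  # add the second moment of a uniform voxel: the mask is a union of voxel
  # cubes, not a point cloud
  cv <- cv + diag(mask$spacing^2 / 12)
  eg <- eigen(cv, symmetric = TRUE)
  semi <- sqrt(5 * eg$values)
  structure(list(center = center, semi_axes = semi, axes = eg$vectors,
                 volume = mask_volume(mask),
                 flattening = semi[1] / semi[3]),
            class = "ellipsoid_fit")
}

#' @export
print.ellipsoid_fit <- function(x, ...) {
  cat(sprintf(
    "ellipsoid_fit: semi-axes %.2f/%.2f/%.2f um, volume %.1f um3, flattening %.2f\n",
    x$semi_axes[1], x$semi_axes[2], x$semi_axes[3], x$volume, x$flattening))
  invisible(x)
}

#' Normalized radial coordinate of every mask voxel
#'
#' Two radial metrics, both increasing from the nuclear centre (0-ish) to
#' the periphery:
#' \describe{
#'   \item{edt}{\code{1 - d(v)/max(d)} where d is the anisotropic Euclidean
#'     distance (um) to the nearest background voxel. Defined for arbitrary
#'     mask shapes; the deepest interior voxel gets 0.}
#'   \item{ellipsoid}{the Mahalanobis-type scale s at which the voxel lies
#'     on the s-scaled fitted ellipsoid surface (s = 1 on the fitted
#'     surface).}
#' }
#' On a sphere the two are equivalent up to discretization; on flattened
#' nuclei they genuinely differ (see the package vignette).
#'
#' @param mask a \code{nucleus_mask}.
#' @param mode \code{"edt"} (default) or \code{"ellipsoid"}.
#' @param fit optional precomputed [fit_ellipsoid()] result.
#' @return numeric vector parallel to \code{mask$idx}.
#' @export
radial_coordinate <- function(mask, mode = c("edt", "ellipsoid"), fit = NULL) {
  stopifnot(inherits(mask, "nucleus_mask"))
  mode <- match.arg(mode)
  if (mode == "edt") {
    arr <- logical(prod(mask$dim)); arr[mask$idx] <- TRUE
    dsq <- .edt_sq_3d(arr, mask$dim, mask$spacing)
    d <- sqrt(dsq[mask$idx])
    1 - d / max(d)
  } else {
    if (is.null(fit)) fit <- fit_ellipsoid(mask)
    b <- sweep(voxel_coords_um(mask), 2, fit$center) %*% fit$axes
    sqrt(rowSums(sweep(b, 2, fit$semi_axes, `/`)^2))
  }
}

#' Partition a nucleus into K co-centric shells of equal volume
#'
#' Shell boundaries are empirical volume quantiles of the radial coordinate
#' at cumulative fractions k/K: mask voxels are ranked by radial coordinate
#' (ties broken deterministically in raster order) and split into K
#' consecutive blocks of as-equal-as-possible size, so every shell volume
#' is within one voxel of total/K. Shell 1 is the innermost.
#'
#' @param mask a \code{nucleus_mask}.
#' @param K number of shells (default 5).
#' @param mode radial metric, see [radial_coordinate()].
#' @param fit optional precomputed ellipsoid fit (ellipsoid mode).
#' @return object of class \code{shell_partition}: per-voxel shell index
#'   (parallel to \code{mask$idx}), boundaries, shell volumes, mode.
#' @export
equal_volume_shells <- function(mask, K = 5L, mode = c("edt", "ellipsoid"),
                                fit = NULL) {
  stopifnot(inherits(mask, "nucleus_mask"), K >= 1)
  mode <- match.arg(mode)
  n <- length(mask$idx)
  if (n < K) stop("mask has fewer voxels (", n, ") than shells (", K, ")")
  if (mode == "ellipsoid" && is.null(fit)) fit <- fit_ellipsoid(mask)
  r <- radial_coordinate(mask, mode, fit = fit)
  ord <- order(r)                      # stable; ties fall in raster order
  sizes <- diff(floor(n * (0:K) / K))
  shell <- integer(n)
  shell[ord] <- rep.int(seq_len(K), sizes)
  bnd <- if (K > 1) r[ord][cumsum(sizes)[seq_len(K - 1)]] else numeric()
  structure(list(K = as.integer(K), shell = shell, boundaries = bnd,
                 shell_volumes = sizes * prod(mask$spacing),
                 mode = mode, mask = mask, radial = r, fit = fit),
            class = "shell_partition")
}

#' @export
print.shell_partition <- function(x, ...) {
  cat("shell_partition: K =", x$K, "(", x$mode, "mode ), shell volumes",
      paste(sprintf("%.1f", x$shell_volumes), collapse = "/"), "um3\n")
  invisible(x)
}

# Shell index of a physical point (um, zyx) within a partition. The point
# must fall in a mask voxel (or be snappable to one within 1 voxel; else
# NA). In edt mode the shell is that of the containing voxel -- the radial
# field only exists on the grid. In ellipsoid mode the radial coordinate
# has a closed form at any point, so it is evaluated at the sub-voxel
# centroid and cut at the partition boundaries; this avoids the net
# drift toward sparse shells that containing-voxel blur induces on coarse
# z-grids (dense shells leak into sparse neighbours under symmetric blur).
point_shell <- function(partition, p) {
  mask <- partition$mask
  inside <- FALSE
  vox_shell <- NA_integer_
  ijk <- pmin(pmax(round(p / mask$spacing) + 1, 1), mask$dim)
  lin <- ijk[1] + mask$dim[1] * ((ijk[2] - 1) + mask$dim[2] * (ijk[3] - 1))
  j <- match(lin, mask$idx)
  if (!is.na(j)) {
    inside <- TRUE
    vox_shell <- partition$shell[j]
  } else {
    bestd <- Inf
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      q <- ijk + c(dz, dy, dx)
      if (any(q < 1) || any(q > mask$dim)) next
      lin <- q[1] + mask$dim[1] * ((q[2] - 1) + mask$dim[2] * (q[3] - 1))
      j <- match(lin, mask$idx)
      if (is.na(j)) next
      dd <- sum(((q - 1) * mask$spacing - p)^2)
      if (dd < bestd) {
        bestd <- dd
        inside <- TRUE
        vox_shell <- partition$shell[j]
      }
    }
  }
  if (!inside) return(NA_integer_)
  if (partition$mode == "ellipsoid" && !is.null(partition$fit)) {
    fit <- partition$fit
    s <- sqrt(sum((as.numeric((p - fit$center) %*% fit$axes) /
                     fit$semi_axes)^2))
    return(1L + findInterval(s, partition$boundaries, left.open = TRUE))
  }
  vox_shell
}

#' Build per-probe, per-condition shell distributions from assigned spots
#'
#' Each spot's shell is the shell index of the voxel containing its
#' centroid in its nucleus's partition (sub-voxel centroids just outside
#' the mask are snapped to the nearest mask voxel within one voxel;
#' unsnappable spots are discarded and counted). Counts are aggregated over
#' nuclei by probe and condition.
#'
#' @param spots data.frame with columns nucleus_label (or nucleus), z_um,
#'   y_um, x_um, probe, condition.
#' @param partitions named list of \code{shell_partition}, names matching
#'   \code{nucleus_label}.
#' @return a \code{shell_distribution} data.frame (probe, condition,
#'   shell1..shellK counts, n) with attributes \code{assignments} (per-spot
#'   audit trail) and \code{discarded}.
#' @export
assign_spots <- function(spots, partitions) {
  lab <- spots$nucleus_label %||% spots$nucleus
  stopifnot(!is.null(lab))
  K <- partitions[[1]]$K
  shell <- integer(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    part <- partitions[[as.character(lab[i])]]
    if (is.null(part)) stop("no shell partition for nucleus ", lab[i])
    shell[i] <- point_shell(part,
                            as.numeric(spots[i, c("z_um", "y_um", "x_um")]))
  }
  keep <- !is.na(shell)
  audit <- data.frame(nucleus = lab, probe = spots$probe,
                      condition = spots$condition, shell = shell)
  agg <- audit[keep, ]
  cells <- unique(agg[c("probe", "condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- agg$shell[agg$probe == cells$probe[i] &
                       agg$condition == cells$condition[i]]
    shell_distribution(cells$probe[i], cells$condition[i],
                       tabulate(sub, K))
  })
  res <- do.call(rbind, rows)
  attr(res, "assignments") <- audit
  attr(res, "discarded") <- sum(!keep)
  res
}

#' Construct a shell-distribution record
#'
#' @param probe probe label (e.g. "HSA1").
#' @param condition condition label (e.g. "Mb24h").
#' @param counts K non-negative integer counts, innermost shell first.
#' @return one-row data.frame of class \code{shell_distribution} with
#'   columns probe, condition, shell1..shellK and n.
#' @export
shell_distribution <- function(probe, condition, counts) {
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  K <- length(counts)
  df <- data.frame(probe = probe, condition = condition,
                   t(setNames(as.integer(counts), paste0("shell", seq_len(K)))),
                   n = as.integer(sum(counts)))
  class(df) <- c("shell_distribution", "data.frame")
  df
}

#' Counts and percentages of a shell-distribution table
#' @param x a \code{shell_distribution} data.frame.
#' @return matrix of counts (rows = probe/condition) or percentages
#'   (2-decimal convention).
#' @export
shell_counts <- function(x) {
  cols <- grep("^shell[0-9]+$", names(x), value = TRUE)
  m <- as.matrix(as.data.frame(x)[cols])
  rownames(m) <- paste(x$probe, x$condition, sep = "/")
  m
}

#' @rdname shell_counts
#' @export
shell_percentages <- function(x) {
  m <- shell_counts(x)
  round2(100 * m / rowSums(m))
}

#' Per-nucleus morphometry: volume and flattening
#'
#' One record per non-flagged mask (flagged masks -- suspected touching or
#' ragged components -- are excluded from morphometry).
#'
#' @param masks list of \code{nucleus_mask}.
#' @return data.frame with nucleus, condition, volume_um3, flattening.
#' @export
morphometry_table <- function(masks) {
  masks <- Filter(function(m) !isTRUE(m$flagged), masks)
  if (!length(masks))
    return(data.frame(nucleus = integer(), condition = character(),
                      volume_um3 = numeric(), flattening = numeric()))
  do.call(rbind, lapply(masks, function(m) {
    f <- fit_ellipsoid(m)
    data.frame(nucleus = m$label, condition = m$condition,
               volume_um3 = f$volume, flattening = f$flattening)
  }))
}
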