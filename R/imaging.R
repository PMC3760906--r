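#' Multi-channel 3D image stack
#'
#' @param channels named list of 3-D numeric arrays, all with identical
#'   \code{dim = c(nz, ny, nx)}.
#' @param spacing voxel size in um, order (z, y, x); strictly positive.
#' @return object of class \code{image_stack}.
#' @export
image_stack <- function(channels, spacing) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))),
            length(spacing) == 3, all(spacing > 0))
  d <- dim(channels[[1]])
  for (ch in channels) {
    if (!identical(dim(ch), d)) stop("all channels must share dimensions")
    if (!all(is.finite(ch))) stop("intensities must be finite")
    if (any(ch < 0)) stop("intensities must be non-negative")
  }
  structure(list(channels = channels, dim = d,
                 spacing = as.numeric(spacing)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat("image_stack ", paste(x$dim, collapse = " x "), " (z y x), spacing ",
      paste(x$spacing, collapse = "/"), " um, channels: ",
      paste(names(x$channels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

new_nucleus_mask <- function(label, idx, dim, spacing, condition = NA_character_,
                             flagged = FALSE) {
  stopifnot(length(idx) >= 1)
  structure(list(label = as.integer(label), idx = as.integer(idx),
                 dim = as.integer(dim), spacing = as.numeric(spacing),
                 condition = condition, flagged = flagged),
            class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat("nucleus_mask #", x$label, ": ", length(x$idx), " voxels (",
      sprintf("%.1f", mask_volume(x)), " um3)",
      if (isTRUE(x$flagged)) " [flagged]", "\n", sep = "")
  invisible(x)
}

#' Physical volume of a nucleus mask in cubic micrometres
#' @param mask a \code{nucleus_mask}.
#' @return voxel count times voxel volume.
#' @export
mask_volume <- function(mask) length(mask$idx) * prod(mask$spacing)

# (z, y, x) integer indices (1-based) of mask voxels
voxel_ijk <- function(mask) {
  i <- mask$idx - 1L
  nz <- mask$dim[1]; ny <- mask$dim[2]
  z <- i %% nz
  y <- (i %/% nz) %% ny
  x <- i %/% (nz * ny)
  cbind(z = z + 1L, y = y + 1L, x = x + 1L)
}

#' Physical coordinates (um) of the voxel centres of a mask
#' @param mask a \code{nucleus_mask}.
#' @return n x 3 matrix, columns (z, y, x) in micrometres.
#' @export
voxel_coords_um <- function(mask) {
  ijk <- voxel_ijk(mask)
  sweep(ijk - 1, 2, mask$spacing, `*`)
}

# Otsu threshold maximizing between-class variance on a 256-bin histogram
otsu_threshold <- function(x, nbins = 256L) {
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(p)
  mu <- cumsum(p * mids)
  mt <- mu[nbins]
  between <- (mt * w - mu)^2 / (w * (1 - w))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Segment nuclei from the counterstain channel of a 3D stack
#'
#' Gaussian pre-smoothing, a global Otsu threshold, per-z-slice hole
#' filling, 3-D 26-connected component labelling, and removal of components
#' smaller than \code{min_volume_um3}. Surviving masks are relabelled in
#' order of decreasing volume. Touching or grossly non-ellipsoidal
#' components (mask volume far from the fitted-ellipsoid volume) are kept
#' but flagged so morphometry can exclude them.
#'
#' @param stack an [image_stack()].
#' @param channel channel name (default \code{"dna"}).
#' @param smooth_sigma_um isotropic pre-smoothing SD in um.
#' @param min_volume_um3 minimum component volume retained.
#' @param condition optional condition label stamped on each mask.
#' @return list of \code{nucleus_mask} (possibly empty, with a warning).
#' @export
segment_nuclei <- function(stack, channel = "dna", smooth_sigma_um = 0.2,
                           min_volume_um3 = 50, condition = NA_character_) {
  stopifnot(inherits(stack, "image_stack"))
  if (!channel %in% names(stack$channels))
    stop("no channel named '", channel, "' in stack")
  img <- stack$channels[[channel]]
  sp <- stack$spacing
  if (max(img) <= 0) {
    warning("empty image: no nuclei segmented")
    return(list())
  }
  sm <- gaussian_blur_3d(img, rep(smooth_sigma_um, 3), sp)
  thr <- otsu_threshold(as.numeric(sm))
  fg <- sm > thr
  fg <- .fill_holes_slices(as.logical(fg), dim(img))
  lab <- .cc_label_3d26(fg, dim(img))
  if (max(lab) == 0L) {
    warning("no components above threshold")
    return(list())
  }
  sizes <- tabulate(lab[lab > 0L])
  voxvol <- prod(sp)
  keep <- which(sizes * voxvol >= min_volume_um3)
  if (!length(keep)) {
    warning("all components below min_volume_um3")
    return(list())
  }
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  masks <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    m <- new_nucleus_mask(label = i, idx = which(lab == keep[i]),
                          dim = dim(img), spacing = sp,
                          condition = condition)
    # flag components whose voxel volume is far from the volume of their
    # inertia-equivalent ellipsoid: merged or ragged objects
    fit <- try(fit_ellipsoid(m), silent = TRUE)
    if (inherits(fit, "try-error")) {
      m$flagged <- TRUE
    } else {
      ratio <- mask_volume(m) / (4 / 3 * pi * prod(fit$semi_axes))
      m$flagged <- ratio < 0.7 || ratio > 1.3
    }
    masks[[i]] <- m
  }
  masks
}

# separable Laplacian-of-Gaussian response, sign-flipped so bright blobs
# are maxima; sigma_um per axis
log_response <- function(img, sigma_um, spacing) {
  d <- dim(img)
  sv <- pmax(sigma_um / spacing, 0.5)
  g <- lapply(1:3, function(a) gauss1d_wrapped(d[a], sv[a]))
  g2 <- lapply(1:3, function(a) {
    dd <- pmin(0:(d[a] - 1), d[a] - (0:(d[a] - 1)))
    (dd^2 / sv[a]^4 - 1 / sv[a]^2) * g[[a]]
  })
  kern <- g2[[1]] %o% g[[2]] %o% g[[3]] +
    g[[1]] %o% g2[[2]] %o% g[[3]] +
    g[[1]] %o% g[[2]] %o% g2[[3]]
  -mean(sv)^2 *
    Re(stats::fft(stats::fft(img) * stats::fft(kern), inverse = TRUE)) /
    length(img)
}

#' Detect FISH spot signals in a probe channel
#'
#' Laplacian-of-Gaussian filtering matched to the expected spot radius,
#' 3-D local maxima above \code{mean + snr_k * sd} of the filtered in-mask
#' values, and sub-voxel centroid refinement by intensity-weighted mean of
#' the positive filter response in a 3x3x3 neighbourhood. Each spot is
#' assigned to the mask containing its centroid; spots outside every mask
#' are discarded and counted in the \code{"discarded"} attribute.
#'
#' @param stack an [image_stack()].
#' @param channel probe channel name (default \code{"fish"}).
#' @param masks list of \code{nucleus_mask} from [segment_nuclei()].
#' @param spot_radius_um expected physical spot radius (sets the LoG scale
#'   per axis; default 0.4 um).
#' @param snr_k threshold in SDs above the mean filtered in-mask value.
#' @param probe probe label stamped on the result.
#' @return data.frame of spots (nucleus_label, z_um, y_um, x_um,
#'   peak_intensity, probe) with attribute \code{discarded}.
#' @export
detect_spots <- function(stack, channel = "fish", masks,
                         spot_radius_um = 0.4, snr_k = 5,
                         probe = NA_character_) {
  stopifnot(inherits(stack, "image_stack"))
  if (!channel %in% names(stack$channels))
    stop("no channel named '", channel, "' in stack")
  img <- stack$channels[[channel]]
  sp <- stack$spacing
  resp <- log_response(img, rep(spot_radius_um / sqrt(3), 3), sp)
  inmask <- unlist(lapply(masks, `[[`, "idx"))
  empty <- data.frame(nucleus_label = integer(), z_um = numeric(),
                      y_um = numeric(), x_um = numeric(),
                      peak_intensity = numeric(), probe = character())
  if (!length(inmask)) {
    attr(empty, "discarded") <- 0L
    return(empty)
  }
  bg <- resp[inmask]
  thr <- mean(bg) + snr_k * sd(bg)
  hits <- .local_max_3d26(as.numeric(resp), dim(img), thr)
  if (!length(hits)) {
    attr(empty, "discarded") <- 0L
    return(empty)
  }
  d <- dim(img)
  labarr <- integer(prod(d))
  for (m in masks) labarr[m$idx] <- m$label
  out <- vector("list", length(hits))
  discarded <- 0L
  for (i in seq_along(hits)) {
    h <- hits[i] - 1L
    z <- h %% d[1] + 1L
    y <- (h %/% d[1]) %% d[2] + 1L
    x <- h %/% (d[1] * d[2]) + 1L
    zz <- max(1, z - 1):min(d[1], z + 1)
    yy <- max(1, y - 1):min(d[2], y + 1)
    xx <- max(1, x - 1):min(d[3], x + 1)
    w <- pmax(resp[zz, yy, xx, drop = FALSE], 0)
    if (sum(w) == 0) w[] <- 1
    cz <- sum(slice.index(w, 1) * w) / sum(w)
    cy <- sum(slice.index(w, 2) * w) / sum(w)
    cx <- sum(slice.index(w, 3) * w) / sum(w)
    ctr <- c(zz[1] + cz - 1, yy[1] + cy - 1, xx[1] + cx - 1)  # 1-based
    ijk <- pmin(pmax(round(ctr), 1), d)
    lab <- labarr[ijk[1] + d[1] * ((ijk[2] - 1) + d[2] * (ijk[3] - 1))]
    if (lab == 0L) { discarded <- discarded + 1L; next }
    out[[i]] <- data.frame(nucleus_label = lab,
                           z_um = (ctr[1] - 1) * sp[1],
                           y_um = (ctr[2] - 1) * sp[2],
                           x_um = (ctr[3] - 1) * sp[3],
                           peak_intensity = img[z, y, x],
                           probe = probe)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  attr(res, "discarded") <- discarded
  res
}
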