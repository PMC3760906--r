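#' Read a shell-distribution table (printed-table layout)
#'
#' Expects a TSV with columns \code{probe}, \code{condition} and
#' \code{shell1..shellK} holding either percentages (2-decimal convention,
#' each row summing to 100 +/- 0.05) or integer counts. Percentage rows
#' failing the sum check are rejected with the offending line number.
#'
#' @param path TSV file.
#' @param values \code{"auto"} (default: counts iff all integers and rows
#'   do not sum to 100), \code{"percent"} or \code{"count"}.
#' @return data.frame; count tables get class \code{shell_distribution}
#'   and an \code{n} column, percentage tables an attribute
#'   \code{values = "percent"}.
#' @export
read_table1 <- function(path, values = c("auto", "percent", "count")) {
  values <- match.arg(values)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("probe", "condition")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  shellcols <- grep("^shell[0-9]+$", names(df), value = TRUE)
  if (length(shellcols) < 2) stop("need at least 2 shell columns")
  m <- as.matrix(df[shellcols])
  if (!is.numeric(m) || any(is.na(m)))
    stop("malformed shell values at line ",
         which(rowSums(is.na(df[shellcols])) > 0)[1] + 1L)
  if (any(m < 0)) stop("negative shell values at line ",
                       which(rowSums(m < 0) > 0)[1] + 1L)
  if (values == "auto")
    values <- if (all(m == round(m)) &&
                  !all(abs(rowSums(m) - 100) <= 0.05)) "count" else "percent"
  if (values == "percent") {
    bad <- which(abs(rowSums(m) - 100) > 0.05)
    if (length(bad))
      stop("percentage row not summing to 100 +/- 0.05 at line ",
           bad[1] + 1L, " (sum = ", sprintf("%.2f", rowSums(m)[bad[1]]), ")")
    out <- df[c(need, shellcols)]
    attr(out, "values") <- "percent"
    out
  } else {
    out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i)
      shell_distribution(df$probe[i], df$condition[i], m[i, ])))
    attr(out, "values") <- "count"
    out
  }
}

#' Write a shell-distribution table as TSV
#'
#' Counts are written as-is; percentages are re-derived from the counts at
#' the 2-decimal convention into \code{pct1..pctK} columns.
#'
#' @param dist a \code{shell_distribution} data.frame (counts).
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
write_table1 <- function(dist, path) {
  cnt <- shell_counts(dist)
  pct <- shell_percentages(dist)
  colnames(pct) <- sub("^shell", "pct", colnames(cnt))
  out <- data.frame(probe = dist$probe, condition = dist$condition,
                    cnt, n = rowSums(cnt), pct, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Centromere shell-distribution percentages of the seven assayed probes
#'
#' The packaged two-condition (proliferating myoblasts at 24 h, fused
#' myocytes at 7 d) shell-percentage table for the centromeric probes of
#' chromosomes 1, 3, 7, 11, 12, 17 and X, in the printed-table layout.
#'
#' @return percentage data.frame as from [read_table1()].
#' @export
centromere_shell_table <- function() {
  read_table1(system.file("extdata", "centromere_shell_percentages.tsv",
                          package = "nucshell", mustWork = TRUE),
              values = "percent")
}

#' Write / read an image stack as multi-page TIFF with a metadata sidecar
#'
#' Pages are z-slices, channel-major (all slices of channel 1, then
#' channel 2, ...), stored as 32-bit float scaled to [0, 1]; the scale
#' factor, grid dimensions, channel names and voxel spacing go to a
#' \code{<path>.meta.tsv} sidecar so the round trip is lossless up to
#' float-32 precision. Reading refuses to guess missing spacing.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return \code{path} (write) or an \code{image_stack} (read).
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  scale <- max(1e-12, max(vapply(stack$channels, max, 1)))
  pages <- list()
  for (ch in stack$channels)
    for (z in seq_len(stack$dim[1]))
      pages[[length(pages) + 1L]] <- ch[z, , ] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- data.frame(key = c("nz", "ny", "nx", "spacing_z", "spacing_y",
                             "spacing_x", "scale", "channels"),
                     value = c(stack$dim, stack$spacing, scale,
                               paste(names(stack$channels), collapse = ",")))
  utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param spacing voxel spacing (z, y, x) um; required if no sidecar.
#' @export
read_stack_tiff <- function(path, spacing = NULL) {
  metafile <- paste0(path, ".meta.tsv")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (file.exists(metafile)) {
    meta <- utils::read.delim(metafile, stringsAsFactors = FALSE)
    val <- setNames(meta$value, meta$key)
    dims <- as.integer(val[c("nz", "ny", "nx")])
    spacing <- as.numeric(val[c("spacing_z", "spacing_y", "spacing_x")])
    scale <- as.numeric(val["scale"])
    chn <- strsplit(val[["channels"]], ",")[[1]]
  } else {
    if (is.null(spacing))
      stop("no metadata sidecar and no spacing given; voxel spacing is ",
           "required and never silently defaulted")
    dims <- c(length(pages), dim(pages[[1]]))
    scale <- 1
    chn <- "ch1"
  }
  nz <- dims[1]
  channels <- setNames(vector("list", length(chn)), chn)
  for (ci in seq_along(chn)) {
    a <- array(0, dims)
    for (z in seq_len(nz)) a[z, , ] <- pages[[(ci - 1) * nz + z]]
    channels[[ci]] <- a * scale
  }
  image_stack(channels, spacing)
}

#' Export nucleus masks (or a shell partition) as a 16-bit label TIFF
#'
#' Voxel values are integer labels (nucleus id, or shell index for a
#' partition) divided by 65535, one z-slice per page, for visual audit.
#'
#' @param x list of \code{nucleus_mask}, or a \code{shell_partition}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_label_tiff <- function(x, path) {
  if (inherits(x, "shell_partition")) {
    d <- x$mask$dim
    lab <- integer(prod(d))
    lab[x$mask$idx] <- x$shell
  } else {
    d <- x[[1]]$dim
    lab <- integer(prod(d))
    for (m in x) lab[m$idx] <- m$label
  }
  arr <- array(lab / 65535, d)
  pages <- lapply(seq_len(d[1]), function(z) arr[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write / read detected spots as TSV
#' @param spots spot data.frame from [detect_spots()].
#' @param path TSV path.
#' @return \code{path} (write) or the spot data.frame (read).
#' @export
write_spots_tsv <- function(spots, path) {
  utils::write.table(spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_spots_tsv
#' @export
read_spots_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
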