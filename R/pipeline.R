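pipeline_keys <- c("schema_version", "seed", "K", "mode", "out_dir",
                   "simulation", "segmentation", "detection", "stats",
                   "table1")

#' Structured configuration for a full pipeline run
#'
#' One key-value document holding every stage parameter. Unknown keys are
#' rejected; every parameter is echoed into the run manifest. When
#' \code{table1} (a path to a printed-layout percentage TSV) is set, the
#' pipeline runs in compare-only mode: counts are reconstructed from the
#' percentages and the statistical comparison is run directly.
#'
#' @param seed master seed for all randomness (stages derive substreams).
#' @param K number of shells.
#' @param mode radial metric for the shell partition
#'   (\code{"edt"} default, or \code{"ellipsoid"}).
#' @param simulation named list of [simulation_config()] arguments
#'   (ignored in compare-only mode).
#' @param segmentation named list: smooth_sigma_um, min_volume_um3.
#' @param detection named list: spot_radius_um, snr_k.
#' @param stats named list: adjust (BH across probes, default FALSE).
#' @param table1 optional path enabling compare-only mode.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, K = 5L, mode = "edt",
                            simulation = list(), segmentation = list(),
                            detection = list(), stats = list(),
                            table1 = NULL) {
  cfg <- list(schema_version = 1L, seed = as.integer(seed),
              K = as.integer(K), mode = mode,
              simulation = simulation,
              segmentation = modifyList(list(smooth_sigma_um = 0.2,
                                             min_volume_um3 = 50),
                                        segmentation),
              detection = modifyList(list(spot_radius_um = 0.4, snr_k = 5),
                                     detection),
              stats = modifyList(list(adjust = FALSE), stats),
              table1 = table1)
  stopifnot(mode %in% c("edt", "ellipsoid"), cfg$K >= 1)
  extra <- setdiff(names(cfg), pipeline_keys)
  if (length(extra)) stop("unknown config key(s): ",
                          paste(extra, collapse = ", "))
  for (nm in c("segmentation", "detection", "stats")) {
    known <- names(formals(pipeline_config))
    bad <- setdiff(names(cfg[[nm]]),
                   switch(nm,
                          segmentation = c("smooth_sigma_um", "min_volume_um3"),
                          detection = c("spot_radius_um", "snr_k"),
                          stats = c("adjust")))
    if (length(bad)) stop("unknown ", nm, " key(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)), f)
  unname(tools::md5sum(f))
}

write_atomic_json <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full shell-positioning pipeline
#'
#' In simulation mode the stages are: simulate (nuclei, spots, rendered
#' stacks) -> segment -> morphometry -> shell partition -> spot detection
#' -> shell assignment -> between-condition comparison (chi-square per
#' probe, Mann-Whitney on volume and flattening). In compare-only mode
#' (config \code{table1} set) counts are reconstructed from a printed
#' percentage table and only the chi-square layer runs. Every output table
#' is written to \code{out_dir} tagged with the config hash, and a run
#' manifest (JSON, written atomically) records parameters and per-stage
#' counts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return list with the stage outputs (distributions, comparison,
#'   morphometry, morph_tests) and \code{manifest}.
#' @export
run_pipeline <- function(config, out_dir = tempfile("nucshell_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  tag <- function(df) { attr(df, "config_hash") <- hash; df }

  if (!is.null(config$table1)) {
    pct <- read_table1(config$table1, values = "percent")
    shellcols <- grep("^shell[0-9]+$", names(pct), value = TRUE)
    dist <- do.call(rbind, lapply(seq_len(nrow(pct)), function(i) {
      rec <- reconstruct_counts(as.numeric(pct[i, shellcols]))
      if (!rec$exact)
        warning("no exact count reconstruction for ", pct$probe[i], " / ",
                pct$condition[i])
      shell_distribution(pct$probe[i], pct$condition[i], rec$counts)
    }))
    comparison <- compare_shell_distributions(dist,
                                              adjust = config$stats$adjust)
    write_table1(dist, file.path(out_dir, "distributions.tsv"))
    utils::write.table(cbind(comparison, config_hash = hash),
                       file.path(out_dir, "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(tool = "nucshell",
                     version = as.character(utils::packageVersion("nucshell")),
                     config_hash = hash, config = unclass(config),
                     input_hashes =
                       as.list(tools::md5sum(config$table1)),
                     started = t0,
                     finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     counts = list(distribution_rows = nrow(dist),
                                   probes_compared = nrow(comparison)))
    write_atomic_json(manifest, file.path(out_dir, "manifest.json"))
    return(invisible(list(distributions = tag(dist),
                          comparison = tag(comparison),
                          manifest = manifest, out_dir = out_dir)))
  }

  simargs <- modifyList(config$simulation, list(seed = config$seed))
  sim <- do.call(simulation_config, simargs)
  exp <- simulate_fish_experiment(sim)

  masks <- list()
  audit <- list()
  counts_acc <- list()
  n_detected <- 0L; n_discarded <- 0L; n_unsegmented <- 0L
  for (f in exp$fields) {
    segs <- withCallingHandlers(
      segment_nuclei(f$stack, "dna",
                     smooth_sigma_um = config$segmentation$smooth_sigma_um,
                     min_volume_um3 = config$segmentation$min_volume_um3,
                     condition = f$condition),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!length(segs)) { n_unsegmented <- n_unsegmented + 1L; next }
    m <- segs[[1]]        # one nucleus per simulated field
    m$label <- f$id
    masks[[length(masks) + 1L]] <- m
    part <- equal_volume_shells(m, K = config$K, mode = config$mode)
    spots <- detect_spots(f$stack, "fish", list(m),
                          spot_radius_um = config$detection$spot_radius_um,
                          snr_k = config$detection$snr_k, probe = f$probe)
    n_detected <- n_detected + nrow(spots)
    n_discarded <- n_discarded + attr(spots, "discarded")
    if (!nrow(spots)) next
    spots$nucleus_label <- f$id
    spots$condition <- f$condition
    d <- assign_spots(spots, setNames(list(part), f$id))
    n_discarded <- n_discarded + attr(d, "discarded")
    audit[[length(audit) + 1L]] <- attr(d, "assignments")
    key <- paste(f$probe, f$condition, sep = "\r")
    counts_acc[[key]] <- (counts_acc[[key]] %||% numeric(config$K)) +
      shell_counts(d)[1, ]
  }
  dist <- do.call(rbind, lapply(names(counts_acc), function(k) {
    pc <- strsplit(k, "\r", fixed = TRUE)[[1]]
    shell_distribution(pc[1], pc[2], counts_acc[[k]])
  }))
  comparison <- compare_shell_distributions(dist,
                                            adjust = config$stats$adjust)
  morph <- morphometry_table(masks)
  conds <- names(sim$condition_scale)
  morph_tests <- do.call(rbind, lapply(c("volume_um3", "flattening"),
    function(v) {
      x <- morph[[v]][morph$condition == conds[1]]
      y <- morph[[v]][morph$condition == conds[2]]
      r <- mann_whitney_u(x, y)
      data.frame(variable = v, U = r$U, n1 = r$n1, n2 = r$n2,
                 p_value = r$p_value)
    }))

  write_table1(dist, file.path(out_dir, "distributions.tsv"))
  for (nm in c("comparison", "morph_tests"))
    utils::write.table(cbind(get(nm), config_hash = hash),
                       file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(morph, config_hash = hash),
                     file.path(out_dir, "morphometry.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, audit),
                     file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(tool = "nucshell",
                   version = as.character(utils::packageVersion("nucshell")),
                   config_hash = hash, config = unclass(config),
                   started = t0,
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   counts = list(fields = length(exp$fields),
                                 nuclei_segmented = length(masks),
                                 fields_unsegmented = n_unsegmented,
                                 spots_true = nrow(exp$spots),
                                 spots_detected = n_detected,
                                 spots_discarded = n_discarded,
                                 spots_assigned = sum(shell_counts(dist))))
  write_atomic_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(distributions = tag(dist), comparison = tag(comparison),
                 morphometry = tag(morph), morph_tests = tag(morph_tests),
                 simulation = exp, manifest = manifest, out_dir = out_dir))
}
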