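# Small reusable synthetic objects. Everything is generated in code; the
# memo environment avoids recomputing shared fixtures across test files.

fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fx[[key]])) fx[[key]] <- force(expr)
  fx[[key]]
}

noiseless <- list(photon = FALSE, background = 0, read_sd = 0)

sphere_config <- function(r = 5, spacing = c(0.5, 0.2, 0.2), cv = 0,
                          psf = c(0, 0, 0), noise = noiseless, ...) {
  simulation_config(seed = 1, voxel_spacing = spacing,
                    semi_axes_mean = rep(r, 3), semi_axes_cv = cv,
                    condition_scale = list(A = c(1, 1, 1)),
                    psf_sigma = psf, noise_model = noise, ...)
}

make_sphere <- function(r = 5, spacing = c(0.5, 0.2, 0.2), seed = 1)
  simulate_nucleus(sphere_config(r = r, spacing = spacing), "A", seed = seed)

# default-noise two-condition config at the generator's study conditions
default_config <- function(seed = 1, n = 4, probs = list(p = rep(0.2, 5)))
  simulation_config(seed = seed, n_nuclei_per_condition = n,
                    shell_probs = probs)

# Table 1 percentage rows, via the packaged file (percent layout)
table1_rows <- function() {
  t1 <- centromere_shell_table()
  shellcols <- grep("^shell", names(t1))
  split(setNames(lapply(seq_len(nrow(t1)), function(i)
    as.numeric(t1[i, shellcols])),
    paste(t1$probe, t1$condition, sep = "/")), NULL)[[1]]
}

# independent textbook Pearson chi-square on a 2 x K table of counts
pearson_chisq_oracle <- function(a, b) {
  tab <- rbind(a, b)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# independent brute-force BH step-up: q_(i) = min_{j >= i} m * p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m))
    q[o[i]] <- min(1, min(m * p[o][i:m] / (i:m)))
  q
}
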