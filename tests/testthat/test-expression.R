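test_that("quantile normalization: fixed point, worked case, idempotence", {
  m <- matrix(rep(c(2, 5, 9), 4), nrow = 3)
  expect_equal(quantile_normalize(m), m)  # identical columns unchanged
  w <- cbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  expect_equal(unname(quantile_normalize(w)),
               cbind(c(4, 5, 6), c(4, 5, 6), c(4, 5, 6)))
  set.seed(11)
  r <- matrix(rnorm(600), 100, 6)
  q1 <- quantile_normalize(r)
  srt <- apply(q1, 2, sort)
  expect_lt(max(abs(srt - srt[, 1])), 1e-12)  # identical sorted columns
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
})

test_that("BH adjustment matches a brute-force step-up on small vectors", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(21)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("null expression data yields (almost) no discoveries", {
  hits <- vapply(1:5, function(seed) {
    sim <- simulate_expression(2000, 3, spike_fraction = 0, seed = seed)
    de <- differential_expression(sim$matrix, sim$groups)
    sum(de$direction != "ns")
  }, 1L)
  expect_lte(mean(hits) / 2000, 0.01)  # FDR-controlled at alpha
})

test_that("spiked genes at 8-fold are recovered with high power", {
  pw <- vapply(1:3, function(seed) {
    sim <- simulate_expression(2000, 3, spike_fraction = 0.1,
                               effect_log2fc = 3, noise_sd = 0.25,
                               seed = seed)
    de <- differential_expression(sim$matrix, sim$groups)
    ok <- de$direction != "ns" &
      sign(de$log2_fc) == sign(sim$truth$true_lfc)
    mean(ok[sim$truth$spiked])
  }, 1)
  expect_gte(mean(pw), 0.9)
})

test_that("classification is exclusive, exhaustive and obeys the thresholds", {
  set.seed(42)
  sim <- simulate_expression(500, 3, 0.1, 2, seed = 42)
  de <- differential_expression(sim$matrix, sim$groups,
                                fc_threshold = 1, alpha = 0.01)
  expect_true(all(de$direction %in% c("up", "down", "ns")))
  expect_identical(de$direction == "up", de$log2_fc >= 1 & de$q < 0.01)
  expect_identical(de$direction == "down", de$log2_fc <= -1 & de$q < 0.01)
  # BH monotonicity: q non-decreasing in raw-p rank order
  o <- order(de$p)
  expect_true(all(diff(de$q[o]) >= -1e-15))
})

test_that("zero-variance genes fall back to a mean-comparison verdict", {
  m <- rbind(c(1, 1, 1, 5, 5, 5), c(2, 2, 2, 2, 2, 2))
  rownames(m) <- c("gshift", "gflat")
  expect_message(de <- differential_expression(m, rep(c("A", "B"), each = 3)),
                 "zero variance")
  expect_equal(de$p[de$gene == "gshift"], 0)
  expect_equal(de$p[de$gene == "gflat"], 1)
})

test_that("welch flavour remains available and differs from pooled", {
  set.seed(9)
  sim <- simulate_expression(300, 4, 0.1, 2, noise_sd = 0.5, seed = 9)
  dw <- differential_expression(sim$matrix, sim$groups, pooled = FALSE)
  dp <- differential_expression(sim$matrix, sim$groups, pooled = TRUE)
  expect_false(isTRUE(all.equal(dw$p, dp$p)))
  expect_equal(dw$log2_fc, dp$log2_fc)
})

test_that("chromosome mapping tallies match construction and logs unmapped", {
  rec <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    log2_fc = c(2, 1.5, -2, -1.2, 0),
                    p = 1e-5, q = 1e-5,
                    direction = c("up", "up", "down", "down", "ns"))
  class(rec) <- c("de_table", "data.frame")
  pos <- data.frame(gene = c("a", "b", "c"),
                    chromosome = c("HSA1", "HSA7", "HSA1"))
  mp <- map_to_chromosomes(rec, pos)
  expect_equal(mp$unmapped, 1)  # "d" is differential but unplaced
  tal <- mp$tally[order(mp$tally$chromosome), ]
  expect_equal(tal$chromosome, c("HSA1", "HSA7"))
  expect_equal(tal$up, c(1, 1))
  expect_equal(tal$down, c(1, 0))
  expect_error(map_to_chromosomes(rec, rbind(pos, pos[1, ])), "unique")
})

test_that("packaged annotation fixture is self-consistent through the mapper", {
  fx <- read.delim(system.file("extdata", "synthetic_de_annotation.tsv",
                               package = "nucshell"),
                   stringsAsFactors = FALSE)
  rec <- data.frame(gene = fx$gene,
                    log2_fc = ifelse(fx$direction == "up", 2, -2),
                    p = 1e-6, q = 1e-6, direction = fx$direction)
  class(rec) <- c("de_table", "data.frame")
  mp <- map_to_chromosomes(rec, fx[c("gene", "chromosome", "cytoband")])
  expect_equal(mp$unmapped, 0)
  own <- table(fx$chromosome, fx$direction)
  for (i in seq_len(nrow(mp$tally))) {
    ch <- mp$tally$chromosome[i]
    expect_equal(mp$tally$up[i], unname(own[ch, "up"]))
    expect_equal(mp$tally$down[i], unname(own[ch, "down"]))
  }
})
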