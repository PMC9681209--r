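test_that("kernel smoothing matches the weighted-mean definition", {
  # a single probe keeps its raw value
  expect_equal(smooth_delta(100, 0.37), 0.37)

  # a constant vector is a fixed point of any weighted mean
  pos <- c(0, 120, 400, 950, 2100)
  expect_equal(smooth_delta(pos, rep(0.25, 5)), rep(0.25, 5))

  # hand-checkable 3-probe case against the longhand kernel oracle
  pos3 <- c(0, 100, 200)
  d3 <- c(0.4, 0.4, -0.4)
  sm <- smooth_delta(pos3, d3, lambda = 1000, C = 2)
  for (i in 1:3) {
    expect_equal(sm[i], kernel_smooth_oracle(pos3, d3, i, 1000, 2),
                 tolerance = 1e-12)
  }

  # oracle equivalence on an irregular layout, including probes beyond
  # the bandwidth cutoff
  set.seed(5)
  posn <- sort(sample(0:5000, 25))
  dn <- rnorm(25, sd = 0.2)
  smn <- smooth_delta(posn, dn)
  for (i in seq_along(posn)) {
    expect_equal(smn[i], kernel_smooth_oracle(posn, dn, i, 1000, 2),
                 tolerance = 1e-12)
  }

  expect_error(smooth_delta(c(200, 100), c(0, 0)), "sorted")
  expect_error(smooth_delta(c(1, 2), 0.1), "same length")
})

test_that("DMR calling applies the probe, cutoff, gap and size rules", {
  # 6 probes 100 bp apart, delta -0.4: exactly one hypo DMR of 6 probes
  p <- make_flat_pair(seq(0, 500, by = 100), beta_t = 0.3, beta_c = 0.7)
  d <- call_dmrs(p$manifest, p$tumour, p$control)
  expect_equal(nrow(d), 1L)
  expect_equal(d$direction, "hypo")
  expect_equal(d$n_probes, 6L)
  expect_equal(d$start, 0L)
  expect_equal(d$end, 501L)
  expect_equal(d$mean_delta_beta, -0.4, tolerance = 1e-12)

  # the same cluster with only 5 probes falls below the minimum
  p5 <- make_flat_pair(seq(0, 400, by = 100), 0.3, 0.7)
  expect_equal(nrow(call_dmrs(p5$manifest, p5$tumour, p5$control)), 0L)

  # two qualifying clusters 5000 bp apart stay separate (gap > lambda)
  pos2 <- c(seq(0, 500, by = 100), seq(5500, 6000, by = 100))
  p2 <- make_flat_pair(pos2, 0.3, 0.7)
  d2 <- call_dmrs(p2$manifest, p2$tumour, p2$control)
  expect_equal(nrow(d2), 2L)
  expect_equal(d2$start, c(0L, 5500L))

  # empty input yields an empty table, not an error
  e <- call_dmrs(p$manifest,
                 p$tumour[integer(0), , drop = FALSE],
                 p$control[integer(0), , drop = FALSE])
  expect_equal(nrow(e), 0L)
})

test_that("swapping tumour and control flips direction, keeps coordinates", {
  co <- gen_methyl_cohort(300, 1, 12, 0.5, seed = 21)
  pr <- co$pairs[[1]]
  fwd <- call_dmrs(co$manifest, pr$tumour, pr$control)
  rev <- call_dmrs(co$manifest, pr$control, pr$tumour)
  expect_gt(nrow(fwd), 0L)
  expect_equal(fwd[c("chrom", "start", "end", "n_probes")],
               rev[c("chrom", "start", "end", "n_probes")])
  expect_equal(fwd$mean_delta_beta, -rev$mean_delta_beta)
  expect_true(all(fwd$direction != rev$direction))
})

test_that("every probe inside an emitted DMR passes the smoothed cutoff", {
  params <- dmr_params()
  for (seed in 1:3) {
    co <- gen_methyl_cohort(400, 1, 15, 0.6, seed = seed)
    pr <- co$pairs[[1]]
    d <- call_dmrs(co$manifest, pr$tumour, pr$control, params)
    delta <- rowMeans(pr$tumour) - rowMeans(pr$control)
    sm <- smooth_delta(co$manifest$pos, delta[co$manifest$probe_id],
                       params$lambda, params$C)
    for (r in seq_len(nrow(d))) {
      inside <- co$manifest$pos >= d$start[r] & co$manifest$pos < d$end[r]
      expect_true(all(abs(sm[inside]) >= params$beta_cutoff))
    }
  }
})

test_that("planted regions are recovered from noisy synthetic cohorts", {
  for (seed in 1:3) {
    co <- gen_methyl_cohort(620, 1, 40, 0.5, delta_beta_magnitude = 0.4,
                            noise_sd = 0.05, seed = seed)
    pr <- co$pairs[[1]]
    rec <- dmr_recovery(call_dmrs(co$manifest, pr$tumour, pr$control),
                        co$truth$regions)
    expect_gte(rec$precision, 0.95)
    expect_gte(rec$recall, 0.95)
  }
})

test_that("probe tallies report raw and smoothed calls by sign", {
  p <- make_flat_pair(seq(0, 500, by = 100), 0.3, 0.7)
  tal <- probe_call_tally(p$manifest, p$tumour, p$control)
  expect_equal(tal["raw", "n_hypo"], 6)
  expect_equal(tal["smoothed", "n_hypo"], 6)
  expect_equal(tal["raw", "n_hyper"], 0)
})

test_that("DMR BED export is half-open and round-trips", {
  co <- gen_methyl_cohort(300, 1, 10, 0.5, seed = 9)
  pr <- co$pairs[[1]]
  d <- call_dmrs(co$manifest, pr$tumour, pr$control)
  f <- withr::local_tempfile(fileext = ".bed")
  write_dmrs_bed(d, f)
  back <- read_dmrs_bed(f)
  expect_equal(back$chrom, d$chrom)
  expect_equal(back$start, d$start)
  expect_equal(back$end, d$end)
  expect_equal(back$direction, d$direction)
  # raw BED text uses the 0-based half-open start
  first <- strsplit(readLines(f, n = 1L), "\t")[[1]]
  expect_equal(as.integer(first[2]), d$start[1])
  expect_equal(as.integer(first[3]), d$end[1])

  # empty table -> empty file -> empty table
  write_dmrs_bed(d[0, ], f)
  expect_equal(nrow(read_dmrs_bed(f)), 0L)
})
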