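make_simple_reads <- function() {
  reads <- data.frame(
    read_id = c("r1", "r2", "r3"), contig = "chr1",
    ref_start = 0L, ref_end = 200L, strand = "+",
    stringsAsFactors = FALSE)
  calls <- data.frame(
    read_id = c("r1", "r2", "r3"), contig = "chr1", strand = "+",
    read_pos = 100L, ref_pos = 100L, base = "A", mod_code = "a",
    score = c(230L, 240L, 40L), stringsAsFactors = FALSE)
  mod_reads(reads, calls)
}

test_that("pileup counts calls and thresholds scores per position", {
  x <- make_simple_reads()
  p <- pileup(x, "chr1", 90L, 110L, "a", 225L)
  expect_equal(p$depth[p$pos == 100L], 3L)
  expect_equal(p$frac[p$pos == 100L], 2 / 3)
  expect_true(all(p$depth[p$pos != 100L] == 0L))
  # threshold 0: every called position fully methylated
  p0 <- pileup(x, "chr1", 90L, 110L, "a", 0L)
  expect_equal(p0$frac[p0$depth > 0], 1)
  expect_error(pileup(x, "chrX", 0L, 10L), "contig")
})

test_that("pileup equals the brute-force per-read oracle on a simulated fixture", {
  cfg <- tiny_sim_config(seed = 41L, coverage = 3)
  sim <- simulate_dataset(cfg, "target")
  reg <- c(4000L, 9000L)
  p <- pileup(sim$reads, "chrS", reg[1], reg[2], "a", 225L)
  o <- oracle_pileup(sim$reads, "chrS", reg[1], reg[2], "a", 225L)
  expect_identical(p$depth, o$depth)
  expect_identical(p$meth, o$meth)
})

test_that("site-centered aggregation orients offsets by site strand", {
  reads <- data.frame(read_id = "r1", contig = "chr1", ref_start = 500L,
                      ref_end = 2500L, strand = "+", stringsAsFactors = FALSE)
  calls <- data.frame(read_id = "r1", contig = "chr1", strand = "+",
                      read_pos = 600L, ref_pos = 1100L, base = "A",
                      mod_code = "a", score = 250L, stringsAsFactors = FALSE)
  x <- mod_reads(reads, calls)
  site_plus <- data.frame(contig = "chr1", start = 995L, end = 1005L,
                          strand = "+")
  prof <- aggregate_at_sites(x, site_plus, 300L, "a", 225L)
  expect_equal(prof$offset[which(prof$frac == 1)], 100L)
  site_minus <- site_plus; site_minus$strand <- "-"
  prof_m <- aggregate_at_sites(x, site_minus, 300L, "a", 225L)
  expect_equal(prof_m$offset[which(prof_m$frac == 1)], -100L)
})

test_that("aggregation conserves integer counts and respects strand-flip mirroring", {
  cfg <- tiny_sim_config(seed = 43L, coverage = 4)
  sim <- simulate_dataset(cfg, "target")
  prof <- aggregate_at_sites(sim$reads, sim$sites, 500L, "a", 225L)
  expect_equal(sum(prof$meth),
               sum(prof$depth * ifelse(is.na(prof$frac), 0, prof$frac)))
  flipped <- sim$sites
  flipped$strand <- ifelse(flipped$strand == "+", "-", "+")
  prof_f <- aggregate_at_sites(sim$reads, flipped, 500L, "a", 225L)
  expect_equal(prof_f$depth, rev(prof$depth))
  expect_equal(prof_f$meth, rev(prof$meth))
})

test_that("splitting sites in half and pooling counts reproduces the full profile", {
  cfg <- tiny_sim_config(seed = 44L, coverage = 4)
  sim <- simulate_dataset(cfg, "target")
  full <- aggregate_at_sites(sim$reads, sim$sites, 400L, "a", 225L)
  h1 <- aggregate_at_sites(sim$reads, sim$sites[1:2, ], 400L, "a", 225L)
  h2 <- aggregate_at_sites(sim$reads, sim$sites[3:5, ], 400L, "a", 225L)
  expect_equal(h1$depth + h2$depth, full$depth)
  expect_equal(h1$meth + h2$meth, full$meth)
  frac <- ifelse(full$depth > 0, (h1$meth + h2$meth) / (h1$depth + h2$depth),
                 NA_real_)
  expect_equal(frac, full$frac)
})

test_that("smoothing is an equal-weight box filter with truncated edges", {
  mk <- function(frac) fiberfoot:::new_aggregate_profile(
    offset = -100:100, meth = rep(0L, 201), depth = rep(10L, 201),
    n_sites = 1L, mod_code = "a", threshold_score = 225L, frac = frac)
  cst <- smooth_profile(mk(rep(0.4, 201)), 50L)
  expect_equal(cst$frac, rep(0.4, 201))
  imp <- smooth_profile(mk(c(rep(0, 100), 1, rep(0, 100))), 50L)
  expect_equal(imp$frac[abs(imp$offset) <= 25], rep(1 / 51, 51))
  expect_equal(imp$frac[abs(imp$offset) > 25], rep(0, 150))
  # interior mean preservation
  set.seed(3)
  f <- runif(201)
  sm <- smooth_profile(mk(f), 20L)
  expect_lt(abs(mean(sm$frac[11:191]) - mean(rowMeans(sapply(-10:10, function(s)
    f[11:191 + s])))), 1e-12)
  expect_identical(smooth_profile(mk(f), 0L)$frac, f)
})

test_that("control subtraction is plain positionwise difference", {
  mk <- function(frac) fiberfoot:::new_aggregate_profile(
    offset = -50:50, meth = rep(1L, 101), depth = rep(10L, 101),
    n_sites = 1L, mod_code = "a", threshold_score = 225L, frac = frac)
  t0 <- mk(rep(0.3, 101)); c0 <- mk(rep(0.1, 101))
  d <- subtract_control(t0, c0)
  expect_equal(d$frac, rep(0.2, 101))
  expect_equal(subtract_control(t0, t0)$frac, rep(0, 101))
  # negative values are retained
  expect_equal(subtract_control(c0, t0)$frac, rep(-0.2, 101))
  bad <- fiberfoot:::new_aggregate_profile(
    offset = -50:50, meth = rep(1L, 101), depth = rep(10L, 101),
    n_sites = 1L, mod_code = "m", threshold_score = 225L,
    frac = rep(0.1, 101))
  expect_error(subtract_control(t0, bad), "mod_code")
})

test_that("enrichment ratio divides central mean fractions", {
  mk <- function(meth) fiberfoot:::new_aggregate_profile(
    offset = -400:400, meth = meth, depth = rep(10L, 801),
    n_sites = 1L, mod_code = "a", threshold_score = 225L)
  t0 <- mk(rep(2L, 801)); c0 <- mk(rep(1L, 801))
  expect_equal(enrichment_ratio(t0, c0)$ratio, 2)
  expect_equal(enrichment_ratio(t0, t0)$ratio, 1)
  z <- enrichment_ratio(t0, mk(rep(0L, 801)))
  expect_true(is.infinite(z$ratio) && z$control_zero)
})

test_that("profile TSV round-trips values and metadata", {
  cfg <- tiny_sim_config(seed = 47L, coverage = 2)
  sim <- simulate_dataset(cfg, "target")
  prof <- aggregate_at_sites(sim$reads, sim$sites, 200L, "a", 225L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, path)
  back <- read_profile_tsv(path)
  expect_equal(back$frac, prof$frac)
  expect_equal(back$depth, prof$depth)
  expect_equal(attr(back, "threshold_score"), attr(prof, "threshold_score"))
})
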