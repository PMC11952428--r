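test_that("score-to-probability uses SAM bin midpoints and matches the printed confidences", {
  expect_equal(round(ml_to_prob(225L), 2), 0.88)
  expect_equal(round(ml_to_prob(250L), 2), 0.98)
  expect_equal(ml_to_prob(0L), 0.5 / 256)
  expect_equal(ml_to_prob(255L), 255.5 / 256)
  p <- ml_to_prob(0:255)
  expect_true(all(diff(p) > 0))
  expect_error(ml_to_prob(-1L), "0\\.\\.255")
  expect_error(ml_to_prob(256L), "0\\.\\.255")
  expect_error(ml_to_prob(2.5), "integer")
})

test_that("MM delta decoding projects calls onto the reference", {
  dec <- decode_read(toy_record())
  expect_equal(dec$calls$ref_pos, c(100L, 104L))
  expect_equal(dec$calls$score, c(230L, 40L))
  expect_equal(dec$strand, "+")
  expect_equal(dec$ref_start, 100L)
  expect_equal(dec$ref_end, 105L)

  # a 2-base deletion between the two adenines shifts the second call by +2
  del <- decode_read(toy_record(cigar = "3M2D2M"))
  expect_equal(del$calls$ref_pos, c(100L, 106L))

  # empty MM tag -> zero calls
  none <- decode_read(toy_record(mm = "", ml = integer(0)))
  expect_equal(nrow(none$calls), 0L)
})

test_that("malformed and unsupported tags are rejected or skipped", {
  expect_error(decode_read(toy_record(ml = c(230L))), "MM/ML length mismatch")
  expect_warning(
    dec <- decode_read(toy_record(mm = "A+a,0;C+h,0;", ml = c(230L, 10L),
                                  seq = "AACTA")),
    "unsupported modification channel")
  expect_equal(nrow(dec$calls), 1L)
  expect_error(decode_read(toy_record(mm = "A+a,0,5;", ml = c(1L, 2L))),
               "more A skips")
})

test_that("encode_read inverts decode_read and validates bases", {
  enc <- encode_read("AACTA", data.frame(read_pos = c(0L, 4L),
                                         mod_code = "a",
                                         score = c(230L, 40L)))
  expect_equal(enc$mm, "A+a,0,1;")
  expect_equal(enc$ml, c(230L, 40L))
  expect_equal(encode_read("AACTA", data.frame(read_pos = integer(0),
                                               mod_code = character(0),
                                               score = integer(0)))$mm, "")
  expect_error(encode_read("AACTA", data.frame(read_pos = 2L, mod_code = "a",
                                               score = 10L)),
               "non-A base")
})

test_that("encode/decode round-trips random fibers on both strands", {
  set.seed(101)
  for (i in 1:10) {
    rt <- roundtrip_fiber(reverse = i %% 2L == 0L)
    expect_equal(rt$got, rt$want)
  }
})

test_that("reverse-strand records project calls through the flipped orientation", {
  set.seed(202)
  aligned <- random_dna(1500L)          # forward-reference SEQ
  orig <- revcomp_str(aligned)          # original sequencing direction
  calls <- random_calls(orig)
  enc <- encode_read(orig, calls)
  dec <- decode_read(toy_record(seq = aligned, pos = 1001L, mm = enc$mm,
                                ml = enc$ml, flag = 16L))
  expect_equal(dec$strand, "-")
  # independent mapping: original-read offset i sits at ref_start + L - 1 - i
  got <- dec$calls[order(dec$calls$mod_code, dec$calls$read_pos),
                   c("read_pos", "ref_pos", "mod_code", "score")]
  want <- calls[order(calls$mod_code, calls$read_pos), ]
  expect_equal(got$read_pos, want$read_pos)
  expect_equal(got$score, want$score)
  expect_equal(got$ref_pos, 1000L + 1500L - 1L - want$read_pos)
  # the aligned span is identical to the forward interpretation
  expect_equal(c(dec$ref_start, dec$ref_end), c(1000L, 2500L))
})

test_that("binarization is a single cutoff and monotone in the threshold", {
  expect_equal(binarize(c(230L, 40L), 225L), c(TRUE, FALSE))
  expect_true(all(binarize(sample(0:255, 50), 0L)))
  set.seed(9)
  scores <- sample(0:255, 500, replace = TRUE)
  counts <- vapply(c(0L, 100L, 225L, 250L, 255L),
                   function(t) sum(binarize(scores, t)), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(binarize(scores, 300L), "0\\.\\.255")
})

test_that("SAM write/read round-trips a simulated dataset", {
  cfg <- tiny_sim_config(seed = 31L, coverage = 2)
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(cfg, "target", dir = dir)
  back <- read_modsam(sim$paths$sam)
  expect_equal(nrow(back$reads), nrow(sim$reads$reads))
  key <- function(cc) {
    k <- cc[order(cc$read_id, cc$mod_code, cc$ref_pos),
            c("read_id", "ref_pos", "mod_code", "score")]
    rownames(k) <- NULL
    k
  }
  expect_equal(key(back$calls), key(sim$reads$calls))
  # haplotype parsed from contig names
  expect_true(all(is.na(back$reads$haplotype)))
})
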