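# Shared fixtures and independent oracles, all built in code.

tiny_sim_config <- function(seed = 7L, coverage = 8, ...) {
  fiber_sim_config(seed = seed, genome_length = 60000L, n_sites = 5L,
                   site_spacing = 10000L, coverage = coverage,
                   frag_len_mean = 8000L, frag_len_sd = 800L, ...)
}

# one perfect-match SAM record as a plain list
toy_record <- function(seq = "AACTA", pos = 101L, cigar = NULL,
                       mm = "A+a,0,1;", ml = c(230L, 40L), flag = 0L,
                       rname = "chr1", qname = "r1") {
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  list(qname = qname, flag = flag, rname = rname, pos = pos, cigar = cigar,
       seq = seq, mm = mm, ml = ml)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# random original-orientation calls on a sequence (both channels)
random_calls <- function(seq, n_a = 30L, n_m = 10L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  a_pos <- which(chars == "A") - 1L
  cg <- which(chars[-length(chars)] == "C" & chars[-1L] == "G") - 1L
  a_pos <- sort(sample(a_pos, min(n_a, length(a_pos))))
  m_pos <- sort(sample(cg, min(n_m, length(cg))))
  data.frame(
    read_pos = c(a_pos, m_pos),
    mod_code = c(rep("a", length(a_pos)), rep("m", length(m_pos))),
    score = sample(0:255, length(a_pos) + length(m_pos), replace = TRUE),
    stringsAsFactors = FALSE)
}

# build a mod_reads object from explicit read/call rows
manual_mod_reads <- function(read_tbl, call_tbl) {
  mod_reads(read_tbl, call_tbl)
}

# nested-loop pileup oracle: count calls per position read by read
oracle_pileup <- function(x, contig, start, end, mod_code, threshold) {
  n <- end - start
  depth <- integer(n); meth <- integer(n)
  for (rid in unique(x$reads$read_id)) {
    cc <- x$calls[x$calls$read_id == rid, , drop = FALSE]
    for (i in seq_len(nrow(cc))) {
      if (cc$contig[i] != contig || cc$mod_code[i] != mod_code) next
      p <- cc$ref_pos[i]
      if (is.na(p) || p < start || p >= end) next
      j <- p - start + 1L
      depth[j] <- depth[j] + 1L
      if (cc$score[i] >= threshold) meth[j] <- meth[j] + 1L
    }
  }
  list(depth = depth, meth = meth)
}

# brute-force 3D median filter with reflection padding
oracle_median_3d <- function(vol, kernel = c(7L, 7L, 3L)) {
  d <- dim(vol); h <- (kernel - 1L) %/% 2L
  refl <- function(i, n) { if (i < 1L) 2L - i else if (i > n) 2L * n - i else i }
  out <- array(0, d)
  for (y in 1:d[1]) for (x in 1:d[2]) for (z in 1:d[3]) {
    vals <- numeric(0)
    for (dy in -h[1]:h[1]) for (dx in -h[2]:h[2]) for (dz in -h[3]:h[3])
      vals <- c(vals, vol[refl(y + dy, d[1]), refl(x + dx, d[2]),
                          refl(z + dz, d[3])])
    out[y, x, z] <- stats::median(vals)
  }
  out
}

# all-pairs containment classification oracle
oracle_classify <- function(sites, annotations) {
  cls <- annotations$class
  out <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    ctr <- (sites$start[i] + sites$end[i]) %/% 2L
    hit <- which(annotations$contig == sites$contig[i] &
                   annotations$start <= ctr & annotations$end > ctr)
    if (length(hit) == 0L) { out[i] <- "none"; next }
    w <- annotations$end[hit] - annotations$start[hit]
    hit <- hit[order(w, hit)]
    out[i] <- cls[hit[1L]]
  }
  out
}

# round-trip one fiber's calls through MM/ML tags and a SAM record
roundtrip_fiber <- function(seq_len_bp = 2000L, reverse = FALSE, ref_start = 500L) {
  seq <- random_dna(seq_len_bp)
  calls <- random_calls(seq)
  enc <- encode_read(seq, calls)
  rec <- toy_record(seq = if (reverse) revcomp_str(seq) else seq,
                    pos = ref_start + 1L, mm = enc$mm, ml = enc$ml,
                    flag = if (reverse) 16L else 0L)
  dec <- decode_read(rec)
  got <- dec$calls[order(dec$calls$mod_code, dec$calls$read_pos),
                   c("read_pos", "mod_code", "score")]
  want <- calls[order(calls$mod_code, calls$read_pos), ]
  rownames(got) <- rownames(want) <- NULL
  list(got = got, want = want, decoded = dec)
}

revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}
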