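# ---- score/probability scale -------------------------------------------------

#' Convert an 8-bit modification score to a probability
#'
#' Modified-base callers store per-call confidence as an integer 0-255 in the
#' ML auxiliary tag; score `s` denotes the probability bin
#' `[s/256, (s+1)/256)`. This function returns the bin midpoint
#' `(s + 0.5)/256`, so score 225 corresponds to 0.88 and score 250 to 0.98
#' (two decimals) -- the conventional thresholds for aggregate and
#' single-read analyses respectively.
#'
#' @param score integer vector, each element in 0..255.
#' @return numeric vector of probabilities in (0, 1).
#' @examples
#' ml_to_prob(c(225, 250))
#' @export
ml_to_prob <- function(score) {
  if (length(score) == 0L) return(numeric(0))
  if (!is.numeric(score) || any(is.na(score)) || any(score != floor(score)))
    stop("'score' must be integer-valued and non-missing")
  if (any(score < 0 | score > 255))
    stop("'score' must lie in 0..255")
  (score + 0.5) / 256
}

#' Binarize modification calls at a score threshold
#'
#' A call is labeled methylated iff its score is greater than or equal to the
#' threshold; all other called positions are unmethylated (they stay in
#' pileup denominators, keeping depth stable across thresholds).
#'
#' @param score integer vector of ML scores (0..255).
#' @param threshold_score single integer in 0..255.
#' @return logical vector, `TRUE` = methylated.
#' @export
binarize <- function(score, threshold_score) {
  if (length(threshold_score) != 1L || is.na(threshold_score) ||
      threshold_score < 0 || threshold_score > 255 ||
      threshold_score != floor(threshold_score))
    stop("'threshold_score' must be a single integer in 0..255")
  score >= threshold_score
}

# ---- small sequence helpers --------------------------------------------------

revcomp_chr <- function(x) {
  # reverse complement of a plain character DNA string
  vapply(x, function(s) {
    comp <- chartr("ACGTacgtN", "TGCAtgcaN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Map each SEQ offset (0-based) to a 0-based reference position via the CIGAR.
# Offsets consumed by S or I get NA; D/N advance the reference only.
cigar_ref_map <- function(cigar, ref_start) {
  ops  <- strsplit(gsub("[0-9]+", "", cigar), "", fixed = TRUE)[[1L]]
  lens <- as.integer(strsplit(gsub("[MIDNSHP=X]", " ", cigar), " +")[[1L]])
  lens <- lens[!is.na(lens)]
  if (length(ops) != length(lens)) stop("malformed CIGAR: ", cigar)
  out <- integer(0)
  rp <- ref_start
  for (i in seq_along(ops)) {
    op <- ops[i]; n <- lens[i]
    if (op %in% c("M", "=", "X")) {
      out <- c(out, seq.int(rp, length.out = n)); rp <- rp + n
    } else if (op %in% c("I", "S")) {
      out <- c(out, rep(NA_integer_, n))
    } else if (op %in% c("D", "N")) {
      rp <- rp + n
    } else if (op == "H" || op == "P") {
      # consumes neither SEQ nor reference
    } else stop("unsupported CIGAR op: ", op)
  }
  out
}

cigar_ref_span <- function(cigar) {
  ops  <- strsplit(gsub("[0-9]+", "", cigar), "", fixed = TRUE)[[1L]]
  lens <- as.integer(strsplit(gsub("[MIDNSHP=X]", " ", cigar), " +")[[1L]])
  lens <- lens[!is.na(lens)]
  sum(lens[ops %in% c("M", "=", "X", "D", "N")])
}

# ---- MM/ML tag parsing -------------------------------------------------------

parse_mm_channels <- function(mm) {
  mm <- sub(";+$", "", mm)
  if (!nzchar(mm)) return(list())
  chans <- strsplit(mm, ";", fixed = TRUE)[[1L]]
  lapply(chans, function(ch) {
    m <- regmatches(ch, regexec("^([ACGTUN])([+-])([a-zA-Z0-9]+)([.?]?)(,(.*))?$", ch))[[1L]]
    if (length(m) == 0L) stop("malformed MM channel: ", ch)
    deltas <- if (is.na(m[7L]) || !nzchar(m[7L])) integer(0) else as.integer(strsplit(m[7L], ",", fixed = TRUE)[[1L]])
    list(base = m[2L], strand = m[3L], code = m[4L], flavor = m[5L], deltas = deltas)
  })
}

#' Decode the MM/ML tags of one aligned SAM record
#'
#' Converts the delta-encoded modified-base positions of a mapped record into
#' read coordinates (original sequencing orientation) and projects them
#' through the CIGAR onto the reference. Only the `A+a` (6mA) and `C+m`
#' (CpG 5mC) channels are supported; other channels are skipped with a
#' warning. Calls landing in insertions or soft clips carry `NA` `ref_pos`.
#'
#' @param record a list with elements `qname`, `flag`, `rname`, `pos`
#'   (1-based leftmost), `cigar`, `seq`, `mm` (MM tag body), `ml` (integer
#'   vector of ML scores).
#' @return a `ReadModRecord`: list with `read_id`, `contig`, `ref_start`,
#'   `ref_end` (0-based half-open), `strand`, `haplotype` and a `calls`
#'   data.frame (`read_pos`, `ref_pos`, `base`, `mod_code`, `score`) sorted
#'   by `ref_pos`.
#' @export
decode_read <- function(record) {
  stopifnot(is.list(record))
  flag <- as.integer(record$flag)
  if (bitwAnd(flag, 4L) != 0L) stop("record ", record$qname, " is unmapped")
  reverse <- bitwAnd(flag, 16L) != 0L
  seq_aln <- toupper(record$seq)
  L <- nchar(seq_aln)
  orig <- if (reverse) revcomp_chr(seq_aln) else seq_aln
  ref_start <- as.integer(record$pos) - 1L
  refmap <- cigar_ref_map(record$cigar, ref_start)
  if (length(refmap) != L)
    stop("CIGAR/SEQ length mismatch for read ", record$qname)

  chans <- parse_mm_channels(if (is.null(record$mm)) "" else record$mm)
  ml <- if (is.null(record$ml)) integer(0) else as.integer(record$ml)
  n_listed <- sum(vapply(chans, function(ch) length(ch$deltas), integer(1)))
  if (n_listed != length(ml))
    stop("MM/ML length mismatch for read ", record$qname,
         " (", n_listed, " positions vs ", length(ml), " scores)")

  orig_chars <- strsplit(orig, "", fixed = TRUE)[[1L]]
  out <- list(); used <- 0L
  for (ch in chans) {
    n <- length(ch$deltas)
    scores <- ml[seq_len(n) + used]; used <- used + n
    key <- paste0(ch$base, ch$strand, ch$code)
    if (!key %in% c("A+a", "C+m")) {
      warning("skipping unsupported modification channel '", key,
              "' on read ", record$qname)
      next
    }
    if (n == 0L) next
    occ <- which(orig_chars == ch$base) - 1L       # 0-based original-read positions
    idx <- cumsum(ch$deltas + 1L)
    if (length(occ) < max(idx))
      stop("MM tag of read ", record$qname, " lists more ", ch$base,
           " skips than the read contains")
    read_pos <- occ[idx]
    seq_off <- if (reverse) L - 1L - read_pos else read_pos
    out[[length(out) + 1L]] <- data.frame(
      read_pos = read_pos,
      ref_pos  = refmap[seq_off + 1L],
      base     = ch$base,
      mod_code = ch$code,
      score    = scores,
      stringsAsFactors = FALSE
    )
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(read_pos = integer(0), ref_pos = integer(0),
               base = character(0), mod_code = character(0),
               score = integer(0), stringsAsFactors = FALSE)
  calls <- calls[order(calls$ref_pos, calls$read_pos, na.last = TRUE), , drop = FALSE]
  rownames(calls) <- NULL
  contig <- record$rname
  list(
    read_id   = record$qname,
    contig    = contig,
    ref_start = ref_start,
    ref_end   = ref_start + cigar_ref_span(record$cigar),
    strand    = if (reverse) "-" else "+",
    haplotype = haplotype_from_contig(contig),
    calls     = calls
  )
}

haplotype_from_contig <- function(contig) {
  ifelse(grepl("_MATERNAL$", contig), "maternal",
         ifelse(grepl("_PATERNAL$", contig), "paternal", NA_character_))
}

#' Encode modification calls as MM/ML tag bodies
#'
#' Inverse of [decode_read()] at the tag level: given the read sequence in
#' its original sequencing orientation and calls in original-read
#' coordinates, produce the delta-encoded MM string and the ML score vector.
#' `decode_read(encode_read(x))` reproduces the input calls exactly.
#'
#' @param read_sequence character scalar, original-orientation read sequence.
#' @param calls data.frame with `read_pos` (0-based, original orientation),
#'   `mod_code` (`"a"` or `"m"`) and `score`.
#' @return list with elements `mm` (character scalar, possibly `""`) and
#'   `ml` (integer vector).
#' @export
encode_read <- function(read_sequence, calls) {
  stopifnot(is.character(read_sequence), length(read_sequence) == 1L)
  chars <- strsplit(toupper(read_sequence), "", fixed = TRUE)[[1L]]
  if (nrow(calls) == 0L) return(list(mm = "", ml = integer(0)))
  if (any(!calls$mod_code %in% c("a", "m")))
    stop("unsupported mod_code in calls")
  parts <- character(0); ml <- integer(0)
  for (spec in list(c("a", "A"), c("m", "C"))) {
    code <- spec[1L]; base <- spec[2L]
    sub <- calls[calls$mod_code == code, , drop = FALSE]
    if (nrow(sub) == 0L) next
    sub <- sub[order(sub$read_pos), , drop = FALSE]
    if (anyDuplicated(sub$read_pos)) stop("duplicate call positions for channel ", code)
    if (any(chars[sub$read_pos + 1L] != base))
      stop("call on channel ", code, " at a non-", base, " base")
    occ <- which(chars == base) - 1L
    idx <- match(sub$read_pos, occ)
    deltas <- diff(c(0L, idx)) - 1L
    parts <- c(parts, paste0(base, "+", code, ",", paste(deltas, collapse = ",")))
    ml <- c(ml, as.integer(sub$score))
  }
  list(mm = if (length(parts)) paste0(paste(parts, collapse = ";"), ";") else "",
       ml = ml)
}

# ---- mod_reads container -----------------------------------------------------

#' Construct a mod_reads object
#'
#' The central in-memory container: a table of aligned reads and a flat table
#' of their modification calls. Coordinates are 0-based half-open.
#'
#' @param reads data.frame with columns `read_id`, `contig`, `ref_start`,
#'   `ref_end`, `strand` and optionally `seq` (aligned orientation) and
#'   `haplotype`.
#' @param calls data.frame with columns `read_id`, `contig`, `strand`,
#'   `read_pos`, `ref_pos`, `base`, `mod_code`, `score` (and optionally
#'   `true_mod` for simulated data).
#' @return an object of class `mod_reads`.
#' @export
mod_reads <- function(reads, calls) {
  stopifnot(all(c("read_id", "contig", "ref_start", "ref_end", "strand") %in% names(reads)),
            all(c("read_id", "contig", "ref_pos", "mod_code", "score") %in% names(calls)))
  if (is.null(reads$haplotype)) reads$haplotype <- haplotype_from_contig(reads$contig)
  structure(list(reads = reads, calls = calls), class = "mod_reads")
}

#' @export
print.mod_reads <- function(x, ...) {
  cat("mod_reads: ", nrow(x$reads), " reads, ", nrow(x$calls), " calls (",
      sum(x$calls$mod_code == "a"), " 6mA, ",
      sum(x$calls$mod_code == "m"), " 5mCpG) on ",
      length(unique(x$reads$contig)), " contig(s)\n", sep = "")
  invisible(x)
}

# ---- SAM I/O -----------------------------------------------------------------

#' Read a SAM file carrying MM/ML modified-base tags
#'
#' Parses mapped records, decodes their MM/ML tags with [decode_read()], and
#' returns a [mod_reads] object. Unmapped and secondary/supplementary
#' records are skipped (counts reported via message). BAM input can be
#' converted with `samtools view -h` first.
#'
#' @param path path to a SAM file.
#' @param keep_seq keep read sequences in the reads table (default `FALSE`).
#' @return a [mod_reads] object.
#' @export
read_modsam <- function(path, keep_seq = FALSE) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  skipped <- 0L
  reads <- vector("list", length(body))
  calls <- vector("list", length(body))
  kept <- 0L
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 4L) != 0L || bitwAnd(flag, 256L) != 0L || bitwAnd(flag, 2048L) != 0L) {
      skipped <- skipped + 1L; next
    }
    tags <- f[-(1:11)]
    mm <- sub("^M[Mm]:Z:", "", grep("^M[Mm]:Z:", tags, value = TRUE)[1L])
    mlraw <- sub("^M[Ll]:B:C,?", "", grep("^M[Ll]:B:C", tags, value = TRUE)[1L])
    ml <- if (is.na(mlraw) || !nzchar(mlraw)) integer(0) else
      as.integer(strsplit(mlraw, ",", fixed = TRUE)[[1L]])
    if (is.na(mm)) mm <- ""
    rec <- decode_read(list(qname = f[1L], flag = flag, rname = f[3L],
                            pos = as.integer(f[4L]), cigar = f[6L],
                            seq = f[10L], mm = mm, ml = ml))
    kept <- kept + 1L
    rdf <- data.frame(read_id = rec$read_id, contig = rec$contig,
                      ref_start = rec$ref_start, ref_end = rec$ref_end,
                      strand = rec$strand, haplotype = rec$haplotype,
                      stringsAsFactors = FALSE)
    if (keep_seq) rdf$seq <- f[10L]
    reads[[kept]] <- rdf
    if (nrow(rec$calls)) {
      cc <- rec$calls
      cc$read_id <- rec$read_id; cc$contig <- rec$contig; cc$strand <- rec$strand
      calls[[kept]] <- cc
    }
  }
  if (skipped > 0L)
    message("read_modsam: skipped ", skipped, " unmapped/secondary record(s)")
  reads <- do.call(rbind, reads[seq_len(kept)])
  calls <- do.call(rbind, Filter(Negate(is.null), calls[seq_len(kept)]))
  if (is.null(calls))
    calls <- data.frame(read_pos = integer(0), ref_pos = integer(0),
                        base = character(0), mod_code = character(0),
                        score = integer(0), read_id = character(0),
                        contig = character(0), strand = character(0),
                        stringsAsFactors = FALSE)
  rownames(reads) <- rownames(calls) <- NULL
  mod_reads(reads, calls)
}

#' Write a mod_reads object as a SAM file with MM/ML tags
#'
#' Reads must carry their aligned-orientation sequence in `reads$seq`;
#' records are written with perfect-match CIGARs spanning
#' `ref_start..ref_end`. Calls are re-encoded with [encode_read()].
#'
#' @param x a [mod_reads] object with a `seq` column.
#' @param path output SAM path.
#' @param contig_lengths named integer vector for the `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_modsam <- function(x, path, contig_lengths) {
  stopifnot(inherits(x, "mod_reads"), !is.null(x$reads$seq))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(contig_lengths), "\tLN:", as.integer(contig_lengths)))
  rd <- x$reads[order(x$reads$contig, x$reads$ref_start), , drop = FALSE]
  call_split <- split(x$calls, x$calls$read_id)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  for (i in seq_len(nrow(rd))) {
    r <- rd[i, ]
    reverse <- r$strand == "-"
    orig <- if (reverse) revcomp_chr(r$seq) else r$seq
    cc <- call_split[[r$read_id]]
    if (is.null(cc)) cc <- data.frame(read_pos = integer(0), mod_code = character(0),
                                      score = integer(0))
    enc <- encode_read(orig, cc)
    tags <- character(0)
    if (nzchar(enc$mm))
      tags <- c(paste0("MM:Z:", enc$mm),
                paste0("ML:B:C,", paste(enc$ml, collapse = ",")))
    writeLines(paste(c(r$read_id, if (reverse) 16L else 0L, r$contig,
                       r$ref_start + 1L, 60L,
                       paste0(nchar(r$seq), "M"), "*", 0L, 0L, r$seq, "*",
                       tags), collapse = "\t"), con)
  }
  invisible(path)
}
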