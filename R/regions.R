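# Native motif scanning and interval classification: exact IUPAC-consensus
# matching on both strands (Biostrings does the degenerate-base matching) and
# center-in-annotation classification of sites, replacing external motif and
# interval tools for the analyses here.

#' Read a BED file (0-based half-open) into a sites data.frame
#' @param path BED path (3-6 columns).
#' @return data.frame with `contig`, `start`, `end`, `name`, `score`,
#'   `strand` (missing columns filled with defaults).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df)[seq_len(min(6L, ncol(df)))] <-
    c("contig", "start", "end", "name", "score", "strand")[seq_len(min(6L, ncol(df)))]
  if (is.null(df$name)) df$name <- paste0("region_", seq_len(nrow(df)))
  if (is.null(df$score)) df$score <- 0
  if (is.null(df$strand)) df$strand <- "+"
  df
}

#' Write a sites data.frame as BED
#' @param sites data.frame with `contig`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path) {
  df <- data.frame(sites$contig, sites$start, sites$end,
                   if (is.null(sites$name)) "." else sites$name,
                   if (is.null(sites$score)) 0 else sites$score,
                   if (is.null(sites$strand)) "." else sites$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Scan sequences for exact IUPAC-consensus motif matches
#'
#' Reports every match of the degenerate consensus on both strands;
#' minus-strand matches (of the reverse complement) are reported with
#' strand `"-"` and forward-reference coordinates. Overlapping matches are
#' all reported. Palindromic motifs match both strands at the same
#' coordinates.
#'
#' @param sequences named character vector of contig sequences, a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @param pattern IUPAC consensus, length >= 4.
#' @return data.frame with `contig`, `start`, `end` (0-based half-open),
#'   `name`, `strand`.
#' @export
scan_motif <- function(sequences, pattern) {
  pattern <- toupper(pattern)
  if (nchar(pattern) < 4L) stop("pattern length must be >= 4")
  if (!all(strsplit(pattern, "")[[1L]] %in% names(IUPAC_CODES)))
    stop("pattern contains invalid IUPAC codes")
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq_", seq_along(sequences))
  names(sequences) <- sub(" .*", "", names(sequences))
  fwd <- Biostrings::DNAString(pattern)
  rev <- Biostrings::reverseComplement(fwd)
  out <- list()
  for (i in seq_along(sequences)) {
    ct <- names(sequences)[i]
    for (str in c("+", "-")) {
      pat <- if (str == "+") fwd else rev
      m <- Biostrings::matchPattern(pat, sequences[[i]], fixed = FALSE)
      if (length(m) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        contig = ct, start = BiocGenerics::start(m) - 1L,
        end = BiocGenerics::end(m), strand = str, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      strand = character(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(df$contig, df$start, df$strand), , drop = FALSE]
  df$name <- paste0("match_", seq_len(nrow(df)))
  rownames(df) <- NULL
  df[, c("contig", "start", "end", "name", "strand")]
}

#' Classify sites by the annotation containing their center
#'
#' Each site is labeled with the class of the annotation interval containing
#' its center (`floor((start + end)/2)`); sites in no annotation get class
#' `"none"`. Multiple containing annotations are resolved by the smallest
#' interval, then by sort order.
#'
#' @param sites data.frame with `contig`, `start`, `end`.
#' @param annotations data.frame with `contig`, `start`, `end` and a
#'   `class` (or `name`) column.
#' @return `sites` with an added `class` column.
#' @export
classify_by_region <- function(sites, annotations) {
  cls <- annotations$class
  if (is.null(cls)) cls <- annotations$name
  if (is.null(cls)) stop("annotations need a 'class' or 'name' column")
  centers <- (sites$start + sites$end) %/% 2L
  sg <- GenomicRanges::GRanges(sites$contig,
                               IRanges::IRanges(start = centers + 1L, width = 1L))
  ag <- GenomicRanges::GRanges(annotations$contig,
                               IRanges::IRanges(start = annotations$start + 1L,
                                                end = annotations$end))
  hits <- GenomicRanges::findOverlaps(sg, ag)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  lab <- rep("none", nrow(sites))
  if (length(q)) {
    ord <- order(q, annotations$end[s] - annotations$start[s], s)
    q <- q[ord]; s <- s[ord]
    first <- !duplicated(q)
    lab[q[first]] <- cls[s[first]]
  }
  sites$class <- lab
  sites
}

#' Per-class aggregate profiles
#'
#' Splits classified sites by class and delegates to
#' [aggregate_at_sites()] per class. Classes with fewer than `min_sites`
#' sites are flagged low-confidence (attribute `low_confidence`); empty
#' classes yield a warning and are dropped.
#'
#' @param x a [mod_reads] object.
#' @param classified_sites output of [classify_by_region()].
#' @param halfwidth,mod_code,threshold_score passed to
#'   [aggregate_at_sites()].
#' @param min_sites low-confidence flag threshold (default 5).
#' @return named list of `aggregate_profile`s, one per class.
#' @export
class_profiles <- function(x, classified_sites, halfwidth = 1000L,
                           mod_code = "a", threshold_score = 225L,
                           min_sites = 5L) {
  stopifnot("class" %in% names(classified_sites))
  out <- list()
  for (cl in unique(classified_sites$class)) {
    sub <- classified_sites[classified_sites$class == cl, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("class '", cl, "' has no sites; skipped")
      next
    }
    p <- aggregate_at_sites(x, sub, halfwidth = halfwidth,
                            mod_code = mod_code,
                            threshold_score = threshold_score)
    attr(p, "low_confidence") <- nrow(sub) < min_sites
    if (nrow(sub) < min_sites)
      message("class_profiles: class '", cl, "' has only ", nrow(sub),
              " site(s); profile flagged low-confidence")
    out[[cl]] <- p
  }
  out
}
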