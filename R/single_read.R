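# Per-read binary methylation vectors in site-centered coordinates, as shown
# in single-read panels: one row per (read x site window) pair, columns are
# offsets, rows grouped by strand and sorted by descending methylated
# fraction within the displayed window.

#' Extract single-read methylation vectors at sites
#'
#' Each read overlapping a site window contributes one row per overlapped
#' site. Cells are 1 (call at or above threshold), 0 (call below threshold)
#' or `NA` (no call, or offset outside the read span). Offsets are flipped
#' for minus-strand sites. The per-row `methyl_fraction` is computed within
#' the displayed window by default (`whole_read = TRUE` uses all of the
#' read's calls of this modification instead).
#'
#' @param x a [mod_reads] object.
#' @param sites data.frame with `contig`, `start`, `end`, `strand`.
#' @param halfwidth window half-width W (bp).
#' @param mod_code `"a"` or `"m"`.
#' @param threshold_score binarization threshold; single-read panels
#'   conventionally use 250.
#' @param whole_read compute `methyl_fraction` over the whole read.
#' @return a `read_matrix`: list with `matrix` (rows = read x site pairs,
#'   columns = offsets `-W..W`), `rows` (read_id, site, strand,
#'   methyl_fraction), `offsets`.
#' @export
reads_at_sites <- function(x, sites, halfwidth = 1000L, mod_code = "a",
                           threshold_score = 250L, whole_read = FALSE) {
  stopifnot(inherits(x, "mod_reads"), halfwidth > 0L)
  W <- as.integer(halfwidth)
  width <- 2L * W + 1L
  centers <- (sites$start + sites$end) %/% 2L
  rd <- x$reads
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = rd$ref_start + 1L, end = rd$ref_end),
    IRanges::IRanges(start = centers - W + 1L, width = width))
  # restrict to matching contigs
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  keep <- rd$contig[q] == sites$contig[s]
  q <- q[keep]; s <- s[keep]
  if (length(q) == 0L) {
    message("reads_at_sites: no reads overlap any site window")
    return(structure(list(matrix = matrix(NA_integer_, 0, width,
                                          dimnames = list(NULL, seq.int(-W, W))),
                          rows = data.frame(read_id = character(0),
                                            site = integer(0),
                                            strand = character(0),
                                            methyl_fraction = numeric(0)),
                          offsets = seq.int(-W, W)),
                     class = "read_matrix"))
  }
  call_split <- split(seq_len(nrow(x$calls)),
                      factor(x$calls$read_id, levels = unique(rd$read_id)))
  cc <- x$calls
  mat <- matrix(NA_integer_, length(q), width,
                dimnames = list(NULL, seq.int(-W, W)))
  frac <- numeric(length(q))
  for (i in seq_along(q)) {
    r <- q[i]; site <- s[i]
    ctr <- centers[site]
    idx <- call_split[[rd$read_id[r]]]
    idx <- idx[cc$mod_code[idx] == mod_code & !is.na(cc$ref_pos[idx])]
    off <- cc$ref_pos[idx] - ctr
    if (sites$strand[site] == "-") off <- -off
    inw <- off >= -W & off <= W
    meth <- binarize(cc$score[idx], threshold_score)
    mat[i, off[inw] + W + 1L] <- as.integer(meth[inw])
    frac[i] <- if (whole_read) {
      if (length(idx)) mean(meth) else NA_real_
    } else {
      if (any(inw)) mean(meth[inw]) else NA_real_
    }
  }
  rows <- data.frame(read_id = rd$read_id[q], site = s,
                     strand = rd$strand[q], methyl_fraction = frac,
                     stringsAsFactors = FALSE)
  structure(list(matrix = mat, rows = rows, offsets = seq.int(-W, W)),
            class = "read_matrix")
}

#' Order a read matrix for display
#'
#' Rows are grouped by read alignment strand ("+" block first), then sorted
#' within each block by descending methylated fraction; ties are broken by
#' lexicographic read identifier, so the ordering is deterministic and
#' invariant to the input row permutation.
#'
#' @param rm a `read_matrix` from [reads_at_sites()].
#' @return the reordered `read_matrix`.
#' @export
order_matrix <- function(rm) {
  stopifnot(inherits(rm, "read_matrix"))
  rows <- rm$rows
  ord <- order(factor(rows$strand, levels = c("+", "-")),
               -ifelse(is.na(rows$methyl_fraction), -Inf, rows$methyl_fraction),
               rows$read_id, rows$site)
  rm$matrix <- rm$matrix[ord, , drop = FALSE]
  rm$rows <- rows[ord, , drop = FALSE]
  rownames(rm$rows) <- NULL
  rm
}

#' @export
print.read_matrix <- function(x, ...) {
  cat("read_matrix: ", nrow(x$rows), " read-site row(s) x ",
      length(x$offsets), " offsets (",
      sum(x$rows$strand == "+"), " plus / ", sum(x$rows$strand == "-"),
      " minus strand)\n", sep = "")
  invisible(x)
}

#' Write a read matrix as TSV
#' @param rm a `read_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_read_matrix_tsv <- function(rm, path) {
  df <- cbind(rm$rows, as.data.frame(rm$matrix, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
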