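# Pileups and motif-centered aggregate enrichment profiles. Aggregation pools
# base-level counts across sites (depth-weighted), keeping integer accounting
# exact before smoothing; smoothing is a plain centered moving average on the
# fraction scale, as in the figure conventions it reproduces.

new_aggregate_profile <- function(offset, meth, depth, n_sites, mod_code,
                                  threshold_score, smoothing_window = 0L,
                                  n_clipped = 0L, frac = NULL) {
  if (is.null(frac)) frac <- ifelse(depth > 0, meth / depth, NA_real_)
  structure(
    data.frame(offset = offset, frac = frac, depth = depth, meth = meth),
    n_sites = n_sites, mod_code = mod_code, threshold_score = threshold_score,
    smoothing_window = smoothing_window, n_clipped = n_clipped,
    class = c("aggregate_profile", "data.frame"))
}

profile_meta <- function(p)
  attributes(p)[c("n_sites", "mod_code", "threshold_score", "smoothing_window")]

#' @export
print.aggregate_profile <- function(x, ...) {
  cat("aggregate_profile: ", attr(x, "n_sites"), " site(s), mod '",
      attr(x, "mod_code"), "', threshold ", attr(x, "threshold_score"),
      ", smoothing ", attr(x, "smoothing_window"), " bp, offsets ",
      min(x$offset), "..", max(x$offset), "\n", sep = "")
  invisible(as.data.frame(x))
}

#' Per-position modified-base pileup over a region
#'
#' At each reference position of the region, `depth` counts reads carrying a
#' call of the requested modification there and `frac` the proportion of
#' those calls at or above the score threshold. Strands are pooled.
#'
#' @param x a [mod_reads] object.
#' @param contig contig name.
#' @param start,end 0-based half-open region bounds.
#' @param mod_code `"a"` (6mA) or `"m"` (CpG 5mC).
#' @param threshold_score binarization threshold (default 225).
#' @return data.frame with `pos`, `frac`, `depth`, `meth`.
#' @export
pileup <- function(x, contig, start, end, mod_code = "a",
                   threshold_score = 225L) {
  stopifnot(inherits(x, "mod_reads"), end > start)
  if (!contig %in% x$reads$contig)
    stop("contig '", contig, "' not present in reads")
  cc <- x$calls
  sel <- cc$contig == contig & cc$mod_code == mod_code &
    !is.na(cc$ref_pos) & cc$ref_pos >= start & cc$ref_pos < end
  pos <- cc$ref_pos[sel]
  meth_call <- binarize(cc$score[sel], threshold_score)
  n <- end - start
  depth <- tabulate(pos - start + 1L, nbins = n)
  meth <- tabulate((pos - start + 1L)[meth_call], nbins = n)
  data.frame(pos = seq.int(start, end - 1L),
             frac = ifelse(depth > 0, meth / depth, NA_real_),
             depth = depth, meth = meth)
}

#' Site-centered aggregate methylation profile
#'
#' Pools per-base methylation counts across sites at offsets `-W..+W` from
#' each site center (`floor((start + end)/2)`), reversing the offset axis
#' for minus-strand sites so profiles are in motif orientation. Counts are
#' depth-weighted across sites. Sites whose window crosses a contig edge
#' contribute clipped windows (count recorded in the `n_clipped` attribute).
#'
#' @param x a [mod_reads] object.
#' @param sites data.frame with `contig`, `start`, `end`, `strand`.
#' @param halfwidth window half-width W in bp.
#' @param mod_code `"a"` or `"m"`.
#' @param threshold_score binarization threshold (default 225).
#' @param contig_length optional contig length for edge-clip accounting.
#' @return an `aggregate_profile` (data.frame of `offset`, `frac`, `depth`,
#'   `meth` with metadata attributes).
#' @export
aggregate_at_sites <- function(x, sites, halfwidth = 1000L, mod_code = "a",
                               threshold_score = 225L, contig_length = NULL) {
  stopifnot(inherits(x, "mod_reads"), nrow(sites) >= 1L, halfwidth > 0L)
  W <- as.integer(halfwidth)
  centers <- (sites$start + sites$end) %/% 2L
  cc <- x$calls
  cc <- cc[cc$mod_code == mod_code & !is.na(cc$ref_pos), , drop = FALSE]
  width <- 2L * W + 1L
  depth <- integer(width); meth <- integer(width)
  n_clipped <- 0L
  for (ct in unique(sites$contig)) {
    si <- which(sites$contig == ct)
    ci <- cc$contig == ct
    if (!any(ci)) next
    qpos <- cc$ref_pos[ci]
    qmeth <- binarize(cc$score[ci], threshold_score)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = qpos + 1L, width = 1L),
      IRanges::IRanges(start = centers[si] - W + 1L, width = width))
    if (length(hits) == 0L) next
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    off <- qpos[q] - centers[si][s]
    neg <- sites$strand[si][s] == "-"
    off[neg] <- -off[neg]
    depth <- depth + tabulate(off + W + 1L, nbins = width)
    meth <- meth + tabulate((off + W + 1L)[qmeth[q]], nbins = width)
    if (!is.null(contig_length))
      n_clipped <- n_clipped + sum(centers[si] - W < 0L |
                                     centers[si] + W >= contig_length)
  }
  if (n_clipped > 0L)
    message("aggregate_at_sites: ", n_clipped, " site window(s) clipped at contig edges")
  new_aggregate_profile(seq.int(-W, W), meth, depth, nrow(sites), mod_code,
                        threshold_score, 0L, n_clipped)
}

#' Smooth an aggregate profile with a centered moving average
#'
#' Equal-weight moving average of the methylated fraction over `window`
#' offsets; edges use the truncated window; `window = 0` is the identity.
#' Offsets with undefined fraction (zero depth) are excluded from local
#' averages. A depth-weighted variant is available via `depth_weighted`.
#'
#' @param profile an `aggregate_profile`.
#' @param window smoothing window in bp (full width; the figure conventions
#'   are 50 bp for interphase panels, 30 bp for mitotic panels).
#' @param depth_weighted weight offsets by depth instead of equally.
#' @return a smoothed `aggregate_profile` (depth retained unchanged).
#' @export
smooth_profile <- function(profile, window = 50L, depth_weighted = FALSE) {
  stopifnot(inherits(profile, "aggregate_profile"), window >= 0)
  if (window == 0L) return(profile)
  half <- as.integer(window) %/% 2L
  w <- if (depth_weighted) profile$depth else as.numeric(!is.na(profile$frac))
  v <- ifelse(is.na(profile$frac), 0, profile$frac) * w
  cs_v <- c(0, cumsum(v)); cs_w <- c(0, cumsum(w))
  n <- nrow(profile)
  hi <- pmin(seq_len(n) + half, n)
  lo <- pmax(seq_len(n) - half, 1L)
  sum_v <- cs_v[hi + 1L] - cs_v[lo]
  sum_w <- cs_w[hi + 1L] - cs_w[lo]
  out <- new_aggregate_profile(profile$offset, profile$meth, profile$depth,
                               attr(profile, "n_sites"), attr(profile, "mod_code"),
                               attr(profile, "threshold_score"),
                               as.integer(window), attr(profile, "n_clipped"),
                               frac = ifelse(sum_w > 0, sum_v / sum_w, NA_real_))
  out
}

check_compatible <- function(a, b) {
  if (!identical(a$offset, b$offset))
    stop("profiles have different offset axes")
  ma <- profile_meta(a); mb <- profile_meta(b)
  for (f in c("mod_code", "threshold_score", "smoothing_window"))
    if (!identical(ma[[f]], mb[[f]]))
      stop("profiles differ in ", f, " (", ma[[f]], " vs ", mb[[f]], ")")
  invisible(TRUE)
}

#' Subtract a non-targeting control profile
#'
#' Position-wise difference of methylated fractions (target minus control),
#' as in background-subtracted enrichment panels. Values may be negative
#' (control excess is informative); no renormalization is applied. Depth is
#' reported as the position-wise minimum of the two depths.
#'
#' @param target,control `aggregate_profile`s with identical offsets,
#'   modification, threshold and smoothing.
#' @return an `aggregate_profile` of differences.
#' @export
subtract_control <- function(target, control) {
  check_compatible(target, control)
  new_aggregate_profile(target$offset, target$meth - control$meth,
                        pmin(target$depth, control$depth),
                        attr(target, "n_sites"), attr(target, "mod_code"),
                        attr(target, "threshold_score"),
                        attr(target, "smoothing_window"),
                        attr(target, "n_clipped"),
                        frac = target$frac - control$frac)
}

#' Fold enrichment of target over control near site centers
#'
#' Ratio of mean methylated fractions over `|offset| <= window` between a
#' target and a non-targeting control profile (both unsmoothed). The default
#' window of 300 bp spans the motif footprint, the first phased nucleosome
#' and the first flanking linker, where tethered signal concentrates.
#'
#' @param target,control unsmoothed `aggregate_profile`s at the same
#'   threshold.
#' @param window half-width of the central window (bp).
#' @return list with `ratio` (Inf with `control_zero = TRUE` when the
#'   control mean is zero), `target_mean`, `control_mean`.
#' @export
enrichment_ratio <- function(target, control, window = 300L) {
  check_compatible(target, control)
  if (attr(target, "smoothing_window") != 0L)
    stop("enrichment_ratio expects unsmoothed profiles")
  sel <- abs(target$offset) <= window
  tmean <- sum(target$meth[sel]) / sum(target$depth[sel])
  cmean <- sum(control$meth[sel]) / sum(control$depth[sel])
  if (cmean == 0)
    return(list(ratio = Inf, control_zero = TRUE, target_mean = tmean,
                control_mean = 0))
  list(ratio = tmean / cmean, control_zero = FALSE, target_mean = tmean,
       control_mean = cmean)
}

#' Write an aggregate profile as TSV
#' @param profile an `aggregate_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  meta <- profile_meta(profile)
  hdr <- sprintf("# n_sites=%d mod_code=%s threshold_score=%d smoothing_window=%d",
                 meta$n_sites, meta$mod_code, meta$threshold_score,
                 meta$smoothing_window)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(profile), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an aggregate profile written by [write_profile_tsv()]
#' @param path TSV path.
#' @return an `aggregate_profile`.
#' @export
read_profile_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- strsplit(sub("^# *", "", hdr), " ")[[1L]]
  meta <- stats::setNames(lapply(strsplit(kv, "="), `[`, 2L),
                          vapply(strsplit(kv, "="), `[`, character(1), 1L))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  new_aggregate_profile(df$offset, df$meth, df$depth,
                        as.integer(meta$n_sites), meta$mod_code,
                        as.integer(meta$threshold_score),
                        as.integer(meta$smoothing_window), 0L,
                        frac = df$frac)
}

#' Write a per-position pileup as bedGraph
#' @param pile output of [pileup()].
#' @param contig contig name.
#' @param path output path.
#' @param track track name.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(pile, contig, path, track = "methylated_fraction") {
  keep <- pile$depth > 0
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", track), con)
  if (any(keep))
    utils::write.table(
      data.frame(contig, pile$pos[keep], pile$pos[keep] + 1L,
                 signif(pile$frac[keep], 6)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
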