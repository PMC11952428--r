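# Haplotype-resolved analyses: reads are assigned to parental alleles purely
# by the contig they align to (a haplotype-resolved diploid assembly with
# _MATERNAL/_PATERNAL contig suffixes), mirroring alignment-based phasing at
# imprinted loci such as the H19 ICR, where the CpG-hypomethylated maternal
# allele is bound and the CpG-methylated paternal allele is not.

#' Split reads by parental haplotype
#'
#' Assignment is purely by aligned contig name: contigs suffixed
#' `_MATERNAL` / `_PATERNAL` go to the respective stream; anything else is
#' unassigned (count reported via message).
#'
#' @param x a [mod_reads] object.
#' @return list with `maternal`, `paternal` (both [mod_reads]) and
#'   `n_unassigned`.
#' @export
split_by_haplotype <- function(x) {
  stopifnot(inherits(x, "mod_reads"))
  hap <- x$reads$haplotype
  if (!any(!is.na(hap)))
    stop("zero reads assigned to a haplotype: contig names lack ",
         "_MATERNAL/_PATERNAL suffixes")
  n_un <- sum(is.na(hap))
  if (n_un > 0L)
    message("split_by_haplotype: ", n_un, " read(s) on unsuffixed contigs left unassigned")
  take <- function(which_hap) {
    ids <- x$reads$read_id[!is.na(hap) & hap == which_hap]
    mod_reads(x$reads[x$reads$read_id %in% ids, , drop = FALSE],
              x$calls[x$calls$read_id %in% ids, , drop = FALSE])
  }
  list(maternal = take("maternal"), paternal = take("paternal"),
       n_unassigned = n_un)
}

two_prop_z <- function(k1, n1, k2, n2) {
  p_pool <- (k1 + k2) / (n1 + n2)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  if (se == 0) return(0)
  (k1 / n1 - k2 / n2) / se
}

#' Allele-specific 6mA and CpG methylation contrast
#'
#' Computes mean 6mA methylated fraction (threshold 225 by default) and mean
#' CpG methylated fraction per allele over homologous windows of the two
#' parental contigs, and reports the imprinting deltas
#' `delta_6ma = maternal - paternal` and `delta_cpg = paternal - maternal`,
#' each with a two-proportion z statistic on the pooled call counts.
#'
#' @param x a [mod_reads] object aligned to a diploid assembly.
#' @param maternal_region,paternal_region lists `list(contig, start, end)`
#'   giving homologous windows (coordinates may differ between alleles).
#' @param threshold_6ma,threshold_cpg binarization thresholds.
#' @return an `allele_summary`: per-allele means, read counts, deltas and z
#'   statistics.
#' @export
imprinting_contrast <- function(x, maternal_region, paternal_region,
                                threshold_6ma = 225L, threshold_cpg = 225L) {
  stopifnot(inherits(x, "mod_reads"))
  side <- function(region) {
    cc <- x$calls
    sel <- cc$contig == region$contig & !is.na(cc$ref_pos) &
      cc$ref_pos >= region$start & cc$ref_pos < region$end
    a <- sel & cc$mod_code == "a"
    m <- sel & cc$mod_code == "m"
    rd <- x$reads
    n_reads <- sum(rd$contig == region$contig &
                     rd$ref_start < region$end & rd$ref_end > region$start)
    if (sum(a) == 0L && sum(m) == 0L)
      stop("insufficient data: no calls in region ", region$contig, ":",
           region$start, "-", region$end)
    list(n_a = sum(a), k_a = sum(binarize(cc$score[a], threshold_6ma)),
         n_m = sum(m), k_m = sum(binarize(cc$score[m], threshold_cpg)),
         n_reads = n_reads)
  }
  mat <- side(maternal_region); pat <- side(paternal_region)
  out <- list(
    maternal = list(mean_6ma = mat$k_a / mat$n_a, mean_cpg = mat$k_m / mat$n_m,
                    n_calls_6ma = mat$n_a, n_calls_cpg = mat$n_m,
                    n_reads = mat$n_reads),
    paternal = list(mean_6ma = pat$k_a / pat$n_a, mean_cpg = pat$k_m / pat$n_m,
                    n_calls_6ma = pat$n_a, n_calls_cpg = pat$n_m,
                    n_reads = pat$n_reads),
    delta_6ma = mat$k_a / mat$n_a - pat$k_a / pat$n_a,
    delta_cpg = pat$k_m / pat$n_m - mat$k_m / mat$n_m,
    z_6ma = two_prop_z(mat$k_a, mat$n_a, pat$k_a, pat$n_a),
    z_cpg = two_prop_z(pat$k_m, pat$n_m, mat$k_m, mat$n_m)
  )
  class(out) <- "allele_summary"
  out
}

#' @export
print.allele_summary <- function(x, ...) {
  cat(sprintf("allele_summary:\n  maternal: 6mA %.4f (%d calls), CpG %.4f (%d calls), %d reads\n",
              x$maternal$mean_6ma, x$maternal$n_calls_6ma,
              x$maternal$mean_cpg, x$maternal$n_calls_cpg, x$maternal$n_reads))
  cat(sprintf("  paternal: 6mA %.4f (%d calls), CpG %.4f (%d calls), %d reads\n",
              x$paternal$mean_6ma, x$paternal$n_calls_6ma,
              x$paternal$mean_cpg, x$paternal$n_calls_cpg, x$paternal$n_reads))
  cat(sprintf("  delta_6ma (mat - pat) = %+.4f (z = %.2f)\n", x$delta_6ma, x$z_6ma))
  cat(sprintf("  delta_cpg (pat - mat) = %+.4f (z = %.2f)\n", x$delta_cpg, x$z_cpg))
  invisible(x)
}
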