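# End-to-end orchestration: simulate (or load) a target/control pair, build
# aggregate profiles for both modifications, subtract the control, fit the
# flanking-peak decay, render the single-read matrix, and (diploid runs)
# contrast the alleles. Deterministic given the seeds in the config.

#' Build a validated pipeline configuration
#'
#' Two presets mirror the two display conventions: `"interphase"`
#' (50 bp smoothing, 1000 bp half-width) and `"mitotic"` (30 bp smoothing).
#' Aggregate analyses binarize at score 225, single-read panels at 250.
#'
#' @param preset `"interphase"` or `"mitotic"`.
#' @param sim a [fiber_sim_config] describing the simulated input (used
#'   when no files are supplied).
#' @param target_sam,control_sam,sites_bed optional paths to aligned SAM
#'   files and a site BED; when given they replace the simulation.
#' @param threshold_aggregate,threshold_single binarization thresholds.
#' @param smoothing_window,halfwidth profile parameters (preset defaults).
#' @param enrichment_window central window for the fold-enrichment summary.
#' @param decay_smoothing smoothing window used before peak detection.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("interphase", "mitotic"),
                            sim = fiber_sim_config(),
                            target_sam = NULL, control_sam = NULL,
                            sites_bed = NULL,
                            threshold_aggregate = 225L,
                            threshold_single = 250L,
                            smoothing_window = NULL,
                            halfwidth = 1000L,
                            enrichment_window = 300L,
                            decay_smoothing = 30L) {
  preset <- match.arg(preset)
  if (is.null(smoothing_window))
    smoothing_window <- if (preset == "mitotic") 30L else 50L
  cfg <- list(preset = preset, sim = sim, target_sam = target_sam,
              control_sam = control_sam, sites_bed = sites_bed,
              threshold_aggregate = as.integer(threshold_aggregate),
              threshold_single = as.integer(threshold_single),
              smoothing_window = as.integer(smoothing_window),
              halfwidth = as.integer(halfwidth),
              enrichment_window = as.integer(enrichment_window),
              decay_smoothing = as.integer(decay_smoothing))
  for (f in c("threshold_aggregate", "threshold_single"))
    if (cfg[[f]] < 0L || cfg[[f]] > 255L)
      stop("validation error: ", f, " must lie in 0..255")
  if (cfg$halfwidth <= 0L || cfg$smoothing_window < 0L)
    stop("validation error: halfwidth must be > 0 and smoothing_window >= 0")
  for (f in c("target_sam", "control_sam", "sites_bed"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("validation error: ", f, " path does not exist: ", cfg[[f]])
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  sem <- cfg[setdiff(names(cfg), c("target_sam", "control_sam", "sites_bed"))]
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(sem, tf)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a target and a non-targeting control dataset, then:
#' 6mA and CpG aggregate profiles, smoothing, control subtraction, fold
#' enrichment, flanking-peak exponential decay fit, ordered single-read
#' matrix, and -- for diploid simulations -- the allele contrast. Writes
#' TSV outputs and a machine-readable JSON summary when `out_dir` is given.
#'
#' @param config a [pipeline_config].
#' @param out_dir optional output directory.
#' @return list with `profiles` (target/control/subtracted, 6mA and CpG),
#'   `enrichment`, `decay` (fit + peaks), `single_read`, optional
#'   `imprinting`, and `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$target_sam)) {
    target <- read_modsam(config$target_sam)
    control <- if (!is.null(config$control_sam)) read_modsam(config$control_sam) else NULL
    sites <- read_bed(config$sites_bed)
  } else {
    ts <- simulate_dataset(config$sim, "target")
    cs <- simulate_dataset(config$sim, "igg")
    target <- ts$reads; control <- cs$reads; sites <- ts$sites
  }
  W <- config$halfwidth; thr <- config$threshold_aggregate
  prof <- list()
  for (mc in c("a", "m")) {
    prof[[mc]] <- list(target = aggregate_at_sites(target, sites, W, mc, thr))
    if (!is.null(control)) {
      prof[[mc]]$control <- aggregate_at_sites(control, sites, W, mc, thr)
      prof[[mc]]$subtracted <- subtract_control(
        smooth_profile(prof[[mc]]$target, config$smoothing_window),
        smooth_profile(prof[[mc]]$control, config$smoothing_window))
    }
  }
  enr <- if (!is.null(control))
    enrichment_ratio(prof$a$target, prof$a$control, config$enrichment_window)
  else NULL
  decay <- tryCatch(
    profile_decay_fit(prof$a$target, window = config$decay_smoothing),
    error = function(e) { warning("decay fit failed: ", conditionMessage(e)); NULL })
  sr <- order_matrix(reads_at_sites(target, sites, W, "a",
                                    config$threshold_single))
  imprint <- NULL
  if (is.null(config$target_sam) && config$sim$diploid) {
    # homologous windows spanning the site cluster (ICR-style contrast)
    ctr <- unique(sites$center)
    span <- c(min(ctr) - config$halfwidth, max(ctr) + config$halfwidth)
    imprint <- imprinting_contrast(
      target,
      list(contig = paste0(config$sim$contig, "_MATERNAL"),
           start = span[1L], end = span[2L]),
      list(contig = paste0(config$sim$contig, "_PATERNAL"),
           start = span[1L], end = span[2L]),
      threshold_6ma = thr, threshold_cpg = thr)
  }
  summary <- list(
    package_version = as.character(utils::packageVersion("fiberfoot")),
    config_hash = config_hash(config),
    preset = config$preset,
    threshold_aggregate = config$threshold_aggregate,
    threshold_single = config$threshold_single,
    smoothing_window = config$smoothing_window,
    halfwidth = config$halfwidth,
    n_target_reads = nrow(target$reads),
    n_control_reads = if (!is.null(control)) nrow(control$reads) else 0L,
    enrichment_ratio = if (!is.null(enr)) enr$ratio else NA_real_,
    decay_a = if (!is.null(decay)) decay$fit$a else NA_real_,
    decay_lambda = if (!is.null(decay)) decay$fit$lam else NA_real_,
    decay_converged = !is.null(decay) && isTRUE(decay$fit$converged),
    imprint_z_6ma = if (!is.null(imprint)) imprint$z_6ma else NA_real_,
    imprint_z_cpg = if (!is.null(imprint)) imprint$z_cpg else NA_real_)
  out <- list(profiles = prof, enrichment = enr, decay = decay,
              single_read = sr, imprinting = imprint, summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_profile_tsv(prof$a$target, file.path(out_dir, "profile_6ma_target.tsv"))
    if (!is.null(control)) {
      write_profile_tsv(prof$a$control, file.path(out_dir, "profile_6ma_control.tsv"))
      write_profile_tsv(prof$a$subtracted, file.path(out_dir, "profile_6ma_subtracted.tsv"))
      write_profile_tsv(prof$m$subtracted, file.path(out_dir, "profile_cpg_subtracted.tsv"))
    }
    write_read_matrix_tsv(sr, file.path(out_dir, "single_reads.tsv"))
    if (!is.null(decay)) {
      utils::write.table(as.data.frame(decay$peaks),
                         file.path(out_dir, "peaks.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(a = decay$fit$a, lam = decay$fit$lam, c = decay$fit$c,
                   se_a = decay$fit$se_a, se_lam = decay$fit$se_lam,
                   n_peaks = decay$fit$n_peaks, rss = decay$fit$rss),
        file.path(out_dir, "decay_fit.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
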