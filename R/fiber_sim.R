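# Synthetic single-fiber datasets under the tethered-methyltransferase model:
# a bound factor footprints its motif, nucleosomes phase off the bound site,
# the tethered enzyme methylates accessible adenines with probability decaying
# exponentially in distance, and free enzyme adds accessibility-dependent
# background in every condition. Endogenous CpG methylation is an allele
# property, anticorrelated with binding competence near sites.

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Configuration for the single-fiber simulator
#'
#' Defaults define the package's reference study conditions: 50 strongly
#' bound motif instances 10 kb apart on a 600 kb contig, sequenced to 25x
#' with ~15 kb fragments. Tethered deposition peaks at `A_teth` = 0.6 and
#' decays with constant `lam_teth` = 1/200 per bp; a 60 bp footprint
#' half-width and a 190 bp nucleosome repeat (147 bp cores, random-walk
#' positional jitter with per-step sd `jitter_sd` = 10 bp) shape
#' accessibility; free-enzyme background runs at `bg_rate` = 0.03 per
#' accessible adenine, boosted `site_access_boost`-fold within
#' `boost_halfwidth` of any site. Integer call scores are drawn from
#' discretized 255*Beta distributions (`score_meth`, `score_unmeth`).
#'
#' @param seed integer seed; identical seed + config give identical output.
#' @param contig base contig name.
#' @param genome_length,n_sites,site_spacing,motif reference geometry.
#' @param p_bound probability a fiber is bound at a site (haploid/target).
#' @param A_teth,lam_teth tethered deposition amplitude and per-bp decay.
#' @param footprint_halfwidth,NRL,core_len,jitter_sd,phase_n_nucs chromatin
#'   geometry: footprint half-width, nucleosome repeat length, core length,
#'   per-step positional jitter sd, and number of phased nucleosomes per
#'   flank.
#' @param bg_rate,site_access_boost,boost_halfwidth free-enzyme background.
#' @param cpg_near_bound,cpg_near_unbound,cpg_far,cpg_near_halfwidth CpG
#'   methylation probabilities near binding-competent sites, near
#'   non-competent sites, and elsewhere.
#' @param score_meth,score_unmeth Beta shape pairs for the score noise model.
#' @param frag_len_mean,frag_len_sd,coverage read geometry.
#' @param diploid emit `_MATERNAL`/`_PATERNAL` contig copies with
#'   allele-specific binding (`p_bound_maternal`, `p_bound_paternal`) and
#'   CpG states.
#' @param p_bound_maternal,p_bound_paternal allele-specific occupancy.
#' @return a validated list of class `fiber_sim_config`.
#' @export
fiber_sim_config <- function(seed = 1L, contig = "chrS",
                             genome_length = 600000L, n_sites = 50L,
                             site_spacing = 10000L,
                             motif = "CCACCAGGGGGCGCTA",
                             p_bound = 0.85, A_teth = 0.6, lam_teth = 1 / 200,
                             footprint_halfwidth = 60L, NRL = 190L,
                             core_len = 147L, jitter_sd = 10,
                             phase_n_nucs = 8L,
                             bg_rate = 0.03, site_access_boost = 3,
                             boost_halfwidth = 200L,
                             cpg_near_bound = 0.1, cpg_near_unbound = 0.9,
                             cpg_far = 0.7, cpg_near_halfwidth = 300L,
                             score_meth = c(9, 1), score_unmeth = c(1, 9),
                             frag_len_mean = 15000L, frag_len_sd = 1500L,
                             coverage = 25,
                             diploid = FALSE,
                             p_bound_maternal = 0.8, p_bound_paternal = 0) {
  cfg <- as.list(environment())
  probs <- c(p_bound, A_teth, bg_rate, cpg_near_bound, cpg_near_unbound,
             cpg_far, p_bound_maternal, p_bound_paternal)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(strsplit(toupper(motif), "")[[1L]] %in% names(IUPAC_CODES)))
    stop("motif contains non-IUPAC codes")
  if (NRL <= core_len) stop("NRL must exceed core_len")
  if (coverage <= 0) stop("coverage must be positive")
  if (n_sites * site_spacing >= genome_length)
    stop("n_sites * site_spacing must be smaller than genome_length")
  if (lam_teth < 0 || jitter_sd < 0) stop("lam_teth and jitter_sd must be >= 0")
  cfg$motif <- toupper(motif)
  structure(cfg, class = "fiber_sim_config")
}

sample_iupac <- function(motif) {
  paste(vapply(strsplit(motif, "")[[1L]],
               function(ch) sample(IUPAC_CODES[[ch]], 1L), character(1)),
        collapse = "")
}

#' Simulate a reference genome with planted motif sites
#'
#' Generates a random-base contig with the configured motif planted at
#' regular spacing on alternating strands (minus-strand instances are
#' reverse-complemented). In diploid mode two identical-length contigs named
#' `<contig>_MATERNAL` and `<contig>_PATERNAL` share the same site offsets.
#'
#' @param config a [fiber_sim_config].
#' @return list with `genome` (named character vector of contig sequences),
#'   `sites` (BED-like data.frame with strand), and `motif_instances`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "fiber_sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  base_seq <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- nchar(config$motif)
  centers <- as.integer(config$site_spacing / 2 +
                          (seq_len(config$n_sites) - 1L) * config$site_spacing)
  strands <- rep(c("+", "-"), length.out = config$n_sites)
  starts <- centers - m %/% 2L
  inst <- character(config$n_sites)
  for (i in seq_len(config$n_sites)) {
    realization <- sample_iupac(config$motif)
    inst[i] <- realization
    planted <- if (strands[i] == "-") revcomp_chr(realization) else realization
    base_seq[starts[i] + seq_len(m)] <- strsplit(planted, "")[[1L]]
  }
  seq_str <- paste(base_seq, collapse = "")
  contigs <- if (config$diploid)
    paste0(config$contig, c("_MATERNAL", "_PATERNAL")) else config$contig
  genome <- stats::setNames(rep(seq_str, length(contigs)), contigs)
  sites <- do.call(rbind, lapply(contigs, function(ct)
    data.frame(contig = ct, start = starts, end = starts + m,
               name = paste0("site_", seq_len(config$n_sites)),
               strand = strands, center = centers,
               stringsAsFactors = FALSE)))
  rownames(sites) <- NULL
  list(genome = genome, sites = sites, motif_instances = inst)
}

#' Accessibility multiplier at a signed offset from a motif center
#'
#' Bound fibers: 0 inside the footprint (|d| < footprint half-width) and
#' inside each phased nucleosome core (cores butt against the footprint
#' boundary and repeat every NRL; the k-th core is displaced by `jitter[k]`,
#' zero by default). Unbound fibers: cores tile the axis with an arbitrary
#' phase. Accessible positions return 1.
#'
#' @param d integer vector of signed offsets (bp) from the motif center.
#' @param bound logical scalar.
#' @param config a [fiber_sim_config].
#' @param phase_offset phase of the unbound nucleosome array in `[0, NRL)`.
#' @param jitter numeric vector of per-nucleosome-index displacements (bp),
#'   recycled to `phase_n_nucs`, applied to both flanks.
#' @return numeric vector of 0/1 multipliers.
#' @export
accessibility <- function(d, bound, config, phase_offset = 0, jitter = NULL) {
  stopifnot(inherits(config, "fiber_sim_config"))
  fh <- config$footprint_halfwidth; NRL <- config$NRL; cl <- config$core_len
  K <- config$phase_n_nucs
  if (is.null(jitter)) jitter <- rep(0, K) else jitter <- rep_len(jitter, K)
  if (!bound) {
    pos <- (d - phase_offset) %% NRL
    return(as.numeric(pos >= cl))
  }
  a <- abs(d)
  occ <- a < fh
  for (k in seq_len(K)) {
    lo <- fh + (k - 1L) * NRL + jitter[k]
    occ <- occ | (a >= lo & a < lo + cl)
  }
  as.numeric(!occ)
}

score_from_state <- function(state, config) {
  n <- length(state)
  b <- numeric(n)
  if (any(state))  b[state]  <- stats::rbeta(sum(state),  config$score_meth[1],   config$score_meth[2])
  if (any(!state)) b[!state] <- stats::rbeta(sum(!state), config$score_unmeth[1], config$score_unmeth[2])
  pmin(pmax(as.integer(round(255 * b)), 0L), 255L)
}

# Per-fiber occupancy over [s, e): random-phase cores genome-wide, overridden
# by footprint + phased cores around each bound site.
fiber_occupancy <- function(s, e, bound_centers, config) {
  len <- e - s
  NRL <- config$NRL; cl <- config$core_len; fh <- config$footprint_halfwidth
  K <- config$phase_n_nucs
  phase <- stats::runif(1, 0, NRL)
  x <- seq.int(s, e - 1L)
  occ <- ((x - phase) %% NRL) < cl
  zone <- fh + K * NRL
  for (cc in bound_centers) {
    zi <- x >= cc - zone & x < cc + zone
    if (!any(zi)) next
    occ[zi] <- abs(x[zi] - cc) < fh
    for (side in c(-1, 1)) {
      jit <- stats::rnorm(K, 0, config$jitter_sd * sqrt(seq_len(K)))
      for (k in seq_len(K)) {
        lo <- cc + side * (fh + (k - 1L) * NRL) + jit[k]
        core <- if (side > 0) x >= lo & x < lo + cl else x > lo - cl & x <= lo
        occ[core & zi] <- TRUE
      }
    }
  }
  stats::setNames(!occ, NULL)
}

# distance from each position to its nearest center (centers sorted)
min_center_dist <- function(pos, centers) {
  if (length(centers) == 0L) return(rep(Inf, length(pos)))
  centers <- sort(centers)
  idx <- findInterval(pos, centers)
  left  <- centers[pmax(idx, 1L)]
  right <- centers[pmin(idx + 1L, length(centers))]
  pmin(abs(pos - left), abs(pos - right))
}

# True methylation probability for adenines of one fiber.
fiber_6ma_probs <- function(pos, access, bound_centers, all_centers, config) {
  p_teth <- if (length(bound_centers)) {
    config$A_teth * exp(-config$lam_teth * min_center_dist(pos, bound_centers))
  } else rep(0, length(pos))
  dall <- min_center_dist(pos, all_centers)
  boost <- ifelse(dall <= config$boost_halfwidth, config$site_access_boost, 1)
  p_bg <- pmin(config$bg_rate * boost, 1)
  access * (1 - (1 - p_teth) * (1 - p_bg))
}

#' Simulate one fiber overlapping a motif site
#'
#' Draws a single fragment spanning the site and returns its true
#' modification states and integer scores; used for closed-form checks of
#' the generative model. [simulate_dataset()] is the batch interface.
#'
#' @param config a [fiber_sim_config].
#' @param site_center 0-based center of the site on the simulated contig.
#' @param bound is the fiber bound at this site?
#' @param ref output of [simulate_reference()]; generated if `NULL`.
#' @param binding_competent does a binding-competent factor occupy this
#'   locus on this allele (controls near-site CpG state)?
#' @return list with `ref_start`, `ref_end`, `strand`, and a calls
#'   data.frame including `true_mod`.
#' @export
simulate_fiber <- function(config, site_center, bound, ref = NULL,
                           binding_competent = TRUE) {
  if (is.null(ref)) ref <- simulate_reference(config)
  contig <- names(ref$genome)[1L]
  gchars <- strsplit(ref$genome[[1L]], "")[[1L]]
  L <- nchar(ref$genome[[1L]])
  flen <- max(1000L, as.integer(round(stats::rnorm(1, config$frag_len_mean,
                                                   config$frag_len_sd))))
  s <- max(0L, min(L - flen,
                   site_center - as.integer(stats::runif(1, 0.1, 0.9) * flen)))
  e <- s + flen
  strand <- sample(c("+", "-"), 1L)
  fiber_calls(s, e, strand, gchars,
              bound_centers = if (bound) site_center else numeric(0),
              all_centers = unique(ref$sites$center),
              competent_centers = if (binding_competent)
                unique(ref$sites$center) else numeric(0),
              config = config)
}

# Core generative step shared by simulate_fiber and simulate_dataset.
fiber_calls <- function(s, e, strand, gchars, bound_centers, all_centers,
                        competent_centers, config) {
  chunk <- gchars[(s + 1L):e]
  occ_access <- fiber_occupancy(s, e, bound_centers, config)
  # adenines on the sequenced strand: ref A for + reads, ref T for - reads
  a_idx <- which(chunk == if (strand == "+") "A" else "T")
  a_ref <- s + a_idx - 1L
  p_a <- fiber_6ma_probs(a_ref, occ_access[a_idx], bound_centers, all_centers, config)
  true_a <- stats::runif(length(a_ref)) < p_a
  # CpG cytosines: + reads call the C of CG; - reads the complementary C at the G
  cg_i <- which(chunk[-length(chunk)] == "C" & chunk[-1L] == "G")
  c_idx <- if (strand == "+") cg_i else cg_i + 1L
  c_ref <- s + c_idx - 1L
  if (length(c_ref)) {
    near <- min_center_dist(c_ref, all_centers) <= config$cpg_near_halfwidth
    comp <- min_center_dist(c_ref, competent_centers) <= config$cpg_near_halfwidth
    p_c <- ifelse(near, ifelse(comp, config$cpg_near_bound,
                               config$cpg_near_unbound), config$cpg_far)
    true_c <- stats::runif(length(c_ref)) < p_c
  } else true_c <- logical(0)
  read_pos <- function(ref) if (strand == "+") ref - s else (e - 1L) - ref
  calls <- data.frame(
    read_pos = c(read_pos(a_ref), read_pos(c_ref)),
    ref_pos  = c(a_ref, c_ref),
    base     = c(rep("A", length(a_ref)), rep("C", length(c_ref))),
    mod_code = c(rep("a", length(a_ref)), rep("m", length(c_ref))),
    score    = c(score_from_state(true_a, config), score_from_state(true_c, config)),
    true_mod = c(true_a, true_c),
    stringsAsFactors = FALSE
  )
  calls <- calls[order(calls$ref_pos), , drop = FALSE]
  rownames(calls) <- NULL
  list(ref_start = s, ref_end = e, strand = strand, calls = calls)
}

#' Simulate a full aligned modified-base dataset
#'
#' Generates the reference, draws fragments to the configured coverage, and
#' emits every adenine (on the sequenced strand) and every CpG cytosine as a
#' modification call with an integer score, together with per-read and
#' per-base ground truth. The `igg` condition zeroes site occupancy so only
#' accessibility-driven free-enzyme background remains; endogenous CpG
#' states are unchanged. Deterministic given `config$seed`.
#'
#' @param config a [fiber_sim_config].
#' @param condition `"target"` (antibody-directed) or `"igg"`
#'   (non-targeting control).
#' @param dir if non-`NULL`, write `reference.fa`, `sites.bed`,
#'   `reads_<condition>.sam` and `truth_<condition>.tsv` there.
#' @return list with `reads` (a [mod_reads]; calls carry `true_mod`),
#'   `truth` (per-read table: `read_id`, `site_id`, `bound`, `haplotype`),
#'   `sites`, `ref`, and `paths` when `dir` is given.
#' @export
simulate_dataset <- function(config, condition = c("target", "igg"), dir = NULL) {
  stopifnot(inherits(config, "fiber_sim_config"))
  condition <- match.arg(condition)
  ref <- simulate_reference(config)
  contigs <- names(ref$genome)
  gchars <- lapply(ref$genome, function(s) strsplit(s, "")[[1L]])
  L <- config$genome_length
  n_reads <- as.integer(round(config$coverage * L * length(contigs) /
                                config$frag_len_mean))
  set.seed(config$seed + if (condition == "igg") 1000003L else 0L)

  p_bound_for <- function(contig) {
    if (condition == "igg") return(0)
    if (grepl("_MATERNAL$", contig)) config$p_bound_maternal
    else if (grepl("_PATERNAL$", contig)) config$p_bound_paternal
    else config$p_bound
  }
  competent_for <- function(contig) {
    pb <- if (grepl("_MATERNAL$", contig)) config$p_bound_maternal
          else if (grepl("_PATERNAL$", contig)) config$p_bound_paternal
          else config$p_bound
    if (pb > 0) unique(ref$sites$center) else numeric(0)
  }

  centers <- unique(ref$sites$center)
  reads_l <- vector("list", n_reads)
  calls_l <- vector("list", n_reads)
  keep_seq <- !is.null(dir)
  for (i in seq_len(n_reads)) {
    contig <- if (length(contigs) == 1L) contigs else sample(contigs, 1L)
    flen <- max(1000L, as.integer(round(stats::rnorm(1, config$frag_len_mean,
                                                     config$frag_len_sd))))
    flen <- min(flen, L)
    s <- as.integer(floor(stats::runif(1, 0, L - flen + 1)))
    e <- s + flen
    strand <- sample(c("+", "-"), 1L)
    over <- centers[centers >= s & centers < e]
    pb <- p_bound_for(contig)
    bound_at <- over[stats::runif(length(over)) < pb]
    fc <- fiber_calls(s, e, strand, gchars[[contig]], bound_at, centers,
                      competent_for(contig), config)
    rid <- sprintf("read_%05d", i)
    site_id <- if (length(over))
      paste0("site_", match(over[which.min(abs(over - (s + e) / 2))], centers))
      else NA_character_
    reads_l[[i]] <- list(read_id = rid, contig = contig, ref_start = s,
                         ref_end = e, strand = strand,
                         site_id = site_id, bound = length(bound_at) > 0L,
                         n_sites_overlapped = length(over),
                         seq = if (keep_seq)
                           paste(gchars[[contig]][(s + 1L):e], collapse = "") else NA_character_)
    cc <- fc$calls
    cc$read_id <- rid; cc$contig <- contig; cc$strand <- strand
    calls_l[[i]] <- cc
  }
  reads <- do.call(rbind, lapply(reads_l, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  reads$haplotype <- haplotype_from_contig(reads$contig)
  calls <- do.call(rbind, calls_l)
  rownames(reads) <- rownames(calls) <- NULL
  mr <- mod_reads(reads[, c("read_id", "contig", "ref_start", "ref_end",
                            "strand", "haplotype", "seq")], calls)
  truth <- reads[, c("read_id", "site_id", "bound", "haplotype",
                     "n_sites_overlapped")]
  out <- list(reads = mr, truth = truth, sites = ref$sites, ref = ref,
              condition = condition, config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "reference.fa")
    gss <- Biostrings::DNAStringSet(ref$genome)
    Biostrings::writeXStringSet(gss, fa)
    bed <- file.path(dir, "sites.bed")
    write_bed(ref$sites, bed)
    sam <- file.path(dir, paste0("reads_", condition, ".sam"))
    write_modsam(mr, sam, stats::setNames(rep(L, length(contigs)), contigs))
    tr <- file.path(dir, paste0("truth_", condition, ".tsv"))
    utils::write.table(truth, tr, sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- list(fasta = fa, bed = bed, sam = sam, truth = tr)
  } else {
    out$reads$reads$seq <- NULL
  }
  out
}

#' Generative values of the decay-fit estimands
#'
#' The exponential fitted to flanking methylation peaks estimates the peak
#' methylated fraction extrapolated to distance 0 (`a`) and the spatial
#' decay constant (`lam`). Under the generative model their values are
#' `a = p_bound * A_teth * TPR(threshold)` -- occupancy and basecaller
#' sensitivity scale observed peak heights -- and `lam = lam_teth`.
#'
#' @param config a [fiber_sim_config].
#' @param threshold_score binarization threshold used in the analysis.
#' @param allele for diploid configs, which allele's occupancy to use.
#' @return list with `a`, `lam`, and the true-positive rate `tpr`.
#' @export
expected_decay_params <- function(config, threshold_score = 225L,
                                  allele = c("haploid", "maternal", "paternal")) {
  allele <- match.arg(allele)
  pb <- switch(allele, haploid = config$p_bound,
               maternal = config$p_bound_maternal,
               paternal = config$p_bound_paternal)
  tpr <- 1 - stats::pbeta((threshold_score - 0.5) / 255,
                          config$score_meth[1], config$score_meth[2])
  list(a = pb * config$A_teth * tpr, lam = config$lam_teth, tpr = tpr)
}
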