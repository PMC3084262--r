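#' End-to-end recruiter-screen study on synthetic data
#'
#' Generates a dataset at the default study conditions with `n_decoys`
#' additional factors whose marginal binding rates match the planted
#' recruiters but whose recruitment weight is zero, derives the
#' co-repressor target set (binding p below `p_target`), simulates
#' deletion-strain expression and (optionally) region sequences with every
#' factor's motif planted at its bound regions, and runs the five-test
#' composite screen.
#'
#' @param seed integer seed; all sub-seeds are derived from it.
#' @param n_regions number of regions.
#' @param n_decoys number of weight-zero decoy factors.
#' @param include_motif run the motif over-representation test (requires
#'   generating sequences and PWMs for every factor).
#' @param p_target binding p-value defining co-repressor targets.
#' @param motif_p per-site score p-value used for motif site calls in the
#'   over-representation test; the stringent default keeps the expected
#'   number of background matches per kb-scale region well below one, so
#'   region-level motif presence stays informative.
#' @return list: scorecard (sorted composite ranking), raw (per-test raw
#'   scores), planted (recruiter names), weights (planted weights),
#'   target_ids, dataset.
#' @export
screen_study <- function(seed, n_regions = 6000, n_decoys = 50,
                         include_motif = TRUE, p_target = 0.001,
                         motif_p = 1e-4) {
  decoys <- sprintf("DEC%02d", seq_len(n_decoys))
  cfg <- sim_config(n_regions = n_regions, decoys = decoys)
  d <- generate_dataset(cfg, seed = seed)
  factors <- cfg$factors
  y <- d$occupancy[, cfg$corepressor]
  target_ids <- rownames(d$pvalues)[d$pvalues[, cfg$corepressor] < p_target]
  gm <- make_gene_map(d$regions, seed = seed + 1L)
  ex <- generate_expression(d, gm, seed = seed + 2L)
  seqs <- pwms <- NULL
  if (include_motif) {
    set.seed(seed + 3L)
    pwms <- stats::setNames(lapply(factors, random_pwm), factors)
    plant <- stats::setNames(lapply(factors, function(f) {
      rownames(d$occupancy)[d$truth$bound[, f]]
    }), factors)
    seqs <- generate_sequences(d$regions, pwms, plant,
                               seed = seed + 4L)$sequences
  }
  screen <- run_recruiter_screen(y, target_ids,
                                 d$occupancy[, factors, drop = FALSE],
                                 d$pvalues[, factors, drop = FALSE],
                                 expression = ex, gene_map = gm,
                                 sequences = seqs, pwms = pwms,
                                 motif_p = motif_p)
  list(scorecard = screen$scorecard, raw = screen$raw,
       planted = names(cfg$weights), weights = cfg$weights,
       target_ids = target_ids, dataset = d)
}

#' Parameter-recovery study for the occupancy regression pipeline
#'
#' Generates a dataset at the default study conditions plus `n_decoys`
#' weight-zero factors and runs the full pipeline (Gaussian imputation,
#' univariate screen, cross-validated fit, removal of non-significant
#' recruiters), then compares the recovered model with the planted truth.
#'
#' @param seed integer seed.
#' @param n_regions number of regions.
#' @param n_decoys number of weight-zero decoy candidates offered to the
#'   pipeline.
#' @return list: model, planted (named weights), estimated (same order, NA
#'   where dropped), active_set_exact (planted recruiters all retained and
#'   no decoy retained), max_abs_error (Inf when the active set is wrong),
#'   dataset.
#' @export
regression_study <- function(seed, n_regions = 6000, n_decoys = 3) {
  decoys <- sprintf("DEC%02d", seq_len(n_decoys))
  cfg <- sim_config(n_regions = n_regions, decoys = decoys)
  d <- generate_dataset(cfg, seed = seed)
  fit <- fit_occupancy_model(d, seed = seed + 1L)
  w <- cfg$weights
  est <- stats::setNames(rep(NA_real_, length(w)), names(w))
  common <- intersect(names(w), fit$model$included)
  est[common] <- fit$model$weights[common]
  exact <- setequal(fit$model$included, names(w))
  list(model = fit$model, planted = w, estimated = est,
       active_set_exact = exact,
       max_abs_error = if (exact) max(abs(est - w)) else Inf,
       dataset = d)
}

# flat tiled array layout used by the peak-calling studies
tiled_profile <- function(n_chrom, elements_per_chrom, element_bp) {
  n <- n_chrom * elements_per_chrom
  prof <- data.frame(
    region_id = sprintf("e%06d", seq_len(n)),
    chrom = rep(sprintf("chr%04d", seq_len(n_chrom)),
                each = elements_per_chrom),
    start = rep(seq(0L, by = element_bp, length.out = elements_per_chrom),
                n_chrom),
    stringsAsFactors = FALSE
  )
  prof$end <- prof$start + element_bp
  prof$value <- 0
  class(prof) <- c("signal_profile", "data.frame")
  prof
}

#' Null calibration study for the peak caller
#'
#' Simulates pure Gaussian noise profiles over many chromosomes of tiled
#' array elements, runs window scoring and FDR filtering, and reports the
#' realized fraction of windows falsely called significant.
#'
#' @param seed integer seed.
#' @param n_chrom number of simulated chromosomes.
#' @param elements_per_chrom tiled elements per chromosome.
#' @param element_bp element width in bp.
#' @param fdr FDR cutoff.
#' @return list: n_windows, n_false, fpr, chroms_with_false.
#' @export
peak_null_study <- function(seed, n_chrom = 1000, elements_per_chrom = 100,
                            element_bp = 800, fdr = 0.001) {
  set.seed(seed)
  prof <- tiled_profile(n_chrom, elements_per_chrom, element_bp)
  prof$value <- stats::rnorm(nrow(prof))
  windows <- call_windows(prof)
  sig <- fdr_filter(windows, fdr)
  list(n_windows = nrow(windows), n_false = nrow(sig),
       fpr = nrow(sig) / nrow(windows),
       chroms_with_false = length(unique(sig$chrom)))
}

#' Planted-peak recovery study for the peak caller
#'
#' Plants one rectangular peak (a run of consecutive elements elevated by
#' `amplitude` noise standard deviations) per chromosome at a random
#' position, runs the full peak-calling pipeline including the mock filter,
#' and reports recall (fraction of planted peaks recovered by a called peak
#' whose representative element lies within the planted span).
#'
#' @param seed integer seed.
#' @param n_chrom number of chromosomes, one planted peak each.
#' @param elements_per_chrom tiled elements per chromosome.
#' @param element_bp element width in bp.
#' @param amplitude planted enrichment in units of the noise sd.
#' @param peak_elements consecutive elevated elements per peak (span width =
#'   `peak_elements * element_bp`).
#' @param fdr FDR cutoff.
#' @return list: recall, n_planted, n_recovered, representatives_in_span,
#'   peaks.
#' @export
peak_recovery_study <- function(seed, n_chrom = 200,
                                elements_per_chrom = 100, element_bp = 800,
                                amplitude = 4, peak_elements = 2,
                                fdr = 0.001) {
  set.seed(seed)
  prof <- tiled_profile(n_chrom, elements_per_chrom, element_bp)
  prof$value <- stats::rnorm(nrow(prof))
  first <- sample.int(elements_per_chrom - peak_elements, n_chrom,
                      replace = TRUE) + 1L
  planted <- data.frame(
    chrom = sprintf("chr%04d", seq_len(n_chrom)),
    span_start = (first - 1L) * element_bp,
    span_end = (first - 1L + peak_elements) * element_bp,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n_chrom)) {
    idx <- (i - 1L) * elements_per_chrom + first[i] + seq_len(peak_elements) -
      1L
    prof$value[idx] <- prof$value[idx] + amplitude
  }
  mock <- prof
  mock$value <- stats::rnorm(nrow(prof))
  peaks <- call_peaks(prof, mock, fdr = fdr)
  rep_idx <- match(peaks$representative_element, prof$region_id)
  rep_start <- prof$start[rep_idx]
  rep_end <- prof$end[rep_idx]
  pl <- planted[match(peaks$chrom, planted$chrom), ]
  in_span <- rep_start >= pl$span_start & rep_end <= pl$span_end
  recovered <- unique(peaks$chrom[in_span])
  list(recall = length(recovered) / n_chrom, n_planted = n_chrom,
       n_recovered = length(recovered),
       representatives_in_span = mean(in_span), peaks = peaks)
}
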