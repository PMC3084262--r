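#' Default recruiter weights for the synthetic generator
#'
#' Named vector of linear recruitment weights for the nine DNA-binding
#' cofactors used as the generator's default planted model, together with the
#' default intercept (attribute `"intercept"`). These defaults define the
#' reference regime of the simulator: a co-repressor whose occupancy is a
#' weighted sum of recruiter occupancies plus Gaussian noise.
#'
#' @return Named numeric vector of weights; the intercept is attached as the
#'   `"intercept"` attribute.
#' @export
#' @examples
#' w <- default_recruiter_weights()
#' attr(w, "intercept")
default_recruiter_weights <- function() {
  w <- c(
    SUT1 = 0.454, NRG1 = 0.348, ROX1 = 0.215, SKO1 = 0.198, CUP9 = 0.513,
    YAP6 = 0.706, CIN5 = 0.395, PHD1 = 0.190, SKN7 = 0.170
  )
  attr(w, "intercept") <- 0.129
  w
}

#' Noise standard deviation calibrated to a target genome-wide R-squared
#'
#' Given the planted weights and the two-component mixture used for recruiter
#' occupancies (unbound ~ Normal(0, occ_sd), bound ~ Normal(mu_bound, occ_sd)
#' with probability `bound_fraction`), solves for the residual standard
#' deviation sigma such that the population R-squared of the generative model
#' equals `target_r2`:
#' \deqn{R^2 = \frac{\sum_r \beta_r^2 \mathrm{Var}(x_r)}{\sum_r \beta_r^2
#'   \mathrm{Var}(x_r) + \sigma^2}}
#' with Var(x_r) = pi (1-pi) mu_b^2 + occ_sd^2 for independent recruiters.
#'
#' @param weights named numeric vector of planted weights.
#' @param target_r2 population R-squared to calibrate to (default 0.43, the
#'   genome-wide explanatory power the model is designed to emulate).
#' @param bound_fraction probability a recruiter is bound at a region.
#' @param mu_bound mean log2 ratio of the bound mixture component.
#' @param occ_sd within-component standard deviation of recruiter log2 ratios.
#' @return scalar sigma (> 0).
#' @export
calibrate_noise_sd <- function(weights, target_r2 = 0.43, bound_fraction = 0.1,
                               mu_bound = 2, occ_sd = 0.5) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  var_x <- bound_fraction * (1 - bound_fraction) * mu_bound^2 + occ_sd^2
  var_signal <- sum(weights^2) * var_x
  sqrt(var_signal * (1 - target_r2) / target_r2)
}

#' Generator configuration
#'
#' Assembles and validates the settings for [generate_dataset()]. Defaults
#' describe the reference study conditions: ~6,000 intergenic regions spread
#' over 16 chromosomes, nine planted recruiters at the default weights,
#' recruiter occupancies drawn from a bound/unbound Gaussian mixture, 5%
#' missing entries at random, and residual noise calibrated so that the
#' planted linear model explains about 43% of co-repressor variance
#' genome-wide.
#'
#' @param n_regions number of regulatory regions (>= 10).
#' @param n_chrom number of chromosomes regions are laid out on.
#' @param region_length integer range (min, max) of region lengths in bp.
#' @param weights named vector of planted recruitment weights beta_r.
#' @param intercept planted intercept.
#' @param decoys character vector of additional factor names with zero weight
#'   (profiled but not contributing to co-repressor occupancy).
#' @param bound_fraction per-factor probability of the bound mixture component.
#' @param mu_bound mean of the bound component (log2 ratio units).
#' @param occ_sd standard deviation of both mixture components.
#' @param noise_sd residual sigma of the co-repressor column; `NULL` (default)
#'   calibrates it with [calibrate_noise_sd()] to `target_r2`.
#' @param target_r2 calibration target used when `noise_sd` is `NULL`.
#' @param missing_rate fraction of recruiter entries set missing completely at
#'   random.
#' @param redundancy default redundancy used by [generate_deletion_profile()];
#'   1 means fully redundant recruitment (a deletion leaves occupancy
#'   unchanged in expectation), 0 fully dependent.
#' @param derepression_slope slope linking co-repressor occupancy to the
#'   log2 expression change of the downstream gene in the deletion strain.
#' @param corepressor name of the co-repressor column.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 6000, n_chrom = 16,
                       region_length = c(200L, 1500L),
                       weights = default_recruiter_weights(),
                       intercept = attr(default_recruiter_weights(), "intercept"),
                       decoys = character(0),
                       bound_fraction = 0.1, mu_bound = 2, occ_sd = 0.5,
                       noise_sd = NULL, target_r2 = 0.43,
                       missing_rate = 0.05,
                       redundancy = 1, derepression_slope = 1,
                       corepressor = "TUP1") {
  if (!is.numeric(n_regions) || length(n_regions) != 1L || n_regions < 10) {
    stop("invalid-config: n_regions must be a single number >= 10")
  }
  if (is.null(names(weights)) || any(names(weights) == "")) {
    stop("invalid-config: weights must be a fully named vector")
  }
  factors <- c(names(weights), decoys)
  if (anyDuplicated(factors)) stop("invalid-config: duplicated factor names")
  if (length(factors) < 1L) stop("invalid-config: at least one factor required")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("invalid-config: missing_rate must be in [0, 1)")
  }
  if (redundancy < 0 || redundancy > 1) {
    stop("invalid-config: redundancy must be in [0, 1]")
  }
  if (is.null(noise_sd)) {
    noise_sd <- calibrate_noise_sd(weights, target_r2, bound_fraction,
                                   mu_bound, occ_sd)
  }
  if (noise_sd < 0) stop("invalid-config: noise_sd must be >= 0")
  structure(list(
    n_regions = as.integer(n_regions), n_chrom = as.integer(n_chrom),
    region_length = as.integer(region_length),
    weights = weights, intercept = intercept, decoys = decoys,
    factors = factors, bound_fraction = bound_fraction, mu_bound = mu_bound,
    occ_sd = occ_sd, noise_sd = noise_sd, missing_rate = missing_rate,
    redundancy = redundancy, derepression_slope = derepression_slope,
    corepressor = corepressor
  ), class = "sim_config")
}

#' Lay out non-overlapping intergenic regions
#'
#' Regions are placed sequentially on `n_chrom` chromosomes with small random
#' gaps, using 0-based half-open coordinates, so that regions on the same
#' chromosome never overlap.
#'
#' @param n_regions number of regions.
#' @param n_chrom number of chromosomes.
#' @param region_length min/max region length in bp.
#' @return data.frame with columns region_id, chrom, start, end, category.
#' @keywords internal
generate_regions <- function(n_regions, n_chrom, region_length) {
  chrom <- sort(rep_len(seq_len(n_chrom), n_regions))
  len <- sample.int(region_length[2] - region_length[1] + 1L, n_regions,
                    replace = TRUE) + region_length[1] - 1L
  gap <- sample.int(500L, n_regions, replace = TRUE)
  start <- integer(n_regions)
  pos <- integer(n_chrom)
  for (i in seq_len(n_regions)) {
    c_i <- chrom[i]
    start[i] <- pos[c_i]
    pos[c_i] <- pos[c_i] + len[i] + gap[i]
  }
  data.frame(
    region_id = sprintf("iYGR%04d", seq_len(n_regions)),
    chrom = sprintf("chr%02d", chrom),
    start = start, end = start + len,
    category = "intergenic",
    stringsAsFactors = FALSE
  )
}

#' Generate a genome-scale synthetic occupancy dataset
#'
#' Draws recruiter occupancy columns from a two-component Gaussian mixture
#' (unbound: Normal(0, occ_sd); bound with probability `bound_fraction`:
#' Normal(mu_bound, occ_sd)), then generates the co-repressor column as
#' `intercept + sum_r beta_r x_r + Normal(0, noise_sd)`. Companion binding
#' p-values are upper-tail probabilities under each factor's unbound (null)
#' component; the co-repressor p-value is computed against its no-recruiter
#' null (all recruiters unbound). A fraction of recruiter entries is then set
#' missing completely at random. The full latent (pre-missingness) matrix and
#' the bound-state indicators are kept as ground truth.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; identical (config, seed) reproduces the dataset
#'   bit-for-bit.
#' @return A list of class `occupancy_dataset` with elements `regions`,
#'   `occupancy` (regions x factors matrix, co-repressor column last),
#'   `pvalues`, and `truth` (planted weights/intercept, noise sd, bound-state
#'   matrix, latent occupancy, planted target ids, redundancy, derepression
#'   slope, seed).
#' @export
#' @examples
#' d <- generate_dataset(sim_config(n_regions = 200), seed = 1)
#' dim(d$occupancy)
generate_dataset <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(names(config$weights) %in% config$factors)) {
    stop("unknown-factor: planted_weights reference a factor not in the panel")
  }
  set.seed(seed)
  regions <- generate_regions(config$n_regions, config$n_chrom,
                              config$region_length)
  n <- config$n_regions
  k <- length(config$factors)
  bound <- matrix(
    stats::runif(n * k) < config$bound_fraction, n, k,
    dimnames = list(regions$region_id, config$factors)
  )
  x <- matrix(
    stats::rnorm(n * k, mean = ifelse(bound, config$mu_bound, 0),
                 sd = config$occ_sd),
    n, k, dimnames = dimnames(bound)
  )
  pv <- stats::pnorm(x, mean = 0, sd = config$occ_sd, lower.tail = FALSE)

  w <- config$weights[config$factors]
  w[is.na(w)] <- 0
  names(w) <- config$factors
  signal <- drop(x %*% w)
  y <- config$intercept + signal + stats::rnorm(n, 0, config$noise_sd)

  # no-recruiter null for the co-repressor column: all recruiters unbound
  null_sd <- sqrt(config$noise_sd^2 + sum(w^2) * config$occ_sd^2)
  y_pv <- stats::pnorm(y, mean = config$intercept, sd = null_sd,
                       lower.tail = FALSE)

  latent <- x
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * k) < config$missing_rate, n, k)
    x[miss] <- NA_real_
    pv[miss] <- NA_real_
  }

  occupancy <- cbind(x, y)
  colnames(occupancy) <- c(config$factors, config$corepressor)
  pvalues <- cbind(pv, y_pv)
  colnames(pvalues) <- colnames(occupancy)
  rownames(occupancy) <- rownames(pvalues) <- regions$region_id

  positive <- names(config$weights)[config$weights > 0]
  planted_targets <- regions$region_id[
    rowSums(bound[, positive, drop = FALSE]) > 0
  ]

  truth <- list(
    planted_weights = config$weights, planted_intercept = config$intercept,
    noise_sd = config$noise_sd, bound = bound, latent_occupancy = latent,
    planted_target_ids = planted_targets,
    redundancy = config$redundancy,
    derepression_slope = config$derepression_slope,
    corepressor = config$corepressor, seed = seed
  )
  structure(list(regions = regions, occupancy = occupancy, pvalues = pvalues,
                 truth = truth, config = config),
            class = "occupancy_dataset")
}

#' @export
print.occupancy_dataset <- function(x, ...) {
  cat(sprintf(
    "occupancy_dataset: %d regions x %d factors (+ %s), noise_sd = %.3f, seed = %s\n",
    nrow(x$occupancy), ncol(x$occupancy) - 1L, x$truth$corepressor,
    x$truth$noise_sd, format(x$truth$seed)
  ))
  invisible(x)
}

#' Generate biological replicate profiles
#'
#' Each replicate is the input profile plus independent Gaussian noise; the
#' per-region mean across replicates converges to the profile as the number of
#' replicates grows.
#'
#' @param profile numeric vector (one factor's occupancy column).
#' @param n_reps number of replicates (>= 1).
#' @param rep_noise_sd replicate noise standard deviation.
#' @param seed integer seed.
#' @return numeric matrix, regions x replicates.
#' @export
generate_replicates <- function(profile, n_reps, rep_noise_sd = 1, seed = 1) {
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1) {
    stop("invalid-config: n_reps must be >= 1")
  }
  n_reps <- as.integer(n_reps)
  set.seed(seed)
  n <- length(profile)
  reps <- matrix(stats::rnorm(n * n_reps, sd = rep_noise_sd), n, n_reps) +
    profile
  colnames(reps) <- sprintf("rep%02d", seq_len(n_reps))
  rownames(reps) <- names(profile)
  reps
}

#' Co-repressor occupancy profile in a recruiter-deletion strain
#'
#' Recomputes the co-repressor column with the deleted recruiter's
#' contribution `beta_d * x_d` multiplied by `redundancy` (1 = fully
#' redundant, occupancy unchanged in expectation; 0 = fully dependent, the
#' deleted factor's contribution is lost) and residual noise re-drawn.
#'
#' @param dataset an `occupancy_dataset`.
#' @param deleted_factor name of the deleted recruiter (must have a planted
#'   weight).
#' @param redundancy value in (0, 1); defaults to the dataset's configured
#'   redundancy.
#' @param seed integer seed for the re-drawn noise.
#' @return numeric vector of deletion-strain co-repressor occupancy, named by
#'   region id.
#' @export
generate_deletion_profile <- function(dataset, deleted_factor,
                                      redundancy = NULL, seed = 1) {
  stopifnot(inherits(dataset, "occupancy_dataset"))
  truth <- dataset$truth
  if (!deleted_factor %in% names(truth$planted_weights)) {
    stop("unknown-factor: '", deleted_factor, "' has no planted weight")
  }
  if (is.null(redundancy)) redundancy <- truth$redundancy
  stopifnot(redundancy >= 0, redundancy <= 1)
  set.seed(seed)
  w <- truth$planted_weights
  x <- truth$latent_occupancy[, names(w), drop = FALSE]
  contrib <- drop(x %*% w)
  del_term <- (1 - redundancy) * w[[deleted_factor]] * x[, deleted_factor]
  y <- truth$planted_intercept + contrib - del_term +
    stats::rnorm(nrow(x), 0, truth$noise_sd)
  names(y) <- rownames(x)
  y
}

#' Generate region sequences with planted motif sites
#'
#' Background bases are drawn i.i.d. from `background`; for each factor in the
#' planting rule, one site sampled from the factor's PWM probabilities is
#' written into each designated region at a random offset and strand, and the
#' insertion recorded.
#'
#' @param regions data.frame with region_id and end-start lengths (as produced
#'   by [generate_dataset()]).
#' @param pwms named list of [pwm()] objects.
#' @param plant named list: factor name -> character vector of region_ids that
#'   receive one planted site each. Use `list()` for no planting.
#' @param seed integer seed.
#' @param background length-4 base probabilities (A, C, G, T).
#' @return list with `sequences` (a [Biostrings::DNAStringSet] named by
#'   region_id) and `sites` (data.frame: region_id, factor, offset, strand,
#'   site).
#' @export
generate_sequences <- function(regions, pwms, plant = list(), seed = 1,
                               background = rep(0.25, 4)) {
  stopifnot(is.data.frame(regions), all(c("region_id", "start", "end") %in%
                                          names(regions)))
  lens <- regions$end - regions$start
  widths <- vapply(pwms, function(p) nrow(p$matrix), integer(1))
  if (length(widths) && any(lens < max(widths))) {
    stop("region-too-short: every region must be at least as long as the ",
         "longest PWM (", max(widths), " bp)")
  }
  bad <- setdiff(names(plant), names(pwms))
  if (length(bad)) stop("unknown-factor: no PWM for ", paste(bad, collapse = ", "))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  big <- paste(sample(bases, sum(lens), replace = TRUE, prob = background),
               collapse = "")
  ends <- cumsum(lens)
  seqs <- substring(big, ends - lens + 1L, ends)
  names(seqs) <- regions$region_id

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  sites <- list()
  for (factor in names(plant)) {
    p <- pwms[[factor]]
    w <- nrow(p$matrix)
    ids <- plant[[factor]]
    missing_ids <- setdiff(ids, regions$region_id)
    if (length(missing_ids)) {
      stop("unknown-region: ", paste(missing_ids, collapse = ", "))
    }
    m <- length(ids)
    if (m == 0L) next
    L <- lens[match(ids, regions$region_id)]
    site_mat <- vapply(seq_len(w), function(j) {
      sample(bases, m, replace = TRUE, prob = p$matrix[j, ])
    }, character(m))
    site_mat <- matrix(site_mat, nrow = m)
    site_seq <- do.call(paste0, as.data.frame(site_mat,
                                              stringsAsFactors = FALSE))
    rc_mat <- matrix(comp[site_mat[, rev(seq_len(w)), drop = FALSE]],
                     nrow = m)
    rc_seq <- do.call(paste0, as.data.frame(rc_mat, stringsAsFactors = FALSE))
    strand <- sample(c("+", "-"), m, replace = TRUE)
    inserted <- ifelse(strand == "+", site_seq, rc_seq)
    offset <- vapply(L - w + 1L, function(u) sample.int(u, 1L),
                     integer(1)) - 1L
    for (t in seq_len(m)) {
      s <- seqs[[ids[t]]]
      substr(s, offset[t] + 1L, offset[t] + w) <- inserted[t]
      seqs[[ids[t]]] <- s
    }
    sites[[factor]] <- data.frame(
      region_id = ids, factor = factor, offset = offset, strand = strand,
      site = site_seq, stringsAsFactors = FALSE
    )
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(region_id = character(0), factor = character(0),
               offset = integer(0), strand = character(0),
               site = character(0), stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  list(sequences = Biostrings::DNAStringSet(seqs), sites = sites)
}

#' Map genes to upstream regulatory regions
#'
#' Convenience generator of a gene map: a fraction of regions each get one
#' downstream gene (emulating unidirectional promoters); remaining genes are
#' unmapped and will carry pure noise in [generate_expression()].
#'
#' @param regions region table.
#' @param mapped_fraction fraction of regions with a mapped gene.
#' @param n_unmapped number of additional genes with no regulatory region.
#' @param seed integer seed.
#' @return data.frame: gene_id, region_id (NA when unmapped), orientation.
#' @export
make_gene_map <- function(regions, mapped_fraction = 0.8, n_unmapped = 0,
                          seed = 1) {
  set.seed(seed)
  ids <- regions$region_id
  mapped <- sort(sample.int(length(ids), round(mapped_fraction * length(ids))))
  gm <- data.frame(
    gene_id = sprintf("YGENE%05d", seq_len(length(mapped) + n_unmapped)),
    region_id = c(ids[mapped], rep(NA_character_, n_unmapped)),
    orientation = "+",
    stringsAsFactors = FALSE
  )
  gm
}

#' Simulate deletion-strain expression changes (derepression)
#'
#' Each mapped gene's log2 expression change in the co-repressor deletion
#' strain is `slope * occupancy(region) + Normal(0, noise_sd)`; genes without
#' an assigned region receive pure noise. Positive slope encodes
#' derepression: the more co-repressor was bound upstream, the more the gene
#' goes up when the co-repressor is deleted.
#'
#' @param dataset an `occupancy_dataset`.
#' @param gene_map data.frame gene_id, region_id (NA allowed), orientation.
#' @param slope derepression slope; defaults to the dataset's configured value.
#' @param noise_sd expression noise sigma.
#' @param seed integer seed.
#' @return data.frame: gene_id, region_id, log2_change.
#' @export
generate_expression <- function(dataset, gene_map, slope = NULL,
                                noise_sd = 1, seed = 1) {
  stopifnot(inherits(dataset, "occupancy_dataset"))
  if (is.null(slope)) slope <- dataset$truth$derepression_slope
  ids <- dataset$regions$region_id
  known <- is.na(gene_map$region_id) | gene_map$region_id %in% ids
  if (!all(known)) {
    stop("unknown-region: ",
         paste(unique(gene_map$region_id[!known]), collapse = ", "))
  }
  if (anyDuplicated(stats::na.omit(gene_map$region_id))) {
    stop("invalid-config: a region may host at most one mapped gene")
  }
  set.seed(seed)
  y <- dataset$occupancy[, dataset$truth$corepressor]
  occ <- ifelse(is.na(gene_map$region_id), 0,
                y[match(gene_map$region_id, ids)])
  change <- slope * occ + stats::rnorm(nrow(gene_map), 0, noise_sd)
  data.frame(gene_id = gene_map$gene_id, region_id = gene_map$region_id,
             log2_change = change, stringsAsFactors = FALSE)
}

#' Generate a random informative PWM
#'
#' Produces a motif of the given width whose columns are Dirichlet-like draws
#' concentrated on one preferred base per position; useful for decoy factors
#' in screen simulations.
#'
#' @param name factor name.
#' @param width motif width in bp.
#' @param concentration weight on the preferred base (0.25 = uninformative,
#'   near 1 = sharp consensus).
#' @param background length-4 background probabilities.
#' @return a [pwm()] object.
#' @export
random_pwm <- function(name, width = 8L, concentration = 0.95,
                       background = rep(0.25, 4)) {
  m <- matrix((1 - concentration) / 3, width, 4)
  pref <- sample.int(4L, width, replace = TRUE)
  m[cbind(seq_len(width), pref)] <- concentration
  pwm(name, m, background)
}
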