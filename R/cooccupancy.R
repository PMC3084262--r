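#' Classify co-repressor targets by cofactor co-occupancy
#'
#' A target is co-occupied iff at least one cofactor binds it at
#' `p < p_bind`; targets whose cofactor p-values are all missing are flagged
#' `no-data`; the rest are `not-co-occupied`.
#'
#' @param target_ids character vector of target region ids.
#' @param cofactor_pvals regions x cofactors matrix of binding p-values
#'   (rownames = region ids; NA allowed).
#' @param p_bind binding p-value threshold.
#' @return data.frame: region_id, status, n_bound, cofactors_bound
#'   (comma-separated; empty unless co-occupied), plus a `counts` attribute
#'   with the per-status tally.
#' @export
classify_targets <- function(target_ids, cofactor_pvals, p_bind = 0.001) {
  stopifnot(p_bind > 0, p_bind < 1 || p_bind == 1)
  idx <- match(target_ids, rownames(cofactor_pvals))
  if (all(is.na(idx))) {
    stop("empty-join: no target ids found in the cofactor p-value table")
  }
  status <- character(length(target_ids))
  n_bound <- integer(length(target_ids))
  bound_names <- character(length(target_ids))
  for (i in seq_along(target_ids)) {
    if (is.na(idx[i])) {
      status[i] <- "no-data"
      next
    }
    p <- cofactor_pvals[idx[i], ]
    if (all(is.na(p))) {
      status[i] <- "no-data"
    } else {
      hit <- which(!is.na(p) & p < p_bind)
      n_bound[i] <- length(hit)
      if (length(hit)) {
        status[i] <- "co-occupied"
        bound_names[i] <- paste(colnames(cofactor_pvals)[hit], collapse = ",")
      } else {
        status[i] <- "not-co-occupied"
      }
    }
  }
  out <- data.frame(region_id = target_ids, status = status,
                    n_bound = n_bound, cofactors_bound = bound_names,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(factor(
    status, levels = c("co-occupied", "not-co-occupied", "no-data")))
  out
}

#' Bin targets by the number of bound recruiters
#'
#' For each target, counts the recruiters bound at `p < p_bind` (missing
#' p-values never count), groups targets by that count, and summarises the
#' co-repressor Z per group.
#'
#' @param corepressor_z named numeric vector of co-repressor Z over targets.
#' @param cofactor_pvals regions x factors p-value matrix.
#' @param recruiters character vector of recruiter column names.
#' @param p_bind binding threshold.
#' @return data.frame: k (recruiter count), n_targets, mean_z, se_z,
#'   single_member (TRUE where n = 1, se reported as 0).
#' @export
bin_by_recruiter_count <- function(corepressor_z, cofactor_pvals, recruiters,
                                   p_bind = 0.001) {
  stopifnot(length(recruiters) >= 1L)
  counts <- count_bound(names(corepressor_z), cofactor_pvals, recruiters,
                        p_bind)
  out <- do.call(rbind, lapply(split(seq_along(counts), counts), function(ix) {
    z <- corepressor_z[ix]
    n <- length(ix)
    data.frame(k = counts[ix[1]], n_targets = n, mean_z = mean(z),
               se_z = if (n > 1L) stats::sd(z) / sqrt(n) else 0,
               single_member = n == 1L)
  }))
  rownames(out) <- NULL
  out
}

#' Count bound factors per region
#'
#' @param region_ids regions to count over.
#' @param cofactor_pvals regions x factors p-value matrix.
#' @param factors factor columns to consider.
#' @param p_bind binding threshold; missing entries never count as bound.
#' @return integer vector named by region id.
#' @export
count_bound <- function(region_ids, cofactor_pvals, factors, p_bind = 0.001) {
  pv <- cofactor_pvals[match(region_ids, rownames(cofactor_pvals)),
                       factors, drop = FALSE]
  counts <- rowSums(!is.na(pv) & pv < p_bind)
  counts[is.na(match(region_ids, rownames(cofactor_pvals)))] <- 0
  out <- as.integer(counts)
  names(out) <- region_ids
  out
}

#' Regress occupancy on recruiter count
#'
#' Ordinary least squares of co-repressor occupancy on the number of bound
#' recruiters, as a single numeric regressor.
#'
#' @param occupancy_z numeric vector.
#' @param counts non-negative integer vector of the same length.
#' @return list: slope, intercept, r_squared, p_value (slope t-test).
#' @export
regress_on_count <- function(occupancy_z, counts) {
  stopifnot(length(occupancy_z) == length(counts), length(counts) >= 3L,
            all(counts >= 0))
  if (stats::var(counts) == 0) {
    stop("degenerate-regressor: counts are constant")
  }
  fit <- stats::lm(occupancy_z ~ counts)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4])
}

#' Scale occupancy profiles to a common reference
#'
#' Each profile is multiplied by the factor that makes its mean over the
#' bound regions equal to the reference profile's mean over the same
#' regions; this controls for IP-efficiency differences between experiments
#' before comparing wild-type and deletion strains.
#'
#' @param profiles named list of numeric vectors (region-id named), the first
#'   (or `reference`) being the reference experiment.
#' @param bound_region_ids region ids over which means are equalised.
#' @param reference name or index of the reference profile.
#' @return named list of scaled profiles, with scale factors in the
#'   `"scale_factors"` attribute.
#' @export
scale_to_reference <- function(profiles, bound_region_ids, reference = 1L) {
  stopifnot(length(bound_region_ids) >= 1L, length(profiles) >= 1L)
  means <- vapply(profiles, function(p) {
    mean(p[bound_region_ids])
  }, numeric(1))
  ref_mean <- means[[reference]]
  if (any(!is.finite(means)) || any(means == 0)) {
    stop("unscalable-profile: a profile has zero or undefined mean over the ",
         "bound regions")
  }
  factors <- ref_mean / means
  out <- Map(function(p, f) p * f, profiles, factors)
  attr(out, "scale_factors") <- factors
  out
}

#' Compare wild-type and deletion-strain occupancy by target group
#'
#' For each group of regions (e.g. targets bound by a given cofactor, or
#' targets containing its motif), reports the wild-type and deletion-strain
#' mean Z with standard errors and a paired t-test on the per-region
#' difference. Profiles should be put on a common scale with
#' [scale_to_reference()] first.
#'
#' @param wt_z,del_z region-id named numeric vectors.
#' @param groups named list: group name -> region ids.
#' @return data.frame: group, n, mean_wt, mean_del, se_wt, se_del, p_value
#'   (NA with a warning for groups of fewer than 2 members).
#' @export
group_comparison <- function(wt_z, del_z, groups) {
  stopifnot(length(groups) >= 1L)
  out <- lapply(names(groups), function(g) {
    ids <- intersect(groups[[g]], intersect(names(wt_z), names(del_z)))
    n <- length(ids)
    wt <- wt_z[ids]; del <- del_z[ids]
    p <- NA_real_
    if (n < 2L) {
      warning("insufficient-group: '", g, "' has fewer than 2 members; ",
              "means reported, test skipped")
    } else {
      d <- wt - del
      p <- if (stats::sd(d) == 0) {
        if (mean(d) == 0) 1 else 0
      } else {
        stats::t.test(wt, del, paired = TRUE)$p.value
      }
    }
    data.frame(group = g, n = n,
               mean_wt = mean(wt), mean_del = mean(del),
               se_wt = if (n > 1) stats::sd(wt) / sqrt(n) else 0,
               se_del = if (n > 1) stats::sd(del) / sqrt(n) else 0,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# region-level expression vector: log2 change of the gene mapped to each region
expression_by_region <- function(expression, gene_map) {
  gm <- gene_map[!is.na(gene_map$region_id), , drop = FALSE]
  ex <- expression$log2_change[match(gm$gene_id, expression$gene_id)]
  stats::setNames(ex, gm$region_id)
}

#' Derepression test: bound versus unbound targets
#'
#' Welch two-sample t-test comparing the deletion-strain expression change of
#' genes downstream of bound regions (binding `p < 0.001` by default) against
#' genes downstream of unbound regions (`p > 0.05`); regions in between are
#' excluded from both groups.
#'
#' @param expression data.frame gene_id, log2_change.
#' @param bound_ids,unbound_ids region id vectors for the two groups.
#' @param gene_map data.frame gene_id, region_id.
#' @return list: mean_bound, mean_unbound, se_bound, se_unbound, n_bound,
#'   n_unbound, p_value.
#' @export
derepression_test <- function(expression, bound_ids, unbound_ids, gene_map) {
  ex <- expression_by_region(expression, gene_map)
  b <- ex[names(ex) %in% bound_ids]
  u <- ex[names(ex) %in% unbound_ids]
  b <- b[!is.na(b)]; u <- u[!is.na(u)]
  if (length(b) < 2L || length(u) < 2L) {
    stop("empty-group: need >= 2 mapped genes in each of bound and unbound")
  }
  tt <- stats::t.test(b, u, var.equal = FALSE)
  list(mean_bound = mean(b), mean_unbound = mean(u),
       se_bound = stats::sd(b) / sqrt(length(b)),
       se_unbound = stats::sd(u) / sqrt(length(u)),
       n_bound = length(b), n_unbound = length(u),
       p_value = tt$p.value)
}

#' Decile binning of genes by derepression
#'
#' Genes with a mapped region are ranked by expression change and split into
#' `n_bins` equal-count bins (ties broken by stable input order); the mean
#' ChIP Z of the corresponding regions is reported per bin.
#'
#' @param expression data.frame gene_id, log2_change.
#' @param chip_z region-id named numeric vector of ChIP Z-scores.
#' @param gene_map data.frame gene_id, region_id.
#' @param n_bins number of bins (default 10).
#' @return data.frame: bin (1 = least derepressed), n, mean_change, mean_z.
#' @export
decile_binning <- function(expression, chip_z, gene_map, n_bins = 10L) {
  gm <- gene_map[!is.na(gene_map$region_id), , drop = FALSE]
  change <- expression$log2_change[match(gm$gene_id, expression$gene_id)]
  z <- chip_z[gm$region_id]
  keep <- !is.na(change) & !is.na(z)
  change <- change[keep]; z <- z[keep]
  n <- length(change)
  if (n < n_bins) stop("insufficient-genes: ", n, " mapped genes for ",
                       n_bins, " bins")
  ord <- order(change)  # stable for ties
  bin <- rep(seq_len(n_bins), diff(floor(seq(0, n, length.out = n_bins + 1))))
  out <- data.frame(
    bin = seq_len(n_bins),
    n = as.integer(tabulate(bin, n_bins)),
    mean_change = vapply(split(change[ord], bin), mean, numeric(1)),
    mean_z = vapply(split(z[ord], bin), mean, numeric(1))
  )
  rownames(out) <- NULL
  out
}
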