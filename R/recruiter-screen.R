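#' Motif over-representation among targets
#'
#' One-sided binomial test for enrichment of a factor's motif among target
#' regions relative to the rest of the genome: with `k` of `n` target
#' regions containing at least one site (per-position p-value below
#' `p_threshold` on either strand) and a background rate estimated as the
#' fraction of background regions containing a site, returns
#' `P(X >= k), X ~ Binomial(n, rate)`. The background rate is clamped below
#' by `1 / (2 * n_background)` to avoid a degenerate zero-rate null.
#'
#' @param target_seqs,background_seqs `Biostrings::DNAStringSet` (or named
#'   character vectors) for target and background regions.
#' @param pwm a [pwm()] object.
#' @param p_threshold per-site score p-value cutoff.
#' @return list: p_value, k, n, background_rate.
#' @export
motif_overrepresentation <- function(target_seqs, background_seqs, pwm,
                                     p_threshold = 0.005) {
  if (length(target_seqs) == 0L || length(background_seqs) == 0L) {
    stop("empty-input: both region sets must be non-empty")
  }
  k <- sum(pwm_hit_regions(target_seqs, pwm, p_threshold))
  n <- length(target_seqs)
  bg_hits <- sum(pwm_hit_regions(background_seqs, pwm, p_threshold))
  rate <- max(bg_hits / length(background_seqs),
              1 / (2 * length(background_seqs)))
  rate <- min(rate, 1)
  p <- stats::pbinom(k - 1L, n, rate, lower.tail = FALSE)
  list(p_value = p, k = k, n = n, background_rate = rate)
}

#' Sensitivity of a factor for the co-repressor's targets
#'
#' Fraction of co-repressor targets bound by the factor:
#' `|tf_bound / corepressor targets| / |corepressor targets|`.
#'
#' @param tf_bound_ids region ids bound by the factor (p < 0.001).
#' @param target_ids co-repressor target region ids.
#' @return value in `[0, 1]`.
#' @export
sensitivity <- function(tf_bound_ids, target_ids) {
  if (length(target_ids) == 0L) {
    stop("empty-denominator: no co-repressor targets")
  }
  length(intersect(tf_bound_ids, target_ids)) / length(unique(target_ids))
}

#' Specificity of a factor for the co-repressor's targets
#'
#' Fraction of the factor's own binding sites that fall within co-repressor
#' targets. A factor with no bound sites has no specificity test; `NA` is
#' returned (the test is marked missing, not an error).
#'
#' @inheritParams sensitivity
#' @return value in `[0, 1]`, or `NA` when the factor binds nowhere.
#' @export
specificity <- function(tf_bound_ids, target_ids) {
  if (length(tf_bound_ids) == 0L) return(NA_real_)
  length(intersect(tf_bound_ids, target_ids)) / length(unique(tf_bound_ids))
}

#' Top-quartile correlation of two occupancy measures
#'
#' Pearson correlation of paired measurements computed over the union of the
#' two top quartiles: indices whose x ranks in the top quarter of x or whose
#' y ranks in the top quarter of y (quartile boundary at `ceiling(n/4)` by
#' descending rank, ties broken by stable index order). Pairs with a missing
#' value are excluded before quartiling. This focuses the correlation on the
#' informative (occupied) end of both measures without hard target
#' selection.
#'
#' @param x,y paired numeric vectors.
#' @param min_pairs minimum complete pairs required; below it the test is
#'   marked missing (`NA`).
#' @return Pearson r over the union subset, or `NA` when there are too few
#'   complete pairs or the subset has zero variance in either variable.
#' @export
quartile_correlation <- function(x, y, min_pairs = 8L) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < min_pairs) return(NA_real_)
  k <- ceiling(n / 4)
  top_x <- order(-x)[seq_len(k)]
  top_y <- order(-y)[seq_len(k)]
  sel <- union(top_x, top_y)
  if (stats::sd(x[sel]) == 0 || stats::sd(y[sel]) == 0) return(NA_real_)
  stats::cor(x[sel], y[sel])
}

#' Percentile ranks across a factor panel
#'
#' Ascending mid-ranks (ties averaged) over the non-missing scores, scaled
#' to `100 * rank / n_nonmissing`; the best untied score gets 100, and
#' missing scores stay missing. Percent ranks are invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores named numeric vector, NA = factor lacks this test.
#' @return named numeric vector of percent ranks in (0, 100], NA preserved.
#' @export
percent_ranks <- function(scores) {
  ok <- !is.na(scores)
  if (sum(ok) < 2L) stop("degenerate-panel: need >= 2 non-missing scores")
  out <- rep(NA_real_, length(scores))
  names(out) <- names(scores)
  r <- rank(scores[ok], ties.method = "average")
  out[ok] <- 100 * r / sum(ok)
  out
}

#' Aggregate per-test percent ranks into a recruiter ranking
#'
#' The composite score of a factor is the mean of its available percent
#' ranks (tests the factor lacks are simply not averaged). Factors are
#' sorted descending by average rank; ties are broken by the number of tests
#' used (more first), then by name. Factors with no available test are
#' dropped with a warning.
#'
#' @param rank_table data.frame or matrix of percent ranks, one row per
#'   factor (rownames = factor names), one column per test.
#' @return data.frame: factor, the per-test percent ranks, average_rank,
#'   n_tests_used; sorted best-first.
#' @export
aggregate_ranks <- function(rank_table) {
  rank_table <- as.matrix(rank_table)
  n_tests <- rowSums(!is.na(rank_table))
  if (any(n_tests == 0L)) {
    warning("factors with zero available tests dropped: ",
            paste(rownames(rank_table)[n_tests == 0L], collapse = ", "))
    rank_table <- rank_table[n_tests > 0L, , drop = FALSE]
    n_tests <- n_tests[n_tests > 0L]
  }
  avg <- rowMeans(rank_table, na.rm = TRUE)
  ord <- order(-avg, -n_tests, rownames(rank_table))
  out <- data.frame(factor = rownames(rank_table),
                    rank_table,
                    average_rank = avg,
                    n_tests_used = as.integer(n_tests),
                    stringsAsFactors = FALSE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Five-test composite screen for candidate recruiters
#'
#' Runs, for every factor in the panel, the five predictive tests: (a) motif
#' over-representation among co-repressor targets versus the rest of the
#' genome (entered as -log10 p; missing for factors without a PWM), (b)
#' sensitivity — the fraction of co-repressor targets the factor binds, (c)
#' specificity — the fraction of the factor's sites inside co-repressor
#' targets (missing for factors binding nowhere), (d) top-quartile
#' correlation of factor occupancy with co-repressor occupancy, and (e)
#' top-quartile correlation of factor occupancy with deletion-strain
#' expression change of downstream genes. Each test's raw scores are turned
#' into percent ranks over the panel and averaged over the tests available
#' to each factor.
#'
#' @param corepressor_z region-id named co-repressor occupancy vector.
#' @param target_ids co-repressor target region ids.
#' @param occupancy regions x factors log2-ratio matrix.
#' @param pvalues companion binding p-value matrix.
#' @param factors factor columns to screen.
#' @param expression optional data.frame gene_id, log2_change (test e).
#' @param gene_map optional gene-to-region map for test (e).
#' @param sequences optional region sequences (test a).
#' @param pwms optional named list of [pwm()] objects (test a).
#' @param p_bind binding-call threshold for tests (b) and (c).
#' @param motif_p per-site motif call threshold for test (a).
#' @return list with `scorecard` (the sorted [aggregate_ranks()] table) and
#'   `raw` (per-test raw scores).
#' @export
run_recruiter_screen <- function(corepressor_z, target_ids, occupancy,
                                 pvalues, factors = colnames(occupancy),
                                 expression = NULL, gene_map = NULL,
                                 sequences = NULL, pwms = NULL,
                                 p_bind = 0.001, motif_p = 0.005) {
  stopifnot(length(factors) >= 2L, length(target_ids) >= 1L)
  region_ids <- rownames(occupancy)
  raw <- matrix(NA_real_, length(factors), 5,
                dimnames = list(factors, c("motif_enrichment", "sensitivity",
                                           "specificity",
                                           "binding_correlation",
                                           "expression_correlation")))

  expr_region <- if (!is.null(expression) && !is.null(gene_map)) {
    expression_by_region(expression, gene_map)[region_ids]
  } else NULL

  if (!is.null(sequences) && !is.null(pwms)) {
    seq_ids <- names(sequences)
    tgt <- encode_sequences(sequences[seq_ids %in% target_ids])
    bg <- encode_sequences(sequences[!seq_ids %in% target_ids])
  }

  for (f in factors) {
    pv <- pvalues[, f]
    bound <- region_ids[!is.na(pv) & pv < p_bind]
    raw[f, "sensitivity"] <- sensitivity(bound, target_ids)
    raw[f, "specificity"] <- specificity(bound, target_ids)
    raw[f, "binding_correlation"] <-
      quartile_correlation(occupancy[, f], corepressor_z[region_ids])
    if (!is.null(expr_region)) {
      raw[f, "expression_correlation"] <-
        quartile_correlation(occupancy[, f], expr_region)
    }
    if (!is.null(sequences) && !is.null(pwms) && f %in% names(pwms) &&
        length(tgt) && length(bg)) {
      ov <- motif_overrepresentation(tgt, bg, pwms[[f]], motif_p)
      raw[f, "motif_enrichment"] <- -log10(max(ov$p_value, 1e-300))
    }
  }

  ranks <- apply(raw, 2, function(col) {
    if (sum(!is.na(col)) < 2L) return(rep(NA_real_, length(col)))
    percent_ranks(col)
  })
  rownames(ranks) <- factors
  list(scorecard = aggregate_ranks(ranks), raw = as.data.frame(raw))
}
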