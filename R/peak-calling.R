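#' Standardize biological replicates and take the per-element median
#'
#' Each replicate is Z-transformed (mean 0, sd 1 across its array elements);
#' the profile value of each element is the median of its standardized values
#' across replicates. This puts all replicates on a common enrichment scale
#' before peak detection.
#'
#' @param replicates numeric matrix (elements x replicates) or list of equal
#'   length numeric vectors.
#' @param regions data.frame with region_id, chrom, start, end describing the
#'   array elements, in the same row order.
#' @return A `signal_profile` data.frame (region_id, chrom, start, end,
#'   value) sorted by (chrom, start).
#' @export
standardize_replicates <- function(replicates, regions) {
  if (is.list(replicates) && !is.data.frame(replicates)) {
    replicates <- do.call(cbind, replicates)
  }
  replicates <- as.matrix(replicates)
  stopifnot(nrow(replicates) == nrow(regions), ncol(replicates) >= 1L)
  sds <- apply(replicates, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate-replicate: replicate ", which(sds == 0)[1],
         " has zero variance")
  }
  z <- scale(replicates)
  value <- apply(z, 1, stats::median)
  out <- data.frame(region_id = regions$region_id, chrom = regions$chrom,
                    start = regions$start, end = regions$end,
                    value = value, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signal_profile", "data.frame")
  out
}

#' Fit the Gaussian background null by reflection
#'
#' Enrichment is assumed one-sided (signal only inflates the upper tail), so
#' the null is estimated from the sub-median half of the data: mu is the
#' median, and sigma the root mean square deviation of the sub-median values
#' about it (equivalently, of the lower half reflected about the median).
#' This makes the fit robust to positive signal contamination.
#'
#' @param values numeric vector of profile values (>= 2 required; >= 100
#'   recommended).
#' @return list with `mu` and `sigma`.
#' @export
estimate_background <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("degenerate-profile: need >= 2 finite values")
  mu <- stats::median(values)
  lower <- values[values <= mu]
  sigma <- sqrt(mean((lower - mu)^2))
  if (sigma == 0) stop("degenerate-profile: constant values")
  list(mu = mu, sigma = sigma)
}

#' Score sliding windows against the Gaussian background
#'
#' Per chromosome, candidate windows `[k * step, k * step + window)` are laid
#' across the span of the array elements; each window is scored by the mean
#' value of the elements it overlaps, and assigned the upper-tail probability
#' of that mean under the fitted background null (`Normal(mu, sigma /
#' sqrt(n))` for `n` contributing elements). Windows overlapping no element
#' are skipped. When a chromosome's element span is shorter than the window,
#' a single window anchored at the span start is used.
#'
#' @param profile a `signal_profile` data.frame.
#' @param window_bp window size in bp.
#' @param step_bp step size in bp; must satisfy `window_bp >= step_bp > 0`.
#' @param background optional list(mu, sigma); fitted from the profile with
#'   [estimate_background()] when `NULL`.
#' @return data.frame of windows: chrom, window_start, window_end,
#'   n_elements, mean_z, p_value.
#' @export
call_windows <- function(profile, window_bp = 1000, step_bp = 250,
                         background = NULL) {
  if (nrow(profile) == 0L) stop("empty-input: profile has no elements")
  stopifnot(window_bp >= step_bp, step_bp > 0)
  if (is.null(background)) background <- estimate_background(profile$value)
  out <- lapply(split(profile, profile$chrom), function(p) {
    span_start <- min(p$start)
    span_end <- max(p$end)
    last_start <- span_end - window_bp
    starts <- if (last_start < span_start) span_start else
      seq(span_start, last_start, by = step_bp)
    nw <- length(starts)
    n_el <- integer(nw)
    mean_z <- numeric(nw)
    for (i in seq_len(nw)) {
      hit <- p$start < starts[i] + window_bp & p$end > starts[i]
      n_el[i] <- sum(hit)
      if (n_el[i] > 0L) mean_z[i] <- mean(p$value[hit])
    }
    keep <- n_el > 0L
    data.frame(chrom = p$chrom[1], window_start = starts[keep],
               window_end = starts[keep] + window_bp,
               n_elements = n_el[keep], mean_z = mean_z[keep],
               p_value = stats::pnorm(mean_z[keep], background$mu,
                                      background$sigma / sqrt(n_el[keep]),
                                      lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "background") <- background
  out
}

#' Benjamini-Hochberg filter on window p-values
#'
#' Step-up q-values are computed over all tested windows; windows with
#' q below the cutoff are retained.
#'
#' @param windows window table from [call_windows()].
#' @param fdr q-value cutoff (peaks kept at q < fdr).
#' @return the significant subset of `windows` with a `q_value` column added.
#' @export
fdr_filter <- function(windows, fdr = 0.001) {
  stopifnot(all(windows$p_value >= 0 & windows$p_value <= 1))
  windows$q_value <- stats::p.adjust(windows$p_value, method = "BH")
  out <- windows[windows$q_value < fdr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach the highest-valued covering element to each window
#'
#' @param windows window table (chrom, window_start, window_end).
#' @param profile the `signal_profile` the windows were scored on.
#' @return `windows` with representative_element and representative_z added.
#' @export
annotate_representatives <- function(windows, profile) {
  if (nrow(windows) == 0L) {
    windows$representative_element <- character(0)
    windows$representative_z <- numeric(0)
    return(windows)
  }
  rep_el <- character(nrow(windows))
  rep_z <- numeric(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    p <- profile[profile$chrom == windows$chrom[i] &
                   profile$start < windows$window_end[i] &
                   profile$end > windows$window_start[i], , drop = FALSE]
    j <- which.max(p$value)
    rep_el[i] <- p$region_id[j]
    rep_z[i] <- p$value[j]
  }
  windows$representative_element <- rep_el
  windows$representative_z <- rep_z
  windows
}

#' Filter peaks against a mock-IP control
#'
#' A peak is retained iff its representative element's signal Z exceeds the
#' mock Z at the same element by more than 1 and the mock Z itself is below
#' 2. The comparison is element-wise on standardized values.
#'
#' @param peaks window/peak table with `representative_element` and
#'   `representative_z` columns (see [annotate_representatives()] /
#'   [call_peaks()]).
#' @param mock_profile a `signal_profile` for the mock IP covering the same
#'   elements.
#' @param z_margin required signal-minus-mock margin.
#' @param mock_max maximum allowed mock Z.
#' @return the retained subset of `peaks`, with a `mock_z` column added.
#' @export
mock_filter <- function(peaks, mock_profile, z_margin = 1, mock_max = 2) {
  idx <- match(peaks$representative_element, mock_profile$region_id)
  if (anyNA(idx) && nrow(peaks) > 0L) {
    stop("missing-mock-coverage: elements absent from mock profile: ",
         paste(peaks$representative_element[is.na(idx)], collapse = ", "))
  }
  mock_z <- mock_profile$value[idx]
  keep <- (peaks$representative_z - mock_z) > z_margin & mock_z < mock_max
  out <- peaks[which(keep), , drop = FALSE]
  out$mock_z <- mock_z[which(keep)]
  rownames(out) <- NULL
  out
}

#' Collapse neighbouring peaks
#'
#' Peaks on the same chromosome whose windows lie within `gap_bp` of one
#' another are merged into one peak spanning their union; the representative
#' element of a merged peak is the highest-valued element across the merged
#' span, its mean_z the maximum window mean, its p/q the minima. The
#' operation is idempotent and independent of input order.
#'
#' @param peaks window/peak table (chrom, window_start, window_end, mean_z,
#'   p_value, optionally q_value).
#' @param profile the `signal_profile` used to (re)derive representative
#'   elements over merged spans.
#' @param gap_bp maximum gap merged across.
#' @return A `peak_set` data.frame: chrom, window_start, window_end, mean_z,
#'   p_value, q_value, representative_element, representative_z.
#' @export
collapse_peaks <- function(peaks, profile, gap_bp = 1000) {
  if (nrow(peaks) == 0L) {
    out <- annotate_representatives(peaks, profile)
    class(out) <- c("peak_set", "data.frame")
    return(out)
  }
  peaks <- peaks[order(peaks$chrom, peaks$window_start), , drop = FALSE]
  grp <- integer(nrow(peaks))
  g <- 1L
  grp[1] <- g
  if (nrow(peaks) > 1L) {
    cur_end <- peaks$window_end[1]
    for (i in 2:nrow(peaks)) {
      same <- peaks$chrom[i] == peaks$chrom[i - 1L]
      if (same && peaks$window_start[i] - cur_end <= gap_bp) {
        cur_end <- max(cur_end, peaks$window_end[i])
      } else {
        g <- g + 1L
        cur_end <- peaks$window_end[i]
      }
      grp[i] <- g
    }
  }
  merged <- do.call(rbind, lapply(split(peaks, grp), function(p) {
    data.frame(chrom = p$chrom[1],
               window_start = min(p$window_start),
               window_end = max(p$window_end),
               n_elements = NA_integer_,
               mean_z = max(p$mean_z),
               p_value = min(p$p_value),
               q_value = if ("q_value" %in% names(p)) min(p$q_value) else
                 NA_real_,
               stringsAsFactors = FALSE)
  }))
  merged <- annotate_representatives(merged, profile)
  el_n <- vapply(seq_len(nrow(merged)), function(i) {
    sum(profile$chrom == merged$chrom[i] &
          profile$start < merged$window_end[i] &
          profile$end > merged$window_start[i])
  }, integer(1))
  merged$n_elements <- el_n
  merged <- merged[order(merged$chrom, merged$window_start), , drop = FALSE]
  rownames(merged) <- NULL
  class(merged) <- c("peak_set", "data.frame")
  merged
}

#' Call co-repressor binding peaks from a standardized profile
#'
#' The full detection pipeline: sliding windows scored against the reflected
#' Gaussian background ([call_windows()]), Benjamini-Hochberg FDR control
#' ([fdr_filter()]), optional mock-IP filtering on representative elements
#' ([mock_filter()]), and collapsing of neighbouring windows
#' ([collapse_peaks()]).
#'
#' @param profile a `signal_profile` (see [standardize_replicates()]).
#' @param mock_profile optional mock-IP `signal_profile`.
#' @param window_bp,step_bp sliding-window geometry.
#' @param fdr q-value cutoff.
#' @param gap_bp collapse distance.
#' @return a `peak_set` data.frame (see [collapse_peaks()]).
#' @export
call_peaks <- function(profile, mock_profile = NULL, window_bp = 1000,
                       step_bp = 250, fdr = 0.001, gap_bp = 1000) {
  windows <- call_windows(profile, window_bp, step_bp)
  sig <- fdr_filter(windows, fdr)
  sig <- annotate_representatives(sig, profile)
  if (!is.null(mock_profile)) sig <- mock_filter(sig, mock_profile)
  collapse_peaks(sig, profile, gap_bp)
}

#' Write a peak set as BED6
#'
#' Coordinates are 0-based half-open; the name field carries the
#' representative element id and the score field the representative Z scaled
#' by 100 and truncated to integer.
#'
#' @param peaks a `peak_set`.
#' @param path output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- data.frame(peaks$chrom, peaks$window_start, peaks$window_end,
                    peaks$representative_element,
                    as.integer(round(peaks$representative_z * 100)), ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
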