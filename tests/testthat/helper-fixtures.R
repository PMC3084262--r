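# shared builders for small in-code fixtures

# tiled array elements on one or more chromosomes, 0-based half-open
tiled_regions <- function(n_elements, element_bp = 100, n_chrom = 1) {
  chrom <- rep(sprintf("chr%d", seq_len(n_chrom)),
               each = ceiling(n_elements / n_chrom))[seq_len(n_elements)]
  start <- unlist(lapply(split(seq_len(n_elements), chrom), function(ix) {
    seq(0L, by = element_bp, length.out = length(ix))
  }), use.names = FALSE)
  ord <- order(chrom)
  data.frame(region_id = sprintf("e%04d", seq_len(n_elements)),
             chrom = chrom[ord], start = start,
             end = start + element_bp, stringsAsFactors = FALSE)
}

# signal_profile from a value vector over tiled elements
profile_from_values <- function(values, element_bp = 100, n_chrom = 1) {
  prof <- tiled_regions(length(values), element_bp, n_chrom)
  prof$value <- values
  class(prof) <- c("signal_profile", "data.frame")
  prof
}

# a minimal two-recruiter config for fast dataset tests
small_config <- function(n_regions = 200, ...) {
  sim_config(n_regions = n_regions,
             weights = c(A = 1, B = 0.5), intercept = 0.2, ...)
}

# brute-force window scores: every candidate start on the same grid as
# call_windows, scored by looping over elements (independent of the scanner)
brute_force_windows <- function(profile, window_bp = 1000, step_bp = 250,
                                background) {
  out <- list()
  for (ch in unique(profile$chrom)) {
    p <- profile[profile$chrom == ch, ]
    span_start <- min(p$start)
    last_start <- max(p$end) - window_bp
    starts <- if (last_start < span_start) span_start else
      seq(span_start, last_start, by = step_bp)
    for (ws in starts) {
      vals <- c()
      n <- 0L
      for (i in seq_len(nrow(p))) {
        if (p$start[i] < ws + window_bp && p$end[i] > ws) {
          vals <- c(vals, p$value[i])
          n <- n + 1L
        }
      }
      if (n == 0L) next
      m <- mean(vals)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, window_start = ws, window_end = ws + window_bp,
        n_elements = n, mean_z = m,
        p_value = pnorm(m, background$mu, background$sigma / sqrt(n),
                        lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# brute-force PWM hit enumeration over all windows and both strands, using
# the published score distribution but its own window scoring loop
brute_force_pwm_hits <- function(sequence, pwm, p_threshold) {
  dist <- pwm_score_distribution(pwm)
  sc <- dist$int_scores
  w <- nrow(sc)
  rc <- sc[rev(seq_len(w)), 4:1, drop = FALSE]
  chars <- strsplit(toupper(sequence), "")[[1]]
  codes <- match(chars, c("A", "C", "G", "T"))
  hits <- list()
  for (i in seq_len(length(chars) - w + 1L)) {
    win <- codes[i:(i + w - 1L)]
    if (anyNA(win)) next
    for (st in 1:2) {
      m <- if (st == 1L) sc else rc
      s <- sum(m[cbind(seq_len(w), win)])
      idx <- s - dist$offset + 1L
      pv <- if (idx < 1L) 1 else if (idx > length(dist$tail)) 0 else
        dist$tail[idx]
      if (pv < p_threshold) {
        hits[[length(hits) + 1L]] <- data.frame(
          offset = i - 1L, strand = c("+", "-")[st], score = s * dist$bin,
          p_value = pv, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(offset = integer(0), strand = character(0),
               score = numeric(0), p_value = numeric(0))
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
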