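#' Position weight matrix
#'
#' Constructs a PWM: a positions x 4 matrix of base probabilities (columns
#' A, C, G, T) with a background base distribution. A pseudocount is added so
#' all entries are strictly positive, and rows are renormalised to sum to 1.
#'
#' @param name factor name.
#' @param matrix positions x 4 numeric matrix of base probabilities.
#' @param background length-4 background probabilities (must sum to 1).
#' @param pseudocount added to every cell before renormalisation.
#' @return object of class `pwm` with elements name, matrix, background.
#' @export
pwm <- function(name, matrix, background = rep(0.25, 4), pseudocount = 0.01) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L) stop("invalid-pwm: matrix must have 4 columns (ACGT)")
  if (any(matrix < 0) || any(!is.finite(matrix))) {
    stop("invalid-pwm: probabilities must be finite and non-negative")
  }
  rs <- rowSums(matrix)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("invalid-pwm: each row must sum to 1 (got ",
         paste(signif(rs, 4), collapse = ", "), ")")
  }
  m <- matrix + pseudocount
  m <- m / rowSums(m)
  if (abs(sum(background) - 1) > 1e-9 || any(background <= 0)) {
    stop("invalid-pwm: background must be positive and sum to 1")
  }
  colnames(m) <- c("A", "C", "G", "T")
  structure(list(name = name, matrix = m, background = as.numeric(background)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s' (%d bp), consensus %s\n", x$name, nrow(x$matrix),
              paste(c("A", "C", "G", "T")[apply(x$matrix, 1, which.max)],
                    collapse = "")))
  invisible(x)
}

# log-odds scores discretized to integer units of `bin` log2 units;
# discretization makes the exact null score distribution computable by
# dynamic programming and keeps scanner and p-value lookup on the same scale
pwm_int_scores <- function(pwm, bin = 0.01) {
  s <- log2(sweep(pwm$matrix, 2, pwm$background, "/"))
  storage.mode(s) <- "double"
  matrix(as.integer(round(s / bin)), nrow(s), 4,
         dimnames = dimnames(pwm$matrix))
}

#' Exact null distribution of PWM scores
#'
#' Computes, by dynamic programming over positions, the exact distribution of
#' the discretized log-odds score of a random sequence drawn from the PWM's
#' background model, and returns a lookup giving for every achievable integer
#' score the upper-tail probability P(S >= s).
#'
#' @param pwm a [pwm()] object.
#' @param bin score discretization width in log2 units.
#' @return list with `offset` (minimum integer score), `tail` (vector of
#'   upper-tail probabilities indexed from `offset`), `bin`, and
#'   `int_scores` (the discretized score matrix used).
#' @export
pwm_score_distribution <- function(pwm, bin = 0.01) {
  sc <- pwm_int_scores(pwm, bin)
  probs <- 1
  offset <- 0L
  bg <- pwm$background
  for (j in seq_len(nrow(sc))) {
    row <- sc[j, ]
    new_min <- offset + min(row)
    new_max <- offset + length(probs) - 1L + max(row)
    new <- numeric(new_max - new_min + 1L)
    for (b in 1:4) {
      idx <- (offset + row[b] - new_min) + seq_along(probs)
      new[idx] <- new[idx] + probs * bg[b]
    }
    probs <- new
    offset <- new_min
  }
  tail <- rev(cumsum(rev(probs)))
  tail <- pmin(tail, 1)
  list(offset = offset, tail = tail, bin = bin, int_scores = sc)
}

# upper-tail p-value of integer score(s) under the background null
pwm_score_pvalue <- function(dist, int_score) {
  idx <- int_score - dist$offset + 1L
  p <- numeric(length(idx))
  p[idx <= 0L] <- 1
  p[idx > length(dist$tail)] <- 0
  inside <- idx >= 1L & idx <= length(dist$tail)
  p[inside] <- dist$tail[idx[inside]]
  p
}

# smallest integer score whose null upper-tail probability is < p_threshold,
# or NA if no achievable score is that significant
pwm_score_threshold <- function(dist, p_threshold) {
  ok <- which(dist$tail < p_threshold)
  if (!length(ok)) return(NA_integer_)
  dist$offset + ok[1] - 1L
}

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A, C, G, T, N.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# encode a DNA character string as integer codes A=0 C=1 G=2 T=3, N/other=4
encode_dna <- function(x) {
  v <- utf8ToInt(toupper(x))
  codes <- rep.int(4L, max(v, 85L) + 1L)
  codes[utf8ToInt("A") + 1L] <- 0L
  codes[utf8ToInt("C") + 1L] <- 1L
  codes[utf8ToInt("G") + 1L] <- 2L
  codes[utf8ToInt("T") + 1L] <- 3L
  codes[v + 1L]
}

# score matrix for scanning the reverse strand on the forward sequence:
# reverse position order and complement the base columns
revcomp_int_scores <- function(int_scores) {
  int_scores[rev(seq_len(nrow(int_scores))), c(4L, 3L, 2L, 1L), drop = FALSE]
}

#' Scan a sequence with a PWM using exact score p-values
#'
#' Both strands are scanned with discretized log-odds scores against the
#' background model; a window is a hit iff the exact null p-value of its
#' score, computed from the dynamic-programming score distribution, is below
#' `p_threshold`. Windows containing N are never hits.
#'
#' @param sequence character scalar or `Biostrings::DNAString` over ACGTN.
#' @param pwm a [pwm()] object.
#' @param p_threshold per-position significance threshold for a site call.
#' @param dist optional precomputed [pwm_score_distribution()] (for repeated
#'   scanning with the same PWM).
#' @return data.frame of hits: offset (0-based from region start), strand,
#'   score (log2 log-odds), p_value.
#' @export
pwm_scan <- function(sequence, pwm, p_threshold = 0.005, dist = NULL) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  if (is.null(dist)) dist <- pwm_score_distribution(pwm)
  seq_chr <- as.character(sequence)
  codes <- encode_dna(seq_chr)
  w <- nrow(dist$int_scores)
  if (length(codes) < w) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), p_value = numeric(0)))
  }
  sc <- scan_pwm_codes(codes, dist$int_scores,
                       revcomp_int_scores(dist$int_scores))
  thr <- pwm_score_threshold(dist, p_threshold)
  hits <- list()
  for (strand_i in 1:2) {
    s <- sc[[strand_i]]
    keep <- which(!is.na(s) & !is.na(thr) & s >= thr)
    if (length(keep)) {
      hits[[strand_i]] <- data.frame(
        offset = keep - 1L,
        strand = c("+", "-")[strand_i],
        score = s[keep] * dist$bin,
        p_value = pwm_score_pvalue(dist, s[keep]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(offset = integer(0), strand = character(0),
               score = numeric(0), p_value = numeric(0))
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Which regions contain at least one motif hit
#'
#' Vectorised helper over a set of sequences: for each sequence, whether any
#' window on either strand reaches the score threshold implied by
#' `p_threshold`.
#'
#' @param sequences `Biostrings::DNAStringSet`, named character vector, or a
#'   list of pre-encoded integer vectors from [encode_sequences()] (avoids
#'   re-encoding when many PWMs scan the same regions).
#' @param pwm a [pwm()] object.
#' @param p_threshold per-position site-call threshold.
#' @return named logical vector.
#' @export
pwm_hit_regions <- function(sequences, pwm, p_threshold = 0.005) {
  dist <- pwm_score_distribution(pwm)
  thr <- pwm_score_threshold(dist, p_threshold)
  codes_list <- if (inherits(sequences, "encoded_dna")) sequences else
    encode_sequences(sequences)
  fwd <- dist$int_scores
  rev_ <- revcomp_int_scores(fwd)
  if (is.na(thr)) {
    out <- rep(FALSE, length(codes_list))
  } else {
    out <- scan_pwm_any_many(unclass(codes_list), fwd, rev_, thr)
  }
  names(out) <- names(codes_list)
  out
}

#' Pre-encode sequences for repeated PWM scanning
#'
#' @param sequences `Biostrings::DNAStringSet` or named character vector.
#' @return list of integer code vectors (class `encoded_dna`), one per
#'   sequence.
#' @export
encode_sequences <- function(sequences) {
  out <- lapply(as.character(sequences), encode_dna)
  structure(out, class = "encoded_dna")
}

#' Write PWMs in a plain-matrix text format
#'
#' One block per motif: a `MOTIF <name>` line, a `background:` line, then one
#' row of four probabilities (A C G T) per position.
#'
#' @param pwms named list of [pwm()] objects.
#' @param path output file.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(paste("background:", paste(format(p$background, digits = 6),
                                          collapse = " ")), con)
    utils::write.table(format(p$matrix, digits = 6), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs written by [write_pwms()]
#'
#' @param path input file.
#' @return named list of [pwm()] objects.
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  out <- list()
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:(bounds[i + 1L] - 1L)]
    name <- sub("^MOTIF ", "", block[1])
    bg <- as.numeric(strsplit(sub("^background: *", "", block[2]), " +")[[1]])
    rows <- block[-(1:2)]
    rows <- rows[nzchar(trimws(rows))]
    m <- do.call(rbind, lapply(strsplit(trimws(rows), " +"), as.numeric))
    out[[name]] <- pwm(name, m, bg, pseudocount = 0)
  }
  out
}
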