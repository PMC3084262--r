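#' Write an occupancy dataset as tab-delimited text
#'
#' Produces `<prefix>_occupancy.tsv` (region_id, chrom, start, end, then one
#' log2-ratio column per factor), `<prefix>_pvalues.tsv` (same layout with
#' binding p-values), and `<prefix>_truth.tsv` (key-value sidecar with the
#' planted weights, intercept, noise sd and seed).
#'
#' @param dataset an `occupancy_dataset`.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_occupancy <- function(dataset, prefix) {
  occ_path <- paste0(prefix, "_occupancy.tsv")
  pv_path <- paste0(prefix, "_pvalues.tsv")
  truth_path <- paste0(prefix, "_truth.tsv")
  meta <- dataset$regions[, c("region_id", "chrom", "start", "end")]
  utils::write.table(cbind(meta, as.data.frame(dataset$occupancy)), occ_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(meta, as.data.frame(dataset$pvalues)), pv_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- dataset$truth
  kv <- rbind(
    data.frame(key = paste0("weight.", names(tr$planted_weights)),
               value = unname(tr$planted_weights)),
    data.frame(key = c("intercept", "noise_sd", "redundancy",
                       "derepression_slope", "seed", "corepressor"),
               value = c(tr$planted_intercept, tr$noise_sd, tr$redundancy,
                         tr$derepression_slope, tr$seed, tr$corepressor))
  )
  utils::write.table(kv, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(occ_path, pv_path, truth_path))
}

#' Read an occupancy matrix written by [write_occupancy()]
#'
#' @param occupancy_path path to the occupancy TSV.
#' @param pvalues_path optional path to the companion p-value TSV.
#' @return list: regions (data.frame), occupancy (matrix), pvalues (matrix or
#'   NULL).
#' @export
read_occupancy <- function(occupancy_path, pvalues_path = NULL) {
  read_one <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    meta <- tab[, c("region_id", "chrom", "start", "end")]
    m <- as.matrix(tab[, setdiff(names(tab), names(meta)), drop = FALSE])
    rownames(m) <- meta$region_id
    list(regions = meta, matrix = m)
  }
  occ <- read_one(occupancy_path)
  pv <- if (!is.null(pvalues_path)) read_one(pvalues_path)$matrix else NULL
  list(regions = occ$regions, occupancy = occ$matrix, pvalues = pv)
}

#' Write a per-replicate signal profile
#'
#' Tab-delimited: region_id, chrom, start, end, then one column per
#' replicate (or a single `value` column for a standardized profile).
#'
#' @param profile `signal_profile` data.frame or (regions, matrix) pair.
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a signal profile written by [write_profile()]
#'
#' @param path input file.
#' @return `signal_profile` data.frame.
#' @export
read_profile <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("signal_profile", "data.frame")
  out
}
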