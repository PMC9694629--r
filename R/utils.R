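# shared helpers: rounding, plain-text writers, small validators

#' Round half away from zero
#'
#' Frequencies and percentages in reports are rounded half-up (0.005 -> 0.01),
#' matching how the recombination-frequency and MTPT percentages are printed,
#' rather than R's round-half-even.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a tibble as a TSV report with a header line
#'
#' @param x data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv_report <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Write genomic intervals as BED (0-based half-open)
#'
#' @param x data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `name`, `score`, `strand`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  n <- nrow(x)
  bed <- data.frame(chrom = x$chrom,
                    start = as.integer(x$start) - 1L,
                    end = as.integer(x$end),
                    name = if ("name" %in% names(x)) x$name else rep(".", n),
                    score = if ("score" %in% names(x)) x$score else rep(0, n),
                    strand = if ("strand" %in% names(x)) x$strand else rep(".", n))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# positive scalar integer check
check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    abort(sprintf("`%s` must be a single value in [0, 1]", name))
  as.numeric(x)
}

# derive a per-stage RNG seed from a master seed; stays below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97L + offset) %% 2147483587)
}
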