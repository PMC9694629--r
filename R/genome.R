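# sequence containers and circular-coordinate arithmetic
#
# A genome is a Biostrings::DNAStringSet, one entry per chromosome; every
# chromosome is treated as circular (plant mitochondrial and plastid
# chromosomes are circles; a `circular` attribute can mark exceptions but
# nothing in the pipeline currently relaxes the assumption). Coordinates in
# every user-facing table are 1-based inclusive; an interval whose end is
# smaller than its start wraps through the origin.

#' Read a genome from a FASTA file
#'
#' Reads one circular chromosome per FASTA record. Residues are uppercased
#' and U is converted to T; any character outside `A`, `C`, `G`, `T`, `N`
#' is rejected with an error naming the record. Record ids are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path path to a FASTA file
#' @return a [Biostrings::DNAStringSet] with one entry per chromosome
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">chr1", "acgtacgt", ">chr2", "TTGGCCAA"), fa)
#' genome <- read_genome_fasta(fa)
#' lengths(genome)
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(sprintf("not a FASTA file: %s (%s)",
                                                    path, conditionMessage(e))))
  if (length(raw) == 0) abort(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    abort(sprintf("duplicate record id(s) in %s: %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  seqs <- toupper(as.character(raw))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    offending <- gsub("[ACGTN]", "", seqs[bad][1])
    abort(sprintf("illegal character(s) '%s' in record '%s'",
                  substr(offending, 1, 5), ids[bad][1]))
  }
  if (any(nchar(seqs) < 1)) abort(sprintf("zero-length record in %s", path))
  as_genome(setNames(seqs, ids))
}

#' Build a genome object from named character sequences
#'
#' @param x named character vector of DNA sequences (A/C/G/T/N)
#' @return a [Biostrings::DNAStringSet]
#' @export
as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.null(names(x)) || anyDuplicated(names(x)))
    abort("sequences must have unique names")
  if (any(grepl("[^ACGTN]", x))) abort("sequences may only contain A, C, G, T, N")
  Biostrings::DNAStringSet(x)
}

#' Write a genome to FASTA (70-column wrapped)
#'
#' @param genome a [Biostrings::DNAStringSet]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path, width = 70L)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick reverse complement over `A`, `C`, `G`, `T`; `N`
#' maps to `N`. Vectorised over its input.
#'
#' @param seq character vector of DNA strings
#' @return character vector of reverse complements
#' @export
#' @examples
#' dna_revcomp("AAAC")  # "GTTT"
dna_revcomp <- function(seq) {
  if (any(grepl("[^ACGTN]", seq)))
    abort("sequence contains characters outside {A, C, G, T, N}")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Extract a (possibly origin-wrapping) segment of a circular chromosome
#'
#' Returns residues `start..end` inclusive in the forward reading frame.
#' When `start > end` the segment wraps through the origin, so the result
#' has length `((end - start) mod L) + 1`.
#'
#' @param genome a [Biostrings::DNAStringSet], a single DNA string, or a
#'   named character vector of chromosomes
#' @param chrom chromosome id (ignored when `genome` is a bare string)
#' @param start,end 1-based inclusive coordinates, each in `[1, L]`
#' @return the extracted DNA string
#' @export
#' @examples
#' extract_circular("ABCDEFGH", start = 7, end = 2)  # wraps: "GHAB"
extract_circular <- function(genome, chrom = NULL, start, end) {
  seq <- resolve_chromosome(genome, chrom)
  L <- nchar(seq)
  start <- check_count(start, "start"); end <- check_count(end, "end")
  if (start > L || end > L)
    abort(sprintf("coordinate out of range: start=%d end=%d on length-%d chromosome",
                  start, end, L))
  if (start <= end) {
    substr(seq, start, end)
  } else {
    paste0(substr(seq, start, L), substr(seq, 1, end))
  }
}

# accept DNAStringSet / named character / bare string and return one
# chromosome as a character string
resolve_chromosome <- function(genome, chrom = NULL) {
  if (methods::is(genome, "DNAStringSet")) {
    if (is.null(chrom)) {
      if (length(genome) != 1) abort("`chrom` is required for multi-chromosome genomes")
      return(as.character(genome[[1]]))
    }
    if (!chrom %in% names(genome))
      abort(sprintf("chromosome '%s' not found in genome", chrom))
    return(as.character(genome[[chrom]]))
  }
  if (is.character(genome) && length(genome) == 1 && is.null(chrom)) return(genome)
  if (is.character(genome) && !is.null(names(genome))) {
    if (is.null(chrom) && length(genome) == 1) return(unname(genome))
    if (!chrom %in% names(genome))
      abort(sprintf("chromosome '%s' not found in genome", chrom))
    return(unname(genome[[chrom]]))
  }
  if (is.character(genome) && length(genome) == 1) return(genome)
  abort("`genome` must be a DNAStringSet or a (named) character vector")
}

# chromosome lengths as a named integer vector, from a genome object or a
# bare named numeric vector of lengths
chromosome_lengths <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(setNames(Biostrings::width(x), names(x)))
  if (is.numeric(x) && !is.null(names(x))) return(setNames(as.integer(x), names(x)))
  if (is.character(x) && !is.null(names(x))) return(setNames(nchar(x), names(x)))
  abort("expected a genome or a named vector of chromosome lengths")
}
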