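# circular-molecule rearrangement algebra
#
# A molecule is a circular, ordered run of elements: inter-repeat
# segments and repeat-copy markers, each carrying genome coordinates, an
# output sign (+ read as stored, - reverse-complemented) and, for
# markers, the strand on which the canonical repeat body reads
# (`rep_strand`). Repeat copies are atomic blocks: recombination never
# cuts inside the body, so for exact repeats the junction placement is
# irrelevant and for inexact ones it sits at the body's 5' edge.
# Reciprocal exchange at the two copies of a repeat gives the three
# classic outcomes: a direct intra-molecular repeat splits the circle in
# two, an inverted one inverts the intervening segment, and an
# inter-molecular repeat fuses two circles. Total length is conserved in
# every case.

#' Decompose a genome into circular molecules with repeat markers
#'
#' @param genome a [Biostrings::DNAStringSet], named character vector, or
#'   a named numeric vector of chromosome lengths (sequences are only
#'   needed later, by [realize_sequence()])
#' @param repeats repeat-pair tibble ([find_repeats()] layout); copies
#'   must not overlap and must not wrap the origin
#' @return a `molecule_set`: list of per-molecule element tibbles plus a
#'   `label` ("Mac") and `provenance` ("assembly")
#' @export
genome_to_molecules <- function(genome, repeats = NULL) {
  lens <- chromosome_lengths(genome)
  if (is.null(repeats)) repeats <- empty_repeat_table()
  copies <- repeat_copies(repeats)
  mols <- list()
  for (cid in names(lens)) {
    L <- lens[[cid]]
    cc <- copies[copies$chrom == cid, , drop = FALSE]
    if (any(cc$end < cc$start))
      abort(sprintf("repeat copy wrapping the origin of '%s' is not supported in topology", cid))
    cc <- cc[order(cc$start), , drop = FALSE]
    if (nrow(cc) > 1) {
      ov <- which(cc$start[-1] <= cc$end[-nrow(cc)])
      if (length(ov) > 0)
        abort(sprintf("overlapping repeat copies on '%s': %s and %s",
                      cid, cc$marker[ov[1]], cc$marker[ov[1] + 1]))
    }
    if (nrow(cc) == 0) {
      mols[[cid]] <- element_row("segment", paste0(cid, ":1-", L), "+",
                                 cid, 1L, L, L, NA_character_)
      next
    }
    el <- list()
    for (k in seq_len(nrow(cc))) {
      el[[length(el) + 1]] <- element_row(
        "repeat", cc$marker[k], "+", cid, cc$start[k], cc$end[k],
        cc$end[k] - cc$start[k] + 1L, cc$rep_strand[k])
      nxt <- if (k < nrow(cc)) cc$start[k + 1] else cc$start[1] + L
      seg_start <- cc$end[k] + 1L
      seg_len <- nxt - cc$end[k] - 1L
      if (seg_len > 0) {
        s0 <- ((seg_start - 1L) %% L) + 1L
        e0 <- ((seg_start + seg_len - 2L) %% L) + 1L
        el[[length(el) + 1]] <- element_row(
          "segment", sprintf("%s:%d-%d", cid, s0, e0), "+",
          cid, s0, e0, seg_len, NA_character_)
      }
    }
    mols[[cid]] <- dplyr::bind_rows(el)
  }
  new_molecule_set(mols, label = "Mac", provenance = "assembly")
}

repeat_copies <- function(repeats) {
  if (nrow(repeats) == 0)
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  marker = character(), rep_strand = character()))
  dplyr::bind_rows(
    tibble(chrom = repeats$chrom1, start = repeats$start1, end = repeats$end1,
           marker = paste0(repeats$repeat_id, "/1"), rep_strand = "+"),
    tibble(chrom = repeats$chrom2, start = repeats$start2, end = repeats$end2,
           marker = paste0(repeats$repeat_id, "/2"),
           rep_strand = ifelse(repeats$orientation == "inverted", "-", "+")))
}

element_row <- function(type, id, sign, chrom, start, end, length, rep_strand) {
  tibble(type = type, id = id, sign = sign, chrom = chrom,
         start = as.integer(start), end = as.integer(end),
         length = as.integer(length), rep_strand = rep_strand)
}

new_molecule_set <- function(molecules, label, provenance) {
  structure(list(molecules = molecules, label = label,
                 provenance = provenance),
            class = "molecule_set")
}

#' @export
print.molecule_set <- function(x, ...) {
  cat(sprintf("molecule set [%s, from %s]: %d circular molecule(s), %s bp total\n",
              x$label, x$provenance, length(x$molecules),
              format(total_length(x), big.mark = ",")))
  for (nm in names(x$molecules)) {
    m <- x$molecules[[nm]]
    cat(sprintf("  %s (%s bp): %s\n", nm,
                format(sum(m$length), big.mark = ","),
                paste0(ifelse(m$sign == "-", "-", ""), m$id, collapse = " ")))
  }
  invisible(x)
}

#' Total base pairs in a molecule set
#' @param mols a `molecule_set`
#' @return numeric total length
#' @export
total_length <- function(mols) {
  sum(vapply(mols$molecules, function(m) sum(as.numeric(m$length)), numeric(1)))
}

#' Tidy a molecule set into one tibble
#' @param x a `molecule_set`
#' @param ... unused
#' @return tibble of elements with a `molecule` column
#' @export
tidy.molecule_set <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$molecules, function(m, nm) {
    dplyr::mutate(m, molecule = nm, .before = 1)
  }))
}

# reverse-complement an element run: reverse order, flip signs and
# marker strands
rc_elements <- function(m) {
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m$sign <- ifelse(m$sign == "+", "-", "+")
  m$rep_strand <- ifelse(is.na(m$rep_strand), m$rep_strand,
                         ifelse(m$rep_strand == "+", "-", "+"))
  m
}

rotate_elements <- function(m, first) {
  if (first == 1) return(m)
  m[c(first:nrow(m), seq_len(first - 1)), , drop = FALSE]
}

#' Reciprocal recombination at one repeat
#'
#' Performs the exchange at the two copies of `repeat_id`. Both copies on
#' one circle: a direct repeat splits it into two circles (one copy
#' each); an inverted repeat returns one circle with the intervening
#' run reverse-complemented. Copies on two circles: the circles fuse.
#' "Direct" and "inverted" are evaluated in the molecules' current
#' frames (markers remember the strand of the repeat body), so repeated
#' recombination composes correctly.
#'
#' @param mols a `molecule_set`
#' @param repeat_id id of the repeat to recombine at
#' @return a new `molecule_set` labelled "Mic" with provenance
#'   `repeat_id`; total length is conserved
#' @export
recombine <- function(mols, repeat_id) {
  stopifnot(inherits(mols, "molecule_set"))
  loc <- locate_markers(mols, repeat_id)
  before <- total_length(mols)
  out <- mols$molecules
  if (loc$mol1 == loc$mol2) {
    m <- out[[loc$mol1]]
    i1 <- loc$idx1
    if (m$rep_strand[i1] == "-") {
      m <- rc_elements(m)
      i1 <- nrow(m) - loc$idx1 + 1L
    }
    m <- rotate_elements(m, i1)
    i2 <- which(m$type == "repeat" & m$id == paste0(repeat_id, "/2"))
    if (length(i2) == 0) i2 <- which(m$type == "repeat" & m$id == paste0(repeat_id, "/1"))[2]
    x <- if (i2 > 2) m[2:(i2 - 1), , drop = FALSE] else m[0, ]
    y <- if (i2 < nrow(m)) m[(i2 + 1):nrow(m), , drop = FALSE] else m[0, ]
    if (m$rep_strand[i2] == m$rep_strand[1]) {
      # direct: split into two circles, one repeat copy each
      prod <- list(dplyr::bind_rows(m[1, ], x), dplyr::bind_rows(m[i2, ], y))
      names(prod) <- paste0(loc$mol1, ".", 1:2)
    } else {
      # inverted: the intervening run flips
      prod <- list(dplyr::bind_rows(m[1, ], rc_elements(x), m[i2, ], y))
      names(prod) <- loc$mol1
    }
    out[[loc$mol1]] <- NULL
    out <- c(out, prod)
  } else {
    m1 <- out[[loc$mol1]]; m2 <- out[[loc$mol2]]
    i1 <- loc$idx1
    if (m1$rep_strand[i1] == "-") {
      m1 <- rc_elements(m1); i1 <- nrow(m1) - loc$idx1 + 1L
    }
    m1 <- rotate_elements(m1, i1)
    i2 <- loc$idx2
    if (m2$rep_strand[i2] == "-") {
      m2 <- rc_elements(m2); i2 <- nrow(m2) - loc$idx2 + 1L
    }
    m2 <- rotate_elements(m2, i2)
    fused <- dplyr::bind_rows(m1, m2)
    nm <- paste0(loc$mol1, "+", loc$mol2)
    out[[loc$mol1]] <- NULL; out[[loc$mol2]] <- NULL
    out <- c(out, setNames(list(fused), nm))
  }
  res <- new_molecule_set(out, label = "Mic", provenance = repeat_id)
  if (!isTRUE(all.equal(before, total_length(res))))
    abort("internal error: length not conserved by recombination")
  res
}

locate_markers <- function(mols, repeat_id) {
  hits <- list()
  for (nm in names(mols$molecules)) {
    m <- mols$molecules[[nm]]
    w <- which(m$type == "repeat" & m$id %in% paste0(repeat_id, c("/1", "/2")))
    for (i in w) hits[[length(hits) + 1]] <- list(mol = nm, idx = i, id = m$id[i])
  }
  if (length(hits) != 2)
    abort(sprintf("repeat '%s' must have exactly two copies in the molecule set (found %d)",
                  repeat_id, length(hits)))
  ord <- order(vapply(hits, function(h) h$id, character(1)))
  hits <- hits[ord]
  list(mol1 = hits[[1]]$mol, idx1 = hits[[1]]$idx,
       mol2 = hits[[2]]$mol, idx2 = hits[[2]]$idx)
}

#' Enumerate recombination products of the active repeats
#'
#' With `depth = 1` (the default) this returns one minor-conformation
#' molecule set per active repeat: the single-event products. Larger
#' depths compose up to `depth` events breadth-first, de-duplicating
#' structurally identical sets by canonical form.
#'
#' @param mols the major-conformation `molecule_set`
#' @param active_repeats character vector of repeat ids (or a data frame
#'   with `repeat_id` and logical `active`)
#' @param depth maximum number of composed recombination events
#' @return list of `molecule_set`s (empty when no repeat is active)
#' @export
enumerate_conformation_space <- function(mols, active_repeats, depth = 1) {
  if (is.data.frame(active_repeats)) {
    active_repeats <- active_repeats$repeat_id[
      if ("active" %in% names(active_repeats)) active_repeats$active else TRUE]
  }
  if (length(active_repeats) == 0) return(list())
  first <- lapply(active_repeats, function(r) recombine(mols, r))
  if (depth <= 1) return(first)
  seen <- c(canonical_form(mols), vapply(first, canonical_form, character(1)))
  out <- first
  frontier <- first
  for (d in seq_len(depth - 1)) {
    nxt <- list()
    for (ms in frontier) {
      for (r in active_repeats) {
        cand <- recombine(ms, r)
        cf <- canonical_form(cand)
        if (!cf %in% seen) {
          seen <- c(seen, cf)
          nxt[[length(nxt) + 1]] <- cand
        }
      }
    }
    out <- c(out, nxt)
    frontier <- nxt
    if (length(frontier) == 0) break
  }
  out
}

#' Canonical form of a molecule set
#'
#' Each circle is rotated to its lexicographically smallest signed
#' element string, on whichever strand minimises it; the set is the
#' sorted multiset of circle strings. Two molecule sets are structurally
#' identical iff their canonical forms are equal.
#'
#' @param mols a `molecule_set`
#' @return a single character key
#' @export
canonical_form <- function(mols) {
  keys <- vapply(mols$molecules, function(m) {
    tok <- function(mm) paste0(mm$type, ":", mm$id, ":", mm$sign,
                               ifelse(is.na(mm$rep_strand), "", paste0(":", mm$rep_strand)))
    best <- NULL
    for (variant in list(m, rc_elements(m))) {
      t <- tok(variant)
      for (i in seq_along(t)) {
        cand <- paste(c(t[i:length(t)], t[seq_len(i - 1)]), collapse = "|")
        if (is.null(best) || cand < best) best <- cand
      }
    }
    best
  }, character(1))
  paste(sort(keys), collapse = " || ")
}

#' Materialise a molecule as a DNA sequence
#'
#' Concatenates the elements' residues in order, honouring signs.
#'
#' @param molecule an element tibble (one entry of `mols$molecules`) or a
#'   `molecule_set` together with `name`
#' @param genome the genome the coordinates refer to (sequences required)
#' @param name molecule name when `molecule` is a `molecule_set`
#' @return a DNA string whose length equals the molecule length
#' @export
realize_sequence <- function(molecule, genome, name = NULL) {
  if (inherits(molecule, "molecule_set")) {
    if (is.null(name)) abort("`name` is required to realize one molecule of a set")
    molecule <- molecule$molecules[[name]]
    if (is.null(molecule)) abort(sprintf("no molecule named '%s'", name))
  }
  genome <- as_genome(genome)
  pieces <- vapply(seq_len(nrow(molecule)), function(i) {
    if (!molecule$chrom[i] %in% names(genome))
      abort(sprintf("segment '%s' is not traceable to the genome", molecule$id[i]))
    s <- extract_circular(genome, molecule$chrom[i], molecule$start[i], molecule$end[i])
    if (molecule$sign[i] == "-") dna_revcomp(s) else s
  }, character(1))
  paste(pieces, collapse = "")
}

#' Export a molecule set as FASTA plus a JSON structure report
#'
#' @param mols a `molecule_set`
#' @param genome genome with sequences
#' @param fasta_path,json_path output paths (either may be NULL to skip)
#' @return invisibly, a list with the realized sequences and the report
#' @export
export_molecules <- function(mols, genome, fasta_path = NULL, json_path = NULL) {
  seqs <- vapply(names(mols$molecules), function(nm)
    realize_sequence(mols, genome, name = nm), character(1))
  if (!is.null(fasta_path))
    write_genome_fasta(setNames(seqs, names(mols$molecules)), fasta_path)
  report <- list(
    label = mols$label, provenance = mols$provenance,
    total_bp = total_length(mols),
    molecules = purrr::imap(mols$molecules, function(m, nm) {
      list(id = nm, length = sum(m$length),
           elements = as.list(m[c("type", "id", "sign", "length")]))
    }))
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sequences = seqs, report = report))
}
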