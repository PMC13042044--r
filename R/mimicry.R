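#' Positional motif pattern for epitope-mimicry scanning
#'
#' An anchor peptide plus the set of 1-based positions that a candidate
#' window must share with it exactly.  The default use case is scanning a
#' bacterial proteome for windows sharing the TCR-contact residues of a
#' host epitope (e.g. positions 2, 5, 7 and 8 of a 9-mer from the MOG
#' 40-48 region) while scoring overall identity across the window.
#'
#' @param anchor anchor peptide, uppercase standard one-letter residues.
#' @param required_positions non-empty integer vector of 1-based positions
#'   within the anchor.
#' @return An object of class `motif_pattern`.
#' @export
motif_pattern <- function(anchor, required_positions) {
  if (!is.character(anchor) || length(anchor) != 1 || nchar(anchor) == 0)
    stopf("anchor must be a single non-empty peptide string")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", anchor))
    stopf("anchor contains a non-standard residue letter")
  required_positions <- sort(unique(as.integer(required_positions)))
  if (length(required_positions) == 0)
    stopf("required_positions must be non-empty")
  if (any(required_positions < 1 | required_positions > nchar(anchor)))
    stopf("required_positions must lie within 1..%d", nchar(anchor))
  structure(list(anchor = anchor,
                 required_positions = required_positions),
            class = "motif_pattern")
}

# Offsets (1-based) of windows matching the pattern in a character vector
# of residues.  Vectorised over offsets; non-standard residues (e.g. X)
# simply never equal an anchor residue.
.match_offsets <- function(chars, pattern) {
  L <- nchar(pattern$anchor)
  n_off <- length(chars) - L + 1L
  if (n_off < 1) return(integer())
  a <- strsplit(pattern$anchor, "")[[1]]
  keep <- rep(TRUE, n_off)
  for (p in pattern$required_positions)
    keep <- keep & chars[seq_len(n_off) + p - 1L] == a[p]
  which(keep)
}

#' Fractional sequence similarity between two equal-length peptides
#'
#' The count of positions with identical residues divided by the length
#' (percent identity as a fraction); no substitution matrix is used.
#'
#' @param window,anchor peptides of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
window_similarity <- function(window, anchor) {
  if (nchar(window) != nchar(anchor))
    stopf("window and anchor lengths differ (%d vs %d)",
          nchar(window), nchar(anchor))
  w <- strsplit(window, "")[[1]]
  a <- strsplit(anchor, "")[[1]]
  mean(w == a)
}

#' Scan a proteome for positional mimicry motifs
#'
#' Slides a window the length of the anchor along every protein (step 1);
#' a window is a hit iff it matches the anchor exactly at every required
#' position.  Similarity is percent identity over the full window and
#' `is_top_hit` marks hits strictly above `top_hit_threshold`.  Proteins
#' shorter than the anchor yield no hits; hits are ordered by
#' `(protein_id, offset)` and `distinct_proteins` counts unique proteins
#' with at least one hit.
#'
#' @param proteins named character vector of protein sequences, or a path
#'   to a protein FASTA file (multi-record, wrapped lines tolerated), or a
#'   [Biostrings::AAStringSet].
#' @param pattern a [motif_pattern()].
#' @param top_hit_threshold similarity strictly above this flags a top hit
#'   (default 0.5).
#' @return list with `hits` (data.frame: `protein_id`, `offset`, `window`,
#'   `similarity`, `is_top_hit`) and `distinct_proteins` (count).
#' @export
scan_proteome <- function(proteins, pattern, top_hit_threshold = 0.5) {
  stopifnot(inherits(pattern, "motif_pattern"))
  seqs <- .as_protein_vector(proteins)
  L <- nchar(pattern$anchor)
  a <- strsplit(pattern$anchor, "")[[1]]
  res <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "")[[1]]
    off <- .match_offsets(chars, pattern)
    if (length(off) == 0) next
    sim <- vapply(off, function(o)
      mean(chars[o:(o + L - 1L)] == a), numeric(1))
    res[[i]] <- data.frame(
      protein_id = names(seqs)[i], offset = off,
      window = vapply(off, function(o)
        paste(chars[o:(o + L - 1L)], collapse = ""), character(1)),
      similarity = sim, is_top_hit = sim > top_hit_threshold,
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(hits))
    hits <- data.frame(protein_id = character(), offset = integer(),
                       window = character(), similarity = numeric(),
                       is_top_hit = logical(), stringsAsFactors = FALSE)
  hits <- hits[order(hits$protein_id, hits$offset), , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits,
       distinct_proteins = length(unique(hits$protein_id)))
}

.as_protein_vector <- function(proteins) {
  if (is.character(proteins) && length(proteins) == 1 &&
      file.exists(proteins)) {
    aa <- Biostrings::readAAStringSet(proteins)
    seqs <- as.character(aa)
    names(seqs) <- sub("\\s.*$", "", names(aa))
    return(seqs)
  }
  if (methods::is(proteins, "AAStringSet")) {
    seqs <- as.character(proteins)
    names(seqs) <- sub("\\s.*$", "", names(proteins))
    return(seqs)
  }
  if (is.character(proteins)) {
    if (is.null(names(proteins)))
      names(proteins) <- make_ids("prot", length(proteins))
    return(proteins)
  }
  stopf("proteins must be sequences, an AAStringSet, or a FASTA path")
}

#' Primer pair on genome coordinates
#'
#' Inclusive 1-based coordinates of a forward and a reverse primer on the
#' same reference; the forward primer must end before the reverse primer
#' starts.
#'
#' @param forward_start,forward_end,reverse_start,reverse_end 1-based
#'   inclusive genome coordinates.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(forward_start, forward_end,
                        reverse_start, reverse_end) {
  if (forward_start > forward_end || reverse_start > reverse_end)
    stopf("primer start must not exceed its end")
  if (forward_end >= reverse_start)
    stopf("forward primer must end before the reverse primer starts")
  structure(list(forward_start = forward_start, forward_end = forward_end,
                 reverse_start = reverse_start, reverse_end = reverse_end),
            class = "primer_pair")
}

#' Amplicon length produced by a primer pair
#'
#' With inclusive 1-based coordinates the amplicon spans
#' `reverse_end - forward_start + 1` base pairs.
#'
#' @param primers a [primer_pair()].
#' @return Length in base pairs (integer).
#' @export
amplicon_length <- function(primers) {
  stopifnot(inherits(primers, "primer_pair"))
  as.integer(primers$reverse_end - primers$forward_start + 1)
}
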