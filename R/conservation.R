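#' Read a multiple alignment from FASTA
#'
#' Sequences are upper-cased; gaps and ambiguity characters are kept. All
#' sequences must have the same gapped length, and codon alignments a
#' length divisible by 3.
#'
#' @param path FASTA file.
#' @param kind `"protein"` or `"codon"`.
#' @return object of class `msa`: list with `sequences` (named character
#'   vector of gapped sequences), `kind`, `length` (columns; codon
#'   columns for codon alignments).
#' @export
read_alignment <- function(path, kind = c("protein", "codon")) {
  kind <- match.arg(kind)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*", "", names(set))
  msa(seqs, kind = kind)
}

#' Construct an alignment object from sequences in memory
#' @param sequences named character vector of equal-length gapped
#'   sequences.
#' @param kind `"protein"` or `"codon"`.
#' @return an `msa` object.
#' @export
msa <- function(sequences, kind = c("protein", "codon")) {
  kind <- match.arg(kind)
  sequences <- toupper(sequences)
  lens <- unname(nchar(sequences))
  if (length(unique(lens)) != 1) {
    bad <- names(sequences)[lens != lens[1]][1]
    stop("ragged alignment: sequence '", bad, "' has length ",
         nchar(sequences[bad]), ", expected ", lens[1])
  }
  ncol_chars <- lens[1]
  if (kind == "codon" && ncol_chars %% 3 != 0)
    stop("codon alignment length ", ncol_chars, " is not divisible by 3")
  structure(
    list(sequences = sequences, kind = kind,
         length = if (kind == "codon") ncol_chars %/% 3L else ncol_chars),
    class = "msa")
}

#' Write an alignment as FASTA
#' @param aln an `msa`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(aln$sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

# One amino-acid state per sequence at a column; NA for missing.
.column_states <- function(aln, column) {
  if (column < 1 || column > aln$length)
    stop("column ", column, " out of range 1..", aln$length)
  if (aln$kind == "protein") {
    ch <- substr(aln$sequences, column, column)
    aa <- ch
    aa[ch %in% c("-", ".", "X", "?", "*")] <- NA
    codon <- rep(NA_character_, length(ch))
  } else {
    codon <- substr(aln$sequences, 3 * (column - 1) + 1, 3 * column)
    valid <- grepl("^[ACGT]{3}$", codon)
    tab <- .codon_table()
    aa <- rep(NA_character_, length(codon))
    aa[valid] <- tab[codon[valid]]
    aa[!is.na(aa) & aa == "*"] <- NA   # stop codons treated as missing
    codon[!valid] <- NA
  }
  list(aa = aa, codon = codon)
}

#' Amino-acid composition at one alignment column
#'
#' Counts and fractions are over sequences with a non-missing state at
#' the column; gaps, ambiguity codes and (for codon alignments)
#' incomplete or non-ACGT codons are excluded from the denominator and
#' tallied as missing. A column is conserved when exactly one state is
#' observed.
#'
#' @param aln an `msa`.
#' @param column 1-based column (codon column for codon alignments).
#' @param min_presence when > 0, sequences with fewer than this fraction
#'   of non-missing positions are dropped before counting (default 0:
#'   keep all).
#' @return object of class `site_composition`: list with `column`,
#'   `counts`, `fractions`, `n_missing`, `conserved_aa`,
#'   `conserved_codon` (NA for protein alignments).
#' @export
site_composition <- function(aln, column, min_presence = 0) {
  seqs <- aln
  if (min_presence > 0) {
    present <- vapply(seq_len(length(aln$sequences)), function(i) {
      s <- aln$sequences[i]
      mean(strsplit(s, "")[[1]] != "-")
    }, numeric(1))
    seqs <- msa(aln$sequences[present >= min_presence], kind = aln$kind)
  }
  st <- .column_states(seqs, column)
  obs <- st$aa[!is.na(st$aa)]
  counts <- table(obs)
  fractions <- if (length(obs)) counts / length(obs) else counts
  conserved_codon <- if (seqs$kind == "codon") {
    oc <- st$codon[!is.na(st$codon)]
    length(oc) > 0 && length(unique(oc)) == 1
  } else NA
  structure(
    list(column = as.integer(column),
         counts = setNames(as.integer(counts), names(counts)),
         fractions = setNames(as.numeric(fractions), names(counts)),
         n_missing = sum(is.na(st$aa)),
         conserved_aa = length(obs) > 0 && length(unique(obs)) == 1,
         conserved_codon = conserved_codon),
    class = "site_composition")
}

#' @export
print.site_composition <- function(x, ...) {
  cat(sprintf("column %d: %s%s\n", x$column,
              paste(sprintf("%s=%.3f", names(x$fractions), x$fractions),
                    collapse = " "),
              if (isTRUE(x$conserved_aa)) " [conserved]" else ""))
  invisible(x)
}

#' Map reference residue numbers to alignment columns
#'
#' Gap-aware cumulative count along the reference sequence: residue `k`
#' of the ungapped reference maps to the alignment column holding its
#' `k`-th non-gap character (codon column for codon alignments).
#'
#' @param aln an `msa`.
#' @param reference_id name of the reference sequence.
#' @param residue_seqs integer vector of 1-based residue numbers in the
#'   ungapped reference.
#' @return integer vector of column indices, named by residue number.
#' @export
map_reference_sites <- function(aln, reference_id, residue_seqs) {
  if (!reference_id %in% names(aln$sequences))
    stop("reference '", reference_id, "' not in alignment")
  ref <- aln$sequences[[reference_id]]
  units <- if (aln$kind == "codon") {
    vapply(seq_len(aln$length),
           function(i) substr(ref, 3 * (i - 1) + 1, 3 * i), character(1))
  } else {
    strsplit(ref, "")[[1]]
  }
  is_res <- if (aln$kind == "codon") !grepl("-", units) else units != "-"
  cum <- cumsum(is_res)
  vapply(setNames(as.integer(residue_seqs), residue_seqs), function(k) {
    if (k < 1 || k > cum[length(cum)])
      stop("residue ", k, " beyond reference length ", cum[length(cum)])
    match(k, cum)
  }, integer(1))
}

#' Per-site composition table for a set of reference residues
#'
#' Convenience wrapper: maps reference residue numbers to columns and
#' tabulates the composition at each.
#'
#' @inheritParams map_reference_sites
#' @return data.frame with one row per (site, observed state):
#'   `resno`, `column`, `state`, `count`, `fraction`, `conserved_aa`,
#'   `conserved_codon`.
#' @export
site_conservation_table <- function(aln, reference_id, residue_seqs) {
  cols <- map_reference_sites(aln, reference_id, residue_seqs)
  rows <- lapply(seq_along(cols), function(i) {
    comp <- site_composition(aln, cols[i])
    data.frame(resno = as.integer(names(cols)[i]), column = cols[i],
               state = names(comp$fractions),
               count = comp$counts, fraction = comp$fractions,
               conserved_aa = comp$conserved_aa,
               conserved_codon = comp$conserved_codon,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
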