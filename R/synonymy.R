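COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify a substitution as synonymous, non-synonymous or non-coding
#'
#' For a position inside a protein-coding gene the alternate base is
#' substituted into its codon (reverse-complementing for minus-strand genes),
#' both codons are translated with the annotation's genetic code (the
#' vertebrate mitochondrial code, NCBI table 2, for the packaged annotation),
#' and the change is `synonymous` iff the amino acids -- stop included --
#' are identical. Positions outside every protein-coding gene are
#' `non_coding`. When a position falls in overlapping coding genes the
#' change is `non_synonymous` if it is non-synonymous in any of them.
#' Positions in a trailing partial codon (mitochondrial genes whose stop
#' codon is completed by polyadenylation) cannot be classified and are
#' treated as `non_coding` with a warning.
#'
#' @param ann A [mito_annotation()] object.
#' @param position 1-based position (scalar).
#' @param alt Alternate base, one of A/C/G/T, different from the reference
#'   base at `position`.
#' @return One of `"synonymous"`, `"non_synonymous"`, `"non_coding"`.
#' @examples
#' ann <- mouse_mt_annotation()
#' classify_substitution(ann, 233, setdiff(c("A","C","G","T"),
#'                                         reference_base(ann, 233))[1])
#' @export
classify_substitution <- function(ann, position, alt) {
  stopifnot(length(position) == 1L, length(alt) == 1L)
  classify_substitutions(ann, position, alt)
}

#' Reference base at one or more positions
#'
#' @param ann A `MitoAnnotation`.
#' @param positions Integer vector of 1-based positions.
#' @return Character vector of reference bases.
#' @export
reference_base <- function(ann, positions) {
  stopifnot(inherits(ann, "MitoAnnotation"))
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > ann$genome_length)) {
    stop("positions must lie in [1, ", ann$genome_length, "]")
  }
  ann$bases[positions]
}

#' Vectorised synonymy classification
#'
#' Same semantics as [classify_substitution()] over parallel vectors of
#' positions and alternate bases.
#'
#' @param ann A `MitoAnnotation`.
#' @param positions Integer vector of 1-based positions.
#' @param alts Character vector of alternate bases, recycled if scalar.
#' @return Character vector of classes, same length as `positions`.
#' @export
classify_substitutions <- function(ann, positions, alts) {
  stopifnot(inherits(ann, "MitoAnnotation"))
  positions <- as.integer(positions)
  if (length(alts) == 1L) alts <- rep(alts, length(positions))
  stopifnot(length(alts) == length(positions))
  if (length(positions) == 0L) return(character(0))
  if (any(positions < 1L | positions > ann$genome_length)) {
    stop("position out of range [1, ", ann$genome_length, "]")
  }
  alts <- toupper(alts)
  if (!all(alts %in% c("A", "C", "G", "T"))) {
    stop("alternate base must be one of A/C/G/T")
  }
  refs <- ann$bases[positions]
  if (any(alts == refs)) {
    i <- which(alts == refs)[1L]
    stop("not a variant: alternate equals reference base '", refs[i],
         "' at position ", positions[i])
  }

  code <- Biostrings::getGeneticCode(ann$genetic_code)
  b <- ann$bases
  any_syn <- logical(length(positions))
  any_nonsyn <- logical(length(positions))
  saw_partial <- FALSE

  cds <- ann$features[ann$features$ftype == "protein_coding", , drop = FALSE]
  for (i in seq_len(nrow(cds))) {
    fr <- cds$frame[i]
    if (is.na(fr)) fr <- 0L
    idx <- which(positions >= cds$start[i] & positions <= cds$end[i])
    if (length(idx) == 0L) next
    len <- cds$end[i] - cds$start[i] + 1L
    n_complete <- (len - fr) %/% 3L

    if (cds$strand[i] == "+") {
      off <- positions[idx] - (cds$start[i] + fr)
      in_frame <- off >= 0L
      codon_i <- off %/% 3L
      partial <- in_frame & codon_i >= n_complete
      use <- in_frame & !partial
      if (any(partial)) saw_partial <- TRUE
      if (any(use)) {
        j <- idx[use]
        ci <- codon_i[use]
        cs <- cds$start[i] + fr + 3L * ci
        ref_codon <- paste0(b[cs], b[cs + 1L], b[cs + 2L])
        within <- off[use] %% 3L
        alt_codon <- mut_codon(ref_codon, within, alts[j])
        syn <- code[ref_codon] == code[alt_codon]
        any_syn[j] <- any_syn[j] | syn
        any_nonsyn[j] <- any_nonsyn[j] | !syn
      }
    } else {
      off <- (cds$end[i] - fr) - positions[idx]
      in_frame <- off >= 0L
      codon_i <- off %/% 3L
      partial <- in_frame & codon_i >= n_complete
      use <- in_frame & !partial
      if (any(partial)) saw_partial <- TRUE
      if (any(use)) {
        j <- idx[use]
        ci <- codon_i[use]
        p1 <- cds$end[i] - fr - 3L * ci
        ref_codon <- paste0(COMPLEMENT[b[p1]], COMPLEMENT[b[p1 - 1L]],
                            COMPLEMENT[b[p1 - 2L]])
        within <- off[use] %% 3L
        alt_codon <- mut_codon(ref_codon, within, COMPLEMENT[alts[j]])
        syn <- code[ref_codon] == code[alt_codon]
        any_syn[j] <- any_syn[j] | syn
        any_nonsyn[j] <- any_nonsyn[j] | !syn
      }
    }
  }
  if (saw_partial) {
    warning("position(s) in a trailing partial codon (incomplete stop) ",
            "cannot be classified; treated as non_coding")
  }
  ifelse(any_nonsyn, "non_synonymous",
         ifelse(any_syn, "synonymous", "non_coding"))
}

# replace the base at 0-based codon offset `within` with `base`
mut_codon <- function(codon, within, base) {
  out <- codon
  substr(out, within + 1L, within + 1L) <- base
  unname(out)
}
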