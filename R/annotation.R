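#' Mitochondrial genome annotation
#'
#' A `MitoAnnotation` bundles the mitochondrial reference sequence
#' (heavy strand, 1-based coordinates) with its feature map: protein-coding
#' genes, tRNAs, rRNAs, the non-coding D-loop control region, and any other
#' non-coding stretches. All downstream coordinate logic (feature lookup,
#' synonymy classification, region summaries) goes through this object.
#'
#' @param sequence Character scalar over A/C/G/T: the heavy-strand reference.
#' @param features A data.frame with columns `name`, `ftype` (one of
#'   `protein_coding`, `tRNA`, `rRNA`, `D_loop`, `other_noncoding`),
#'   `start`, `end` (1-based, inclusive), `strand` (`+`/`-`) and `frame`
#'   (reading-frame offset for protein-coding features, `NA` otherwise).
#' @param genetic_code NCBI translation table identifier; `"2"` is the
#'   vertebrate mitochondrial code.
#'
#' @return An object of class `MitoAnnotation`: a list with elements
#'   `genome_length`, `sequence` (character scalar), `bases` (character
#'   vector of length `genome_length`), `features` (validated data.frame)
#'   and `genetic_code`.
#' @export
mito_annotation <- function(sequence, features, genetic_code = "2") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("reference sequence may only contain A/C/G/T")
  }
  genome_length <- length(bases)
  features <- validate_features(features, genome_length)
  structure(
    list(genome_length = genome_length,
         sequence = sequence,
         bases = bases,
         features = features,
         genetic_code = as.character(genetic_code)),
    class = "MitoAnnotation"
  )
}

validate_features <- function(features, genome_length) {
  required <- c("name", "ftype", "start", "end", "strand")
  missing <- setdiff(required, names(features))
  if (length(missing) > 0L) {
    stop("annotation is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!"frame" %in% names(features)) features$frame <- NA_integer_
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$frame <- suppressWarnings(as.integer(features$frame))
  ok_types <- c("protein_coding", "tRNA", "rRNA", "D_loop", "other_noncoding")
  bad <- !features$ftype %in% ok_types
  if (any(bad)) {
    stop("unknown ftype for feature(s): ",
         paste(features$name[bad], collapse = ", "))
  }
  if (!all(features$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  oob <- features$start < 1L | features$end > genome_length |
    features$start > features$end
  if (any(oob)) {
    stop("feature(s) outside [1, ", genome_length, "] or with start > end: ",
         paste(features$name[oob], collapse = ", "))
  }
  cds <- features$ftype == "protein_coding"
  features$frame[cds & is.na(features$frame)] <- 0L
  rownames(features) <- NULL
  features
}

#' @export
print.MitoAnnotation <- function(x, ...) {
  cat("MitoAnnotation:", x$genome_length, "bp,",
      nrow(x$features), "features",
      sprintf("(genetic code %s)\n", x$genetic_code))
  print(table(x$features$ftype))
  invisible(x)
}

#' Load a mitochondrial annotation from disk
#'
#' Reads a tab-separated gene map (columns `name`, `ftype`, `start`, `end`,
#' `strand`, `frame`; optional `#key=value` header lines declaring
#' `genome_length` and `genetic_code`) together with a single-record FASTA
#' reference, validates both, and returns a [mito_annotation()] object.
#'
#' @param annotation_path Path to the tab-separated feature table.
#' @param fasta_path Path to a single-record FASTA file with the reference
#'   sequence.
#' @return A `MitoAnnotation`.
#' @examples
#' ann <- mouse_mt_annotation()
#' ann$genome_length
#' @export
load_annotation <- function(annotation_path, fasta_path) {
  if (!file.exists(annotation_path)) {
    stop("annotation file not found: ", annotation_path)
  }
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)

  lines <- readLines(annotation_path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(body)]
  header_kv <- parse_header_kv(hdr)

  fields <- strsplit(body, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1L])[1L]
    stop("malformed annotation row at line ",
         which(lines == body[bad])[1L], ": expected ", ncols[1L],
         " tab-separated fields, found ", ncols[bad])
  }
  features <- utils::read.delim(text = paste(body, collapse = "\n"),
                                stringsAsFactors = FALSE)
  n_start <- suppressWarnings(as.integer(features$start))
  n_end <- suppressWarnings(as.integer(features$end))
  bad_num <- is.na(n_start) | is.na(n_end)
  if (any(bad_num)) {
    stop("malformed annotation row for feature '",
         features$name[which(bad_num)[1L]], "': non-integer start/end")
  }

  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) {
    stop("expected a single-record FASTA, found ", length(seqs), " records")
  }
  sequence <- as.character(seqs[[1L]])

  declared <- header_kv[["genome_length"]]
  if (!is.null(declared) && as.integer(declared) != nchar(sequence)) {
    stop("FASTA sequence length (", nchar(sequence),
         ") does not match declared genome_length (", declared, ")")
  }
  code <- header_kv[["genetic_code"]]
  if (is.null(code)) code <- "2"
  mito_annotation(sequence, features, genetic_code = code)
}

parse_header_kv <- function(hdr) {
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", h))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  kv
}

#' Packaged mouse mitochondrial annotation
#'
#' Loads the annotation bundled with the package: a synthetic 16,299 bp
#' mouse-like mitochondrial reference sequence together with a gene map
#' following the standard mouse mitochondrial gene order (12S/16S rRNA,
#' 22 tRNAs, 13 protein-coding genes, D-loop at 15443-16299). The sequence
#' is synthetic (generated, not the RefSeq mouse chrM), so it supports
#' coordinate and synonymy logic but not alignment of real reads.
#'
#' @return A `MitoAnnotation` of length 16,299 bp.
#' @export
mouse_mt_annotation <- function() {
  load_annotation(
    system.file("extdata", "mouse_mt_annotation.tsv",
                package = "heteroplasmR", mustWork = TRUE),
    system.file("extdata", "mouse_mt_synthetic.fasta",
                package = "heteroplasmR", mustWork = TRUE)
  )
}

# priority used when a position falls in several features
region_priority <- c(protein_coding = 1L, tRNA = 2L, rRNA = 3L,
                     D_loop = 4L, other_noncoding = 5L)

#' Locate a position in the mitochondrial gene map
#'
#' Returns every feature whose span contains the position, plus a single
#' primary `region_class`. When a position falls in overlapping features the
#' primary class follows the fixed priority protein_coding > tRNA > rRNA >
#' D_loop; positions inside no feature are `other_noncoding`.
#'
#' @param ann A [mito_annotation()] object.
#' @param position 1-based position (scalar).
#' @return A list with `position`, `hits` (data.frame of name/ftype/strand,
#'   zero rows when the position is intergenic) and `region_class`.
#' @examples
#' loc <- locate(mouse_mt_annotation(), 14131)
#' loc$region_class
#' @export
locate <- function(ann, position) {
  stopifnot(inherits(ann, "MitoAnnotation"), length(position) == 1L)
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > ann$genome_length) {
    stop("position must lie in [1, ", ann$genome_length, "]")
  }
  f <- ann$features
  idx <- which(f$start <= position & f$end >= position)
  hits <- f[idx, c("name", "ftype", "strand"), drop = FALSE]
  rownames(hits) <- NULL
  if (nrow(hits) == 0L) {
    cls <- "other_noncoding"
  } else {
    cls <- hits$ftype[which.min(region_priority[hits$ftype])]
  }
  list(position = position, hits = hits, region_class = cls)
}

#' Primary region class for a vector of positions
#'
#' Vectorised companion to [locate()]: the primary region class for each
#' position under the same overlap priority.
#'
#' @param ann A `MitoAnnotation`.
#' @param positions Integer vector of 1-based positions.
#' @return Character vector of region classes, same length as `positions`.
#' @export
region_classes <- function(ann, positions) {
  stopifnot(inherits(ann, "MitoAnnotation"))
  positions <- as.integer(positions)
  if (length(positions) == 0L) return(character(0))
  if (any(is.na(positions)) || any(positions < 1L) ||
      any(positions > ann$genome_length)) {
    stop("positions must lie in [1, ", ann$genome_length, "]")
  }
  pri <- rep.int(region_priority[["other_noncoding"]], ann$genome_length)
  f <- ann$features[order(region_priority[ann$features$ftype],
                          decreasing = TRUE), ]
  for (i in seq_len(nrow(f))) {
    pri[f$start[i]:f$end[i]] <- region_priority[[f$ftype[i]]]
  }
  names(region_priority)[pri[positions]]
}

#' Packaged catalogue of known rRNA modification sites
#'
#' Loads the bundled table of known post-transcriptional modification classes
#' in the mitochondrial 12S and 16S rRNAs (pseudouridine Psi, m5U, m1A, m4C,
#' m5C, m62A, Gm, Um). The positions are representative placements within the
#' rRNA spans of the packaged synthetic reference, not curated coordinates.
#'
#' @return data.frame with columns `position`, `molecule`, `modification`.
#' @export
modification_catalogue <- function() {
  utils::read.delim(
    system.file("extdata", "rrna_modification_sites_synthetic.tsv",
                package = "heteroplasmR", mustWork = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Compare query positions against a modification-site catalogue
#'
#' For each query position, reports the catalogue entries at that exact
#' position (possibly none). Used to ask whether recurrent variant sites
#' coincide with known rRNA modification positions.
#'
#' @param positions Integer vector of 1-based query positions.
#' @param catalogue data.frame with at least a `position` column; defaults to
#'   the packaged rRNA catalogue.
#' @return data.frame with one row per (query, matching entry) pair plus one
#'   row with `NA` match columns for queries without any match; column
#'   `n_matches` gives the per-query match count.
#' @examples
#' check_known_modification_sites(c(179, 233, 729))
#' @export
check_known_modification_sites <- function(positions,
                                           catalogue = modification_catalogue()) {
  positions <- as.integer(positions)
  if (length(positions) == 0L) {
    return(data.frame(position = integer(0), molecule = character(0),
                      modification = character(0), n_matches = integer(0)))
  }
  out <- lapply(positions, function(p) {
    m <- catalogue[catalogue$position == p, , drop = FALSE]
    if (nrow(m) == 0L) {
      data.frame(position = p, molecule = NA_character_,
                 modification = NA_character_, n_matches = 0L)
    } else {
      data.frame(position = p, molecule = m$molecule,
                 modification = m$modification, n_matches = nrow(m))
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
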