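BASES <- c("A", "C", "G", "T")

# SAM flag bits honoured by the ingester
FLAG_UNMAPPED <- 4L
FLAG_SECONDARY <- 256L
FLAG_DUPLICATE <- 1024L
FLAG_SUPPLEMENTARY <- 2048L

#' Per-position base-count table
#'
#' The pipeline's canonical intermediate: for one sample, quality-filtered
#' counts of A/C/G/T at each covered mitochondrial position. Depth at a
#' position is the row sum of the four counts (i.e. quality-filtered depth,
#' which is the depth used in every downstream formula).
#'
#' @param sample_id Sample identifier (scalar).
#' @param pos Integer vector of 1-based positions, strictly increasing.
#' @param ref Reference base per position.
#' @param A,C,G,T Non-negative integer counts per position.
#' @return data.frame of class `basecount_table` with columns
#'   `sample_id`, `pos`, `ref`, `A`, `C`, `G`, `T`.
#' @export
basecount_table <- function(sample_id, pos = integer(0),
                            ref = character(0),
                            A = integer(0), C = integer(0),
                            G = integer(0), T = integer(0)) {
  tab <- data.frame(sample_id = rep_len(as.character(sample_id),
                                        length(pos)),
                    pos = as.integer(pos), ref = as.character(ref),
                    A = as.integer(A), C = as.integer(C),
                    G = as.integer(G), T = as.integer(T),
                    stringsAsFactors = FALSE)
  validate_basecounts(tab)
}

validate_basecounts <- function(tab) {
  required <- c("sample_id", "pos", "ref", "A", "C", "G", "T")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("base-count table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  tab <- tab[, required]
  counts <- as.matrix(tab[, BASES])
  if (any(is.na(counts)) || any(counts < 0L)) {
    stop("base counts must be non-negative integers")
  }
  if (nrow(tab) > 1L && any(diff(tab$pos) <= 0L)) {
    stop("positions must be strictly increasing")
  }
  if (any(tab$pos < 1L)) stop("positions must be >= 1")
  class(tab) <- c("basecount_table", "data.frame")
  tab
}

#' Quality-filtered depth of a base-count table
#'
#' @param tab A [basecount_table()].
#' @return Integer vector: per-row sum of the four base counts.
#' @export
basecount_depth <- function(tab) {
  as.integer(rowSums(tab[, BASES]))
}

#' Build a base-count table from aligned SAM records
#'
#' Converts aligned reads on the mitochondrial contig into per-position,
#' quality-filtered counts of A/C/G/T. A read contributes nothing when its
#' mapping quality is below `min_mapq` or it is flagged unmapped, duplicate,
#' secondary or supplementary. Within a surviving read, an aligned base is
#' counted at its reference position only when its base quality is at least
#' `min_baseq` and it is not `N`. Insertions and soft/hard-clipped segments
#' contribute no counts; deletions/skips advance the reference coordinate
#' only. Reads whose alignment extends past the genome end are skipped with
#' a warning.
#'
#' @param reads Path to a SAM file, or a data.frame as returned by
#'   [read_sam()].
#' @param filters A [filter_config()]; only `min_mapq`/`min_baseq` are used.
#' @param ann A [mito_annotation()] providing genome length and reference
#'   bases.
#' @param sample_id Sample identifier stored in the table; defaults to the
#'   SAM file name.
#' @return A [basecount_table()] with one row per position with at least one
#'   surviving base.
#' @export
ingest_alignments <- function(reads, filters = filter_config(), ann,
                              sample_id = NULL) {
  stopifnot(inherits(ann, "MitoAnnotation"))
  if (is.character(reads)) {
    if (is.null(sample_id)) {
      sample_id <- sub("\\.sam$", "", basename(reads))
    }
    reads <- read_sam(reads)
  }
  if (is.null(sample_id)) sample_id <- "sample"
  stopifnot(is.data.frame(reads))

  keep <- reads$mapq >= filters$min_mapq &
    bitwAnd(reads$flag, FLAG_UNMAPPED) == 0L &
    bitwAnd(reads$flag, FLAG_DUPLICATE) == 0L &
    bitwAnd(reads$flag, FLAG_SECONDARY) == 0L &
    bitwAnd(reads$flag, FLAG_SUPPLEMENTARY) == 0L
  reads <- reads[keep, , drop = FALSE]

  cells <- vector("list", nrow(reads))
  n_skipped <- 0L
  for (i in seq_len(nrow(reads))) {
    ab <- aligned_bases(reads$pos[i], reads$cigar[i], reads$seq[i],
                        reads$qual[i])
    if (is.null(ab)) next
    if (max(ab$rpos) > ann$genome_length) {
      n_skipped <- n_skipped + 1L
      next
    }
    ok <- ab$bq >= filters$min_baseq & ab$base %in% BASES
    if (!any(ok)) next
    cells[[i]] <- (ab$rpos[ok] - 1L) * 4L + match(ab$base[ok], BASES)
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " read(s) extending past the genome end were skipped")
  }
  cells <- unlist(cells)
  if (is.null(cells)) cells <- integer(0)
  counts <- matrix(tabulate(cells, nbins = 4L * ann$genome_length),
                   ncol = 4L, byrow = TRUE, dimnames = list(NULL, BASES))
  covered <- which(rowSums(counts) > 0L)
  basecount_table(sample_id, covered, ann$bases[covered],
                  counts[covered, "A"], counts[covered, "C"],
                  counts[covered, "G"], counts[covered, "T"])
}

# expand one alignment into (reference position, base, base quality)
aligned_bases <- function(pos, cigar, seq, qual) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(ops) == 0L) {
    if (cigar == "*") return(NULL)
    stop("malformed CIGAR string: ", cigar)
  }
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  kinds <- sub("^\\d+", "", ops)
  sbases <- strsplit(seq, "", fixed = TRUE)[[1]]
  bq <- if (identical(qual, "*")) {
    rep.int(0L, length(sbases))
  } else {
    utf8ToInt(qual) - 33L
  }
  if (length(bq) != length(sbases)) {
    stop("SEQ and QUAL lengths differ for a read at position ", pos)
  }
  rpos <- integer(0); qidx <- integer(0)
  r <- pos; q <- 1L
  for (k in seq_along(kinds)) {
    len <- lens[k]
    switch(kinds[k],
      "M" = , "=" = , "X" = {
        rpos <- c(rpos, r:(r + len - 1L))
        qidx <- c(qidx, q:(q + len - 1L))
        r <- r + len; q <- q + len
      },
      "I" = , "S" = { q <- q + len },
      "D" = , "N" = { r <- r + len },
      "H" = , "P" = NULL
    )
  }
  if (length(rpos) == 0L) return(NULL)
  list(rpos = rpos, base = sbases[qidx], bq = bq[qidx])
}

#' Read aligned records from a SAM file
#'
#' Parses the standard tab-separated SAM columns needed for pileup
#' (QNAME/FLAG/RNAME/POS/MAPQ/CIGAR/SEQ/QUAL). Header lines are skipped.
#'
#' @param path Path to a SAM file.
#' @return data.frame with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      seq = character(0), qual = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 11L)
  if (length(short) > 0L) {
    stop("malformed SAM record (fewer than 11 fields) at data line ",
         short[1L])
  }
  getf <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- suppressWarnings(as.integer(getf(2L)))
  pos <- suppressWarnings(as.integer(getf(4L)))
  mapq <- suppressWarnings(as.integer(getf(5L)))
  bad <- which(is.na(flag) | is.na(pos) | is.na(mapq))
  if (length(bad) > 0L) {
    stop("malformed SAM record (non-integer FLAG/POS/MAPQ) at data line ",
         bad[1L])
  }
  data.frame(qname = getf(1L), flag = flag, rname = getf(3L), pos = pos,
             mapq = mapq, cigar = getf(6L), seq = getf(10L),
             qual = getf(11L), stringsAsFactors = FALSE)
}

#' Write / read the canonical base-count TSV
#'
#' The exchange format is a tab-separated file with header
#' `sample_id pos ref A C G T`, one row per covered position, positions
#' strictly increasing. `write_basecounts()` followed by
#' [read_basecounts()] is the identity on valid tables.
#'
#' @param tab A [basecount_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_basecounts <- function(tab, path) {
  tab <- validate_basecounts(as.data.frame(tab))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_basecounts
#' @return For `read_basecounts()`: the parsed [basecount_table()].
#' @export
read_basecounts <- function(path) {
  if (!file.exists(path)) stop("base-count file not found: ", path)
  lines <- readLines(path)
  header <- c("sample_id", "pos", "ref", "A", "C", "G", "T")
  if (length(lines) == 0L ||
      !identical(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]], header)) {
    stop("base-count header mismatch in ", path,
         " (expected: ", paste(header, collapse = " "), ")")
  }
  body <- lines[-1L][nzchar(lines[-1L])]
  if (length(body) == 0L) return(basecount_table("empty")[0L, ])
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 7L)
  if (length(bad) > 0L) {
    stop("parse error at line ", bad[1L] + 1L, " of ", path,
         ": expected 7 fields")
  }
  getf <- function(i) vapply(fields, `[[`, character(1), i)
  ints <- lapply(c(2L, 4L, 5L, 6L, 7L), function(i) {
    suppressWarnings(as.integer(getf(i)))
  })
  bad <- which(Reduce(`|`, lapply(ints, is.na)))
  if (length(bad) > 0L) {
    stop("parse error at line ", bad[1L] + 1L, " of ", path,
         ": non-integer pos/count")
  }
  neg <- which(Reduce(`|`, lapply(ints[-1L], function(x) x < 0L)))
  if (length(neg) > 0L) {
    stop("parse error at line ", neg[1L] + 1L, " of ", path,
         ": negative count")
  }
  basecount_table(getf(1L)[1L], ints[[1L]], getf(3L),
                  ints[[2L]], ints[[3L]], ints[[4L]], ints[[5L]])
}
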