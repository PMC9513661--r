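#' Variant-calling filter configuration
#'
#' Holds the four quality thresholds of the analysis plus the detection
#' threshold used for presence/absence decisions downstream. Defaults are
#' the study values: read depth at least 100, allele frequency at least 1%
#' (both inclusive), mapping quality at least 20, base quality at least 30.
#'
#' @param min_depth Minimum quality-filtered depth for a position to be
#'   considered (default 100).
#' @param min_af Minimum allele frequency, inclusive (default 0.01).
#' @param min_mapq Minimum read mapping quality (default 20).
#' @param min_baseq Minimum base quality (default 30).
#' @param detection_threshold Heteroplasmy level above which a variant
#'   counts as present in a sample for recurrence/origin/pairing logic
#'   (default 0.01, mirroring `min_af`).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 100L, min_af = 0.01,
                          min_mapq = 20L, min_baseq = 30L,
                          detection_threshold = 0.01) {
  stopifnot(min_depth >= 1L, min_af > 0, min_af <= 1,
            min_mapq >= 0L, min_baseq >= 0L,
            detection_threshold > 0, detection_threshold <= 1)
  structure(list(min_depth = as.integer(min_depth), min_af = min_af,
                 min_mapq = as.integer(min_mapq),
                 min_baseq = as.integer(min_baseq),
                 detection_threshold = detection_threshold),
            class = "filter_config")
}

#' Heteroplasmy level of a variant
#'
#' The mtRNA heteroplasmy level is the variant read count divided by the
#' sequencing depth at the nucleotide position.
#'
#' @param alt_count Variant-supporting read count (0 <= alt_count <= depth).
#' @param depth Sequencing depth at the position (>= 1).
#' @return `alt_count / depth`, vectorised.
#' @examples
#' heteroplasmy(10, 1000)
#' @export
heteroplasmy <- function(alt_count, depth) {
  if (any(depth < 1)) stop("depth must be >= 1")
  if (any(alt_count < 0) || any(alt_count > depth)) {
    stop("alt_count must lie in [0, depth]")
  }
  alt_count / depth
}

empty_calls <- function() {
  data.frame(sample_id = character(0), pos = integer(0),
             ref = character(0), alt = character(0),
             alt_count = integer(0), depth = integer(0),
             h = numeric(0), stringsAsFactors = FALSE)
}

#' Call single-nucleotide variants from a base-count table
#'
#' A transparent threshold caller: at every position whose quality-filtered
#' depth is at least `min_depth`, each base different from the consensus
#' whose frequency is at least `min_af` (inclusive) is emitted as one
#' single-nucleotide variant with heteroplasmy level
#' `h = alt_count / depth`. Multi-allelic positions yield one record per
#' qualifying alternate base. Indels and multi-nucleotide substitutions are
#' outside the model by construction.
#'
#' @param tab A [basecount_table()].
#' @param consensus Consensus sequence to call against: a character scalar
#'   (whole sequence) or vector of per-position bases covering every
#'   position in `tab`. `NULL` (default) uses the table's `ref` column,
#'   i.e. the reference genome. See [consensus_from_tables()] for a
#'   majority-vote alternative.
#' @param filters A [filter_config()].
#' @return data.frame with columns `sample_id`, `pos`, `ref`, `alt`,
#'   `alt_count`, `depth`, `h`, sorted by (`pos`, `alt`). `ref` is the
#'   consensus base the call was made against.
#' @examples
#' tab <- basecount_table("s1", pos = 100, ref = "A",
#'                        A = 970, C = 15, G = 15, T = 0)
#' call_variants(tab)
#' @export
call_variants <- function(tab, consensus = NULL, filters = filter_config()) {
  tab <- validate_basecounts(as.data.frame(tab))
  if (nrow(tab) == 0L) return(empty_calls())
  if (is.null(consensus)) {
    cons <- tab$ref
  } else {
    if (length(consensus) == 1L && nchar(consensus) > 1L) {
      consensus <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
    }
    if (max(tab$pos) > length(consensus)) {
      stop("consensus shorter than the highest position in the table")
    }
    cons <- consensus[tab$pos]
  }
  if (any(is.na(cons) | !cons %in% BASES)) {
    stop("position lacking a consensus base")
  }
  depth <- basecount_depth(tab)
  keep <- depth >= filters$min_depth
  out <- vector("list", 4L)
  for (b in seq_along(BASES)) {
    base <- BASES[b]
    cnt <- tab[[base]]
    # inclusive >= min_af; small tolerance guards float representation of
    # exact boundary fractions such as 10/1000
    hit <- keep & cons != base & cnt > 0L &
      cnt >= filters$min_af * depth - 1e-9
    if (!any(hit)) next
    out[[b]] <- data.frame(sample_id = tab$sample_id[hit],
                           pos = tab$pos[hit], ref = cons[hit],
                           alt = base, alt_count = cnt[hit],
                           depth = depth[hit],
                           h = cnt[hit] / depth[hit],
                           stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(calls)) return(empty_calls())
  calls <- calls[order(calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Majority-vote consensus across a study's base-count tables
#'
#' Pools base counts over all supplied tables and returns, per position, the
#' most frequent base (ties broken by the reference base, then
#' alphabetically). Positions never covered fall back to the reference.
#'
#' @param tabs List of [basecount_table()]s.
#' @param ann A [mito_annotation()] supplying the fallback reference.
#' @return Character vector of length `ann$genome_length`.
#' @export
consensus_from_tables <- function(tabs, ann) {
  stopifnot(inherits(ann, "MitoAnnotation"))
  pooled <- matrix(0, nrow = ann$genome_length, ncol = 4L,
                   dimnames = list(NULL, BASES))
  for (tab in tabs) {
    tab <- as.data.frame(tab)
    pooled[tab$pos, ] <- pooled[tab$pos, , drop = FALSE] +
      as.matrix(tab[, BASES])
  }
  cons <- ann$bases
  covered <- which(rowSums(pooled) > 0)
  for (i in covered) {
    mx <- max(pooled[i, ])
    top <- BASES[pooled[i, ] == mx]
    cons[i] <- if (ann$bases[i] %in% top) ann$bases[i] else top[1L]
  }
  cons
}

#' Write variant calls as minimal VCF 4.2
#'
#' One record per call, `INFO` carrying `DP` (depth) and `AF` (heteroplasmy
#' level), and a single per-sample `FORMAT` column carrying `AD`
#' (reference,alternate counts) and `DP`. [read_vcf()] on the output
#' reproduces the calls exactly.
#'
#' @param calls Call data.frame as produced by [call_variants()], sorted by
#'   (`pos`, `alt`).
#' @param path Output path.
#' @param contig Contig name written in the header (default `chrM`).
#' @param genome_length Contig length for the header.
#' @param extra_header Optional character vector of extra `##` header lines
#'   (e.g. the filter thresholds in force).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, contig = "chrM",
                      genome_length = NA_integer_,
                      extra_header = character(0)) {
  if (nrow(calls) > 0L) {
    o <- order(calls$pos, calls$alt)
    if (!identical(o, seq_len(nrow(calls)))) {
      stop("calls must be sorted by (pos, alt)")
    }
  }
  sample_id <- if (nrow(calls) > 0L) calls$sample_id[1L] else "SAMPLE"
  contig_line <- if (is.na(genome_length)) {
    sprintf("##contig=<ID=%s>", contig)
  } else {
    sprintf("##contig=<ID=%s,length=%d>", contig, as.integer(genome_length))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=heteroplasmR_%s",
            as.character(utils::packageVersion("heteroplasmR"))),
    contig_line,
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Quality-filtered depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Heteroplasmy level (alt count / depth)\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read counts (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Quality-filtered depth\">",
    extra_header,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t")
  )
  records <- character(0)
  if (nrow(calls) > 0L) {
    records <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%s\tAD:DP\t%d,%d:%d",
      contig, calls$pos, calls$ref, calls$alt, calls$depth,
      format_af(calls$h), calls$depth - calls$alt_count, calls$alt_count,
      calls$depth
    )
  }
  writeLines(c(header, records), path)
  invisible(path)
}

format_af <- function(h) {
  sub("0+$", "", sub("\\.?0+$", "", sprintf("%.6f", h)))
}

#' Read calls back from a minimal VCF
#'
#' Parses VCF files written by [write_vcf()]. Heteroplasmy is recomputed
#' from `AD`/`DP` so the round-trip is exact.
#'
#' @param path Path to the VCF.
#' @return Call data.frame (same shape as [call_variants()] output).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1L] != "##fileformat=VCFv4.2") {
    stop("not a VCF 4.2 file: ", path)
  }
  chrom_i <- which(startsWith(lines, "#CHROM"))
  if (length(chrom_i) != 1L) stop("missing #CHROM header line in ", path)
  cols <- strsplit(lines[chrom_i], "\t", fixed = TRUE)[[1]]
  sample_id <- if (length(cols) >= 10L) cols[10L] else "SAMPLE"
  body <- lines[-seq_len(chrom_i)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) return(empty_calls())
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 10L)
  if (length(bad) > 0L) {
    stop("malformed VCF record at data line ", bad[1L], " of ", path)
  }
  getf <- function(i) vapply(fields, `[[`, character(1), i)
  ad <- strsplit(sub(":.*$", "", getf(10L)), ",", fixed = TRUE)
  alt_count <- as.integer(vapply(ad, `[[`, character(1), 2L))
  depth <- as.integer(sub("^.*:", "", getf(10L)))
  calls <- data.frame(sample_id = sample_id,
                      pos = as.integer(getf(2L)), ref = getf(4L),
                      alt = getf(5L), alt_count = alt_count,
                      depth = depth, h = alt_count / depth,
                      stringsAsFactors = FALSE)
  calls
}

#' Write / read the flat calls TSV mirror
#'
#' Tab-separated mirror of the VCF with columns
#' `sample_id pos ref alt alt_count depth h`. `h` is recomputed from the
#' integer columns on read, so the round-trip is exact.
#'
#' @param calls Call data.frame.
#' @param path File path.
#' @return `path` (write) or the calls data.frame (read).
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  calls <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(sample_id = "character",
                                            ref = "character",
                                            alt = "character"))
  required <- c("sample_id", "pos", "ref", "alt", "alt_count", "depth")
  missing <- setdiff(required, names(calls))
  if (length(missing) > 0L) {
    stop("calls file missing column(s): ", paste(missing, collapse = ", "))
  }
  calls$h <- calls$alt_count / calls$depth
  calls[, c(required, "h")]
}
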