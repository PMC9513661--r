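# shared fixtures and independent oracles, built in code

qchar <- function(q) {
  vapply(q, function(x) intToUtf8(33L + x), character(1))
}

qstring <- function(qs) paste(qchar(qs), collapse = "")

# toy 120 bp annotation: one plus-strand CDS starting with codon ATT,
# one minus-strand CDS, a tRNA, an rRNA and a D-loop, with gaps
toy_annotation <- function() {
  set.seed(42)
  bases <- sample(c("A", "C", "G", "T"), 120, replace = TRUE)
  bases[10:12] <- c("A", "T", "T")  # first codon of cdsA
  features <- data.frame(
    name = c("cdsA", "trnX", "cdsB", "rrnX", "dloop"),
    ftype = c("protein_coding", "tRNA", "protein_coding", "rRNA",
              "D_loop"),
    start = c(10L, 31L, 41L, 62L, 101L),
    end = c(30L, 40L, 61L, 80L, 120L),
    strand = c("+", "+", "-", "+", "+"),
    frame = c(0L, NA, 0L, NA, NA),
    stringsAsFactors = FALSE
  )
  mito_annotation(paste(bases, collapse = ""), features)
}

make_read <- function(pos, seq, bq = rep(40L, nchar(seq)), mapq = 60L,
                      flag = 0L, cigar = sprintf("%dM", nchar(seq)),
                      qname = "r1") {
  data.frame(qname = qname, flag = flag, rname = "chrM", pos = pos,
             mapq = mapq, cigar = cigar, seq = seq, qual = qstring(bq),
             stringsAsFactors = FALSE)
}

# minimal two-mouse design: mouse mA with two complexes, mouse mB with one
toy_meta <- function() {
  sample_meta(data.frame(
    sample_id = c("oA1", "cA1", "oA2", "cA2", "oB1", "cB1"),
    mouse_id = c("mA", "mA", "mA", "mA", "mB", "mB"),
    age_group = c(rep("3wk", 4), rep("9wk", 2)),
    cell_type = rep(c("oocyte", "cumulus"), 3),
    complex_id = c("cxA1", "cxA1", "cxA2", "cxA2", "cxB1", "cxB1"),
    stringsAsFactors = FALSE
  ))
}

make_call <- function(sample_id, pos, h, ref = "A", alt = "G",
                      depth = 1000L) {
  alt_count <- as.integer(round(h * depth))
  data.frame(sample_id = sample_id, pos = as.integer(pos), ref = ref,
             alt = alt, alt_count = alt_count, depth = depth,
             h = alt_count / depth, stringsAsFactors = FALSE)
}

# brute-force caller: tests every (position, base) pair independently
caller_oracle <- function(tab, filters) {
  out <- list()
  for (i in seq_len(nrow(tab))) {
    depth <- tab$A[i] + tab$C[i] + tab$G[i] + tab$T[i]
    if (depth < filters$min_depth) next
    for (b in c("A", "C", "G", "T")) {
      if (b == tab$ref[i]) next
      cnt <- tab[[b]][i]
      if (cnt == 0 || cnt / depth < filters$min_af - 1e-12) next
      out[[length(out) + 1L]] <- data.frame(
        sample_id = tab$sample_id[i], pos = tab$pos[i], ref = tab$ref[i],
        alt = b, alt_count = cnt, depth = depth, h = cnt / depth,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(NULL)
  res <- res[order(res$pos, res$alt), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# whole-gene translation oracle for synonymy: substitute at the sequence
# level, translate the complete-codon part of ref and mutant gene with the
# vertebrate mitochondrial code, compare whole proteins; per-gene verdicts
# are combined with the any-non-synonymous rule
syn_oracle_gene <- function(ann, frow, pos, alt) {
  fr <- frow$frame
  if (is.na(fr)) fr <- 0L
  len <- frow$end - frow$start + 1L
  nc <- (len - fr) %/% 3L
  translate_part <- function(chars) {
    g <- paste(chars[frow$start:frow$end], collapse = "")
    dna <- Biostrings::DNAString(g)
    if (frow$strand == "-") dna <- Biostrings::reverseComplement(dna)
    coding <- Biostrings::subseq(dna, fr + 1L, fr + 3L * nc)
    as.character(Biostrings::translate(
      coding, genetic.code = Biostrings::getGeneticCode(ann$genetic_code),
      no.init.codon = TRUE))
  }
  # is the position inside a complete codon of this gene?
  off <- if (frow$strand == "+") pos - (frow$start + fr) else
    (frow$end - fr) - pos
  if (off < 0L || off %/% 3L >= nc) return("non_coding")
  mut <- ann$bases
  mut[pos] <- alt
  if (translate_part(ann$bases) == translate_part(mut)) "synonymous"
  else "non_synonymous"
}

syn_oracle <- function(ann, pos, alt) {
  cds <- ann$features[ann$features$ftype == "protein_coding", ,
                      drop = FALSE]
  hit <- cds[cds$start <= pos & cds$end >= pos, , drop = FALSE]
  if (nrow(hit) == 0L) return("non_coding")
  verdicts <- vapply(seq_len(nrow(hit)), function(i) {
    syn_oracle_gene(ann, hit[i, ], pos, alt)
  }, character(1))
  if (any(verdicts == "non_synonymous")) "non_synonymous"
  else if (any(verdicts == "synonymous")) "synonymous"
  else "non_coding"
}

# sum-of-squares ANOVA oracle
anova_oracle <- function(groups) {
  values <- unlist(groups)
  k <- length(groups)
  n <- length(values)
  grand <- mean(values)
  ssb <- sum(lengths(groups) *
               (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, df = c(k - 1, n - k),
       p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# step-down Sidak formula evaluated directly
holm_sidak_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  terms <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  for (i in seq_len(m)[-1]) terms[i] <- max(terms[i], terms[i - 1])
  out <- numeric(m)
  out[ord] <- pmin(terms, 1)
  out
}
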