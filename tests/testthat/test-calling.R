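flt <- filter_config()

test_that("heteroplasmy is the exact count ratio with domain checks", {
  expect_equal(heteroplasmy(10, 1000), 0.01)
  expect_equal(heteroplasmy(0, 500), 0)
  expect_equal(heteroplasmy(500, 500), 1)
  expect_equal(heteroplasmy(c(1, 2), c(10, 10)), c(0.1, 0.2))
  expect_error(heteroplasmy(1, 0), "depth")
  expect_error(heteroplasmy(11, 10), "alt_count")
})

test_that("depth and allele-frequency thresholds are inclusive boundaries", {
  tab <- basecount_table("s1", pos = 50L, ref = "A",
                         A = 49L, C = 50L, G = 0L, T = 0L)  # depth 99
  expect_equal(nrow(call_variants(tab, filters = flt)), 0L)

  tab <- basecount_table("s1", pos = 50L, ref = "A",
                         A = 50L, C = 50L, G = 0L, T = 0L)  # depth 100
  calls <- call_variants(tab, filters = flt)
  expect_equal(calls$alt, "C")
  expect_equal(calls$h, 0.5)

  # exactly 1% is called, just below is not
  tab <- basecount_table("s1", pos = 50L, ref = "A",
                         A = 990L, C = 10L, G = 0L, T = 0L)
  calls <- call_variants(tab, filters = flt)
  expect_equal(calls$h, 0.01)
  tab <- basecount_table("s1", pos = 50L, ref = "A",
                         A = 991L, C = 9L, G = 0L, T = 0L)
  expect_equal(nrow(call_variants(tab, filters = flt)), 0L)
})

test_that("multi-allelic positions emit one record per alternate", {
  tab <- basecount_table("s1", pos = 50L, ref = "A",
                         A = 970L, C = 15L, G = 15L, T = 0L)
  calls <- call_variants(tab, filters = flt)
  expect_equal(calls$alt, c("C", "G"))
  expect_equal(calls$h, c(0.015, 0.015))
})

test_that("calls match the per-(position, base) brute-force oracle", {
  set.seed(11)
  for (rep in 1:15) {
    n <- sample(1:50, 1)
    pos <- sort(sample(1:200, n))
    ref <- sample(c("A", "C", "G", "T"), n, TRUE)
    counts <- matrix(rnbinom(4 * n, mu = 40, size = 1), ncol = 4)
    tab <- basecount_table("s1", pos, ref, counts[, 1], counts[, 2],
                           counts[, 3], counts[, 4])
    f <- filter_config(min_depth = sample(c(1L, 50L, 100L), 1),
                       min_af = sample(c(0.01, 0.05, 0.2), 1))
    got <- call_variants(tab, filters = f)
    want <- caller_oracle(tab, f)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got, want)
    }
  }
})

test_that("stricter filters yield a subset of calls with h in [min_af, 1]", {
  set.seed(12)
  n <- 40L
  tab <- basecount_table("s1", seq_len(n),
                         sample(c("A", "C", "G", "T"), n, TRUE),
                         rnbinom(n, mu = 100, size = 2),
                         rnbinom(n, mu = 10, size = 2),
                         rnbinom(n, mu = 10, size = 2),
                         rnbinom(n, mu = 10, size = 2))
  loose <- call_variants(tab, filters = filter_config(min_depth = 50L,
                                                      min_af = 0.01))
  strict <- call_variants(tab, filters = filter_config(min_depth = 120L,
                                                       min_af = 0.05))
  loose_keys <- paste(loose$pos, loose$alt)
  strict_keys <- paste(strict$pos, strict$alt)
  expect_true(all(strict_keys %in% loose_keys))
  expect_true(all(loose$h >= 0.01 & loose$h <= 1))
})

test_that("an explicit consensus overrides the reference column", {
  tab <- basecount_table("s1", pos = 3L, ref = "A",
                         A = 30L, C = 170L, G = 0L, T = 0L)
  # majority-vote consensus flips the site: now A is the variant
  cons <- rep("C", 10)
  calls <- call_variants(tab, consensus = cons,
                         filters = filter_config(min_depth = 100L))
  expect_equal(calls$alt, "A")
  expect_equal(calls$ref, "C")
  expect_error(call_variants(tab, consensus = c("A", "C"),
                             filters = flt), "consensus shorter")
})

test_that("majority consensus is recomputed across tables", {
  toy <- toy_annotation()
  ref5 <- reference_base(toy, 5L)
  other <- setdiff(c("A", "C", "G", "T"), ref5)[1L]
  args <- stats::setNames(list(200L, 0L, 0L, 0L), c(other, setdiff(
    c("A", "C", "G", "T"), other)))
  tabs <- lapply(c("s1", "s2"), function(sid) {
    basecount_table(sid, pos = 5L, ref = ref5,
                    A = args[["A"]], C = args[["C"]],
                    G = args[["G"]], T = args[["T"]])
  })
  cons <- consensus_from_tables(tabs, toy)
  expect_equal(cons[5L], other)
  expect_equal(cons[6L], reference_base(toy, 6L))
})

test_that("VCF serialization round-trips exactly", {
  tab <- basecount_table("s1", pos = c(233L, 500L), ref = c("G", "A"),
                         A = c(50L, 900L), C = c(0L, 0L),
                         G = c(950L, 0L), T = c(0L, 100L))
  calls <- call_variants(tab, filters = flt)
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path, genome_length = 16299L)
  expect_identical(read_vcf(path), calls)
  lines <- readLines(path)
  expect_equal(lines[1L], "##fileformat=VCFv4.2")

  write_vcf(calls[0L, ], path)
  expect_equal(nrow(read_vcf(path)), 0L)

  expect_error(write_vcf(calls[2:1, ], path), "sorted")
})

test_that("an independent VCF parser agrees with the writer", {
  tab <- basecount_table("s1", pos = 233L, ref = "G",
                         A = 50L, C = 0L, G = 950L, T = 0L)
  calls <- call_variants(tab, filters = flt)
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path, genome_length = 16299L)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_equal(as.integer(v@fix[, "POS"]), 233L)
  expect_equal(unname(v@fix[, "REF"]), "G")
  expect_equal(unname(v@fix[, "ALT"]), "A")
  info <- vcfR::extract.info(v, "AF", as.numeric = TRUE)
  expect_equal(info, 0.05)
})

test_that("the flat calls TSV round-trips", {
  tab <- basecount_table("s1", pos = c(10L, 20L), ref = c("A", "C"),
                         A = c(500L, 30L), C = c(100L, 570L),
                         G = c(0L, 0L), T = c(0L, 0L))
  calls <- call_variants(tab, filters = flt)
  path <- tempfile(fileext = ".tsv")
  write_calls(calls, path)
  expect_equal(read_calls(path), calls)
})
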