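meta <- toy_meta()
flt <- filter_config()

test_that("metadata validation enforces the study design invariants", {
  expect_s3_class(meta, "sample_meta")
  bad <- as.data.frame(meta)
  bad$age_group[5] <- "3wk"  # mouse mB now in two age groups
  bad2 <- as.data.frame(meta)
  bad2$cell_type[2] <- "oocyte"  # two oocytes in one complex
  expect_error(sample_meta(bad), "age_group")
  expect_error(sample_meta(bad2), "same cell type")
})

test_that("recurrence requires detection in two samples of one mouse", {
  calls <- rbind(make_call("oA1", 100, 0.05), make_call("cA1", 100, 0.20),
                 make_call("oA2", 300, 0.10),                 # singleton
                 make_call("oB1", 400, 0.05), make_call("cA2", 400, 0.05))
  rvs <- recurrent_variants(calls, meta, flt)
  expect_equal(nrow(rvs), 1L)
  expect_equal(rvs$pos, 100L)
  expect_equal(rvs$mouse_id, "mA")
  expect_equal(rvs$n_samples_detected, 2L)
  h <- rvs$per_sample_h[[1L]]
  expect_equal(sort(names(h)), sort(meta$sample_id[meta$mouse_id == "mA"]))
  expect_equal(unname(h[c("oA1", "cA1", "oA2", "cA2")]),
               c(0.05, 0.20, 0, 0))
})

test_that("unknown samples and duplicate records are rejected", {
  expect_error(recurrent_variants(make_call("nope", 1, 0.5), meta, flt),
               "not in metadata")
  dup <- rbind(make_call("oA1", 100, 0.05), make_call("oA1", 100, 0.06))
  expect_error(recurrent_variants(dup, meta, flt), "duplicate")
})

test_that("maternal origin follows the cumulus-detection criterion", {
  # detected in both cumulus samples, absent from oocytes
  calls <- rbind(make_call("cA1", 100, 0.10), make_call("cA2", 100, 0.08))
  rvs <- recurrent_variants(calls, meta, flt)
  expect_equal(rvs$origin, "maternal")
  expect_equal(rvs$oocyte_detection, "cumulus_only")

  # an oocyte just under 1% does not change the class
  calls <- rbind(make_call("cA1", 100, 0.10), make_call("cA2", 100, 0.08),
                 make_call("oA1", 100, 0.009))
  rvs <- recurrent_variants(calls, meta, flt)
  expect_equal(rvs$origin, "maternal")
  expect_equal(rvs$oocyte_detection, "cumulus_only")

  # detected only in the two oocytes: not maternal, oocyte_detected
  calls <- rbind(make_call("oA1", 100, 0.10), make_call("oA2", 100, 0.08))
  rvs <- recurrent_variants(calls, meta, flt)
  expect_equal(rvs$origin, "unclassified")
  expect_equal(rvs$oocyte_detection, "oocyte_detected")

  # with the relaxed single-cumulus criterion a 1-OCC mouse can qualify
  calls <- rbind(make_call("oB1", 100, 0.10), make_call("cB1", 100, 0.08))
  strict <- recurrent_variants(calls, meta, flt)
  relaxed <- recurrent_variants(calls, meta, flt,
                                maternal_min_cumulus = 1L)
  expect_equal(strict$origin, "unclassified")
  expect_equal(relaxed$origin, "maternal")
})

test_that("a mouse without cumulus samples warns and stays unclassified", {
  solo <- sample_meta(data.frame(
    sample_id = c("o1", "o2"), mouse_id = "mC", age_group = "9wk",
    cell_type = "oocyte", complex_id = c("cx1", "cx2"),
    stringsAsFactors = FALSE))
  calls <- rbind(make_call("o1", 100, 0.1), make_call("o2", 100, 0.1))
  expect_warning(rvs <- recurrent_variants(calls, solo, flt),
                 "zero cumulus")
  expect_equal(rvs$origin, "unclassified")
})

test_that("paired deltas follow the oocyte-minus-cumulus sign convention", {
  calls <- rbind(make_call("oA1", 100, 0.05), make_call("cA1", 100, 0.25),
                 make_call("oA1", 200, 0.12), make_call("cA1", 200, 0.12),
                 make_call("cA1", 300, 0.10))
  deltas <- paired_deltas(calls, meta, flt)
  expect_equal(deltas$delta[deltas$pos == 100], -0.20)
  expect_equal(deltas$delta[deltas$pos == 200], 0)
  expect_equal(deltas$delta[deltas$pos == 300], -0.10)
  expect_equal(deltas$h_oocyte[deltas$pos == 300], 0)
})

test_that("incomplete complexes are skipped with a warning", {
  lop <- as.data.frame(meta)[-2L, ]  # drop cA1: cxA1 is oocyte-only
  calls <- rbind(make_call("oA1", 100, 0.05), make_call("oA2", 100, 0.05))
  expect_warning(deltas <- paired_deltas(calls, sample_meta(lop), flt),
                 "cxA1")
  expect_false("cxA1" %in% deltas$complex_id)
})

test_that("delta averages include zeros (A) or exclude them (B)", {
  calls <- rbind(make_call("oA1", 100, 0.30), make_call("cA1", 100, 0.10),
                 make_call("oA2", 100, 0.10), make_call("cA2", 100, 0.20))
  deltas <- paired_deltas(calls, meta, flt)
  avgs <- delta_averages(deltas, meta)
  # three complete complexes; the variant is absent from cxB1
  expect_equal(avgs$n_complexes_observed, 2L)
  expect_equal(avgs$avg_A, (0.2 - 0.1 + 0) / 3)
  expect_equal(avgs$avg_B, (0.2 - 0.1) / 2)
})

test_that("heteroplasmy bins partition with 10% and 50% in the middle bin", {
  expect_equal(unname(bin_by_level(c(0.02, 0.12, 0.60))), c(1L, 1L, 1L))
  expect_equal(unname(bin_by_level(c(0.05, 0.07))), c(2L, 0L, 0L))
  expect_equal(unname(bin_by_level(numeric(0))), c(0L, 0L, 0L))
  expect_equal(unname(bin_by_level(c(0.10, 0.50, 0.5000001))),
               c(0L, 2L, 1L))
  expect_error(bin_by_level(0.005), "below the calling floor")
  set.seed(3)
  h <- runif(200, 0.01, 1)
  expect_equal(sum(bin_by_level(h)), 200L)
})

test_that("synonymy summary counts coding variants once per cell type", {
  ann <- mouse_mt_annotation()
  # pick a guaranteed non-synonymous coding change inside mt-Nd5
  pos <- 12216L
  ref <- reference_base(ann, pos)
  alts <- setdiff(c("A", "C", "G", "T"), ref)
  cls <- classify_substitutions(ann, rep(pos, 3), alts)
  alt <- alts[cls == "non_synonymous"][1L]
  calls <- rbind(make_call("oA1", pos, 0.04, ref = ref, alt = alt),
                 make_call("oA2", pos, 0.03, ref = ref, alt = alt))
  rvs <- recurrent_variants(calls, meta, flt)
  summ <- synonymy_summary(rvs, meta, ann, flt)
  oo_low_nonsyn <- summ$synonymy$count[
    summ$synonymy$cell_type == "oocyte" &
      summ$synonymy$bin == "(1%,10%)" &
      summ$synonymy$class == "non_synonymous"]
  expect_equal(oo_low_nonsyn, 1L)
  expect_equal(sum(summ$synonymy$count[
    summ$synonymy$cell_type == "cumulus"]), 0L)
  expect_equal(sum(summ$regions$count[
    summ$regions$region_class == "protein_coding" &
      summ$regions$cell_type == "oocyte"]), 1L)

  empty <- synonymy_summary(rvs[0L, ], meta, ann, flt)
  expect_true(all(empty$synonymy$count == 0L))
})

test_that("a cohort planted 2:1 non-synonymous:synonymous tabulates 2:1", {
  ann <- mouse_mt_annotation()
  # search coding positions for two non-synonymous and one synonymous change
  cds <- ann$features[ann$features$name == "mt-Nd5", ]
  picks <- list()
  for (pos in seq(cds$start, cds$end)) {
    ref <- reference_base(ann, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      cls <- suppressWarnings(classify_substitution(ann, pos, alt))
      slot <- if (cls == "non_synonymous") c("ns1", "ns2") else
        if (cls == "synonymous") "syn" else character(0)
      for (s in slot) {
        if (is.null(picks[[s]])) {
          picks[[s]] <- list(pos = pos, ref = ref, alt = alt)
          break
        }
      }
      if (length(picks) == 3L) break
    }
    if (length(picks) == 3L) break
  }
  calls <- do.call(rbind, lapply(picks, function(p) {
    rbind(make_call("oA1", p$pos, 0.05, ref = p$ref, alt = p$alt),
          make_call("oA2", p$pos, 0.05, ref = p$ref, alt = p$alt))
  }))
  rvs <- recurrent_variants(calls, meta, flt)
  summ <- synonymy_summary(rvs, meta, ann, flt)
  counts <- tapply(summ$synonymy$count[summ$synonymy$cell_type == "oocyte"],
                   summ$synonymy$class[summ$synonymy$cell_type == "oocyte"],
                   sum)
  expect_equal(unname(counts[["non_synonymous"]]) /
                 unname(counts[["synonymous"]]), 2)
})

test_that("top variants rank deterministically with positional tie-break", {
  calls <- rbind(make_call("oA1", 100, 0.30), make_call("cA1", 100, 0.30),
                 make_call("oA1", 200, 0.20), make_call("cA1", 200, 0.20),
                 make_call("oA1", 300, 0.30), make_call("cA1", 300, 0.30))
  rvs <- recurrent_variants(calls, meta, flt)
  top <- top_variants(rvs, 2L, "mean_h")
  expect_equal(top$pos, c(100L, 300L))  # tie at 0.30 broken by position
  expect_message(all3 <- top_variants(rvs, 10L, "mean_h"), "returning all")
  expect_equal(nrow(all3), 3L)

  deltas <- paired_deltas(calls, meta, flt)
  topd <- top_variants(rvs, 1L, "mean_abs_delta", deltas)
  expect_equal(nrow(topd), 1L)
  expect_error(top_variants(rvs, 1L, "mean_abs_delta"), "requires")
})
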