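log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

run_manifest <- function(outdir, stage, seed = NA_integer_,
                         config = list(), counts = list()) {
  files <- setdiff(list.files(outdir, recursive = TRUE),
                   "manifest.json")
  paths <- file.path(outdir, files)
  manifest <- list(
    tool = "heteroplasmR",
    version = as.character(utils::packageVersion("heteroplasmR")),
    stage = stage, seed = seed, config = config,
    row_counts = counts,
    files = data.frame(file = files,
                       md5 = unname(tools::md5sum(paths)),
                       stringsAsFactors = FALSE),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

prepare_outdir <- function(outdir, force) {
  if (dir.exists(outdir) && length(list.files(outdir)) > 0L && !force) {
    stop("output directory exists and is not empty: ", outdir,
         " (use force = TRUE to overwrite)")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  invisible(outdir)
}

#' Simulate a study and write it to disk
#'
#' Runs [simulate_study()] and writes the metadata TSV, one base-count TSV
#' per sample (`basecounts/<sample_id>.tsv`), the planted-truth tables and
#' a run manifest with file checksums.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory.
#' @param ann A [mito_annotation()].
#' @param force Overwrite a non-empty `outdir` (default `FALSE`).
#' @return The simulation result, invisibly.
#' @export
run_simulate <- function(cfg = sim_config(), outdir,
                         ann = mouse_mt_annotation(), force = FALSE) {
  prepare_outdir(outdir, force)
  sim <- simulate_study(cfg, ann)
  write_meta(sim$meta, file.path(outdir, "metadata.tsv"))
  dir.create(file.path(outdir, "basecounts"), showWarnings = FALSE)
  for (sid in names(sim$counts)) {
    write_basecounts(sim$counts[[sid]],
                     file.path(outdir, "basecounts",
                               paste0(sid, ".tsv")))
  }
  utils::write.table(sim$truth$variants,
                     file.path(outdir, "truth_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$realized,
                     file.path(outdir, "truth_realized.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$modifications,
                     file.path(outdir, "truth_modifications.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("simulate", "%d samples, %d planted variants",
            nrow(sim$meta), nrow(sim$truth$variants))
  run_manifest(outdir, "simulate", seed = cfg$seed,
               config = unclass(cfg)[setdiff(names(cfg),
                                             "modification_sites")],
               counts = list(samples = nrow(sim$meta),
                             planted_variants = nrow(sim$truth$variants)))
  invisible(sim)
}

#' Call variants for one base-count table file
#'
#' Reads a canonical base-count TSV, calls variants with the configured
#' thresholds, and writes both the VCF (with the thresholds echoed in its
#' header) and the flat TSV mirror.
#'
#' @param basecounts_path Path to a base-count TSV.
#' @param out_prefix Output prefix; writes `<prefix>.vcf` and
#'   `<prefix>.tsv`.
#' @param ann A [mito_annotation()].
#' @param filters A [filter_config()].
#' @param consensus Optional consensus sequence (defaults to the
#'   reference; see [call_variants()]).
#' @return The calls data.frame, invisibly.
#' @export
run_call <- function(basecounts_path, out_prefix,
                     ann = mouse_mt_annotation(),
                     filters = filter_config(), consensus = NULL) {
  tab <- read_basecounts(basecounts_path)
  if (nrow(tab) > 0L && max(tab$pos) > ann$genome_length) {
    stop("base-count table references positions beyond the reference (",
         ann$genome_length, " bp)")
  }
  calls <- call_variants(tab, consensus = consensus, filters = filters)
  filter_header <- sprintf(
    "##heteroplasmR_filter=<min_depth=%d,min_af=%g,min_mapq=%d,min_baseq=%d>",
    filters$min_depth, filters$min_af, filters$min_mapq,
    filters$min_baseq)
  write_vcf(calls, paste0(out_prefix, ".vcf"),
            genome_length = ann$genome_length,
            extra_header = filter_header)
  write_calls(calls, paste0(out_prefix, ".tsv"))
  log_stage("call", "%s: %d calls", basename(basecounts_path),
            nrow(calls))
  invisible(calls)
}

#' Run the cohort and statistics reports
#'
#' From per-sample calls and metadata, writes the recurrent-variant table
#' (with origin classes), paired oocyte-cumulus deltas and their averages,
#' heteroplasmy bin counts, synonymy and region summaries, age-group
#' ANOVA / Holm-Sidak tests, top variants under both ranking criteria with
#' per-site paired t-tests, sister-sample CVs, D-loop cumulative curves,
#' and a manifest.
#'
#' @param calls Combined call data.frame, or a directory of `*.tsv` call
#'   files written by [run_call()].
#' @param meta Metadata data.frame or path to a metadata TSV.
#' @param outdir Output directory.
#' @param ann A [mito_annotation()].
#' @param filters A [filter_config()].
#' @param force Overwrite a non-empty `outdir`.
#' @return Invisible list of all computed tables.
#' @export
run_analyze <- function(calls, meta, outdir, ann = mouse_mt_annotation(),
                        filters = filter_config(), force = FALSE) {
  prepare_outdir(outdir, force)
  if (is.character(meta)) meta <- read_meta(meta)
  meta <- sample_meta(meta)
  if (is.character(calls)) {
    files <- list.files(calls, pattern = "\\.tsv$", full.names = TRUE)
    calls <- do.call(rbind, lapply(files, read_calls))
    if (is.null(calls)) calls <- empty_calls()
  }
  tsv <- function(x, name) {
    utils::write.table(x, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  rvs <- recurrent_variants(calls, meta, filters)
  flat <- rvs[, setdiff(names(rvs), "per_sample_h")]
  tsv(flat, "recurrent_variants.tsv")

  deltas <- withCallingHandlers(
    paired_deltas(calls, meta, filters),
    warning = function(w) {
      log_stage("analyze", "%s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  tsv(deltas, "paired_deltas.tsv")
  tsv(delta_averages(deltas, meta), "delta_averages.tsv")

  bins <- if (nrow(calls) > 0L) {
    calls$cell_type <- meta$cell_type[match(calls$sample_id,
                                            meta$sample_id)]
    do.call(rbind, lapply(split(calls, calls$cell_type), function(g) {
      data.frame(cell_type = g$cell_type[1L], bin = BIN_LABELS,
                 count = bin_by_level(g$h, filters$min_af),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(cell_type = character(0), bin = character(0),
               count = integer(0))
  }
  tsv(bins, "bin_counts.tsv")

  syn <- synonymy_summary(rvs, meta, ann, filters)
  tsv(syn$synonymy, "synonymy_counts.tsv")
  tsv(syn$regions, "region_counts.tsv")

  stat_rows <- list()
  for (ct in CELL_TYPES) {
    res <- tryCatch(
      withCallingHandlers(
        age_group_tests(calls, meta, ct),
        warning = function(w) {
          log_stage("analyze", "%s (%s)", conditionMessage(w), ct)
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(res) || is.null(res$omnibus)) next
    stat_rows[[paste0("anova_", ct)]] <- data.frame(
      method = "one_way_anova", group = ct,
      statistic = res$omnibus$statistic,
      df = paste(res$omnibus$df, collapse = ","),
      p_raw = res$omnibus$p_raw, p_adjusted = NA_real_,
      family_id = NA_character_, stringsAsFactors = FALSE)
    if (nrow(res$pairwise) > 0L) {
      stat_rows[[paste0("pairwise_", ct)]] <- data.frame(
        method = "pairwise_t",
        group = paste(ct, res$pairwise$group1, res$pairwise$group2,
                      sep = ":"),
        statistic = res$pairwise$t,
        df = as.character(res$pairwise$df),
        p_raw = res$pairwise$p_raw,
        p_adjusted = res$pairwise$p_adjusted,
        family_id = paste0("holm_sidak_", ct),
        stringsAsFactors = FALSE)
    }
  }

  # oocyte vs cumulus linear fit over complete pairs (both members called)
  both <- deltas[deltas$h_oocyte > 0 & deltas$h_cumulus > 0, ,
                 drop = FALSE]
  fit <- if (nrow(both) >= 3L && stats::var(both$h_oocyte) > 0) {
    linear_fit(both$h_oocyte, both$h_cumulus)
  } else {
    NULL
  }
  if (!is.null(fit)) {
    stat_rows[["linear_fit"]] <- data.frame(
      method = "linear_fit", group = "oocyte_vs_cumulus",
      statistic = fit$statistic, df = as.character(fit$df),
      p_raw = fit$p_raw, p_adjusted = NA_real_,
      family_id = sprintf("r_squared=%.4f", fit$extras$r_squared),
      stringsAsFactors = FALSE)
  }

  top_h <- top_variants(rvs, 5L, "mean_h")
  top_d <- tryCatch(top_variants(rvs, 5L, "mean_abs_delta", deltas),
                    error = function(e) NULL)
  tsv(top_h, "top_variants_mean_h.tsv")
  if (!is.null(top_d)) tsv(top_d, "top_variants_mean_abs_delta.tsv")
  for (i in seq_len(nrow(top_h))) {
    sub <- deltas[deltas$pos == top_h$pos[i] &
                    deltas$alt == top_h$alt[i], , drop = FALSE]
    if (nrow(sub) < 2L || all(sub$delta == 0)) next
    pt <- paired_t(sub$h_oocyte, sub$h_cumulus)
    stat_rows[[paste0("paired_t_", top_h$pos[i])]] <- data.frame(
      method = "paired_t",
      group = sprintf("site_%d_%s", top_h$pos[i], top_h$alt[i]),
      statistic = pt$statistic, df = as.character(pt$df),
      p_raw = pt$p_raw, p_adjusted = NA_real_,
      family_id = sprintf("n_pairs=%d;n_negative_delta=%d",
                          nrow(sub), sum(sub$delta < 0)),
      stringsAsFactors = FALSE)
  }
  stats_report <- do.call(rbind, stat_rows)
  if (is.null(stats_report)) {
    stats_report <- data.frame(method = character(0), group = character(0),
                               statistic = numeric(0), df = character(0),
                               p_raw = numeric(0), p_adjusted = numeric(0),
                               family_id = character(0))
  }
  rownames(stats_report) <- NULL
  tsv(stats_report, "stats_report.tsv")

  cvs <- lapply(stats::setNames(CELL_TYPES, CELL_TYPES), function(ct) {
    withCallingHandlers(
      sister_cv(calls, meta, ct, filters),
      warning = function(w) {
        log_stage("analyze", "%s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  })
  cv_tab <- do.call(rbind, lapply(CELL_TYPES, function(ct) {
    pm <- cvs[[ct]]$per_mouse
    if (nrow(pm) == 0L) return(NULL)
    pm$cell_type <- ct
    pm
  }))
  if (is.null(cv_tab)) {
    cv_tab <- data.frame(mouse_id = character(0), age_group = character(0),
                         n_variants = integer(0), cv = numeric(0),
                         cell_type = character(0))
  }
  tsv(cv_tab, "sister_cv.tsv")

  curves <- dloop_cumulative(calls, meta, ann)
  tsv(curves, "dloop_cumulative.tsv")

  log_stage("analyze", "%d calls, %d recurrent variants, %d paired rows",
            nrow(calls), nrow(rvs), nrow(deltas))
  run_manifest(outdir, "analyze",
               counts = list(calls = nrow(calls),
                             recurrent_variants = nrow(rvs),
                             paired_deltas = nrow(deltas)))
  invisible(list(recurrent = rvs, deltas = deltas, bins = bins,
                 synonymy = syn, stats_report = stats_report,
                 linear_fit = fit, top_mean_h = top_h,
                 top_mean_abs_delta = top_d, sister_cv = cvs,
                 dloop = curves))
}

#' Simulate, call and analyze in one run
#'
#' End-to-end orchestration: simulates a study under `cfg`, calls variants
#' for every sample, and writes the full analysis report set under
#' `outdir` (`sim/`, `calls/`, `analysis/`).
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory.
#' @param ann A [mito_annotation()].
#' @param filters A [filter_config()].
#' @param force Overwrite a non-empty `outdir`.
#' @return Invisible list with `sim`, `calls` and the analysis tables.
#' @export
run_all <- function(cfg = sim_config(), outdir,
                    ann = mouse_mt_annotation(),
                    filters = filter_config(), force = FALSE) {
  prepare_outdir(outdir, force)
  sim <- run_simulate(cfg, file.path(outdir, "sim"),
                      ann = ann, force = force)
  dir.create(file.path(outdir, "calls"), showWarnings = FALSE)
  calls <- do.call(rbind, lapply(names(sim$counts), function(sid) {
    run_call(file.path(outdir, "sim", "basecounts",
                       paste0(sid, ".tsv")),
             file.path(outdir, "calls", sid), ann = ann,
             filters = filters)
  }))
  if (is.null(calls)) calls <- empty_calls()
  res <- run_analyze(calls, sim$meta, file.path(outdir, "analysis"),
                     ann = ann, filters = filters, force = force)
  invisible(c(list(sim = sim, calls = calls), res))
}
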