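AGE_GROUPS <- c("3wk", "9wk", "12mo")
CELL_TYPES <- c("oocyte", "cumulus")

#' Validate a sample metadata table
#'
#' The study design table: one row per sample, linking each sample to its
#' mouse, age group, cell type and oocyte-cumulus complex. Each complex
#' pairs at most one single-oocyte sample with one bulk cumulus sample.
#'
#' @param meta data.frame with columns `sample_id`, `mouse_id`,
#'   `age_group` (`3wk`/`9wk`/`12mo`), `cell_type` (`oocyte`/`cumulus`),
#'   `complex_id`.
#' @return The validated data.frame (invisibly classed `sample_meta`).
#' @export
sample_meta <- function(meta) {
  required <- c("sample_id", "mouse_id", "age_group", "cell_type",
                "complex_id")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L) {
    stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(meta$age_group %in% AGE_GROUPS)) {
    stop("age_group must be one of: ", paste(AGE_GROUPS, collapse = ", "))
  }
  if (!all(meta$cell_type %in% CELL_TYPES)) {
    stop("cell_type must be one of: ", paste(CELL_TYPES, collapse = ", "))
  }
  # a mouse belongs to exactly one age group
  by_mouse <- tapply(meta$age_group, meta$mouse_id,
                     function(x) length(unique(x)))
  if (any(by_mouse > 1L)) stop("a mouse maps to more than one age_group")
  # a complex has at most one sample of each cell type
  key <- paste(meta$complex_id, meta$cell_type)
  if (anyDuplicated(key)) {
    stop("a complex has more than one sample of the same cell type")
  }
  by_cx <- tapply(meta$mouse_id, meta$complex_id,
                  function(x) length(unique(x)))
  if (any(by_cx > 1L)) stop("a complex maps to more than one mouse")
  class(meta) <- c("sample_meta", "data.frame")
  meta
}

#' Read / write the metadata TSV
#'
#' @param meta A metadata data.frame (see [sample_meta()]).
#' @param path File path.
#' @return `path` (write) or the validated metadata (read).
#' @export
write_meta <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_meta
#' @export
read_meta <- function(path) {
  sample_meta(utils::read.delim(path, stringsAsFactors = FALSE,
                                colClasses = "character"))
}

check_calls_meta <- function(calls, meta) {
  unknown <- setdiff(unique(calls$sample_id), meta$sample_id)
  if (length(unknown) > 0L) {
    stop("call sample_id(s) not in metadata: ",
         paste(unknown, collapse = ", "))
  }
  key <- paste(calls$sample_id, calls$pos, calls$alt)
  if (anyDuplicated(key)) {
    stop("duplicate (sample, position, alt) call records")
  }
  invisible(TRUE)
}

#' Per-mouse recurrent variants
#'
#' A variant (position, alternate base) is recurrent for a mouse when it is
#' detected -- heteroplasmy at or above the detection threshold -- in at
#' least two of that mouse's samples (both oocytes, both cumulus samples, or
#' one of each). Variants seen in only one sample of a mouse are dropped;
#' detections in different mice never combine. Origin and oocyte-detection
#' classes are filled by [classify_origin()], which is applied by default.
#'
#' @param calls Combined call data.frame across samples (rows as produced by
#'   [call_variants()]).
#' @param meta Metadata (see [sample_meta()]).
#' @param filters A [filter_config()]; `detection_threshold` defines
#'   presence.
#' @param classify Also run [classify_origin()] (default `TRUE`).
#' @param maternal_min_cumulus Passed to [classify_origin()].
#' @return data.frame with one row per (mouse, position, alt): columns
#'   `mouse_id`, `pos`, `ref`, `alt`, `n_samples_detected`, `max_h`,
#'   `per_sample_h` (list column: named heteroplasmy over all the mouse's
#'   samples, 0 where not detected) and, when `classify` is `TRUE`,
#'   `origin` and `oocyte_detection`.
#' @export
recurrent_variants <- function(calls, meta, filters = filter_config(),
                               classify = TRUE, maternal_min_cumulus = 2L) {
  meta <- sample_meta(meta)
  check_calls_meta(calls, meta)
  empty <- data.frame(mouse_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      n_samples_detected = integer(0), max_h = numeric(0))
  empty$per_sample_h <- list()
  if (nrow(calls) == 0L) return(empty)

  calls$mouse_id <- meta$mouse_id[match(calls$sample_id, meta$sample_id)]
  det <- calls[calls$h >= filters$detection_threshold - 1e-12, ,
               drop = FALSE]
  if (nrow(det) == 0L) return(empty)
  key <- paste(det$mouse_id, det$pos, det$alt, sep = "\r")
  keep_keys <- names(which(table(key) >= 2L))
  det <- det[key %in% keep_keys, , drop = FALSE]
  if (nrow(det) == 0L) return(empty)

  groups <- split(det, paste(det$mouse_id, det$pos, det$alt, sep = "\r"))
  rows <- lapply(groups, function(g) {
    mouse_samples <- meta$sample_id[meta$mouse_id == g$mouse_id[1L]]
    h <- stats::setNames(numeric(length(mouse_samples)), mouse_samples)
    h[g$sample_id] <- g$h
    data.frame(mouse_id = g$mouse_id[1L], pos = g$pos[1L],
               ref = g$ref[1L], alt = g$alt[1L],
               n_samples_detected = nrow(g), max_h = max(g$h),
               per_sample_h = I(list(h)), stringsAsFactors = FALSE)
  })
  rvs <- do.call(rbind, rows)
  rvs <- rvs[order(rvs$mouse_id, rvs$pos, rvs$alt), , drop = FALSE]
  rownames(rvs) <- NULL
  if (classify) {
    rvs <- classify_origin(rvs, meta, filters, maternal_min_cumulus)
  }
  rvs
}

#' Maternal-origin and oocyte-detection classification
#'
#' A recurrent variant is classified `maternal` when it is detected in at
#' least `maternal_min_cumulus` cumulus samples of its mouse (default 2,
#' the literal "more than one cumulus sample" reading; mice with a single
#' complex can only satisfy `maternal_min_cumulus = 1`). Its
#' oocyte-detection class is `oocyte_detected` when any oocyte of the mouse
#' carries it at or above the detection threshold, else `cumulus_only`.
#' Mice without cumulus samples yield `unclassified` with a warning.
#'
#' @param rvs Output of [recurrent_variants()].
#' @param meta Metadata.
#' @param filters A [filter_config()].
#' @param maternal_min_cumulus Minimum number of detecting cumulus samples
#'   for the maternal call (1 or 2).
#' @return `rvs` with `origin` and `oocyte_detection` columns set.
#' @export
classify_origin <- function(rvs, meta, filters = filter_config(),
                            maternal_min_cumulus = 2L) {
  meta <- sample_meta(meta)
  stopifnot(maternal_min_cumulus %in% c(1L, 2L))
  thr <- filters$detection_threshold - 1e-12
  origin <- character(nrow(rvs))
  oo_det <- character(nrow(rvs))
  warned <- FALSE
  for (i in seq_len(nrow(rvs))) {
    h <- rvs$per_sample_h[[i]]
    ct <- meta$cell_type[match(names(h), meta$sample_id)]
    cum_h <- h[ct == "cumulus"]
    oo_h <- h[ct == "oocyte"]
    if (length(cum_h) == 0L) {
      origin[i] <- "unclassified"
      warned <- TRUE
    } else {
      origin[i] <- if (sum(cum_h >= thr) >= maternal_min_cumulus) {
        "maternal"
      } else {
        "unclassified"
      }
    }
    oo_det[i] <- if (any(oo_h >= thr)) "oocyte_detected" else "cumulus_only"
  }
  if (warned) {
    warning("mouse with zero cumulus samples: origin left unclassified")
  }
  rvs$origin <- origin
  rvs$oocyte_detection <- oo_det
  rvs
}

#' Paired oocyte-cumulus heteroplasmy changes
#'
#' For every complete oocyte-cumulus complex, one row per variant present
#' (at or above the detection threshold) in either member, with
#' `delta = h_oocyte - h_cumulus`: a negative delta means the variant is
#' higher in the cumulus cells than in the oocyte. The member without a
#' call contributes 0.
#'
#' @param calls Combined call data.frame.
#' @param meta Metadata.
#' @param filters A [filter_config()].
#' @return data.frame with `mouse_id`, `complex_id`, `pos`, `ref`, `alt`,
#'   `h_oocyte`, `h_cumulus`, `delta`. Complexes missing one member are
#'   skipped with a warning.
#' @export
paired_deltas <- function(calls, meta, filters = filter_config()) {
  meta <- sample_meta(meta)
  check_calls_meta(calls, meta)
  thr <- filters$detection_threshold - 1e-12
  cxs <- unique(meta$complex_id)
  out <- list()
  incomplete <- character(0)
  for (cx in cxs) {
    sub <- meta[meta$complex_id == cx, , drop = FALSE]
    oo <- sub$sample_id[sub$cell_type == "oocyte"]
    cc <- sub$sample_id[sub$cell_type == "cumulus"]
    if (length(oo) != 1L || length(cc) != 1L) {
      incomplete <- c(incomplete, cx)
      next
    }
    oc <- calls[calls$sample_id == oo, , drop = FALSE]
    ccc <- calls[calls$sample_id == cc, , drop = FALSE]
    keys <- unique(rbind(oc[oc$h >= thr, c("pos", "alt", "ref")],
                         ccc[ccc$h >= thr, c("pos", "alt", "ref")]))
    if (nrow(keys) == 0L) next
    h_oo <- oc$h[match(paste(keys$pos, keys$alt),
                       paste(oc$pos, oc$alt))]
    h_cc <- ccc$h[match(paste(keys$pos, keys$alt),
                        paste(ccc$pos, ccc$alt))]
    h_oo[is.na(h_oo)] <- 0
    h_cc[is.na(h_cc)] <- 0
    out[[cx]] <- data.frame(mouse_id = sub$mouse_id[1L], complex_id = cx,
                            pos = keys$pos, ref = keys$ref, alt = keys$alt,
                            h_oocyte = h_oo, h_cumulus = h_cc,
                            delta = h_oo - h_cc, stringsAsFactors = FALSE)
  }
  if (length(incomplete) > 0L) {
    warning("complex(es) missing one member skipped: ",
            paste(incomplete, collapse = ", "))
  }
  deltas <- do.call(rbind, out)
  if (is.null(deltas)) {
    deltas <- data.frame(mouse_id = character(0), complex_id = character(0),
                         pos = integer(0), ref = character(0),
                         alt = character(0), h_oocyte = numeric(0),
                         h_cumulus = numeric(0), delta = numeric(0))
  }
  deltas <- deltas[order(deltas$pos, deltas$alt, deltas$complex_id), ,
                   drop = FALSE]
  rownames(deltas) <- NULL
  deltas
}

#' Per-variant average heteroplasmy change
#'
#' Heatmap-style summaries over complexes: `avg_A` averages the delta over
#' every complete complex, treating complexes where the variant was not
#' observed as 0; `avg_B` averages only over the complexes where the
#' variant was observed.
#'
#' @param deltas Output of [paired_deltas()].
#' @param meta Optional metadata; when supplied, the `avg_A` denominator is
#'   the number of complete complexes in the study, otherwise the number of
#'   complexes appearing in `deltas`.
#' @return data.frame with `pos`, `alt`, `n_complexes_observed`, `avg_A`,
#'   `avg_B`.
#' @export
delta_averages <- function(deltas, meta = NULL) {
  if (is.null(meta)) {
    n_cx <- length(unique(deltas$complex_id))
  } else {
    meta <- sample_meta(meta)
    tab <- table(meta$complex_id, meta$cell_type)
    n_cx <- sum(tab[, "oocyte"] >= 1L & tab[, "cumulus"] >= 1L)
  }
  if (nrow(deltas) == 0L) {
    return(data.frame(pos = integer(0), alt = character(0),
                      n_complexes_observed = integer(0),
                      avg_A = numeric(0), avg_B = numeric(0)))
  }
  groups <- split(deltas, paste(deltas$pos, deltas$alt, sep = "\r"))
  out <- lapply(groups, function(g) {
    data.frame(pos = g$pos[1L], alt = g$alt[1L],
               n_complexes_observed = nrow(g),
               avg_A = sum(g$delta) / n_cx,
               avg_B = mean(g$delta), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$pos, res$alt), , drop = FALSE]
  rownames(res) <- NULL
  res
}

BIN_LABELS <- c("(1%,10%)", "[10%,50%]", "(50%,100%]")

#' Assign heteroplasmy levels to the three reporting bins
#'
#' Bins: below 10%, 10% up to and including 50%, and above 50%. The lower
#' bin is closed at the calling floor (`min_af`), so the three bins
#' partition every callable heteroplasmy level.
#'
#' @param h Numeric vector of heteroplasmy levels.
#' @param min_af Calling floor; values below it are an error.
#' @return Factor with levels `(1%,10%)`, `[10%,50%]`, `(50%,100%]`.
#' @export
assign_bins <- function(h, min_af = 0.01) {
  if (any(h < min_af - 1e-9)) {
    stop("heteroplasmy level below the calling floor (", min_af, ")")
  }
  if (any(h > 1)) stop("heteroplasmy level above 1")
  lab <- ifelse(h < 0.10, BIN_LABELS[1L],
                ifelse(h <= 0.50, BIN_LABELS[2L], BIN_LABELS[3L]))
  factor(lab, levels = BIN_LABELS)
}

#' Count heteroplasmy levels per bin
#'
#' @param h Numeric vector of heteroplasmy levels (each >= `min_af`).
#' @param min_af Calling floor.
#' @return Named integer vector of counts over the three bins; sums to
#'   `length(h)`.
#' @examples
#' bin_by_level(c(0.02, 0.12, 0.60))
#' @export
bin_by_level <- function(h, min_af = 0.01) {
  counts <- table(assign_bins(h, min_af))
  stats::setNames(as.integer(counts), names(counts))
}

#' Synonymy and region summary of recurrent variants
#'
#' Each coding recurrent variant is counted once per cell type in which it
#' is detected, at that cell type's maximum heteroplasmy level, and
#' cross-tabulated by heteroplasmy bin and synonymy class. Non-coding
#' variants are excluded from the synonymy table but reported in the
#' companion region summary (counts per cell type and region class).
#'
#' @param rvs Output of [recurrent_variants()].
#' @param meta Metadata.
#' @param ann A [mito_annotation()].
#' @param filters A [filter_config()].
#' @return List with `synonymy` (cell_type x bin x class counts, long
#'   format) and `regions` (cell_type x region_class counts).
#' @export
synonymy_summary <- function(rvs, meta, ann, filters = filter_config()) {
  meta <- sample_meta(meta)
  thr <- filters$detection_threshold - 1e-12
  syn_grid <- expand.grid(cell_type = CELL_TYPES, bin = BIN_LABELS,
                          class = c("synonymous", "non_synonymous"),
                          stringsAsFactors = FALSE)
  syn_grid$count <- 0L
  region_levels <- names(region_priority)
  reg_grid <- expand.grid(cell_type = CELL_TYPES,
                          region_class = region_levels,
                          stringsAsFactors = FALSE)
  reg_grid$count <- 0L
  if (nrow(rvs) > 0L) {
    classes <- classify_substitutions(ann, rvs$pos, rvs$alt)
    regions <- region_classes(ann, rvs$pos)
    for (i in seq_len(nrow(rvs))) {
      h <- rvs$per_sample_h[[i]]
      ct <- meta$cell_type[match(names(h), meta$sample_id)]
      for (cell in CELL_TYPES) {
        hc <- h[ct == cell]
        if (length(hc) == 0L || !any(hc >= thr)) next
        ridx <- reg_grid$cell_type == cell &
          reg_grid$region_class == regions[i]
        reg_grid$count[ridx] <- reg_grid$count[ridx] + 1L
        if (classes[i] %in% c("synonymous", "non_synonymous")) {
          bin <- as.character(assign_bins(max(hc), filters$min_af))
          sidx <- syn_grid$cell_type == cell & syn_grid$bin == bin &
            syn_grid$class == classes[i]
          syn_grid$count[sidx] <- syn_grid$count[sidx] + 1L
        }
      }
    }
  }
  list(synonymy = syn_grid, regions = reg_grid)
}

#' Top-k variants by heteroplasmy or heteroplasmy change
#'
#' Ranks study-wide variants (position, alternate base) either by their mean
#' heteroplasmy level over all detecting samples (`mean_h`) or by the mean
#' absolute oocyte-cumulus change over the complexes where they were
#' observed (`mean_abs_delta`). Ties break deterministically by (position,
#' alt).
#'
#' @param rvs Output of [recurrent_variants()].
#' @param k Number of variants to return.
#' @param criterion `"mean_h"` or `"mean_abs_delta"`.
#' @param deltas Output of [paired_deltas()]; required for
#'   `"mean_abs_delta"`.
#' @return data.frame of the top `k` variants with the ranking score.
#' @export
top_variants <- function(rvs, k, criterion = c("mean_h", "mean_abs_delta"),
                         deltas = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(k >= 1L)
  if (criterion == "mean_h") {
    if (nrow(rvs) == 0L) {
      return(data.frame(pos = integer(0), alt = character(0),
                        score = numeric(0)))
    }
    groups <- split(seq_len(nrow(rvs)),
                    paste(rvs$pos, rvs$alt, sep = "\r"))
    scored <- lapply(groups, function(ii) {
      hs <- unlist(rvs$per_sample_h[ii])
      data.frame(pos = rvs$pos[ii[1L]], alt = rvs$alt[ii[1L]],
                 score = mean(hs[hs > 0]), stringsAsFactors = FALSE)
    })
    scored <- do.call(rbind, scored)
  } else {
    if (is.null(deltas)) {
      stop("criterion 'mean_abs_delta' requires paired deltas")
    }
    if (nrow(deltas) == 0L) {
      return(data.frame(pos = integer(0), alt = character(0),
                        score = numeric(0)))
    }
    groups <- split(deltas, paste(deltas$pos, deltas$alt, sep = "\r"))
    scored <- lapply(groups, function(g) {
      data.frame(pos = g$pos[1L], alt = g$alt[1L],
                 score = mean(abs(g$delta)), stringsAsFactors = FALSE)
    })
    scored <- do.call(rbind, scored)
  }
  scored <- scored[order(-scored$score, scored$pos, scored$alt), ,
                   drop = FALSE]
  rownames(scored) <- NULL
  if (k > nrow(scored)) {
    message("k exceeds the number of variants; returning all ",
            nrow(scored))
    k <- nrow(scored)
  }
  utils::head(scored, k)
}
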