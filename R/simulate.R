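#' Default modification-artifact sites for the simulator
#'
#' Cell-type-specific apparent variant sites emulating
#' post-transcriptional-modification artifacts: three cumulus-elevated
#' sites in rRNA genes (179, 729) and tRNA-Glu (14131, strongly
#' cumulus-elevated), and one oocyte-elevated site (233, 12S rRNA). Rates
#' are apparent alternate-base fractions per cell type; they are
#' placeholder magnitudes in the descriptive ranges of the study system,
#' not fitted estimates.
#'
#' @return data.frame with columns `pos`, `rate_oocyte`, `rate_cumulus`.
#' @export
default_modification_sites <- function() {
  data.frame(pos = c(179L, 233L, 729L, 14131L),
             rate_oocyte = c(0.02, 0.12, 0.03, 0.005),
             rate_cumulus = c(0.10, 0.04, 0.15, 0.23))
}

#' Synthetic-study configuration
#'
#' Defines the study shape and generative model for [simulate_study()]:
#' three age groups of `n_mice_per_group` mice, `occ_per_mouse`
#' oocyte-cumulus complexes each (overridable per mouse, e.g. one mouse
#' with a single complex and one with three), maternal heteroplasmies
#' shared within a mouse and resampled per sample through a Beta
#' bottleneck analogue, cell-type-specific modification artifacts, uniform
#' sequencing error, and deeper cumulus sequencing.
#'
#' @param n_mice_per_group Mice per age group (default 4).
#' @param occ_per_mouse Complexes per mouse (default 2).
#' @param occ_overrides Named integer vector of per-mouse complex counts,
#'   e.g. `c(m05 = 3, m07 = 1)`.
#' @param maternal_variants_per_mouse Poisson mean of planted maternal
#'   variants per mouse (default 6).
#' @param founder_h_shape1,founder_h_shape2 Beta parameters of the founder
#'   heteroplasmy distribution.
#' @param founder_h_min,founder_h_max Truncation bounds on founder
#'   heteroplasmy (default 0.05-0.95).
#' @param segregation_concentration Precision of the per-sample Beta
#'   resampling around the founder level (bottleneck analogue).
#' @param cumulus_h_scale Multiplicative bias (>= 1) on the cumulus-side
#'   expected heteroplasmy (default 1.5; capped at 0.95).
#' @param modification_sites data.frame of artifact sites (see
#'   [default_modification_sites()]); `NULL` for none.
#' @param modification_concentration Precision of per-sample jitter around
#'   each site's cell-type rate.
#' @param error_rate Per-base miscall probability, spread uniformly over
#'   the three non-reference bases (default 0.001).
#' @param depth_profile Named mean oocyte depth per feature class.
#' @param depth_dispersion Negative-binomial size for per-position depth.
#' @param cumulus_depth_multiplier Depth multiplier for cumulus samples
#'   (default 3).
#' @param seed Integer seed; the whole study is deterministic given it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_mice_per_group = 4L,
                       occ_per_mouse = 2L,
                       occ_overrides = integer(0),
                       maternal_variants_per_mouse = 6,
                       founder_h_shape1 = 1.2,
                       founder_h_shape2 = 12,
                       founder_h_min = 0.05,
                       founder_h_max = 0.95,
                       segregation_concentration = 60,
                       cumulus_h_scale = 1.5,
                       modification_sites = default_modification_sites(),
                       modification_concentration = 200,
                       error_rate = 0.001,
                       depth_profile = c(protein_coding = 3000,
                                         tRNA = 2500, rRNA = 4000,
                                         D_loop = 2000,
                                         other_noncoding = 2000),
                       depth_dispersion = 20,
                       cumulus_depth_multiplier = 3,
                       seed = 1L) {
  stopifnot(n_mice_per_group >= 1L, occ_per_mouse >= 1L,
            maternal_variants_per_mouse >= 0,
            founder_h_min >= 0, founder_h_max <= 1,
            founder_h_min < founder_h_max,
            segregation_concentration > 0,
            cumulus_h_scale >= 1,
            error_rate >= 0, error_rate <= 1,
            all(depth_profile >= 0), cumulus_depth_multiplier >= 1)
  if (!is.null(modification_sites)) {
    stopifnot(all(c("pos", "rate_oocyte", "rate_cumulus") %in%
                    names(modification_sites)),
              all(modification_sites$rate_oocyte >= 0),
              all(modification_sites$rate_oocyte <= 1),
              all(modification_sites$rate_cumulus >= 0),
              all(modification_sites$rate_cumulus <= 1))
  }
  structure(list(n_mice_per_group = as.integer(n_mice_per_group),
                 occ_per_mouse = as.integer(occ_per_mouse),
                 occ_overrides = occ_overrides,
                 maternal_variants_per_mouse = maternal_variants_per_mouse,
                 founder_h_shape1 = founder_h_shape1,
                 founder_h_shape2 = founder_h_shape2,
                 founder_h_min = founder_h_min,
                 founder_h_max = founder_h_max,
                 segregation_concentration = segregation_concentration,
                 cumulus_h_scale = cumulus_h_scale,
                 modification_sites = modification_sites,
                 modification_concentration = modification_concentration,
                 error_rate = error_rate,
                 depth_profile = depth_profile,
                 depth_dispersion = depth_dispersion,
                 cumulus_depth_multiplier = cumulus_depth_multiplier,
                 seed = as.integer(seed)),
            class = "sim_config")
}

transition_partner <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulate a full oocyte-cumulus heteroplasmy study
#'
#' Generates sample metadata, per-sample quality-filtered base-count tables
#' and a ground-truth record. Per mouse, maternal variants are drawn once
#' (Poisson count; positions uniform outside the modification sites;
#' founder level from a truncated Beta) and shared across the mouse's
#' samples through Beta resampling with the configured concentration;
#' cumulus expected levels are scaled by `cumulus_h_scale`. Modification
#' artifact sites add cell-type-specific apparent fractions independent of
#' mouse (alternate base fixed to the transition partner of the reference).
#' Alternate counts are Binomial(depth, h); depths are negative-binomial
#' around the feature-class profile, multiplied by
#' `cumulus_depth_multiplier` for cumulus samples; sequencing error spreads
#' uniformly over the three non-reference bases. The random-number
#' consumption order is fixed (mice in order: variant count, positions,
#' alternates, founder levels; then samples in metadata order: depths,
#' errors, planted-variant levels and counts, modification rates and
#' counts), so a seed pins the whole study byte-for-byte.
#'
#' @param cfg A [sim_config()].
#' @param ann A [mito_annotation()] (default: the packaged mouse map).
#' @return List with `meta` (metadata data.frame), `counts` (named list of
#'   [basecount_table()]s) and `truth` (list: `variants`, `realized`,
#'   `modifications`, `error_rate`, `seed`).
#' @export
simulate_study <- function(cfg = sim_config(),
                           ann = mouse_mt_annotation()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ann, "MitoAnnotation"))
  set.seed(cfg$seed)
  glen <- ann$genome_length

  n_mice <- 3L * cfg$n_mice_per_group
  mouse_ids <- sprintf("m%02d", seq_len(n_mice))
  mouse_age <- rep(AGE_GROUPS, each = cfg$n_mice_per_group)
  meta_rows <- list()
  for (i in seq_len(n_mice)) {
    n_occ <- cfg$occ_per_mouse
    if (mouse_ids[i] %in% names(cfg$occ_overrides)) {
      n_occ <- as.integer(cfg$occ_overrides[[mouse_ids[i]]])
    }
    for (j in seq_len(n_occ)) {
      cx <- sprintf("%s_occ%d", mouse_ids[i], j)
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        sample_id = paste0(cx, c("_oocyte", "_cumulus")),
        mouse_id = mouse_ids[i], age_group = mouse_age[i],
        cell_type = c("oocyte", "cumulus"), complex_id = cx,
        stringsAsFactors = FALSE)
    }
  }
  meta <- sample_meta(do.call(rbind, meta_rows))

  mod <- cfg$modification_sites
  mod_pos <- if (is.null(mod)) integer(0) else as.integer(mod$pos)
  if (!is.null(mod)) {
    mod$ref <- ann$bases[mod$pos]
    mod$alt <- unname(transition_partner[mod$ref])
  }

  # per-mouse maternal variants
  candidates <- setdiff(seq_len(glen), mod_pos)
  var_rows <- list()
  for (m in mouse_ids) {
    n_var <- stats::rpois(1L, cfg$maternal_variants_per_mouse)
    if (n_var == 0L) next
    pos <- sort(sample(candidates, n_var))
    ref <- ann$bases[pos]
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L),
                  character(1))
    plo <- stats::pbeta(cfg$founder_h_min, cfg$founder_h_shape1,
                        cfg$founder_h_shape2)
    phi <- stats::pbeta(cfg$founder_h_max, cfg$founder_h_shape1,
                        cfg$founder_h_shape2)
    founder_h <- stats::qbeta(stats::runif(n_var, plo, phi),
                              cfg$founder_h_shape1, cfg$founder_h_shape2)
    var_rows[[m]] <- data.frame(mouse_id = m, pos = pos, ref = ref,
                                alt = alt, founder_h = founder_h,
                                stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, var_rows)
  if (is.null(variants)) {
    variants <- data.frame(mouse_id = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           founder_h = numeric(0))
  }
  rownames(variants) <- NULL

  depth_mu <- unname(cfg$depth_profile[region_classes(ann, seq_len(glen))])
  cc <- cfg$segregation_concentration
  mc <- cfg$modification_concentration

  counts_list <- vector("list", nrow(meta))
  names(counts_list) <- meta$sample_id
  realized_rows <- list()
  mod_rows <- list()

  for (s in seq_len(nrow(meta))) {
    sid <- meta$sample_id[s]
    is_cum <- meta$cell_type[s] == "cumulus"
    mu <- depth_mu * if (is_cum) cfg$cumulus_depth_multiplier else 1
    depth <- stats::rnbinom(glen, mu = mu, size = cfg$depth_dispersion)

    counts <- matrix(0L, nrow = glen, ncol = 4L,
                     dimnames = list(NULL, BASES))
    # sequencing error split over the three non-reference bases
    if (cfg$error_rate > 0) {
      e <- stats::rbinom(glen, depth, cfg$error_rate)
      e1 <- stats::rbinom(glen, e, 1 / 3)
      e2 <- stats::rbinom(glen, e - e1, 1 / 2)
      e3 <- e - e1 - e2
    } else {
      e <- e1 <- e2 <- e3 <- integer(glen)
    }
    ref_idx <- match(ann$bases, BASES)
    counts[cbind(seq_len(glen), ref_idx)] <- depth - e
    for (r in seq_len(4L)) {
      rows <- which(ref_idx == r)
      others <- setdiff(seq_len(4L), r)
      counts[cbind(rows, others[1L])] <- e1[rows]
      counts[cbind(rows, others[2L])] <- e2[rows]
      counts[cbind(rows, others[3L])] <- e3[rows]
    }

    # planted maternal variants of this sample's mouse
    mv <- variants[variants$mouse_id == meta$mouse_id[s], , drop = FALSE]
    if (nrow(mv) > 0L) {
      h_exp <- mv$founder_h * if (is_cum) cfg$cumulus_h_scale else 1
      h_exp <- pmin(h_exp, 0.95)
      h_real <- stats::rbeta(nrow(mv), cc * h_exp, cc * (1 - h_exp))
      a <- stats::rbinom(nrow(mv), depth[mv$pos], h_real)
      counts[mv$pos, ] <- 0L
      counts[cbind(mv$pos, match(mv$ref, BASES))] <- depth[mv$pos] - a
      counts[cbind(mv$pos, match(mv$alt, BASES))] <- a
      realized_rows[[sid]] <- data.frame(sample_id = sid, pos = mv$pos,
                                         alt = mv$alt, h_true = h_real,
                                         stringsAsFactors = FALSE)
    }

    # modification-artifact sites (cell-type specific)
    if (!is.null(mod) && nrow(mod) > 0L) {
      rate <- if (is_cum) mod$rate_cumulus else mod$rate_oocyte
      app <- numeric(nrow(mod))
      pos_r <- rate > 0
      app[pos_r] <- stats::rbeta(sum(pos_r), mc * rate[pos_r],
                                 mc * (1 - rate[pos_r]))
      a <- stats::rbinom(nrow(mod), depth[mod$pos], app)
      counts[mod$pos, ] <- 0L
      counts[cbind(mod$pos, match(mod$ref, BASES))] <- depth[mod$pos] - a
      counts[cbind(mod$pos, match(mod$alt, BASES))] <- a
      mod_rows[[sid]] <- data.frame(sample_id = sid, pos = mod$pos,
                                    alt = mod$alt, apparent_rate = app,
                                    stringsAsFactors = FALSE)
    }

    covered <- which(rowSums(counts) > 0L)
    counts_list[[sid]] <- basecount_table(
      sid, covered, ann$bases[covered], counts[covered, "A"],
      counts[covered, "C"], counts[covered, "G"], counts[covered, "T"])
  }

  realized <- do.call(rbind, realized_rows)
  if (is.null(realized)) {
    realized <- data.frame(sample_id = character(0), pos = integer(0),
                           alt = character(0), h_true = numeric(0))
  }
  rownames(realized) <- NULL
  modifications <- do.call(rbind, mod_rows)
  if (is.null(modifications)) {
    modifications <- data.frame(sample_id = character(0), pos = integer(0),
                                alt = character(0),
                                apparent_rate = numeric(0))
  }
  rownames(modifications) <- NULL

  list(meta = meta, counts = counts_list,
       truth = list(variants = variants, realized = realized,
                    modifications = modifications,
                    modification_sites = mod,
                    error_rate = cfg$error_rate, seed = cfg$seed))
}

#' Emit SAM records reproducing a base-count table
#'
#' Builds perfectly-aligned reads (MAPQ 60, base quality 40) whose
#' quality-filtered pileup under the default thresholds reproduces the
#' input table exactly: depth layers of the coverage profile become reads,
#' each position's base multiset is spread deterministically over the
#' layers, and runs longer than `read_length` are chunked.
#'
#' @param tab A [basecount_table()].
#' @param read_length Maximum read length (default 100).
#' @param genome_length Contig length; reads beyond it are an error.
#' @return data.frame of SAM fields (`qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual`); zero rows for an empty table.
#' @export
emit_alignments <- function(tab, read_length = 100L,
                            genome_length = max(c(0L, tab$pos))) {
  tab <- validate_basecounts(as.data.frame(tab))
  stopifnot(read_length >= 1L)
  empty <- data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      seq = character(0), qual = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) return(empty)
  if (max(tab$pos) > genome_length) {
    stop("table references positions beyond the genome end")
  }
  depth <- basecount_depth(tab)
  # per position, its bases ordered A,C,G,T; layer l takes the l-th base
  base_stack <- lapply(seq_len(nrow(tab)), function(i) {
    rep(BASES, times = as.integer(tab[i, BASES]))
  })
  reads <- list()
  for (l in seq_len(max(depth))) {
    idx <- which(depth >= l)
    if (length(idx) == 0L) break
    pos <- tab$pos[idx]
    bases <- vapply(seq_along(idx),
                    function(k) base_stack[[idx[k]]][l], character(1))
    run_id <- cumsum(c(1L, diff(pos) != 1L))
    for (r in unique(run_id)) {
      rp <- pos[run_id == r]
      rb <- bases[run_id == r]
      starts <- seq(1L, length(rp), by = read_length)
      for (st in starts) {
        en <- min(st + read_length - 1L, length(rp))
        n <- en - st + 1L
        reads[[length(reads) + 1L]] <- data.frame(
          qname = sprintf("sim_l%d_p%d", l, rp[st]), flag = 0L,
          rname = "chrM", pos = rp[st], mapq = 60L,
          cigar = sprintf("%dM", n),
          seq = paste(rb[st:en], collapse = ""),
          qual = strrep("I", n), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, reads)
}

#' Write SAM records to disk
#'
#' @param reads data.frame of SAM fields as produced by
#'   [emit_alignments()].
#' @param path Output path.
#' @param genome_length Contig length for the `@SQ` header line.
#' @param contig Contig name (default `chrM`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, genome_length, contig = "chrM") {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", contig,
                      as.integer(genome_length)))
  records <- character(0)
  if (!is.null(reads) && nrow(reads) > 0L) {
    records <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                       reads$qname, reads$flag, reads$rname, reads$pos,
                       reads$mapq, reads$cigar, reads$seq, reads$qual)
  }
  writeLines(c(header, records), path)
  invisible(path)
}
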