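stat_result <- function(method, statistic, df, p_raw,
                        p_adjusted = NA_real_, extras = list()) {
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p_raw = unname(p_raw),
                 p_adjusted = p_adjusted, extras = extras),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, df = %s, p = %.4g",
              x$method, x$statistic,
              paste(signif(x$df, 6), collapse = ", "), x$p_raw))
  if (!is.na(x$p_adjusted)) cat(sprintf(" (adjusted %.4g)", x$p_adjusted))
  cat("\n")
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical equal-variance one-way ANOVA across k groups: F with degrees
#' of freedom (k - 1, N - k) and the p-value from the F distribution.
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return A `stat_result` with `statistic` = F, `df` = c(k-1, N-k),
#'   `extras$n` = total N.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) {
    stop("each group needs at least 2 values")
  }
  values <- unlist(groups)
  if (length(unique(values)) == 1L) {
    stop("degenerate input: all values identical")
  }
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::oneway.test(values ~ grp, var.equal = TRUE)
  stat_result("one_way_anova", fit$statistic,
              c(fit$parameter[["num df"]], fit$parameter[["denom df"]]),
              fit$p.value, extras = list(n = length(values),
                                         k = length(groups)))
}

#' Holm-Sidak step-down multiple-testing correction
#'
#' Sorts the raw p-values ascending, applies the Sidak transformation
#' `1 - (1 - p_(i))^(m - i + 1)` to the i-th smallest of m values, enforces
#' monotonicity with a running maximum, clips at 1, and returns the
#' adjusted values in the input order.
#'
#' @param p_raw Numeric vector of raw p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values, same order as the input.
#' @examples
#' holm_sidak(c(0.01, 0.04, 0.03))
#' @export
holm_sidak <- function(p_raw) {
  if (length(p_raw) == 0L) return(numeric(0))
  if (any(is.na(p_raw)) || any(p_raw < 0) || any(p_raw > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_raw)
  ord <- order(p_raw)
  p_sorted <- p_raw[ord]
  adj <- 1 - (1 - p_sorted)^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Paired-sample t-test
#'
#' Two-sided paired t-test: `t = mean(d) / (sd(d) / sqrt(n))` on the
#' differences `d = x - y` with the sample (n-1) standard deviation and
#' n - 1 degrees of freedom.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2).
#' @return A `stat_result` with `statistic` = t, `df` = n - 1.
#' @examples
#' paired_t(c(1, 2, 3), c(2, 3, 5))
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("need at least 2 pairs")
  if (all(x - y == 0)) {
    stop("degenerate input: all paired differences are zero")
  }
  fit <- stats::t.test(x, y, paired = TRUE)
  stat_result("paired_t", fit$statistic, fit$parameter, fit$p.value,
              extras = list(n = length(x),
                            mean_difference = unname(fit$estimate)))
}

#' Ordinary least-squares linear fit
#'
#' Simple linear regression of y on x with the coefficient of
#' determination and the two-sided p-value for a non-zero slope (t
#' distribution, n - 2 degrees of freedom).
#'
#' @param x,y Numeric vectors of equal length (n >= 3); `x` must vary.
#' @return A `stat_result` with `statistic` = slope, `df` = n - 2 and
#'   `extras` carrying `r_squared`, `intercept` and `n`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("x is constant: slope undefined")
  if (stats::var(y) == 0) {
    return(stat_result("linear_fit", 0, length(x) - 2L, 1,
                       extras = list(r_squared = 0, intercept = y[1L],
                                     n = length(x))))
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits; R^2 = 1 is a legitimate outcome here
  sm <- suppressWarnings(summary(fit))
  slope <- stats::coef(fit)[["x"]]
  p <- if (nrow(sm$coefficients) >= 2L && ncol(sm$coefficients) >= 4L) {
    sm$coefficients["x", "Pr(>|t|)"]
  } else {
    NA_real_
  }
  # a constant response has slope 0 and no evidence against it
  if (is.na(p) || is.nan(p)) p <- 1
  stat_result("linear_fit", slope, length(x) - 2L, p,
              extras = list(r_squared = sm$r.squared,
                            intercept = stats::coef(fit)[["(Intercept)"]],
                            n = length(x)))
}

#' Sister-sample coefficient of variation
#'
#' Dispersion of heteroplasmy between sister samples (same mouse, same cell
#' type). For each variant detected in at least two sisters, CV = sample
#' (n-1) standard deviation / mean of the heteroplasmy levels across all of
#' that mouse's sisters (0 where not detected). The per-mouse value is the
#' mean CV over its variants and the per-age value the mean over mice.
#' Mice with fewer than two samples of the cell type are skipped with a
#' warning; variants with zero mean are skipped.
#'
#' @param calls Combined call data.frame.
#' @param meta Metadata.
#' @param cell_type `"oocyte"` or `"cumulus"`.
#' @param filters A [filter_config()].
#' @return List with `per_mouse` (mouse_id, age_group, n_variants, cv) and
#'   `per_age` (age_group, mean_cv, n_mice).
#' @export
sister_cv <- function(calls, meta, cell_type = c("cumulus", "oocyte"),
                      filters = filter_config()) {
  cell_type <- match.arg(cell_type)
  meta <- sample_meta(meta)
  check_calls_meta(calls, meta)
  thr <- filters$detection_threshold - 1e-12
  mice <- unique(meta$mouse_id)
  rows <- list()
  skipped <- character(0)
  for (m in mice) {
    sisters <- meta$sample_id[meta$mouse_id == m &
                                meta$cell_type == cell_type]
    if (length(sisters) < 2L) {
      skipped <- c(skipped, m)
      next
    }
    sub <- calls[calls$sample_id %in% sisters & calls$h >= thr, ,
                 drop = FALSE]
    key <- paste(sub$pos, sub$alt)
    shared <- names(which(table(key) >= 2L))
    cvs <- numeric(0)
    for (kk in shared) {
      g <- sub[key == kk, , drop = FALSE]
      h <- stats::setNames(numeric(length(sisters)), sisters)
      h[g$sample_id] <- g$h
      mu <- mean(h)
      if (mu == 0) next
      cvs <- c(cvs, stats::sd(h) / mu)
    }
    rows[[m]] <- data.frame(
      mouse_id = m,
      age_group = meta$age_group[match(m, meta$mouse_id)],
      n_variants = length(cvs),
      cv = if (length(cvs) > 0L) mean(cvs) else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0L) {
    warning("mice with <2 ", cell_type, " samples skipped: ",
            paste(skipped, collapse = ", "))
  }
  per_mouse <- do.call(rbind, rows)
  if (is.null(per_mouse)) {
    per_mouse <- data.frame(mouse_id = character(0),
                            age_group = character(0),
                            n_variants = integer(0), cv = numeric(0))
  }
  rownames(per_mouse) <- NULL
  with_cv <- per_mouse[!is.na(per_mouse$cv), , drop = FALSE]
  if (nrow(with_cv) > 0L) {
    agg <- stats::aggregate(cv ~ age_group, data = with_cv, FUN = mean)
    n_mice <- stats::aggregate(cv ~ age_group, data = with_cv, FUN = length)
    per_age <- data.frame(age_group = agg$age_group, mean_cv = agg$cv,
                          n_mice = n_mice$cv, stringsAsFactors = FALSE)
  } else {
    per_age <- data.frame(age_group = character(0), mean_cv = numeric(0),
                          n_mice = integer(0))
  }
  list(per_mouse = per_mouse, per_age = per_age)
}

#' D-loop cumulative-frequency curves
#'
#' For each (age group, cell type), the number of D-loop variant
#' observations with heteroplasmy at or above each threshold: a monotone
#' non-increasing step function starting at the group's total D-loop
#' variant count.
#'
#' @param calls Combined call data.frame.
#' @param meta Metadata.
#' @param ann A [mito_annotation()] whose feature map contains a `D_loop`
#'   feature.
#' @param thresholds Grid of heteroplasmy thresholds (default 1% to 100% in
#'   1% steps).
#' @return Long data.frame: `age_group`, `cell_type`, `threshold`, `count`.
#' @export
dloop_cumulative <- function(calls, meta, ann,
                             thresholds = seq(0.01, 1, by = 0.01)) {
  meta <- sample_meta(meta)
  check_calls_meta(calls, meta)
  dl <- ann$features[ann$features$ftype == "D_loop", , drop = FALSE]
  if (nrow(dl) == 0L) stop("annotation has no D_loop feature")
  in_dloop <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(dl))) {
    in_dloop <- in_dloop | (calls$pos >= dl$start[i] &
                              calls$pos <= dl$end[i])
  }
  calls$age_group <- meta$age_group[match(calls$sample_id, meta$sample_id)]
  calls$cell_type <- meta$cell_type[match(calls$sample_id, meta$sample_id)]
  dcalls <- calls[in_dloop, , drop = FALSE]
  grid <- expand.grid(age_group = AGE_GROUPS, cell_type = CELL_TYPES,
                      threshold = thresholds, stringsAsFactors = FALSE)
  grid$count <- mapply(function(ag, ct, x) {
    sum(dcalls$age_group == ag & dcalls$cell_type == ct &
          dcalls$h >= x - 1e-12)
  }, grid$age_group, grid$cell_type, grid$threshold)
  grid[order(grid$age_group, grid$cell_type, grid$threshold), ,
       drop = FALSE]
}

#' Age-group comparison of pooled heteroplasmy levels
#'
#' Pools the heteroplasmy levels of all calls per age group for one cell
#' type, runs the omnibus one-way ANOVA, and follows it with the three
#' pairwise equal-variance t-tests corrected as one family with
#' [holm_sidak()].
#'
#' @param calls Combined call data.frame.
#' @param meta Metadata.
#' @param cell_type `"oocyte"` or `"cumulus"`.
#' @param per_sample_mean Pool per-sample mean heteroplasmy instead of all
#'   call-level values (default `FALSE`: call-level pooling).
#' @return List with `omnibus` (a `stat_result`) and `pairwise`
#'   (data.frame: group1, group2, t, df, p_raw, p_adjusted, family
#'   `holm_sidak`).
#' @export
age_group_tests <- function(calls, meta, cell_type = c("oocyte", "cumulus"),
                            per_sample_mean = FALSE) {
  cell_type <- match.arg(cell_type)
  meta <- sample_meta(meta)
  check_calls_meta(calls, meta)
  sub <- calls[meta$cell_type[match(calls$sample_id,
                                    meta$sample_id)] == cell_type, ,
               drop = FALSE]
  sub$age_group <- meta$age_group[match(sub$sample_id, meta$sample_id)]
  if (per_sample_mean) {
    agg <- stats::aggregate(h ~ sample_id + age_group, data = sub,
                            FUN = mean)
    groups <- split(agg$h, factor(agg$age_group, levels = AGE_GROUPS))
  } else {
    groups <- split(sub$h, factor(sub$age_group, levels = AGE_GROUPS))
  }
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) < 2L) {
    warning("fewer than two age groups with >=2 values: ANOVA skipped")
    return(list(omnibus = NULL,
                pairwise = data.frame(group1 = character(0),
                                      group2 = character(0), t = numeric(0),
                                      df = numeric(0), p_raw = numeric(0),
                                      p_adjusted = numeric(0))))
  }
  omnibus <- one_way_anova(unname(groups))
  pairs <- utils::combn(names(groups), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- groups[[pairs[1L, i]]]
    g2 <- groups[[pairs[2L, i]]]
    fit <- stats::t.test(g1, g2, var.equal = TRUE)
    data.frame(group1 = pairs[1L, i], group2 = pairs[2L, i],
               t = unname(fit$statistic), df = unname(fit$parameter),
               p_raw = fit$p.value, stringsAsFactors = FALSE)
  })
  pairwise <- do.call(rbind, rows)
  pairwise$p_adjusted <- holm_sidak(pairwise$p_raw)
  pairwise$family <- "holm_sidak"
  list(omnibus = omnibus, pairwise = pairwise)
}
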