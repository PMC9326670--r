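#' Classical test theory statistics per form
#'
#' For each form (test set) separately, over the persons administered it:
#' item difficulty `p` (proportion correct), corrected item-total
#' ("part-whole") correlation `r_pw` (Pearson correlation of the item with
#' the sum of the *remaining* administered items), and Cronbach's alpha
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#' Zero-variance items get `r_pw = NA` (reported, never silently dropped).
#'
#' @param matrix a `response_matrix`
#' @return list with `items` (data.frame `form_id`, `item_id`, `p`, `r_pw`,
#'   `n`) and `forms` (data.frame `form_id`, `alpha`, `n_items`,
#'   `n_persons`)
#' @export
ctt_stats <- function(matrix) {
  stopifnot(inherits(matrix, "response_matrix"))
  item_rows <- list()
  form_rows <- list()
  for (fid in unique(matrix$form_id)) {
    rows <- matrix$form_id == fid
    resp <- matrix$responses[rows, , drop = FALSE]
    resp <- resp[, colSums(!is.na(resp)) > 0, drop = FALSE]
    if (ncol(resp) < 2L || nrow(resp) < 3L) {
      stop_config(sprintf(
        "form %s needs >= 2 items and >= 3 persons for CTT", fid))
    }
    total <- rowSums(resp, na.rm = TRUE)
    p <- colMeans(resp, na.rm = TRUE)
    r_pw <- vapply(seq_len(ncol(resp)), function(j) {
      x <- resp[, j]
      rest <- total - ifelse(is.na(x), 0, x)
      ok <- !is.na(x)
      if (stats::sd(x[ok]) == 0 || stats::sd(rest[ok]) == 0) {
        return(NA_real_)
      }
      stats::cor(x[ok], rest[ok])
    }, numeric(1))
    item_rows[[fid]] <- data.frame(
      form_id = fid, item_id = colnames(resp), p = p, r_pw = r_pw,
      n = colSums(!is.na(resp)), row.names = NULL, stringsAsFactors = FALSE)
    # alpha on complete administered columns
    comp <- resp[stats::complete.cases(resp), , drop = FALSE]
    k <- ncol(comp)
    tv <- stats::var(rowSums(comp))
    alpha <- if (tv > 0) {
      (k / (k - 1)) * (1 - sum(apply(comp, 2L, stats::var)) / tv)
    } else NA_real_
    form_rows[[fid]] <- data.frame(
      form_id = fid, alpha = alpha, n_items = k, n_persons = nrow(comp),
      stringsAsFactors = FALSE)
  }
  list(items = do.call(rbind, c(item_rows, list(make.row.names = FALSE))),
       forms = do.call(rbind, c(form_rows, list(make.row.names = FALSE))))
}

#' One-way ANOVA with omega squared
#'
#' Standard fixed-effects one-way decomposition, reported with the
#' less-biased effect size `omega^2 = (SS_between - df_between * MS_within)
#' / (SS_total + MS_within)`, truncated below at 0.
#'
#' @param values numeric vector
#' @param groups grouping vector (same length)
#' @return list of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`, `omega_sq`
#' @export
oneway_anova <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2L) stop_config("need at least 2 groups")
  if (any(table(groups) < 2L)) {
    stop_config("every group needs at least 2 values")
  }
  grand <- mean(values)
  ss_total <- sum((values - grand)^2)
  group_means <- tapply(values, groups, mean)
  group_n <- tapply(values, groups, length)
  ss_between <- sum(group_n * (group_means - grand)^2)
  ss_within <- ss_total - ss_between
  df_between <- nlevels(groups) - 1L
  df_within <- length(values) - nlevels(groups)
  ms_within <- ss_within / df_within
  Fval <- if (ms_within > 0) (ss_between / df_between) / ms_within else {
    if (ss_between > 0) Inf else 0
  }
  p <- stats::pf(Fval, df_between, df_within, lower.tail = FALSE)
  omega <- if (ss_total + ms_within > 0) {
    max(0, (ss_between - df_between * ms_within) / (ss_total + ms_within))
  } else 0
  structure(list(F = Fval, df_between = df_between, df_within = df_within,
                 p = p, omega_sq = omega),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F(%d,%d) = %.3f, p = %.4g, omega^2 = %.3f\n", x$df_between,
              x$df_within, x$F, x$p, x$omega_sq))
  invisible(x)
}

#' Pearson correlation with one-pass +/-3SD outlier trimming
#'
#' `r_raw` is the correlation on all pairs. Trimming removes pairs where
#' either coordinate deviates more than `sd_multiplier` standard deviations
#' from its own mean, with means and SDs computed once on the raw vectors
#' (single pass, marginal criterion); `r_trimmed` is the correlation on the
#' remaining pairs.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @param sd_multiplier trimming threshold in SD units (default 3)
#' @return list: `r_raw`, `r_trimmed`, `n_removed`
#' @export
correlate_with_trim <- function(x, y, sd_multiplier = 3) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_config("correlation undefined for a constant vector")
  }
  keep <- abs(x - mean(x)) <= sd_multiplier * stats::sd(x) &
    abs(y - mean(y)) <= sd_multiplier * stats::sd(y)
  r_raw <- stats::cor(x, y)
  r_trimmed <- if (sum(keep) >= 3L && stats::sd(x[keep]) > 0 &&
                   stats::sd(y[keep]) > 0) {
    stats::cor(x[keep], y[keep])
  } else NA_real_
  list(r_raw = r_raw, r_trimmed = r_trimmed, n_removed = sum(!keep))
}

#' Regress item difficulty on the six construction-rule indicators
#'
#' Ordinary least squares of the 2PL threshold `b` on the 0/1 indicators
#' ADD, SUB, DIS, INT, ROT, COM. Also fits the nested baseline using only
#' the number of rules (the sum of the indicators) and reports the
#' incremental F test of the six-indicator model over it. Standardised
#' weights are `beta = B * sd(x) / sd(y)`.
#'
#' @param item_table data.frame with columns `b`, `ADD` ... `COM` (0/1) and
#'   optionally `rule_count` (computed as the indicator sum if absent)
#' @return list of class `rule_regression`: `coefficients` (data.frame
#'   `term`, `B`, `beta`, `t`, `p`), `r_squared`, `F_model`, `df_model`,
#'   `p_model`, `F_increment`, `df_increment`, `p_increment`, `lm_fit`
#' @export
rule_regression <- function(item_table) {
  need <- c("b", RULE_KINDS)
  if (!all(need %in% names(item_table))) {
    stop_config(paste("item_table must contain columns:",
                      paste(need, collapse = ", ")))
  }
  if (nrow(item_table) < 8L) stop_config("need at least 8 items")
  X <- as.matrix(item_table[, RULE_KINDS])
  const_cols <- RULE_KINDS[apply(X, 2L, function(c) stats::var(c) == 0)]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    offenders <- if (length(const_cols)) const_cols else {
      RULE_KINDS[qrX$pivot[seq(qrX$rank + 1L, ncol(X) + 1L)] - 1L]
    }
    stop_config(paste("rank-deficient rule design matrix; offending",
                      "column(s):", paste(offenders, collapse = ", ")))
  }
  if (!"rule_count" %in% names(item_table)) {
    item_table$rule_count <- rowSums(X)
  }
  full <- stats::lm(b ~ ADD + SUB + DIS + INT + ROT + COM,
                    data = item_table)
  base <- stats::lm(b ~ rule_count, data = item_table)
  sm <- summary(full)
  co <- stats::coef(sm)
  sdy <- stats::sd(item_table$b)
  beta_std <- c(NA_real_, apply(X, 2L, stats::sd) / sdy * co[-1L, 1L])
  coefficients <- data.frame(
    term = c("intercept", RULE_KINDS), B = co[, 1L], beta = beta_std,
    t = co[, 3L], p = co[, 4L], row.names = NULL, stringsAsFactors = FALSE)
  an <- stats::anova(base, full)
  structure(
    list(coefficients = coefficients,
         r_squared = sm$r.squared,
         F_model = sm$fstatistic[[1L]],
         df_model = c(sm$fstatistic[[2L]], sm$fstatistic[[3L]]),
         p_model = stats::pf(sm$fstatistic[[1L]], sm$fstatistic[[2L]],
                             sm$fstatistic[[3L]], lower.tail = FALSE),
         F_increment = an$F[2L],
         df_increment = c(an$Df[2L], an$Res.Df[2L]),
         p_increment = an$`Pr(>F)`[2L],
         lm_fit = full),
    class = "rule_regression"
  )
}

#' @export
print.rule_regression <- function(x, ...) {
  cat(sprintf("Rule regression: R^2 = %.3f, F(%d,%d) = %.2f, p = %.4g\n",
              x$r_squared, x$df_model[1L], x$df_model[2L], x$F_model,
              x$p_model))
  cat(sprintf("Increment over rule count: F(%d,%d) = %.2f, p = %.4g\n",
              x$df_increment[1L], x$df_increment[2L], x$F_increment,
              x$p_increment))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Full psychometric report for a simulated or observed administration
#'
#' Bundles the reporting layer: per-form CTT (difficulty, part-whole,
#' alpha), the two cross-form ANOVAs on CTT difficulty and part-whole
#' correlation, the CTT-difficulty vs equated-threshold correlation with
#' +/-3SD trimming, and the rule regression of equated thresholds on the
#' rule indicators.
#'
#' @param matrix a `response_matrix`
#' @param equated_params data.frame with `item_id`, `a`, `b` on the common
#'   scale
#' @param bank an `item_bank` (for the rule indicators)
#' @return list of class `psychometric_report`
#' @export
psychometric_report <- function(matrix, equated_params, bank) {
  ctt <- ctt_stats(matrix)
  it <- ctt$items
  anova_p <- oneway_anova(it$p, it$form_id)
  ok_rpw <- !is.na(it$r_pw)
  anova_rpw <- oneway_anova(it$r_pw[ok_rpw], it$form_id[ok_rpw])
  merged <- merge(stats::aggregate(p ~ item_id, data = it, FUN = mean),
                  equated_params, by = "item_id")
  trim <- correlate_with_trim(merged$p, merged$b)
  tab <- merge(bank_item_table(bank), equated_params, by = "item_id")
  tab <- tab[!tab$is_practice, ]
  reg <- rule_regression(tab)
  structure(
    list(ctt = ctt, anova_difficulty = anova_p,
         anova_part_whole = anova_rpw,
         difficulty_correlation = trim,
         regression = reg),
    class = "psychometric_report"
  )
}

#' @export
print.psychometric_report <- function(x, ...) {
  cat("== CTT ==\n")
  cat(sprintf("mean difficulty p = %.3f (SD %.3f); mean part-whole = %.3f\n",
              mean(x$ctt$items$p), stats::sd(x$ctt$items$p),
              mean(x$ctt$items$r_pw, na.rm = TRUE)))
  cat(sprintf("mean alpha across forms = %.3f\n", mean(x$ctt$forms$alpha)))
  cat("difficulty ANOVA: "); print(x$anova_difficulty)
  cat("part-whole ANOVA: "); print(x$anova_part_whole)
  cat(sprintf("p vs b: r = %.3f (trimmed %.3f, %d removed)\n",
              x$difficulty_correlation$r_raw,
              x$difficulty_correlation$r_trimmed,
              x$difficulty_correlation$n_removed))
  print(x$regression)
  invisible(x)
}
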