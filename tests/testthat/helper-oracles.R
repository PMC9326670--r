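# Independent brute-force oracles (first principles, loop-based) used to
# cross-check the package's statistics, plus shared cached fixtures.

oracle_ctt <- function(resp) {
  n <- nrow(resp); k <- ncol(resp)
  p <- numeric(k); r_pw <- numeric(k)
  for (j in seq_len(k)) {
    p[j] <- sum(resp[, j]) / n
    rest <- numeric(n)
    for (i in seq_len(n)) rest[i] <- sum(resp[i, -j])
    x <- resp[, j]
    num <- sum((x - mean(x)) * (rest - mean(rest)))
    den <- sqrt(sum((x - mean(x))^2) * sum((rest - mean(rest))^2))
    r_pw[j] <- if (den > 0) num / den else NA_real_
  }
  tot <- numeric(n)
  for (i in seq_len(n)) tot[i] <- sum(resp[i, ])
  item_vars <- numeric(k)
  for (j in seq_len(k)) {
    item_vars[j] <- sum((resp[, j] - mean(resp[, j]))^2) / (n - 1)
  }
  tot_var <- sum((tot - mean(tot))^2) / (n - 1)
  alpha <- (k / (k - 1)) * (1 - sum(item_vars) / tot_var)
  list(p = p, r_pw = r_pw, alpha = alpha)
}

oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  levs <- unique(groups)
  grand <- mean(values)
  ss_b <- 0; ss_w <- 0
  for (g in levs) {
    v <- values[groups == g]
    ss_b <- ss_b + length(v) * (mean(v) - grand)^2
    ss_w <- ss_w + sum((v - mean(v))^2)
  }
  dfb <- length(levs) - 1
  dfw <- length(values) - length(levs)
  msw <- ss_w / dfw
  Fv <- (ss_b / dfb) / msw
  omega <- max(0, (ss_b - dfb * msw) / (ss_b + ss_w + msw))
  list(F = Fv, p = stats::pf(Fv, dfb, dfw, lower.tail = FALSE),
       omega_sq = omega, df = c(dfb, dfw))
}

oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# OLS through explicit normal equations; returns coefficients, R^2 and the
# incremental F of model X1 (with intercept) over nested X0.
oracle_ols <- function(y, X1, X0 = NULL) {
  X1i <- cbind(1, X1)
  beta <- solve(t(X1i) %*% X1i, t(X1i) %*% y)
  res1 <- y - X1i %*% beta
  rss1 <- sum(res1^2)
  tss <- sum((y - mean(y))^2)
  out <- list(beta = drop(beta), r2 = 1 - rss1 / tss)
  if (!is.null(X0)) {
    X0i <- cbind(1, X0)
    b0 <- solve(t(X0i) %*% X0i, t(X0i) %*% y)
    rss0 <- sum((y - X0i %*% b0)^2)
    df_extra <- ncol(X1i) - ncol(X0i)
    df_res <- length(y) - ncol(X1i)
    out$F_inc <- ((rss0 - rss1) / df_extra) / (rss1 / df_res)
    out$df_inc <- c(df_extra, df_res)
  }
  out
}

# Fine-grid integral of the 2PL response curve over a normal ability
# population (independent check on simulated marginal proportions).
oracle_marginal_p <- function(a, b, mean = 0, sd = 1) {
  tt <- seq(mean - 10 * sd, mean + 10 * sd, length.out = 20001)
  sum(stats::plogis(a * (tt - b)) * stats::dnorm(tt, mean, sd)) *
    (tt[2] - tt[1])
}

# Shared fixtures, built once per test run.
.fixture_env <- new.env()

cached_full_bank <- function() {
  if (is.null(.fixture_env$full_bank)) {
    .fixture_env$full_bank <-
      split_and_anchor(build_bank(bank_config(master_seed = 42L)))
  }
  .fixture_env$full_bank
}

toy_config <- function(seed = 5L) {
  bank_config(
    items_per_rule_count = c(`1` = 2L, `2` = 4L, `3` = 4L),
    n_test_sets = 2L,
    set_composition = c(`1` = 1L, `2` = 2L, `3` = 2L),
    anchor_composition = c(`2` = 1L, `3` = 1L),
    master_seed = seed)
}

cached_toy_bank <- function() {
  if (is.null(.fixture_env$toy_bank)) {
    .fixture_env$toy_bank <- split_and_anchor(build_bank(toy_config()))
  }
  .fixture_env$toy_bank
}

# k distinct rule kinds, deterministic in seed
resample_kinds <- function(k, seed) {
  matrixbank:::with_seed(seed, sample(c("ADD", "SUB", "DIS", "INT", "ROT",
                                        "COM"), k))
}

# The four-corner addition worked example: rows add the corner-square
# family; the unique solution is all four corner elements.
figure_stem <- function() {
  list(0L, 1L, c(0L, 1L),
       2L, 3L, c(2L, 3L),
       c(0L, 1L), c(2L, 3L))
}
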