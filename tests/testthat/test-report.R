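test_that("CTT statistics match the hand-computed toy fixture", {
  resp <- matrix(c(1, 1,
                   1, 0,
                   0, 0), nrow = 3, byrow = TRUE,
                 dimnames = list(NULL, c("j1", "j2")))
  ctt <- ctt_stats(response_matrix(resp))
  expect_equal(ctt$items$p, c(2 / 3, 1 / 3))
  # item vs the other item: cor((1,1,0),(1,0,0)) = 0.5
  expect_equal(ctt$items$r_pw, c(0.5, 0.5))
  # alpha = 2 * (1 - (1/3 + 1/3) / 1) = 2/3
  expect_equal(ctt$forms$alpha, 2 / 3)
})

test_that("CTT agrees with the brute-force oracle on random data", {
  set.seed(61)
  resp <- matrix(stats::rbinom(25 * 8, 1, 0.6), nrow = 25,
                 dimnames = list(NULL, sprintf("j%d", 1:8)))
  ctt <- ctt_stats(response_matrix(resp))
  orc <- oracle_ctt(resp)
  expect_equal(ctt$items$p, orc$p, tolerance = 1e-10)
  expect_equal(ctt$items$r_pw, orc$r_pw, tolerance = 1e-10)
  expect_equal(ctt$forms$alpha, orc$alpha, tolerance = 1e-10)
  # duplicating every person leaves the statistics unchanged
  ctt2 <- ctt_stats(response_matrix(rbind(resp, resp)))
  expect_equal(ctt2$items$p, ctt$items$p)
  expect_equal(ctt2$items$r_pw, ctt$items$r_pw)
  expect_equal(ctt2$forms$alpha, ctt$forms$alpha)
})

test_that("an all-correct item reports p = 1 and undefined part-whole", {
  resp <- matrix(c(1, 1, 1, 1, 0, 1, 1, 1, 0), nrow = 3,
                 dimnames = list(NULL, c("j1", "j2", "j3")))
  ctt <- ctt_stats(response_matrix(resp))
  expect_equal(ctt$items$p[1], 1)
  expect_true(is.na(ctt$items$r_pw[1]))
})

test_that("one-way ANOVA matches hand computation and the oracle", {
  res <- oneway_anova(c(0, 1, 2, 3), c("g1", "g1", "g2", "g2"))
  # SSb = 4, MSw = 0.5 -> F = 8; omega = (4 - 0.5) / (5 + 0.5)
  expect_equal(res$F, 8)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 2L)
  expect_equal(res$omega_sq, 3.5 / 5.5)
  set.seed(62)
  v <- stats::rnorm(60)
  g <- rep(c("x", "y", "z"), each = 20)
  res2 <- oneway_anova(v, g)
  orc <- oracle_anova(v, g)
  expect_equal(res2$F, orc$F, tolerance = 1e-10)
  expect_equal(res2$p, orc$p, tolerance = 1e-10)
  expect_equal(res2$omega_sq, orc$omega_sq, tolerance = 1e-10)
  # identical groups -> F = 0, omega = 0; and the algebraic bound
  res3 <- oneway_anova(rep(c(1, 2), 2), rep(c("u", "v"), each = 2))
  expect_equal(res3$F, 0)
  expect_equal(res3$omega_sq, 0)
  ss_b <- sum(tapply(v, g, length) * (tapply(v, g, mean) - mean(v))^2)
  expect_lte(res2$omega_sq, ss_b / sum((v - mean(v))^2))
  expect_error(oneway_anova(1:3, c("a", "a", "b")),
               class = "matrixbank_config_error")
})

test_that("trimmed correlation removes marginal outliers one-pass", {
  x <- 1:20
  y <- 2 * x + 3
  res <- correlate_with_trim(x, y)
  expect_equal(res$r_raw, 1)
  expect_equal(res$r_trimmed, 1)
  expect_equal(res$n_removed, 0L)
  # one extreme leverage point breaking a strong negative relation
  set.seed(63)
  x2 <- c(stats::rnorm(40), 30)
  y2 <- c(-x2[1:40] + stats::rnorm(40, 0, 0.2), 30)
  res2 <- correlate_with_trim(x2, y2)
  expect_equal(res2$n_removed, 1L)
  expect_gt(abs(res2$r_trimmed), abs(res2$r_raw))
  expect_equal(res2$r_raw, oracle_pearson(x2, y2), tolerance = 1e-10)
  expect_equal(res2$r_trimmed, oracle_pearson(x2[1:40], y2[1:40]),
               tolerance = 1e-10)
  expect_error(correlate_with_trim(rep(1, 5), 1:5),
               class = "matrixbank_config_error")
})

test_that("the noiseless rule-model fixture recovers its coefficients", {
  bank <- cached_full_bank()
  tab <- bank_item_table(bank)
  tab <- tab[!tab$is_practice, ]
  w <- c(ADD = 0.41, SUB = 0.51, DIS = 0.77, INT = 0.68, ROT = 0.34,
         COM = 0.12)
  tab$b <- drop(-1.56 + as.matrix(tab[, names(w)]) %*% w)
  # lm warns about the (intentional) essentially perfect fit
  reg <- suppressWarnings(rule_regression(tab))
  expect_equal(reg$coefficients$B,
               unname(c(-1.56, w)), tolerance = 1e-10)
  expect_equal(reg$r_squared, 1, tolerance = 1e-10)
})

test_that("OLS and the incremental F agree with the normal-equation
          oracle", {
  bank <- cached_full_bank()
  tab <- bank_item_table(bank)
  tab <- tab[!tab$is_practice, ]
  set.seed(64)
  w <- c(ADD = 0.41, SUB = 0.51, DIS = 0.77, INT = 0.68, ROT = 0.34,
         COM = 0.12)
  X <- as.matrix(tab[, names(w)])
  tab$b <- drop(-1.56 + X %*% w) + stats::rnorm(nrow(tab), 0, 0.5)
  reg <- rule_regression(tab)
  orc <- oracle_ols(tab$b, X, X0 = matrix(rowSums(X), ncol = 1))
  expect_equal(reg$coefficients$B, unname(orc$beta), tolerance = 1e-10)
  expect_equal(reg$r_squared, orc$r2, tolerance = 1e-10)
  expect_equal(reg$F_increment, orc$F_inc, tolerance = 1e-10)
  expect_equal(reg$df_increment, orc$df_inc)
  # standardised weights: B * sd(x) / sd(y)
  expect_equal(reg$coefficients$beta[-1],
               unname(orc$beta[-1]) * apply(X, 2, stats::sd) /
                 stats::sd(tab$b),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("equal per-rule weights yield a null incremental F", {
  bank <- cached_full_bank()
  tab <- bank_item_table(bank)
  tab <- tab[!tab$is_anchor & !tab$is_practice, ]
  X <- as.matrix(tab[, c("ADD", "SUB", "DIS", "INT", "ROT", "COM")])
  nonsig <- 0L
  for (r in 1:10) {
    set.seed(650 + r)
    tab$b <- -1.56 + 0.45 * tab$rule_count +
      stats::rnorm(nrow(tab), 0, 0.3)
    reg <- rule_regression(tab)
    if (reg$p_increment >= 0.05) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 9L)
})

test_that("degenerate regression designs raise a collinearity error", {
  tab <- data.frame(b = stats::rnorm(12), ADD = 1, SUB = 1, DIS = 0,
                    INT = 0, ROT = 0, COM = 0)
  expect_error(rule_regression(tab), "offending")
  expect_error(rule_regression(tab[1:5, ]),
               class = "matrixbank_config_error")
})
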