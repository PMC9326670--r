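test_that("the 2PL response function matches hand evaluation", {
  expect_equal(probability_correct(data.frame(a = 2, b = 0.3), 0.3), 0.5)
  expect_equal(probability_correct(data.frame(a = 2.09, b = -0.17), 0),
               1 / (1 + exp(-2.09 * 0.17)))
  expect_lt(abs(probability_correct(data.frame(a = 1.5, b = 0.2),
                                    0.2 + 30 / 1.5) - 1), 1e-9)
  p <- probability_correct(data.frame(item_id = c("x", "y"),
                                      a = c(1, 2), b = c(0, 0)),
                           c(-1, 0, 1))
  expect_equal(dim(p), c(3L, 2L))
  expect_true(all(diff(p[, 1]) > 0))
  expect_error(probability_correct(data.frame(a = -1, b = 0), 0),
               class = "matrixbank_config_error")
})

# one moderate calibration shared by several blocks below
calib <- local({
  set.seed(21)
  J <- 15
  pars <- data.frame(item_id = sprintf("i%02d", 1:J),
                     a = stats::runif(J, 1, 3),
                     b = stats::rnorm(J, -0.17, 0.99))
  ab <- sample_abilities(1500, seed = 22)
  rm_ <- simulate_responses(NULL, pars, ab, seed = 23)
  list(pars = pars, ab = ab, rm = rm_, fit = fit_2pl(rm_))
})

test_that("MML-EM recovers generating parameters and is monotone", {
  fit <- calib$fit
  expect_true(fit$converged)
  m <- merge(calib$pars, fit$params, by = "item_id")
  expect_gt(stats::cor(m$b.x, m$b.y), 0.97)
  expect_gt(stats::cor(m$a.x, m$a.y), 0.85)
  expect_lt(mean(abs(m$b.y - m$b.x)), 0.1)
  # EM monotonicity, assert per cycle
  expect_true(all(diff(fit$ll_trace) >= -1e-6))
  # scale identification: estimated b recentred near the generating mean
  expect_lt(abs(mean(m$b.y) - mean(m$b.x)), 0.15)
  expect_true(all(fit$params$se_a > 0 & fit$params$se_b > 0))
})

test_that("duplicate response columns converge to matching parameters", {
  rm_ <- calib$rm
  resp <- rm_$responses
  resp[, "i02"] <- resp[, "i01"]
  fit <- fit_2pl(response_matrix(resp, rm_$person_id, rm_$form_id))
  p <- fit$params
  i1 <- p[p$item_id == "i01", ]
  i2 <- p[p$item_id == "i02", ]
  expect_lt(abs(i1$b - i2$b), 2 * sqrt(i1$se_b^2 + i2$se_b^2))
  expect_lt(abs(i1$a - i2$a), 2 * sqrt(i1$se_a^2 + i2$se_a^2))
})

test_that("degenerate items are excluded with a report", {
  rm_ <- calib$rm
  resp <- rm_$responses[1:200, ]
  resp[, "i03"] <- 1
  expect_warning(
    fit <- fit_2pl(response_matrix(resp)),
    "degenerate")
  expect_equal(fit$dropped, "i03")
  expect_false("i03" %in% fit$params$item_id)
})

test_that("EAP scoring is symmetric, shrunk, and quadrature-stable", {
  # symmetric items, half answered correctly -> theta ~ 0
  pars <- data.frame(item_id = c("s1", "s2"), a = c(2, 2), b = c(-1, 1))
  resp <- matrix(c(1, 0), nrow = 1,
                 dimnames = list("p1", c("s1", "s2")))
  est <- estimate_abilities(pars, response_matrix(resp))
  expect_lt(abs(est$theta_eap), 0.05)
  # all-correct pattern stays finite (prior shrinkage)
  resp2 <- matrix(c(1, 1), nrow = 1, dimnames = list("p1", c("s1", "s2")))
  est2 <- estimate_abilities(pars, response_matrix(resp2))
  expect_true(is.finite(est2$theta_eap) && est2$theta_eap > 0)
  expect_lt(est2$theta_eap, 6)
  # refinement oracle: 10x finer grid agrees to 1e-4
  e1 <- estimate_abilities(calib$fit$params, calib$rm)
  e2 <- estimate_abilities(calib$fit$params, calib$rm, n_quad = 601L)
  expect_lt(max(abs(e1$theta_eap - e2$theta_eap)), 1e-4)
  expect_true(all(e1$posterior_sd > 0))
})

test_that("persons with no observed responses are excluded from scoring", {
  pars <- data.frame(item_id = c("s1", "s2"), a = c(2, 2), b = c(0, 0))
  resp <- matrix(c(1, 0, NA, NA), nrow = 2, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), c("s1", "s2")))
  est <- estimate_abilities(pars, response_matrix(resp))
  expect_equal(nrow(est), 1L)
  expect_equal(attr(est, "excluded"), "p2")
})

test_that("the misfit flag needs both an aberrant msq and significant z", {
  expect_false(misfit_flag(1.0, 1.0, 0, 0))
  expect_true(misfit_flag(1.0, 0.0005, 0, -8))    # tiny outfit, sig z
  expect_false(misfit_flag(1.0, 1.40, 0, 0.5))    # aberrant but not sig
  expect_true(misfit_flag(1.5, 1.0, 2.5, 0))
  expect_false(misfit_flag(1.2, 1.2, 5, 5))       # inside the band
  expect_equal(misfit_flag(c(1, 0.5), c(1, 1), c(0, -3), c(0, 0)),
               c(FALSE, TRUE))
})

test_that("model-true data yield calibrated mean squares, no mass flags", {
  fit <- calib$fit
  eap <- estimate_abilities(fit$params, calib$rm)
  fs <- fit_statistics(fit$params, eap, calib$rm)
  expect_true(all(fs$infit_msq > 0.8 & fs$infit_msq < 1.2))
  # outfit is heavy-tailed for steep/extreme items (single lucky responses
  # at P near 0 dominate), so only its bulk sits in the nominal band
  expect_gte(mean(fs$outfit_msq > 0.8 & fs$outfit_msq < 1.2), 0.7)
  expect_lte(sum(fs$flagged), 1L)
})

test_that("an injected random responder is flagged against banked params", {
  set.seed(31)
  J <- 21
  pars <- data.frame(item_id = sprintf("i%02d", 1:J),
                     a = stats::runif(J, 1, 3),
                     b = stats::rnorm(J, -0.17, 0.99))
  ab <- sample_abilities(2000, seed = 32)
  rm_ <- simulate_responses(NULL, pars, ab, seed = 33)
  rm_ <- inject_misfit(rm_, "i21", "random_responder", seed = 34)
  eap <- estimate_abilities(pars, rm_)
  fs <- fit_statistics(pars, eap, rm_)
  expect_true(fs$flagged[fs$item_id == "i21"])
  expect_gt(fs$outfit_msq[fs$item_id == "i21"], 1.33)
  expect_lte(sum(fs$flagged[fs$item_id != "i21"]), 2L)
})
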