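ref_pars <- data.frame(item_id = c("a1", "a2", "a3", "a4"),
                       a = c(1.2, 1.8, 2.4, 3.0),
                       b = c(-1.5, -0.5, 0.5, 1.5))

test_that("mean-sigma linking matches hand-evaluated cases", {
  # identical anchors -> identity
  co <- link_forms(list(f1 = ref_pars, f2 = ref_pars), ref_pars$item_id)
  expect_equal(co$A, c(1, 1))
  expect_equal(co$B, c(0, 0))
  # pure +0.5 shift, same spread -> A = 1, B = -0.5
  shifted <- ref_pars
  shifted$b <- shifted$b + 0.5
  co <- link_forms(list(f1 = ref_pars, f2 = shifted), ref_pars$item_id)
  expect_equal(co$A[2], 1)
  expect_equal(co$B[2], -0.5)
  # doubled spread around mean 0 -> A = 0.5, B = 0
  doubled <- ref_pars
  doubled$b <- 2 * ref_pars$b
  co <- link_forms(list(f1 = ref_pars, f2 = doubled), ref_pars$item_id)
  expect_equal(co$A[2], 0.5)
  expect_equal(co$B[2], 0)
})

test_that("mean-mean uses the discrimination ratio", {
  g <- ref_pars
  g$a <- ref_pars$a * 2        # looks twice as discriminating
  g$b <- ref_pars$b / 2
  co <- link_forms(list(f1 = ref_pars, f2 = g), ref_pars$item_id,
                   method = "mean_mean")
  expect_equal(co$A[2], 2)
  expect_equal(co$B[2], mean(ref_pars$b) - 2 * mean(g$b))
})

test_that("linking validates its inputs", {
  expect_error(link_forms(list(f1 = ref_pars, f2 = ref_pars[-1, ]),
                          ref_pars$item_id),
               class = "matrixbank_config_error")
  flat <- ref_pars
  flat$b <- 1
  expect_error(link_forms(list(f1 = ref_pars, f2 = flat),
                          ref_pars$item_id),
               "mean_mean")
  expect_error(link_forms(list(f1 = ref_pars, f2 = ref_pars),
                          ref_pars$item_id[1], method = "mean_sigma"),
               class = "matrixbank_config_error")
})

test_that("order invariance: permuting anchors leaves (A, B) unchanged", {
  g <- ref_pars
  g$b <- 1.3 * g$b + 0.4
  co1 <- link_forms(list(f1 = ref_pars, f2 = g), ref_pars$item_id)
  co2 <- link_forms(list(f1 = ref_pars, f2 = g),
                    rev(ref_pars$item_id))
  expect_equal(co1$A, co2$A)
  expect_equal(co1$B, co2$B)
})

test_that("parameter transformation applies and inverts exactly", {
  p <- data.frame(item_id = "x", a = 2, b = 0.5, se_a = 0.1, se_b = 0.2)
  expect_equal(transform_params(p, list(A = 1, B = 0)), p)
  tp <- transform_params(p, list(A = 2, B = 0.1))
  expect_equal(tp$a, 1)
  expect_equal(tp$b, 1.1)
  back <- transform_params(tp, list(A = 1 / 2, B = -0.1 / 2))
  expect_equal(back$a, p$a, tolerance = 1e-12)
  expect_equal(back$b, p$b, tolerance = 1e-12)
  expect_error(transform_params(p, list(A = 2)),
               class = "matrixbank_config_error")
})

test_that("equating check returns F = 0 for identical forms and detects
          an un-equated shift", {
  set.seed(41)
  base <- data.frame(form_id = rep(c("f1", "f2"), each = 20),
                     a = stats::runif(40, 1, 3),
                     b = stats::rnorm(40))
  same <- base
  same$b <- rep(base$b[1:20], 2)
  same$a <- rep(base$a[1:20], 2)
  chk <- equating_check(same)
  expect_equal(chk$b$F, 0)
  expect_equal(chk$b$omega_sq, 0)
  shifted <- base
  shifted$b[shifted$form_id == "f2"] <-
    shifted$b[shifted$form_id == "f2"] + 1
  chk2 <- equating_check(shifted)
  expect_lt(chk2$b$p, 0.001)
  expect_error(equating_check(base[base$form_id == "f1", ]),
               class = "matrixbank_config_error")
})

test_that("calibrate-then-link recovers an induced population shift", {
  # two populations 0.5 apart taking different forms that share anchors;
  # a single replicate's linking error has SD ~ 0.05, so the point check
  # is on this seeded replicate's anchors and the acceptance suite runs
  # the 20-replicate version of the recovery bound
  set.seed(51)
  anchors <- data.frame(item_id = sprintf("a%d", 1:6),
                        a = stats::runif(6, 1, 3),
                        b = c(-1.87, -0.3, -0.16, 0.1, 0.24, 0.67))
  u1 <- data.frame(item_id = sprintf("u1_%02d", 1:22),
                   a = stats::runif(22, 1, 3),
                   b = stats::rnorm(22, -0.17, 0.99))
  u2 <- data.frame(item_id = sprintf("u2_%02d", 1:22),
                   a = stats::runif(22, 1, 3),
                   b = stats::rnorm(22, -0.17, 0.99))
  forms <- list(
    list(form_id = "f1", test_set_item_ids = u1$item_id,
         anchor_item_ids = anchors$item_id),
    list(form_id = "f2", test_set_item_ids = u2$item_id,
         anchor_item_ids = anchors$item_id))
  pars <- rbind(anchors, u1, u2)
  ab1 <- sample_abilities(2000, 0, 1, seed = 52)
  ab2 <- sample_abilities(2000, 0.5, 1, seed = 53)
  ab2$person_id <- sprintf("q%06d", 1:2000)
  rm1 <- simulate_responses(forms[1], pars, ab1, seed = 54,
                            form_assignment = rep(1L, 2000))
  rm2 <- simulate_responses(forms[2], pars, ab2, seed = 55,
                            form_assignment = rep(1L, 2000))
  f1 <- fit_2pl(rm1)
  f2 <- fit_2pl(rm2)
  eq <- equate_forms(list(f1 = f1$params, f2 = f2$params),
                     anchors$item_id)
  co <- attr(eq, "coefficients")
  expect_lt(abs(co$B[co$form_id == "f2"] - 0.5), 0.15)
  # anchor estimates agree across forms within 2 pooled SEs after linking
  a1 <- f1$params[match(anchors$item_id, f1$params$item_id), ]
  a2t <- transform_params(
    f2$params[match(anchors$item_id, f2$params$item_id), ],
    co[co$form_id == "f2", ])
  pooled_se <- sqrt(a1$se_b^2 + a2t$se_b^2)
  expect_true(all(abs(a1$b - a2t$b) < 2 * pooled_se))
})
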