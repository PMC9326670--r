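test_that("the four-corner addition stem solves to all four corners", {
  rep <- solve_stem(figure_stem())
  expect_true(rep$solvable)
  expect_true(rep$unique)
  expect_length(rep$solution, 4L)
  expect_equal(rep$solution, 0:3)
  expect_length(rep$competing_solutions, 0L)
})

test_that("a stem whose consistent hypotheses diverge is not unique", {
  # rows with an empty second cell are consistent with both addition and
  # subtraction, which diverge on the third row
  stem <- list(0L, integer(0), 0L,
               1L, integer(0), 1L,
               c(0L, 1L), 2L)
  rep <- solve_stem(stem)
  expect_true(rep$solvable)
  expect_false(rep$unique)
  expect_gte(length(rep$competing_solutions), 2L)
  has <- function(cands, cell) {
    any(vapply(cands, function(c) setequal(c, cell), logical(1)))
  }
  expect_true(has(rep$competing_solutions, c(0L, 1L, 2L)))  # addition
  expect_true(has(rep$competing_solutions, c(0L, 1L)))      # subtraction
})

test_that("a family with no consistent hypothesis makes a stem unsolvable", {
  # row 1 admits only the completeness set {0,1,3}, row 2 only {0,1,2};
  # no single hypothesis covers both rows
  stem <- list(0L, 1L, 3L,
               0L, 1L, 2L,
               0L, 1L)
  rep <- solve_stem(stem)
  expect_false(rep$solvable)
  expect_false(rep$unique)
})

test_that("composition is deterministic and validates", {
  rules <- list(rule_instance("ADD", 0),
                rule_instance("ROT", 2, direction = "CW"))
  it1 <- compose_item(rules, seed = 101)
  it2 <- compose_item(rules, seed = 101)
  expect_identical(it1, it2)
  it3 <- compose_item(rules, seed = 102)
  expect_false(identical(it1$cells, it3$cells))
  rep <- validate_item(it1)
  expect_true(rep$rules_hold)
  expect_true(rep$unique)
})

test_that("five rules, one per family, partition the cell contents", {
  rules <- list(rule_instance("ADD", 0), rule_instance("SUB", 1),
                rule_instance("DIS", 2),
                rule_instance("ROT", 3, direction = "CCW"),
                rule_instance("COM", 4, required_set = 16:19))
  it <- compose_item(rules, seed = 7)
  expect_equal(it$rule_count, 5L)
  for (cell in it$cells) {
    fams <- element_family(cell)
    # scoped support is disjoint by construction: each element belongs to
    # exactly one rule's family
    expect_true(all(fams %in% 0:4))
  }
  # per-family contents of cell 3 equal the rule applied to the scoped
  # cells 1, 2 (the caller restricts cells to the rule's family)
  scoped <- function(cell, fam) cell[element_family(cell) == fam]
  for (r in rules) {
    expect_equal(
      sort(scoped(it$cells[[3]], r$scope_family)),
      apply_rule(r, scoped(it$cells[[1]], r$scope_family),
                 scoped(it$cells[[2]], r$scope_family)))
  }
  expect_true(validate_item(it)$unique)
})

test_that("overlapping scope families and bad configs are rejected", {
  expect_error(compose_item(list(rule_instance("ADD", 0),
                                 rule_instance("SUB", 0)), seed = 1),
               class = "matrixbank_config_error")
  expect_error(compose_item(list(), seed = 1),
               class = "matrixbank_config_error")
})

test_that("generator-solver round trip holds across rule counts (sample)", {
  set.seed(2024)
  n_ok <- 0L
  n_items <- 0L
  for (k in 1:5) {
    for (i in 1:30) {
      kinds <- sample(matrixbank:::RULE_KINDS, k)
      rules <- matrixbank:::with_seed(7000L + k * 100L + i,
                                      matrixbank:::make_rules(kinds))
      it <- compose_item(rules, seed = 9000L + k * 100L + i)
      rep <- solve_stem(it$cells[1:8])
      n_items <- n_items + 1L
      if (isTRUE(rep$unique) && setequal(rep$solution, it$cells[[9]])) {
        n_ok <- n_ok + 1L
      }
    }
  }
  expect_equal(n_ok, n_items)  # 100% round trip
})

test_that("scoring is a strict exact-match predicate", {
  it <- compose_item(list(rule_instance("ADD", 1)), seed = 55)
  sol <- it$cells[[9]]
  expect_equal(score_response(it, sol), 1L)
  expect_equal(score_response(it, sample(sol)), 1L)  # order irrelevant
  extra <- setdiff(0:19, sol)[1]
  expect_equal(score_response(it, c(sol, extra)), 0L)
  expect_equal(score_response(it, sol[-1]), 0L)
  expect_equal(score_response(it, integer(0)), 0L)
  # exactly one scoring-1 selection among random subsets
  set.seed(4)
  hits <- sum(vapply(1:200, function(i) {
    sel <- which(stats::runif(20) < 0.3) - 1L
    score_response(it, sel)
  }, integer(1)))
  expect_lte(hits, 1L)
})
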