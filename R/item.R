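#' Compose a figural matrix item from construction rules
#'
#' Builds a full 3x3 item whose rows all satisfy the given rules, with the
#' ninth cell withheld as the solution. Cell contents are drawn at random
#' from each rule's scope family; after each draw the stem is handed to the
#' independent solver ([solve_stem()]) and the draw is accepted only if the
#' solver certifies a *unique* solution equal to the generated ninth cell
#' (and a nonempty solution — an item whose correct response is "select
#' nothing" is not administrable in the construction format). Up to
#' `max_attempts` redraws (fresh sub-seed each) are made before failing.
#'
#' Rules must act on pairwise disjoint families; families not under any rule
#' stay empty in every cell, so the solver's hypothesis space is confined to
#' the families actually in play.
#'
#' @param rules list of [rule_instance()] objects, 1 to 5, disjoint scope
#'   families
#' @param seed integer; the item is a deterministic function of
#'   `(rules, seed)`
#' @param item_id optional id string (defaults to `item_<seed>`)
#' @param is_anchor,is_practice flags stored on the item
#' @param max_attempts redraw budget before a generation-failure error
#' @return object of class `matrix_item`: fields `item_id`, `cells` (list of
#'   9 sorted integer vectors, row-major; cell 9 is the solution), `rules`,
#'   `rule_count`, `is_anchor`, `is_practice`, `seed`
#' @examples
#' it <- compose_item(list(rule_instance("ADD", 0)), seed = 7)
#' it$rule_count
#' validate_item(it)$unique
#' @export
compose_item <- function(rules, seed, item_id = NULL, is_anchor = FALSE,
                         is_practice = FALSE, max_attempts = 50L) {
  if (inherits(rules, "rule_instance")) rules <- list(rules)
  check_rule_set(rules)
  seed <- as.integer(seed)
  for (attempt in seq_len(max_attempts)) {
    cells <- with_seed(derive_seed(seed, attempt), draw_cells(rules))
    if (length(cells[[9L]]) == 0L) next
    rep <- solve_stem(cells[1:8])
    if (isTRUE(rep$unique) && setequal(rep$solution, cells[[9L]])) {
      return(structure(
        list(item_id = item_id %||% sprintf("item_%d", seed),
             cells = cells, rules = rules,
             rule_count = length(rules),
             is_anchor = isTRUE(is_anchor),
             is_practice = isTRUE(is_practice),
             seed = seed),
        class = "matrix_item"
      ))
    }
  }
  stop_config(sprintf(
    "could not generate a uniquely solvable item in %d attempts (rules: %s)",
    max_attempts,
    paste(vapply(rules, function(r) sprintf("%s@%d", r$rule_kind,
                                            r$scope_family),
                 character(1)), collapse = ", ")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_rule_set <- function(rules) {
  if (length(rules) < 1L || length(rules) > N_FAMILIES) {
    stop_config("an item needs between 1 and 5 rules")
  }
  if (!all(vapply(rules, inherits, logical(1), "rule_instance"))) {
    stop_config("rules must be rule_instance objects")
  }
  fams <- vapply(rules, `[[`, integer(1), "scope_family")
  if (anyDuplicated(fams)) {
    stop_config("rule scope families must be pairwise disjoint")
  }
  invisible(TRUE)
}

# Draw all nine cells for one attempt; RNG state is the caller's.
draw_cells <- function(rules) {
  cells <- rep(list(integer(0)), 9L)
  for (rule in rules) {
    for (row in 0:2) {
      rc <- draw_row(rule)
      for (j in 1:3) {
        idx <- row * 3L + j
        cells[[idx]] <- as_cell(c(cells[[idx]], rc[[j]]))
      }
    }
  }
  cells
}

# One row's (first, second, third) scoped contents for a single rule.
draw_row <- function(rule) {
  fam <- family_elements(rule$scope_family)
  switch(rule$rule_kind,
    ADD = , SUB = , DIS = {
      c1 <- random_subset(fam)
      c2 <- random_subset(fam)
      list(c1, c2, apply_rule(rule, c1, c2))
    },
    INT = {
      base <- random_subset(fam, max_size = length(fam) - 1L)
      rest <- setdiff(fam, base)
      c1 <- sort(c(base, random_subset(rest, min_size = 0L)))
      c2 <- sort(c(base, random_subset(rest, min_size = 0L)))
      list(c1, c2, apply_rule(rule, c1, c2))
    },
    ROT = {
      c1 <- random_subset(fam, max_size = length(fam) - 1L)
      c2 <- orbit_step(c1, rule$direction)
      list(c1, c2, apply_rule(rule, c1, c2))
    },
    COM = {
      R <- rule$required_set
      # keep the union a strict subset so the third cell is nonempty
      for (k in 1:20) {
        c1 <- random_subset(R)
        c2 <- random_subset(R)
        if (length(union(c1, c2)) < length(R)) break
        c2 <- c1
      }
      list(c1, c2, apply_rule(rule, c1, c2))
    }
  )
}

#' Solve a matrix stem by exhaustive rule-hypothesis enumeration
#'
#' Independent of the generator: for every element family present in the
#' stem, all rule hypotheses (six kinds, both rotation directions, every
#' candidate required set for completeness) are tested for consistency with
#' the two complete rows. Each consistent hypothesis predicts the family's
#' contribution to the missing ninth cell from the third row's first two
#' cells. The stem is *solvable* if every populated family admits at least
#' one consistent hypothesis, and *uniquely* solvable if, per family, all
#' consistent hypotheses agree on the prediction (uniqueness is defined over
#' predicted cells, not over rule labels).
#'
#' @param stem list of 8 cells (integer vectors of element ids), row-major
#' @return list of class `validation_report`: `rules_hold` (NA here; filled
#'   by [validate_item()]), `solvable`, `unique`, `solution` (integer vector
#'   or NULL), `competing_solutions` (list of candidate ninth cells, empty
#'   when unique)
#' @export
solve_stem <- function(stem) {
  stopifnot(is.list(stem), length(stem) == 8L)
  stem <- lapply(stem, as_cell)
  fam_preds <- vector("list", N_FAMILIES)
  solvable <- TRUE
  for (fam in 0:(N_FAMILIES - 1L)) {
    s <- lapply(stem, scope_filter, fam)
    if (all(lengths(s) == 0L)) {
      fam_preds[[fam + 1L]] <- list(integer(0))
      next
    }
    preds <- family_hypotheses(s, fam)
    if (length(preds) == 0L) {
      solvable <- FALSE
      break
    }
    fam_preds[[fam + 1L]] <- preds
  }
  if (!solvable) {
    return(validation_report(solvable = FALSE, unique = FALSE,
                             solution = NULL, competing = list()))
  }
  n_per_fam <- lengths(fam_preds)
  if (all(n_per_fam == 1L)) {
    sol <- as_cell(unlist(lapply(fam_preds, `[[`, 1L)))
    return(validation_report(solvable = TRUE, unique = TRUE, solution = sol,
                             competing = list()))
  }
  # enumerate candidate ninth cells across hypothesis combinations
  combos <- expand.grid(lapply(n_per_fam, seq_len))
  cand <- unique(lapply(seq_len(nrow(combos)), function(i) {
    as_cell(unlist(lapply(seq_len(N_FAMILIES), function(f) {
      fam_preds[[f]][[combos[i, f]]]
    })))
  }))
  if (length(cand) == 1L) {
    return(validation_report(solvable = TRUE, unique = TRUE,
                             solution = cand[[1L]], competing = list()))
  }
  validation_report(solvable = TRUE, unique = FALSE, solution = NULL,
                    competing = cand)
}

validation_report <- function(rules_hold = NA, solvable, unique, solution,
                              competing) {
  structure(list(rules_hold = rules_hold, solvable = solvable,
                 unique = unique, solution = solution,
                 competing_solutions = competing),
            class = "validation_report")
}

# Distinct ninth-cell predictions of all hypotheses consistent with the
# scoped stem of one family. Empty list = no consistent hypothesis.
family_hypotheses <- function(s, fam) {
  preds <- list()
  add_pred <- function(p) {
    p <- as_cell(p)
    for (q in preds) if (setequal(p, q)) return(invisible(NULL))
    preds[[length(preds) + 1L]] <<- p
    invisible(NULL)
  }
  rows_ok <- function(f3) {
    setequal(s[[3L]], f3(s[[1L]], s[[2L]])) &&
      setequal(s[[6L]], f3(s[[4L]], s[[5L]]))
  }
  if (rows_ok(union)) add_pred(union(s[[7L]], s[[8L]]))
  if (rows_ok(setdiff)) add_pred(setdiff(s[[7L]], s[[8L]]))
  symdiff <- function(a, b) union(setdiff(a, b), setdiff(b, a))
  if (rows_ok(symdiff)) add_pred(symdiff(s[[7L]], s[[8L]]))
  if (rows_ok(intersect)) add_pred(intersect(s[[7L]], s[[8L]]))
  for (dir in c("CW", "CCW")) {
    ok <- setequal(s[[2L]], orbit_step(s[[1L]], dir)) &&
      setequal(s[[3L]], orbit_step(s[[2L]], dir)) &&
      setequal(s[[5L]], orbit_step(s[[4L]], dir)) &&
      setequal(s[[6L]], orbit_step(s[[5L]], dir)) &&
      setequal(s[[8L]], orbit_step(s[[7L]], dir))
    if (ok) add_pred(orbit_step(s[[8L]], dir))
  }
  fam_el <- family_elements(fam)
  for (mask in 1:(2^length(fam_el) - 1L)) {
    R <- fam_el[as.logical(bitwAnd(mask, 2^(seq_along(fam_el) - 1L)))]
    u1 <- union(s[[1L]], s[[2L]])
    u2 <- union(s[[4L]], s[[5L]])
    u3 <- union(s[[7L]], s[[8L]])
    ok <- all(u1 %in% R) && setequal(s[[3L]], setdiff(R, u1)) &&
      all(u2 %in% R) && setequal(s[[6L]], setdiff(R, u2)) &&
      all(u3 %in% R)
    if (ok) add_pred(setdiff(R, u3))
  }
  preds
}

#' Validate a composed item
#'
#' Checks (1) structural invariants, (2) that every stored rule relation
#' holds on every row via [apply_rule()], (3) that no element outside the
#' rules' scope families appears anywhere, and (4) that the independent
#' solver certifies a unique solution equal to the stored ninth cell.
#'
#' @param item a `matrix_item`
#' @return a `validation_report` with `rules_hold` filled in
#' @export
validate_item <- function(item) {
  stopifnot(inherits(item, "matrix_item"))
  ok_structure <- length(item$cells) == 9L &&
    item$rule_count == length(item$rules) &&
    !anyDuplicated(vapply(item$rules, `[[`, integer(1), "scope_family"))
  rules_hold <- ok_structure
  if (rules_hold) {
    scoped_fams <- vapply(item$rules, `[[`, integer(1), "scope_family")
    allowed <- unlist(lapply(scoped_fams, family_elements))
    if (!all(unlist(item$cells) %in% allowed)) rules_hold <- FALSE
  }
  if (rules_hold) {
    for (rule in item$rules) {
      for (row in 0:2) {
        c1 <- scope_filter(item$cells[[row * 3L + 1L]], rule$scope_family)
        c2 <- scope_filter(item$cells[[row * 3L + 2L]], rule$scope_family)
        c3 <- scope_filter(item$cells[[row * 3L + 3L]], rule$scope_family)
        got <- tryCatch(apply_rule(rule, c1, c2),
                        matrixbank_rule_violation = function(e) NULL)
        if (is.null(got) || !setequal(got, c3)) {
          rules_hold <- FALSE
          break
        }
      }
      if (!rules_hold) break
    }
  }
  rep <- solve_stem(item$cells[1:8])
  rep$rules_hold <- rules_hold
  if (isTRUE(rep$unique) && !setequal(rep$solution, item$cells[[9L]])) {
    rep$unique <- FALSE
    rep$competing_solutions <- list(rep$solution, item$cells[[9L]])
    rep$solution <- NULL
  }
  rep
}

#' Score a constructed response
#'
#' Dichotomous exact-match scoring: the selection earns 1 if and only if it
#' equals the item's solution set exactly. No partial credit.
#'
#' @param item a `matrix_item`
#' @param selected integer vector of selected element ids (any subset of
#'   0-19)
#' @return integer 0 or 1
#' @export
score_response <- function(item, selected) {
  stopifnot(inherits(item, "matrix_item"))
  as.integer(setequal(as_cell(selected), item$cells[[9L]]))
}

#' @export
print.matrix_item <- function(x, ...) {
  kinds <- vapply(x$rules, `[[`, character(1), "rule_kind")
  cat(sprintf("<matrix_item %s: %d rule(s) [%s]%s>\n", x$item_id,
              x$rule_count, paste(kinds, collapse = ", "),
              if (x$is_anchor) ", anchor" else ""))
  invisible(x)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation: rules_hold=%s solvable=%s unique=%s competing=%d>\n",
    x$rules_hold, x$solvable, x$unique, length(x$competing_solutions)))
  invisible(x)
}
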