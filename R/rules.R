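#' Construction rules
#'
#' Six deterministic relations map the first two cells of a matrix row to the
#' third, each acting on the elements of one family (its *scope*):
#' \describe{
#'   \item{ADD}{addition — union of first and second cell}
#'   \item{SUB}{subtraction — first cell minus second cell}
#'   \item{DIS}{disjunctive union — symmetric difference (shared elements
#'     are eliminated)}
#'   \item{INT}{intersection — only elements present in both cells survive}
#'   \item{ROT}{rotation — elements advance one orbit step per cell,
#'     clockwise or counter-clockwise}
#'   \item{COM}{completeness — a fixed required set must be covered by the
#'     row; the third cell supplies whatever the first two are missing}
#' }
#'
#' @param rule_kind one of `"ADD"`, `"SUB"`, `"DIS"`, `"INT"`, `"ROT"`,
#'   `"COM"`
#' @param scope_family integer 0-4, the element family the rule acts on
#' @param direction `"CW"` or `"CCW"`; required exactly for ROT
#' @param required_set integer vector of element ids; required (nonempty,
#'   within the scope family) exactly for COM
#' @return An object of class `rule_instance`.
#' @examples
#' rule_instance("ADD", 0)
#' rule_instance("ROT", 2, direction = "CCW")
#' rule_instance("COM", 4, required_set = c(16, 17, 18))
#' @export
rule_instance <- function(rule_kind, scope_family, direction = NULL,
                          required_set = NULL) {
  rule_kind <- match.arg(rule_kind, RULE_KINDS)
  scope_family <- as.integer(scope_family)
  stopifnot(scope_family %in% 0:(N_FAMILIES - 1L))
  if (rule_kind == "ROT") {
    if (is.null(direction)) {
      stop("ROT rule requires a direction (\"CW\" or \"CCW\")", call. = FALSE)
    }
    direction <- match.arg(direction, c("CW", "CCW"))
  } else if (!is.null(direction)) {
    stop("direction is only meaningful for ROT rules", call. = FALSE)
  }
  if (rule_kind == "COM") {
    required_set <- as_cell(required_set)
    if (length(required_set) == 0L) {
      stop("COM rule requires a nonempty required_set", call. = FALSE)
    }
    if (!all(required_set %in% family_elements(scope_family))) {
      stop("COM required_set must lie within the scope family", call. = FALSE)
    }
  } else if (!is.null(required_set)) {
    stop("required_set is only meaningful for COM rules", call. = FALSE)
  }
  structure(
    list(rule_kind = rule_kind, scope_family = scope_family,
         direction = direction, required_set = required_set),
    class = "rule_instance"
  )
}

RULE_KINDS <- c("ADD", "SUB", "DIS", "INT", "ROT", "COM")

#' @export
print.rule_instance <- function(x, ...) {
  extra <- ""
  if (x$rule_kind == "ROT") extra <- paste0(", ", x$direction)
  if (x$rule_kind == "COM") {
    extra <- paste0(", required {", paste(x$required_set, collapse = ","), "}")
  }
  cat(sprintf("<rule %s on family %d%s>\n", x$rule_kind, x$scope_family,
              extra))
  invisible(x)
}

# Canonical cell content: sorted unique integer vector of element ids.
as_cell <- function(x) {
  if (is.null(x) || length(x) == 0L) return(integer(0))
  x <- sort(unique(as.integer(x)))
  if (any(x < 0L | x >= N_ELEMENTS)) {
    stop("cell content contains invalid element ids", call. = FALSE)
  }
  x
}

scope_filter <- function(cell, family_id) {
  cell[element_family(cell) == family_id]
}

#' Apply a construction rule to a row prefix
#'
#' Computes the scoped contribution of `rule` to the third cell of a row,
#' given the first and second cells. The caller is responsible for
#' restricting the cells to the rule's scope family (full cells mix the
#' contributions of several rules); the set operations themselves are
#' family-agnostic.
#'
#' @param rule a [rule_instance()]
#' @param first_cell,second_cell integer vectors of element ids (already
#'   restricted to the rule's scope)
#' @return sorted integer vector: the rule's contribution to the third cell
#' @examples
#' apply_rule(rule_instance("ADD", 0), 0L, 1L)        # union: 0 1
#' apply_rule(rule_instance("DIS", 0), c(0L, 1L), c(1L, 2L))  # 0 2
#' @export
apply_rule <- function(rule, first_cell, second_cell) {
  stopifnot(inherits(rule, "rule_instance"))
  f <- as_cell(first_cell)
  s <- as_cell(second_cell)
  switch(rule$rule_kind,
    ADD = as_cell(union(f, s)),
    SUB = as_cell(setdiff(f, s)),
    DIS = as_cell(union(setdiff(f, s), setdiff(s, f))),
    INT = as_cell(intersect(f, s)),
    COM = {
      fs <- union(f, s)
      if (!all(fs %in% rule$required_set)) {
        stop_rule_violation(
          "COM rule: cell elements are not contained in the required set")
      }
      as_cell(setdiff(rule$required_set, fs))
    },
    ROT = {
      if (!setequal(orbit_step(f, rule$direction), s)) {
        stop_rule_violation(
          "ROT rule: second cell is not one orbit step from the first")
      }
      orbit_step(s, rule$direction)
    }
  )
}

stop_rule_violation <- function(msg) {
  stop(errorCondition(msg, class = c("matrixbank_rule_violation",
                                     "matrixbank_error")))
}

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("matrixbank_config_error",
                                     "matrixbank_error")))
}
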