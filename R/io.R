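#' Write an item bank to JSON
#'
#' Every item is re-validated before writing; a bank containing an item that
#' fails validation (rules not holding, or no unique solution matching the
#' stored ninth cell) is refused. The on-disk format is documented by the
#' schema shipped at `system.file("schema", "bank-schema.json",
#' package = "matrixbank")`.
#'
#' @param bank an `item_bank`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_bank <- function(bank, path) {
  stopifnot(inherits(bank, "item_bank"))
  for (it in bank$items) {
    rep <- validate_item(it)
    if (!isTRUE(rep$rules_hold) || !isTRUE(rep$unique)) {
      stop_config(sprintf("refusing to write: item '%s' fails validation",
                          it$item_id))
    }
  }
  cfg <- bank$config
  obj <- list(
    format = "matrixbank-bank",
    version = 1L,
    config = list(
      items_per_rule_count = as.list(cfg$items_per_rule_count),
      n_test_sets = cfg$n_test_sets,
      set_composition = as.list(cfg$set_composition),
      anchor_composition = as.list(cfg$anchor_composition),
      n_practice = cfg$n_practice,
      master_seed = cfg$master_seed
    ),
    items = lapply(bank$items, function(it) {
      list(item_id = it$item_id,
           cells = lapply(it$cells, as.integer),
           rules = lapply(it$rules, function(r) {
             out <- list(kind = r$rule_kind, family = r$scope_family)
             if (!is.null(r$direction)) out$direction <- r$direction
             if (!is.null(r$required_set)) {
               out$required_set <- as.integer(r$required_set)
             }
             out
           }),
           rule_count = it$rule_count,
           is_anchor = it$is_anchor,
           is_practice = it$is_practice,
           seed = it$seed)
    }),
    forms = if (is.null(bank$forms)) NULL else lapply(bank$forms, identity)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                           digits = NA, pretty = FALSE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

stop_parse <- function(pointer, msg) {
  stop(errorCondition(sprintf("bank parse error at %s: %s", pointer, msg),
                      class = c("matrixbank_parse_error",
                                "matrixbank_error")))
}

#' Read an item bank from JSON
#'
#' Parses and validates against the bank schema; violations are reported
#' with a JSON-pointer-style location and no partial bank is returned. Each
#' item is re-validated (rule relations and solution uniqueness) after
#' reconstruction.
#'
#' @param path JSON file path
#' @param revalidate logical; re-run the solver on every item (default TRUE)
#' @return an `item_bank`
#' @export
read_bank <- function(path, revalidate = TRUE) {
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop_parse("/", conditionMessage(e)))
  if (!identical(obj$format, "matrixbank-bank")) {
    stop_parse("/format", "expected \"matrixbank-bank\"")
  }
  cfg <- obj$config
  for (f in c("items_per_rule_count", "n_test_sets", "set_composition",
              "anchor_composition", "n_practice", "master_seed")) {
    if (is.null(cfg[[f]])) stop_parse(paste0("/config/", f), "missing")
  }
  config <- bank_config(
    items_per_rule_count = unlist(cfg$items_per_rule_count),
    n_test_sets = cfg$n_test_sets,
    set_composition = unlist(cfg$set_composition),
    anchor_composition = unlist(cfg$anchor_composition),
    n_practice = cfg$n_practice,
    master_seed = cfg$master_seed)
  if (is.null(obj$items) || !length(obj$items)) {
    stop_parse("/items", "missing or empty")
  }
  items <- lapply(seq_along(obj$items), function(i) {
    ptr <- sprintf("/items/%d", i - 1L)
    o <- obj$items[[i]]
    for (f in c("item_id", "cells", "rules", "rule_count", "seed")) {
      if (is.null(o[[f]])) stop_parse(paste0(ptr, "/", f), "missing")
    }
    if (length(o$cells) != 9L) {
      stop_parse(paste0(ptr, "/cells"), "expected 9 cells")
    }
    cells <- lapply(o$cells, function(c) as_cell(unlist(c)))
    rules <- lapply(seq_along(o$rules), function(k) {
      r <- o$rules[[k]]
      if (is.null(r$kind) || is.null(r$family)) {
        stop_parse(sprintf("%s/rules/%d", ptr, k - 1L),
                   "kind and family required")
      }
      tryCatch(
        rule_instance(r$kind, r$family, direction = r$direction,
                      required_set = if (!is.null(r$required_set)) {
                        unlist(r$required_set)
                      }),
        error = function(e) stop_parse(sprintf("%s/rules/%d", ptr, k - 1L),
                                       conditionMessage(e)))
    })
    if (length(rules) != o$rule_count) {
      stop_parse(paste0(ptr, "/rule_count"),
                 "does not match the number of rules")
    }
    structure(list(item_id = o$item_id, cells = cells, rules = rules,
                   rule_count = as.integer(o$rule_count),
                   is_anchor = isTRUE(o$is_anchor),
                   is_practice = isTRUE(o$is_practice),
                   seed = as.integer(o$seed)),
              class = "matrix_item")
  })
  if (revalidate) {
    for (i in seq_along(items)) {
      rep <- validate_item(items[[i]])
      if (!isTRUE(rep$rules_hold) || !isTRUE(rep$unique)) {
        stop_parse(sprintf("/items/%d", i - 1L),
                   sprintf("item '%s' fails validation",
                           items[[i]]$item_id))
      }
    }
  }
  forms <- if (!is.null(obj$forms)) {
    lapply(obj$forms, function(f) {
      list(form_id = f$form_id,
           test_set_item_ids = unlist(f$test_set_item_ids),
           anchor_item_ids = unlist(f$anchor_item_ids),
           practice_item_ids = unlist(f$practice_item_ids),
           presentation_order = unlist(f$presentation_order))
    })
  }
  structure(list(config = config, items = items, forms = forms),
            class = "item_bank")
}

#' Write a response matrix to CSV
#'
#' Wide format: `person_id`, `form_id`, then one 0/1 column per item;
#' missing-by-design cells are empty.
#'
#' @param matrix a `response_matrix`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_responses <- function(matrix, path) {
  stopifnot(inherits(matrix, "response_matrix"))
  df <- as.data.frame(matrix$responses)
  df[] <- lapply(df, function(col) {
    ifelse(is.na(col), "", format(as.integer(col)))
  })
  out <- cbind(person_id = matrix$person_id, form_id = matrix$form_id, df,
               stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a response matrix from CSV
#'
#' Values must be 0, 1, or empty; anything else is a parse error naming the
#' row and column. Persons with no observed responses are excluded at load
#' time and reported via the `excluded` attribute.
#'
#' @param path CSV file path
#' @return a `response_matrix`; attribute `excluded` lists dropped person
#'   ids
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)
  if (!all(c("person_id", "form_id") %in% names(df)[1:2])) {
    stop_parse("/", "first two columns must be person_id, form_id")
  }
  item_cols <- setdiff(names(df), c("person_id", "form_id"))
  resp <- matrix(NA_real_, nrow = nrow(df), ncol = length(item_cols),
                 dimnames = list(NULL, item_cols))
  for (j in seq_along(item_cols)) {
    v <- trimws(df[[item_cols[j]]])
    bad <- which(!(v %in% c("", "0", "1")))
    if (length(bad)) {
      stop_parse(sprintf("/row %d/column %s", bad[1L], item_cols[j]),
                 sprintf("invalid response value '%s'", v[bad[1L]]))
    }
    resp[, j] <- ifelse(v == "", NA_real_, as.numeric(v))
  }
  no_obs <- rowSums(!is.na(resp)) == 0L
  excluded <- df$person_id[no_obs]
  out <- response_matrix(resp[!no_obs, , drop = FALSE],
                         person_id = df$person_id[!no_obs],
                         form_id = df$form_id[!no_obs])
  attr(out, "excluded") <- excluded
  out
}

#' Write / read an item-parameter table
#'
#' CSV with `item_id`, `a`, `b` and any additional columns (standard
#' errors, fit statistics, flags).
#'
#' @param params data.frame
#' @param path file path
#' @return `path` / data.frame
#' @export
write_params <- function(params, path) {
  utils::write.csv(params, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
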