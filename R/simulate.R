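#' Sample person abilities
#'
#' Draws latent abilities from a normal population on the logit scale. The
#' standard-normal default is the 2PL identification convention; mean/sd
#' overrides support emulating range-restricted (preselected) populations.
#'
#' @param n number of persons (>= 1)
#' @param mean,sd population moments (sd > 0)
#' @param seed integer seed
#' @return data.frame with columns `person_id`, `theta`
#' @export
sample_abilities <- function(n, mean = 0, sd = 1, seed = 1L) {
  if (length(n) != 1L || n < 1L) stop_config("n must be a positive count")
  if (!is.numeric(sd) || sd <= 0) stop_config("sd must be positive")
  theta <- with_seed(as.integer(seed), stats::rnorm(n, mean, sd))
  data.frame(person_id = sprintf("p%06d", seq_len(n)), theta = theta,
             stringsAsFactors = FALSE)
}

#' Construct a response-matrix object
#'
#' @param responses persons x items matrix of 0/1/NA (NA = not
#'   administered / missing by design); must have column names (item ids)
#' @param person_id character vector of person ids (rownames used if NULL)
#' @param form_id character vector: each person's form
#' @return object of class `response_matrix`
#' @export
response_matrix <- function(responses, person_id = NULL, form_id = NULL) {
  responses <- as.matrix(responses)
  if (is.null(colnames(responses))) {
    stop_config("responses must have item ids as column names")
  }
  vals <- responses[!is.na(responses)]
  if (length(vals) && !all(vals %in% c(0, 1))) {
    stop_config("responses must be 0, 1, or missing")
  }
  if (is.null(person_id)) {
    person_id <- rownames(responses) %||% sprintf("p%06d",
                                                  seq_len(nrow(responses)))
  }
  if (is.null(form_id)) form_id <- rep("form_01", nrow(responses))
  rownames(responses) <- person_id
  structure(list(responses = responses, person_id = person_id,
                 form_id = as.character(form_id)),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf(
    "<response_matrix: %d persons x %d items, %d forms, %.1f%% observed>\n",
    nrow(x$responses), ncol(x$responses), length(unique(x$form_id)),
    100 * mean(!is.na(x$responses))))
  invisible(x)
}

#' Simulate construction-based responses under the 2PL model
#'
#' Each person is assigned to one form (round-robin by default, matching an
#' even allocation across test sets); the scored items of that form are
#' answered with success probability given by the 2PL response function at
#' the person's ability. Items not on the person's form are missing by
#' design.
#'
#' @param forms list of forms (as produced by [split_and_anchor()]), or
#'   `NULL` for a complete single-form design over all items in
#'   `item_params`
#' @param item_params data.frame with columns `item_id`, `a`, `b`
#' @param abilities data.frame with columns `person_id`, `theta` (see
#'   [sample_abilities()])
#' @param seed integer seed
#' @param form_assignment optional integer vector of form indices per
#'   person; defaults to round-robin
#' @return a [response_matrix()]
#' @export
simulate_responses <- function(forms, item_params, abilities, seed = 1L,
                               form_assignment = NULL) {
  stopifnot(is.data.frame(item_params),
            all(c("item_id", "a", "b") %in% names(item_params)))
  if (is.null(forms)) {
    forms <- list(list(form_id = "form_01",
                       test_set_item_ids = item_params$item_id,
                       anchor_item_ids = character(0)))
  }
  form_items <- lapply(forms, function(f) {
    c(f$test_set_item_ids, f$anchor_item_ids)
  })
  all_items <- unique(unlist(form_items))
  missing_par <- setdiff(all_items, item_params$item_id)
  if (length(missing_par)) {
    stop_config(paste("no parameters for administered item(s):",
                      paste(missing_par, collapse = ", ")))
  }
  n <- nrow(abilities)
  if (is.null(form_assignment)) {
    form_assignment <- ((seq_len(n) - 1L) %% length(forms)) + 1L
  }
  stopifnot(length(form_assignment) == n)
  resp <- matrix(NA_real_, nrow = n, ncol = length(all_items),
                 dimnames = list(abilities$person_id, all_items))
  with_seed(as.integer(seed), {
    for (f in seq_along(forms)) {
      rows <- which(form_assignment == f)
      if (!length(rows)) next
      items <- form_items[[f]]
      pars <- item_params[match(items, item_params$item_id), ]
      p <- probability_correct(pars, abilities$theta[rows])
      u <- matrix(stats::runif(length(rows) * length(items)),
                  nrow = length(rows))
      resp[rows, items] <- (u < p) + 0
    }
  })
  response_matrix(resp, person_id = abilities$person_id,
                  form_id = vapply(forms, `[[`, character(1),
                                   "form_id")[form_assignment])
}

#' Inject item misfit into a response matrix
#'
#' Deliberately corrupts one item's column to exercise the misfit
#' diagnostics: `"random_responder"` replaces the observed responses with
#' fair coin flips (responses carry no information about ability);
#' `"reversed"` flips every observed response.
#'
#' @param matrix a `response_matrix`
#' @param item_id column to corrupt
#' @param mode `"random_responder"` or `"reversed"`
#' @param seed integer seed (used by `random_responder`)
#' @return the modified `response_matrix`; all other cells untouched
#' @export
inject_misfit <- function(matrix, item_id,
                          mode = c("random_responder", "reversed"),
                          seed = 1L) {
  stopifnot(inherits(matrix, "response_matrix"))
  if (length(mode) != 1L || !mode %in% c("random_responder", "reversed")) {
    stop_config("unknown misfit mode")
  }
  if (!item_id %in% colnames(matrix$responses)) {
    stop_config(sprintf("item '%s' not present in the matrix", item_id))
  }
  col <- matrix$responses[, item_id]
  obs <- !is.na(col)
  if (mode == "random_responder") {
    col[obs] <- with_seed(as.integer(seed),
                          stats::rbinom(sum(obs), 1L, 0.5))
  } else {
    col[obs] <- 1 - col[obs]
  }
  matrix$responses[, item_id] <- col
  matrix
}
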