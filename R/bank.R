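#' Bank construction configuration
#'
#' Defaults reproduce the published design: 220 unique items distributed
#' over rule counts as 20/50/80/50/20 (a roughly normal distribution of
#' complexity), split into 10 test sets of 22 items (2/5/8/5/2 per rule
#' count), with a common block of 6 anchor items (one each at rule counts
#' 1, 2, 4, 5 and two at rule count 3) attached to every set, plus two
#' unscored practice items.
#'
#' `rule_usage_targets` optionally pins, per rule count, how many items use
#' each rule kind (a matrix with rule-count rows and columns ADD, SUB, DIS,
#' INT, ROT, COM). The default for the full-size design reproduces the
#' published kind-usage marginals exactly; pass `NULL` for uniform sampling.
#'
#' @param items_per_rule_count named integer vector: items per rule count
#' @param n_test_sets number of test sets (forms)
#' @param set_composition named integer vector: per-form unique items per
#'   rule count
#' @param anchor_composition named integer vector: anchors per rule count
#' @param n_practice number of practice items (unscored)
#' @param master_seed integer master seed; all generation randomness derives
#'   from it
#' @param rule_usage_targets optional kind-usage matrix (see Details)
#' @return object of class `bank_config`
#' @examples
#' cfg <- bank_config(master_seed = 42)
#' sum(cfg$items_per_rule_count)  # 220
#' @export
bank_config <- function(items_per_rule_count = c(`1` = 20L, `2` = 50L,
                                                 `3` = 80L, `4` = 50L,
                                                 `5` = 20L),
                        n_test_sets = 10L,
                        set_composition = c(`1` = 2L, `2` = 5L, `3` = 8L,
                                            `4` = 5L, `5` = 2L),
                        anchor_composition = c(`1` = 1L, `2` = 1L, `3` = 2L,
                                               `4` = 1L, `5` = 1L),
                        n_practice = 2L,
                        master_seed = 1L,
                        rule_usage_targets = default_usage_targets(
                          items_per_rule_count)) {
  rc <- as.integer(names(items_per_rule_count))
  if (any(is.na(rc)) || any(rc < 1L)) {
    stop_config("items_per_rule_count must be named by rule count")
  }
  if (any(rc > N_FAMILIES)) {
    stop_config(sprintf(
      "rule count %d is infeasible: only %d disjoint element families exist",
      max(rc), N_FAMILIES))
  }
  if (!setequal(names(items_per_rule_count), names(set_composition))) {
    stop_config("set_composition must cover the same rule counts")
  }
  set_composition <- set_composition[names(items_per_rule_count)]
  if (sum(items_per_rule_count) != n_test_sets * sum(set_composition)) {
    stop_config("total items must equal n_test_sets * items per set")
  }
  if (!all(items_per_rule_count == n_test_sets * set_composition)) {
    stop_config(
      "per rule count, bank items must equal n_test_sets * set quota")
  }
  if (!all(as.integer(names(anchor_composition)) %in% 1:N_FAMILIES)) {
    stop_config("anchor rule counts must be between 1 and 5")
  }
  structure(
    list(items_per_rule_count = items_per_rule_count,
         n_test_sets = as.integer(n_test_sets),
         set_composition = set_composition,
         anchor_composition = anchor_composition,
         n_practice = as.integer(n_practice),
         master_seed = as.integer(master_seed),
         rule_usage_targets = rule_usage_targets),
    class = "bank_config"
  )
}

# Published kind-usage counts per rule count (rows) and kind (columns).
# Only defined for the full-size design; scaled configs fall back to NULL
# (uniform kind sampling).
default_usage_targets <- function(items_per_rule_count) {
  full <- identical(unname(as.integer(items_per_rule_count)),
                    c(20L, 50L, 80L, 50L, 20L)) &&
    identical(names(items_per_rule_count), as.character(1:5))
  if (!full) return(NULL)
  m <- matrix(c(4, 4, 3, 3, 3, 3,
                20, 16, 16, 16, 16, 16,
                44, 44, 37, 41, 37, 37,
                35, 36, 32, 35, 31, 31,
                17, 17, 17, 17, 16, 16),
              nrow = 5, byrow = TRUE,
              dimnames = list(1:5, RULE_KINDS))
  storage.mode(m) <- "integer"
  m
}

#' Build a validated item bank
#'
#' Generates every unique item, the common anchor block, and the practice
#' items, each with a verified unique solution. Rule-kind combinations per
#' item are drawn by quota sampling against `rule_usage_targets` when
#' supplied (each item takes the kinds with the largest remaining quota,
#' seeded random tie-breaks), so the bank's kind-usage marginals match the
#' targets exactly; otherwise kinds are sampled uniformly without
#' replacement. Scope families are assigned at random. Fully deterministic
#' per `master_seed`.
#'
#' @param config a [bank_config()]
#' @return object of class `item_bank` with fields `config`, `items` (list
#'   of `matrix_item`; anchors and practice flagged), `forms` (NULL until
#'   [split_and_anchor()])
#' @examples
#' cfg <- bank_config(items_per_rule_count = c(`2` = 3L), n_test_sets = 1L,
#'                    set_composition = c(`2` = 3L),
#'                    anchor_composition = c(`2` = 1L), master_seed = 5L)
#' bank <- build_bank(cfg)
#' sum(!vapply(bank$items, `[[`, logical(1), "is_anchor") &
#'     !vapply(bank$items, `[[`, logical(1), "is_practice"))  # 3
#' @export
build_bank <- function(config) {
  stopifnot(inherits(config, "bank_config"))
  seed <- config$master_seed
  items <- list()
  idx <- 0L
  for (k_chr in names(config$items_per_rule_count)) {
    k <- as.integer(k_chr)
    n_k <- config$items_per_rule_count[[k_chr]]
    targets <- if (!is.null(config$rule_usage_targets) &&
                   k_chr %in% rownames(config$rule_usage_targets)) {
      config$rule_usage_targets[k_chr, ]
    } else NULL
    combos <- with_seed(derive_seed(seed, 1000L + k),
                        sample_kind_combos(n_k, k, targets))
    for (i in seq_len(n_k)) {
      idx <- idx + 1L
      item_seed <- derive_seed(seed, 10000L + idx)
      rules <- with_seed(derive_seed(seed, 20000L + idx),
                         make_rules(combos[[i]]))
      items[[idx]] <- compose_item(rules, seed = item_seed,
                                   item_id = sprintf("u%d_%02d", k, i))
    }
  }
  anchor_counts <- rep(as.integer(names(config$anchor_composition)),
                       config$anchor_composition)
  for (j in seq_along(anchor_counts)) {
    idx <- idx + 1L
    k <- anchor_counts[j]
    kinds <- with_seed(derive_seed(seed, 30000L + j),
                       resample(RULE_KINDS, k))
    rules <- with_seed(derive_seed(seed, 31000L + j), make_rules(kinds))
    items[[idx]] <- compose_item(rules, seed = derive_seed(seed, 32000L + j),
                                 item_id = sprintf("a%d", j),
                                 is_anchor = TRUE)
  }
  practice_kinds <- c("ADD", "ROT")
  for (j in seq_len(config$n_practice)) {
    idx <- idx + 1L
    kind <- practice_kinds[(j - 1L) %% length(practice_kinds) + 1L]
    rules <- with_seed(derive_seed(seed, 40000L + j), make_rules(kind))
    items[[idx]] <- compose_item(rules, seed = derive_seed(seed, 41000L + j),
                                 item_id = sprintf("p%d", j),
                                 is_practice = TRUE)
  }
  structure(list(config = config, items = items, forms = NULL),
            class = "item_bank")
}

# k distinct rule kinds for each of n items, honouring per-kind quotas when
# given. Greedy largest-remaining-quota with random tie-breaks exhausts a
# feasible quota vector exactly.
sample_kind_combos <- function(n, k, targets = NULL) {
  if (is.null(targets)) {
    return(lapply(seq_len(n), function(i) resample(RULE_KINDS, k)))
  }
  quota <- as.integer(targets[RULE_KINDS])
  if (sum(quota) != n * k) {
    stop_config("rule usage targets are inconsistent with the item count")
  }
  combos <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(-quota, sample.int(length(quota)))
    pick <- ord[seq_len(k)]
    if (any(quota[pick] <= 0L)) {
      stop_config("rule usage targets are infeasible")
    }
    quota[pick] <- quota[pick] - 1L
    combos[[i]] <- RULE_KINDS[sort(pick)]
  }
  if (any(quota != 0L)) stop_config("rule usage targets are infeasible")
  combos
}

# Instantiate rule objects for a kind combination: random disjoint families,
# random rotation direction, random required set of size 3-4 for COM.
make_rules <- function(kinds) {
  fams <- resample(0:(N_FAMILIES - 1L), length(kinds))
  lapply(seq_along(kinds), function(i) {
    kind <- kinds[i]
    fam <- fams[i]
    if (kind == "ROT") {
      rule_instance(kind, fam, direction = resample(c("CW", "CCW"), 1L))
    } else if (kind == "COM") {
      size <- resample(3:4, 1L)
      rule_instance(kind, fam,
                    required_set = random_subset(family_elements(fam),
                                                 min_size = size,
                                                 max_size = size))
    } else {
      rule_instance(kind, fam)
    }
  })
}

# Ordinal slots of the six anchors in the 28-item presentation order;
# interleaved to spread them across the session.
ANCHOR_POSITIONS <- c(5L, 9L, 13L, 17L, 21L, 25L)

# Fixed slots when the form is long enough (the full design), otherwise
# evenly spaced distinct slots for scaled-down configurations.
anchor_slots <- function(n_total, n_anchor) {
  if (n_anchor == 0L) return(integer(0))
  fixed <- ANCHOR_POSITIONS[seq_len(min(n_anchor, length(ANCHOR_POSITIONS)))]
  if (n_anchor <= length(ANCHOR_POSITIONS) && max(fixed) <= n_total) {
    return(fixed)
  }
  pos <- unique(floor(seq(2, n_total, length.out = n_anchor)))
  if (length(pos) < n_anchor) pos <- seq_len(n_anchor)
  as.integer(pos)
}

#' Split the bank into anchored test forms
#'
#' Assigns every unique item to exactly one of the test sets by seeded
#' stratified (per rule count) randomisation, attaches the identical anchor
#' block and the practice items to every form, and fixes a presentation
#' order with anchors interleaved at ordinal positions 5, 9, 13, 17, 21, 25.
#'
#' @param bank an `item_bank` from [build_bank()]
#' @return the bank with `forms` filled: each form has `form_id`,
#'   `test_set_item_ids`, `anchor_item_ids`, `practice_item_ids`, and
#'   `presentation_order` (scored items only)
#' @export
split_and_anchor <- function(bank) {
  stopifnot(inherits(bank, "item_bank"))
  config <- bank$config
  seed <- config$master_seed
  is_anchor <- vapply(bank$items, `[[`, logical(1), "is_anchor")
  is_practice <- vapply(bank$items, `[[`, logical(1), "is_practice")
  unique_items <- bank$items[!is_anchor & !is_practice]
  anchor_ids <- vapply(bank$items[is_anchor], `[[`, character(1), "item_id")
  practice_ids <- vapply(bank$items[is_practice], `[[`, character(1),
                         "item_id")
  n_forms <- config$n_test_sets
  per_form <- rep(list(character(0)), n_forms)
  for (k_chr in names(config$set_composition)) {
    k <- as.integer(k_chr)
    quota <- config$set_composition[[k_chr]]
    ids <- vapply(
      unique_items[vapply(unique_items, `[[`, integer(1),
                          "rule_count") == k],
      `[[`, character(1), "item_id")
    ids <- sort(ids)  # assignment depends on the seed, not input order
    if (length(ids) != quota * n_forms) {
      stop_config(sprintf("stratum exhaustion at rule count %d", k))
    }
    shuffled <- with_seed(derive_seed(seed, 50000L + k), resample(ids))
    for (f in seq_len(n_forms)) {
      take <- shuffled[((f - 1L) * quota + 1L):(f * quota)]
      per_form[[f]] <- c(per_form[[f]], take)
    }
  }
  forms <- lapply(seq_len(n_forms), function(f) {
    uniq <- with_seed(derive_seed(seed, 60000L + f), resample(per_form[[f]]))
    order_ids <- character(length(uniq) + length(anchor_ids))
    apos <- anchor_slots(length(order_ids), length(anchor_ids))
    order_ids[apos] <- anchor_ids
    order_ids[-apos] <- uniq
    list(form_id = sprintf("form_%02d", f),
         test_set_item_ids = per_form[[f]],
         anchor_item_ids = anchor_ids,
         practice_item_ids = practice_ids,
         presentation_order = order_ids)
  })
  bank$forms <- forms
  bank
}

#' @export
print.item_bank <- function(x, ...) {
  is_anchor <- vapply(x$items, `[[`, logical(1), "is_anchor")
  is_practice <- vapply(x$items, `[[`, logical(1), "is_practice")
  cat(sprintf(
    "<item_bank: %d unique items, %d anchors, %d practice, %s forms>\n",
    sum(!is_anchor & !is_practice), sum(is_anchor), sum(is_practice),
    if (is.null(x$forms)) "no" else length(x$forms)))
  invisible(x)
}

#' Look up an item by id
#' @param bank an `item_bank`
#' @param item_id id string
#' @return the `matrix_item`
#' @export
bank_item <- function(bank, item_id) {
  ids <- vapply(bank$items, `[[`, character(1), "item_id")
  i <- match(item_id, ids)
  if (is.na(i)) stop_config(sprintf("no item with id '%s'", item_id))
  bank$items[[i]]
}

#' Per-item descriptor table
#'
#' One row per banked item with its rule count, a 0/1 indicator per rule
#' kind, and flags — the design matrix for the difficulty regression.
#'
#' @param bank an `item_bank`
#' @return data.frame with columns `item_id`, `rule_count`, `ADD` ... `COM`,
#'   `is_anchor`, `is_practice`
#' @export
bank_item_table <- function(bank) {
  rows <- lapply(bank$items, function(it) {
    kinds <- vapply(it$rules, `[[`, character(1), "rule_kind")
    ind <- as.integer(RULE_KINDS %in% kinds)
    names(ind) <- RULE_KINDS
    data.frame(item_id = it$item_id, rule_count = it$rule_count,
               t(ind), is_anchor = it$is_anchor,
               is_practice = it$is_practice, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
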