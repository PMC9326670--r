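#' Link separately calibrated forms through common anchors
#'
#' Each non-reference form g is placed on the reference form's scale by a
#' linear transformation estimated from the anchor items shared by all
#' forms. Mean-sigma: `A_g = sd(b_ref) / sd(b_g)` over anchors,
#' `B_g = mean(b_ref) - A_g * mean(b_g)`. Mean-mean uses the discrimination
#' ratio `A_g = mean(a_g) / mean(a_ref)` instead (so transformed
#' discriminations `a/A` match in mean). The reference form gets the
#' identity (A = 1, B = 0).
#'
#' @param per_form_params named list (by form id) of parameter data.frames
#'   (`item_id`, `a`, `b`)
#' @param anchor_ids character vector of anchor item ids (>= 2 for
#'   mean-sigma)
#' @param method `"mean_sigma"` (default) or `"mean_mean"`
#' @param reference_form form id of the reference scale (default: first)
#' @return data.frame of class `equating_coefficients`: `form_id`, `A`,
#'   `B`, `method`
#' @export
link_forms <- function(per_form_params, anchor_ids,
                       method = c("mean_sigma", "mean_mean"),
                       reference_form = names(per_form_params)[1L]) {
  method <- match.arg(method)
  stopifnot(is.list(per_form_params), !is.null(names(per_form_params)))
  if (!reference_form %in% names(per_form_params)) {
    stop_config("reference_form not among the calibrated forms")
  }
  anchors_of <- function(params, form_id) {
    idx <- match(anchor_ids, params$item_id)
    if (anyNA(idx)) {
      stop_config(sprintf("form %s is missing anchor(s): %s", form_id,
                          paste(anchor_ids[is.na(idx)], collapse = ", ")))
    }
    params[idx, ]
  }
  ref <- anchors_of(per_form_params[[reference_form]], reference_form)
  if (method == "mean_sigma" && length(anchor_ids) < 2L) {
    stop_config("mean_sigma needs at least 2 anchors")
  }
  out <- lapply(names(per_form_params), function(fid) {
    if (fid == reference_form) {
      return(data.frame(form_id = fid, A = 1, B = 0, method = method,
                        stringsAsFactors = FALSE))
    }
    g <- anchors_of(per_form_params[[fid]], fid)
    if (method == "mean_sigma") {
      sg <- stats::sd(g$b)
      if (sg < 1e-12) {
        stop_config(paste("zero anchor-threshold variance under mean_sigma;",
                          "consider method = \"mean_mean\""))
      }
      A <- stats::sd(ref$b) / sg
    } else {
      A <- mean(g$a) / mean(ref$a)
    }
    B <- mean(ref$b) - A * mean(g$b)
    data.frame(form_id = fid, A = A, B = B, method = method,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out),
            class = c("equating_coefficients", "data.frame"))
}

#' Transform item parameters onto the common scale
#'
#' Applies `b* = A b + B`, `a* = a / A`. Anchors are transformed like any
#' other item. The transformation is invertible.
#'
#' @param params data.frame `item_id`, `a`, `b` (plus any extra columns,
#'   preserved; `se_a`/`se_b` are rescaled accordingly)
#' @param coeffs one row of [link_forms()] output, or a list with `A`, `B`
#' @return transformed parameter data.frame
#' @export
transform_params <- function(params, coeffs) {
  if (is.data.frame(coeffs)) {
    if (nrow(coeffs) != 1L) {
      stop_config("coeffs must be a single form's coefficients")
    }
    coeffs <- as.list(coeffs)
  }
  if (is.null(coeffs$A) || is.null(coeffs$B)) {
    stop_config("missing equating coefficients")
  }
  params$b <- coeffs$A * params$b + coeffs$B
  params$a <- params$a / coeffs$A
  if ("se_b" %in% names(params)) params$se_b <- coeffs$A * params$se_b
  if ("se_a" %in% names(params)) params$se_a <- params$se_a / coeffs$A
  params
}

#' Equate a set of per-form calibrations
#'
#' Convenience wrapper: [link_forms()] then [transform_params()] per form,
#' returning one combined table. Optionally recentres the final scale so the
#' mean equated threshold is zero.
#'
#' @inheritParams link_forms
#' @param recenter logical; recentre mean b to 0 across all equated items
#' @return data.frame with `form_id` column plus the transformed parameters;
#'   attribute `"coefficients"` holds the linking coefficients
#' @export
equate_forms <- function(per_form_params, anchor_ids,
                         method = c("mean_sigma", "mean_mean"),
                         reference_form = names(per_form_params)[1L],
                         recenter = FALSE) {
  coeffs <- link_forms(per_form_params, anchor_ids, method, reference_form)
  rows <- lapply(seq_len(nrow(coeffs)), function(i) {
    fid <- coeffs$form_id[i]
    tp <- transform_params(per_form_params[[fid]], coeffs[i, ])
    cbind(form_id = fid, tp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (recenter) {
    shift <- mean(out$b)
    out$b <- out$b - shift
  }
  attr(out, "coefficients") <- coeffs
  out
}

#' Check equating success across forms
#'
#' One-way ANOVA of the equated unique-item parameters across forms, run
#' separately for discrimination and threshold. Successful equating should
#' leave no significant form differences when forms sample items from a
#' common population.
#'
#' @param equated_params data.frame with `form_id`, `a`, `b` (unique items
#'   only; exclude the shared anchors, which are identical by construction
#'   in pooled tables)
#' @return list with elements `a` and `b`, each an `anova_result` from
#'   [oneway_anova()]
#' @export
equating_check <- function(equated_params) {
  stopifnot(all(c("form_id", "a", "b") %in% names(equated_params)))
  if (length(unique(equated_params$form_id)) < 2L) {
    stop_config("need at least two forms")
  }
  list(a = oneway_anova(equated_params$a, equated_params$form_id),
       b = oneway_anova(equated_params$b, equated_params$form_id))
}
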