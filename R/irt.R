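#' 2PL response function
#'
#' Probability of a correct response under the two-parameter logistic model:
#' `P(theta) = 1 / (1 + exp(-a * (theta - b)))`, with discrimination `a > 0`
#' and threshold `b`.
#'
#' @param params data.frame with columns `a`, `b` (one row per item), or a
#'   list with scalar `a`, `b`
#' @param theta numeric vector of abilities
#' @return if `params` has one row, a vector over `theta`; otherwise a
#'   `length(theta)` x `nrow(params)` matrix (items in columns)
#' @examples
#' probability_correct(data.frame(a = 2.09, b = -0.17), 0)  # ~0.588
#' @export
probability_correct <- function(params, theta) {
  a <- params$a
  b <- params$b
  if (any(a <= 0)) stop_config("discrimination a must be positive")
  if (length(a) == 1L) {
    return(stats::plogis(a * (theta - b)))
  }
  p <- stats::plogis(outer(theta, a) - rep(a * b, each = length(theta)))
  colnames(p) <- params$item_id
  p
}

# Fixed quadrature: equally spaced nodes with normal-density weights,
# normalised. Standard, reproducible, adequate for the 2PL.
quadrature_grid <- function(n_quad = 61L, range = c(-6, 6),
                            prior_mean = 0, prior_sd = 1) {
  nodes <- seq(range[1L], range[2L], length.out = n_quad)
  w <- stats::dnorm(nodes, prior_mean, prior_sd)
  list(nodes = nodes, weights = w / sum(w))
}

# Guard against saturation: plogis() rounds to exactly 0/1 for |logit|
# beyond ~37, and 0 * log(0) inside the matrix products would poison the
# E-step with NaN.
clamp_prob <- function(p, eps = 1e-12) {
  pmin(pmax(p, eps), 1 - eps)
}

# Split persons into groups sharing an observed-item pattern (one group per
# form under planned missingness) so the E-step is dense matrix algebra.
pattern_groups <- function(resp) {
  obs_key <- apply(!is.na(resp), 1L, function(z) paste(which(z),
                                                       collapse = ","))
  split(seq_len(nrow(resp)), obs_key)
}

# Posterior over quadrature nodes for a block of persons sharing the same
# observed items. logP/log1mP are K(nodes) x J(items); x is n x J.
# Returns list(post = n x K, loglik = n).
posterior_block <- function(x, logP, log1mP, logw) {
  ll <- tcrossprod(x, logP) + tcrossprod(1 - x, log1mP)
  ll <- sweep(ll, 2L, -logw, "-")  # add log prior weights
  m <- apply(ll, 1L, max)
  el <- exp(ll - m)
  denom <- rowSums(el)
  list(post = el / denom, loglik = m + log(denom))
}

#' Calibrate the 2PL by marginal maximum likelihood (EM)
#'
#' MML-EM with a Normal(0, 1) latent prior on a fixed quadrature grid
#' (61 equally spaced nodes on \[-6, 6\] by default). The E-step computes
#' each person's posterior over the grid given their observed responses
#' (planned missingness is handled by grouping persons on their
#' observed-item pattern); the M-step refits each item by Newton-Raphson on
#' the expected complete-data logistic likelihood (at most 10 inner
#' iterations, step-halving, slope floored at 0.001 to prevent sign flips
#' and capped at 10 so that locally dependent or Guttman-like items cannot
#' drive the slope to infinity).
#' Convergence: maximum absolute parameter change below `tol` or
#' `max_cycles` EM cycles; non-convergence is carried as a status flag,
#' never silent. The marginal log-likelihood is recorded every cycle and is
#' non-decreasing.
#'
#' Items with no observed 0s or no observed 1s have no finite MLE; they are
#' excluded from estimation and reported in `$dropped`.
#'
#' Standard errors come from the expected complete-data information at the
#' final E-step (delta method for `(a, b)`), the usual EM approximation.
#'
#' @param matrix a `response_matrix`
#' @param n_quad,range quadrature grid (see Details)
#' @param tol,max_cycles convergence control
#' @return object of class `fit2pl`: `params` (data.frame `item_id`, `a`,
#'   `b`, `se_a`, `se_b`), `loglik`, `ll_trace`, `converged`, `n_cycles`,
#'   `dropped` (character vector of degenerate item ids)
#' @export
fit_2pl <- function(matrix, n_quad = 61L, range = c(-6, 6), tol = 1e-5,
                    max_cycles = 500L) {
  stopifnot(inherits(matrix, "response_matrix"))
  resp <- matrix$responses
  n_obs1 <- colSums(resp == 1, na.rm = TRUE)
  n_obs0 <- colSums(resp == 0, na.rm = TRUE)
  degenerate <- colnames(resp)[n_obs1 == 0 | n_obs0 == 0]
  if (length(degenerate)) {
    warning(sprintf(
      "degenerate item(s) excluded (all-correct or all-wrong): %s",
      paste(degenerate, collapse = ", ")), call. = FALSE)
    resp <- resp[, setdiff(colnames(resp), degenerate), drop = FALSE]
  }
  if (ncol(resp) < 2L) stop_config("need at least two estimable items")
  J <- ncol(resp)
  grid <- quadrature_grid(n_quad, range)
  K <- length(grid$nodes)
  logw <- log(grid$weights)

  groups <- pattern_groups(resp)
  blocks <- lapply(groups, function(rows) {
    items <- which(!is.na(resp[rows[1L], ]))
    list(rows = rows, items = items,
         x = resp[rows, items, drop = FALSE])
  })

  # start values: a = 1, b from the observed proportion correct
  p0 <- pmin(pmax(colMeans(resp, na.rm = TRUE), 0.02), 0.98)
  a <- rep(1, J)
  b <- -stats::qlogis(p0)
  ll_trace <- numeric(0)
  converged <- FALSE
  cycles <- 0L

  for (cycle in seq_len(max_cycles)) {
    cycles <- cycle
    P <- clamp_prob(probability_correct(
      data.frame(item_id = colnames(resp), a = a, b = b), grid$nodes))
    logP <- log(P); log1mP <- log1p(-P)
    rjk <- matrix(0, nrow = J, ncol = K)
    njk <- matrix(0, nrow = J, ncol = K)
    loglik <- 0
    for (blk in blocks) {
      pb <- posterior_block(blk$x, logP[, blk$items, drop = FALSE],
                            log1mP[, blk$items, drop = FALSE], logw)
      loglik <- loglik + sum(pb$loglik)
      rjk[blk$items, ] <- rjk[blk$items, ] + t(crossprod(pb$post, blk$x))
      njk[blk$items, ] <- njk[blk$items, ] +
        matrix(colSums(pb$post), nrow = length(blk$items), ncol = K,
               byrow = TRUE)
    }
    ll_trace <- c(ll_trace, loglik)

    a_new <- a; b_new <- b
    for (j in seq_len(J)) {
      fit <- mstep_item(grid$nodes, rjk[j, ], njk[j, ], a[j], b[j])
      a_new[j] <- fit$a; b_new[j] <- fit$b
    }
    delta <- max(abs(c(a_new - a, b_new - b)))
    a <- a_new; b <- b_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("EM did not converge in %d cycles", max_cycles),
            call. = FALSE)
  }

  # information-based SEs from the final expected counts
  P <- probability_correct(data.frame(item_id = colnames(resp), a = a,
                                      b = b), grid$nodes)
  se <- vapply(seq_len(J), function(j) {
    item_se(grid$nodes, njk[j, ], P[, j], a[j], b[j])
  }, numeric(2))

  structure(
    list(params = data.frame(item_id = colnames(resp), a = a, b = b,
                             se_a = se[1L, ], se_b = se[2L, ],
                             stringsAsFactors = FALSE),
         loglik = ll_trace[length(ll_trace)],
         ll_trace = ll_trace,
         converged = converged,
         n_cycles = cycles,
         dropped = degenerate),
    class = "fit2pl"
  )
}

#' @export
print.fit2pl <- function(x, ...) {
  cat(sprintf(
    "<2PL fit: %d items, loglik %.2f, %d EM cycles, %sconverged%s>\n",
    nrow(x$params), x$loglik, x$n_cycles, if (x$converged) "" else "NOT ",
    if (length(x$dropped)) sprintf(", %d dropped", length(x$dropped))
    else ""))
  invisible(x)
}

# Newton-Raphson on the intercept/slope parameterisation
# logit P_k = alpha + beta * theta_k, maximising
# sum_k r_k log P_k + (n_k - r_k) log(1 - P_k); step-halving keeps the
# expected complete-data likelihood non-decreasing (EM monotonicity).
mstep_item <- function(nodes, r, n, a0, b0, max_iter = 10L) {
  beta <- min(max(a0, 1e-3), 10)
  alpha <- -a0 * b0
  obj <- function(al, be) {
    eta <- al + be * nodes
    # log(1 + e^eta) without overflow
    lse <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
    sum(r * eta - n * lse)
  }
  f0 <- obj(alpha, beta)
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(alpha + beta * nodes)
    w <- n * p * (1 - p)
    g <- c(sum(r - n * p), sum((r - n * p) * nodes))
    H <- matrix(c(sum(w), sum(w * nodes), sum(w * nodes),
                  sum(w * nodes^2)), 2L)
    step <- tryCatch(solve(H, g), error = function(e) g / (sum(w) + 1e-8))
    for (half in 0:8) {
      al1 <- alpha + step[1L]
      be1 <- min(max(beta + step[2L], 1e-3), 10)
      f1 <- obj(al1, be1)
      if (is.finite(f1) && f1 >= f0 - 1e-12) break
      step <- step / 2
    }
    if (!is.finite(f1) || f1 < f0) break
    moved <- max(abs(c(al1 - alpha, be1 - beta)))
    alpha <- al1; beta <- be1; f0 <- f1
    if (moved < 1e-8) break
  }
  list(a = beta, b = -alpha / beta)
}

# Delta-method SEs for (a, b) from the (alpha, beta) information, where
# logit P = alpha + beta * theta, a = beta, b = -alpha / beta.
item_se <- function(nodes, n, p, a, b) {
  w <- n * p * (1 - p)
  info <- matrix(c(sum(w), sum(w * nodes), sum(w * nodes),
                   sum(w * nodes^2)), 2L)
  V <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 2L, 2L))
  if (anyNA(V)) return(c(NA_real_, NA_real_))
  se_a <- sqrt(V[2L, 2L])
  grad_b <- c(-1 / a, -b / a)  # d b / d(alpha, beta)
  se_b <- sqrt(drop(t(grad_b) %*% V %*% grad_b))
  c(se_a, se_b)
}

#' EAP ability estimation
#'
#' Expected a posteriori abilities under the Normal(0, 1) prior on the same
#' fixed quadrature grid as [fit_2pl()]. Deterministic; perfect and zero
#' score patterns get finite estimates through prior shrinkage. Persons with
#' no observed responses are excluded and reported via the `excluded`
#' attribute (mirroring the load-time exclusion of non-responders).
#'
#' @param params data.frame with `item_id`, `a`, `b` (all observed items
#'   must be covered)
#' @param matrix a `response_matrix`
#' @param n_quad,range quadrature grid
#' @return data.frame `person_id`, `theta_eap`, `posterior_sd`; attribute
#'   `excluded` lists person ids with zero observed responses
#' @export
estimate_abilities <- function(params, matrix, n_quad = 61L,
                               range = c(-6, 6)) {
  stopifnot(inherits(matrix, "response_matrix"))
  resp <- matrix$responses
  missing_par <- setdiff(colnames(resp)[colSums(!is.na(resp)) > 0],
                         params$item_id)
  if (length(missing_par)) {
    stop_config(paste("no calibrated parameters for:",
                      paste(missing_par, collapse = ", ")))
  }
  no_obs <- rowSums(!is.na(resp)) == 0L
  excluded <- matrix$person_id[no_obs]
  resp <- resp[!no_obs, , drop = FALSE]
  person_id <- matrix$person_id[!no_obs]

  grid <- quadrature_grid(n_quad, range)
  logw <- log(grid$weights)
  pars <- params[match(colnames(resp), params$item_id), ]
  P <- clamp_prob(probability_correct(pars, grid$nodes))
  logP <- log(P); log1mP <- log1p(-P)

  eap <- numeric(nrow(resp))
  psd <- numeric(nrow(resp))
  for (blk in split(seq_len(nrow(resp)),
                    apply(!is.na(resp), 1L,
                          function(z) paste(which(z), collapse = ",")))) {
    items <- which(!is.na(resp[blk[1L], ]))
    pb <- posterior_block(resp[blk, items, drop = FALSE],
                          logP[, items, drop = FALSE],
                          log1mP[, items, drop = FALSE], logw)
    m1 <- drop(pb$post %*% grid$nodes)
    m2 <- drop(pb$post %*% grid$nodes^2)
    eap[blk] <- m1
    psd[blk] <- sqrt(pmax(m2 - m1^2, 0))
  }
  out <- data.frame(person_id = person_id, theta_eap = eap,
                    posterior_sd = psd, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Infit/outfit item-fit statistics and the misfit flag
#'
#' Residual-based fit diagnostics. For each item, over its observed
#' persons, with `x` the response, `P` the 2PL probability, and
#' `z = (x - P) / sqrt(P(1-P))`:
#' \itemize{
#'   \item outfit mean square = mean(z^2) (unweighted);
#'   \item infit mean square = sum((x-P)^2) / sum(P(1-P))
#'     (information-weighted);
#'   \item ZSTD via the Wilson-Hilferty cube-root transform of each mean
#'     square with its model variance.
#' }
#' An item is flagged when a mean square falls outside \[0.75, 1.33\] *and*
#' the corresponding |ZSTD| >= 1.96 (alpha = .05): both an aberrant
#' magnitude and a significant standardised statistic are required.
#'
#' Conditioning on ability: the default `"posterior"` integrates every
#' residual moment over each person's ability posterior on the quadrature
#' grid (given `params` and the observed responses), which keeps the mean
#' squares calibrated near 1 for model-consistent data even when `params`
#' are fixed reference (banked) values rather than a fresh calibration.
#' `"eap"` evaluates `P` at the EAP point estimates in `abilities` instead
#' (classical Rasch practice); with fixed reference parameters this
#' understates/overstates variances through shrinkage and false-flags
#' aggressively, so it is not the default.
#'
#' @param params data.frame `item_id`, `a`, `b`
#' @param abilities data.frame from [estimate_abilities()]; defines which
#'   persons enter and, for `conditioning = "eap"`, the point abilities
#' @param matrix a `response_matrix`
#' @param conditioning `"posterior"` (default) or `"eap"`
#' @param n_quad,range quadrature grid for `"posterior"`
#' @return data.frame `item_id`, `infit_msq`, `outfit_msq`, `infit_z`,
#'   `outfit_z`, `flagged`, `degenerate`
#' @export
fit_statistics <- function(params, abilities, matrix,
                           conditioning = c("posterior", "eap"),
                           n_quad = 61L, range = c(-6, 6)) {
  conditioning <- match.arg(conditioning)
  stopifnot(inherits(matrix, "response_matrix"))
  resp <- matrix$responses[match(abilities$person_id, matrix$person_id), ,
                           drop = FALSE]
  items <- colnames(resp)
  pars <- params[match(items, params$item_id), ]
  if (anyNA(pars$a)) {
    stop_config("fit_statistics: parameters missing for some items")
  }
  n_persons <- nrow(resp)
  # per person x item expected moments under the chosen conditioning:
  # EPQ = E[P(1-P)], Esq = E[(x-P)^2], Ez2 = E[z^2], C4 = E[PQ(P^3+Q^3)]
  if (conditioning == "eap") {
    P <- clamp_prob(probability_correct(pars, abilities$theta_eap))
    Q <- 1 - P
    EPQ <- P * Q
    Esq <- (resp - P)^2
    Ez2 <- Esq / EPQ
    C4 <- EPQ * (Q^3 + P^3)
  } else {
    grid <- quadrature_grid(n_quad, range)
    logw <- log(grid$weights)
    P <- clamp_prob(probability_correct(pars, grid$nodes))  # K x J
    logP <- log(P); log1mP <- log1p(-P)
    Q <- 1 - P
    EP <- EP2 <- EQoP <- EPoQ <- EC4 <- matrix(NA_real_, n_persons,
                                               length(items))
    key <- apply(!is.na(resp), 1L, function(z) paste(which(z),
                                                     collapse = ","))
    for (blk in split(seq_len(n_persons), key)) {
      obs_items <- which(!is.na(resp[blk[1L], ]))
      if (!length(obs_items)) next
      pb <- posterior_block(resp[blk, obs_items, drop = FALSE],
                            logP[, obs_items, drop = FALSE],
                            log1mP[, obs_items, drop = FALSE], logw)
      EP[blk, obs_items] <- pb$post %*% P[, obs_items, drop = FALSE]
      EP2[blk, obs_items] <- pb$post %*% P[, obs_items, drop = FALSE]^2
      EQoP[blk, obs_items] <- pb$post %*%
        (Q / P)[, obs_items, drop = FALSE]
      EPoQ[blk, obs_items] <- pb$post %*%
        (P / Q)[, obs_items, drop = FALSE]
      EC4[blk, obs_items] <- pb$post %*%
        (P * Q * (Q^3 + P^3))[, obs_items, drop = FALSE]
    }
    EPQ <- EP - EP2
    Esq <- resp * (1 - 2 * EP + EP2) + (1 - resp) * EP2
    Ez2 <- resp * EQoP + (1 - resp) * EPoQ
    C4 <- EC4
  }
  out <- data.frame(item_id = items, infit_msq = NA_real_,
                    outfit_msq = NA_real_, infit_z = NA_real_,
                    outfit_z = NA_real_, flagged = FALSE,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(items)) {
    x <- resp[, j]
    obs <- !is.na(x)
    if (!sum(obs) || stats::var(x[obs]) == 0) {
      out$degenerate[j] <- TRUE
      next
    }
    n <- sum(obs)
    w <- EPQ[obs, j]
    c4 <- C4[obs, j]
    out$outfit_msq[j] <- mean(Ez2[obs, j])
    out$infit_msq[j] <- sum(Esq[obs, j]) / sum(w)
    q2_out <- sum(c4 / w^2) / n^2 - 1 / n
    q2_in <- sum(c4 - w^2) / sum(w)^2
    out$outfit_z[j] <- wilson_hilferty_z(out$outfit_msq[j], q2_out)
    out$infit_z[j] <- wilson_hilferty_z(out$infit_msq[j], q2_in)
  }
  out$flagged <- misfit_flag(out$infit_msq, out$outfit_msq, out$infit_z,
                             out$outfit_z)
  out
}

# ZSTD: cube-root (Wilson-Hilferty) standardisation of a mean square with
# model variance q2.
wilson_hilferty_z <- function(msq, q2) {
  if (!is.finite(msq) || !is.finite(q2) || q2 <= 0) return(NA_real_)
  q <- sqrt(q2)
  (msq^(1 / 3) - 1) * (3 / q) + q / 3
}

#' Misfit cutoff rule
#'
#' An item is flagged when infit or outfit falls below 0.75 or above 1.33
#' *and* the corresponding standardised statistic is significant
#' (|ZSTD| >= 1.96). Both conditions are required.
#'
#' @param infit_msq,outfit_msq,infit_z,outfit_z numeric vectors
#' @param lower,upper mean-square cutoffs
#' @param z_crit significance cutoff for |ZSTD|
#' @return logical vector
#' @export
misfit_flag <- function(infit_msq, outfit_msq, infit_z, outfit_z,
                        lower = 0.75, upper = 1.33, z_crit = 1.96) {
  bad_in <- (infit_msq < lower | infit_msq > upper) &
    !is.na(infit_z) & abs(infit_z) >= z_crit
  bad_out <- (outfit_msq < lower | outfit_msq > upper) &
    !is.na(outfit_z) & abs(outfit_z) >= z_crit
  out <- bad_in | bad_out
  out[is.na(out)] <- FALSE
  out
}
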