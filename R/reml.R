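# Restricted likelihood machinery. Everything works on the record-space
# covariance V = sum_k sigma2_k M_k + sigma2_e I with M_k = Z_k C_k Z_k'
# prebuilt by the model frame. V is positive definite whenever sigma2_e > 0,
# even for singular (e.g. regional) GRMs, so no GRM is ever inverted.

# One evaluation: loglik plus the pieces every REML update needs.
.reml_eval <- function(frame, theta, need_derivs = TRUE) {
  n <- frame$n
  p <- frame$p
  K <- length(frame$M)
  V <- diag(rep(theta[K + 1], n))
  for (k in seq_len(K)) V <- V + theta[k] * frame$M[[k]]
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) {
    abort("V is numerically singular at the supplied variances",
          class = "rhmscan_reml_error")
  }
  Vi <- chol2inv(cV)
  ViX <- Vi %*% frame$X
  XtViX <- crossprod(frame$X, ViX)
  cX <- chol(XtViX)
  U <- forwardsolve(t(cX), t(ViX))               # p x n
  P <- Vi - crossprod(U)                         # Vi - ViX (X'ViX)^-1 X'Vi
  Py <- drop(P %*% frame$y)
  ll <- -0.5 * ((n - p) * log(2 * pi) +
                  2 * sum(log(diag(cV))) +
                  2 * sum(log(diag(cX))) +
                  sum(frame$y * Py))
  out <- list(ll = ll, theta = theta)
  if (need_derivs) {
    Tm <- matrix(0, n, K + 1)
    trPM <- numeric(K + 1)
    for (k in seq_len(K)) {
      Tm[, k] <- frame$M[[k]] %*% Py
      trPM[k] <- sum(P * frame$M[[k]])
    }
    Tm[, K + 1] <- Py
    trPM[K + 1] <- sum(diag(P))
    yPMPy <- drop(crossprod(Py, Tm))
    out$score <- 0.5 * (yPMPy - trPM)
    PT <- P %*% Tm
    out$AI <- 0.5 * crossprod(Tm, PT)
    out$yPMPy <- yPMPy
    out$trPM <- trPM
  }
  out
}

#' Restricted log-likelihood
#'
#' REML log-likelihood of the model frame at fixed variance components,
#' `-1/2 [ (n-p) log 2pi + log|V| + log|X'V^-1 X| + y'Py ]`. The constant
#' convention is fixed, so differences between nested fits on the same records
#' and fixed effects are exact.
#'
#' @param frame an `rhm_model_frame`.
#' @param components named (or positionally ordered) variances: one per random
#'   term in the frame, then the residual `e`. All must be `>= 0` with
#'   `e > 0`.
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(frame, components) {
  stopifnot(inherits(frame, "rhm_model_frame"))
  theta <- .order_components(frame, components)
  if (any(theta < 0) || theta[length(theta)] <= 0 || !any(theta > 0)) {
    abort("variances must be >= 0 with a positive residual",
          class = "rhmscan_reml_error")
  }
  .reml_eval(frame, theta, need_derivs = FALSE)$ll
}

.component_names <- function(frame) c(names(frame$M), "e")

.order_components <- function(frame, components) {
  nm <- .component_names(frame)
  if (!is.null(names(components)) && all(nzchar(names(components)))) {
    missing_c <- setdiff(nm, names(components))
    if (length(missing_c) > 0) {
      abort(paste0("components missing: ", paste(missing_c, collapse = ", ")))
    }
    as.numeric(components[nm])
  } else {
    if (length(components) != length(nm)) {
      abort(sprintf("expected %d components (%s)", length(nm),
                    paste(nm, collapse = ", ")))
    }
    as.numeric(components)
  }
}

#' Fit the model by average-information REML
#'
#' Maximizes the restricted log-likelihood over the non-negative orthant.
#' Each iteration proposes an average-information (AI) Newton step; if the
#' step leaves the feasible region or decreases the log-likelihood it is
#' halved repeatedly, and if that fails an expectation-maximization update
#' (guaranteed uphill, slower) is taken instead. Components that keep
#' drifting to zero are pinned at the boundary `1e-8 * var(y)` and stay in the
#' model; degrees-of-freedom accounting for boundary nulls is left to the
#' mixture LRT. Convergence is declared when the log-likelihood improves by
#' less than `tol`.
#'
#' @param frame an `rhm_model_frame`.
#' @param init optional initial variances (named like the components);
#'   defaults to an equal split of `var(y)`.
#' @param max_iter iteration cap; non-convergence flags the result rather
#'   than raising.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param verbose print the iteration trace.
#' @return An `rhm_fit`: list with `components` (named variances including
#'   residual), `var_p` (their sum), `loglik`, `converged`, `iterations`,
#'   `gradient_norm`, `AI` (average-information matrix at the optimum), `SE`
#'   (component standard errors), `boundary` (logical per component), `frame`
#'   metadata (`trait`, `n`, `p`, term names).
#' @export
fit_reml <- function(frame, init = NULL, max_iter = 200, tol = 1e-6,
                     verbose = FALSE) {
  stopifnot(inherits(frame, "rhm_model_frame"))
  nm <- .component_names(frame)
  K1 <- length(nm)
  vy <- var(frame$y)
  if (vy <= 0) abort("response has zero variance", class = "rhmscan_reml_error")
  lb <- 1e-8 * vy
  theta <- if (is.null(init)) rep(vy / K1, K1) else pmax(.order_components(frame, init), lb)

  q_levels <- c(vapply(frame$terms, function(t) as.numeric(t$n_levels), numeric(1)),
                frame$n)
  ev <- .reml_eval(frame, theta)
  ll0_init <- ev$ll
  converged <- FALSE
  iter <- 0

  while (iter < max_iter) {
    iter <- iter + 1
    # projected AI step: components sitting on the boundary whose gradient
    # points outward are frozen there this iteration; they re-enter as soon
    # as their gradient turns positive
    at_lb <- theta <= lb * (1 + 1e-8)
    free <- !(at_lb & ev$score <= 0)
    free[K1] <- TRUE                      # residual always free
    cand <- NULL
    if (any(free)) {
      Af <- ev$AI[free, free, drop = FALSE]
      step <- tryCatch(solve(Af + diag(1e-10 * max(diag(Af)), sum(free)),
                             ev$score[free]),
                       error = function(e) NULL)
      if (!is.null(step)) {
        fac <- 1
        for (half in 1:12) {
          prop <- theta
          prop[free] <- pmax(theta[free] + fac * step, lb)
          evp <- tryCatch(.reml_eval(frame, prop, need_derivs = FALSE),
                          error = function(e) NULL)
          if (!is.null(evp) && is.finite(evp$ll) && evp$ll >= ev$ll - 1e-10) {
            cand <- prop
            break
          }
          fac <- fac / 2
        }
      }
    }
    if (is.null(cand)) {
      # EM fallback on the free set: sigma + sigma^2/q * (y'PMPy - tr(PM));
      # guaranteed uphill but slow, used only when the AI step fails
      prop <- theta
      prop[free] <- pmax(theta[free] + theta[free]^2 / q_levels[free] *
                           (ev$yPMPy[free] - ev$trPM[free]), lb)
      evp <- tryCatch(.reml_eval(frame, prop, need_derivs = FALSE),
                      error = function(e) NULL)
      if (is.null(evp) || !is.finite(evp$ll) || identical(prop, theta)) break
      cand <- prop
    }
    evc <- .reml_eval(frame, cand)
    delta <- evc$ll - ev$ll
    theta <- cand
    ev <- evc
    if (verbose) {
      message(sprintf("iter %3d  logL %.6f  dlogL %.2e  [%s]",
                      iter, ev$ll, delta,
                      paste(sprintf("%.4g", theta), collapse = ", ")))
    }
    if (abs(delta) < tol) {
      converged <- TRUE
      break
    }
  }

  names(theta) <- nm
  se <- tryCatch(sqrt(diag(solve(ev$AI))), error = function(e) rep(NA_real_, K1))
  structure(list(components = theta,
                 var_p = sum(theta),
                 loglik = ev$ll,
                 loglik_init = ll0_init,
                 converged = converged,
                 iterations = iter,
                 gradient_norm = sqrt(sum(ev$score^2)),
                 AI = ev$AI,
                 SE = setNames(se, nm),
                 boundary = setNames(theta <= lb * (1 + 1e-6), nm),
                 trait = frame$trait,
                 n = frame$n,
                 p = frame$p,
                 term_names = nm),
            class = "rhm_fit")
}

#' @export
print.rhm_fit <- function(x, ...) {
  cat(sprintf("<rhm_fit> trait '%s': logL = %.4f (%s, %d iterations)\n",
              x$trait, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(round(rbind(estimate = x$components, SE = x$SE), 6))
  invisible(x)
}
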