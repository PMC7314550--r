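#' Cox proportional-hazards fit by Newton-Raphson (Efron ties)
#'
#' Maximizes the Efron-tied partial likelihood with Newton-Raphson and
#' step-halving. Standard errors come from the observed information at
#' the optimum.
#' This is the "mortality risk" model: follow-up time with age at
#' assessment entering as an ordinary covariate.
#'
#' @param time positive event/censoring times (follow-up scale).
#' @param event 0/1 event indicators.
#' @param X covariate matrix (or data.frame of numerics), one column per
#'   covariate; must be full rank and contain no constant column.
#' @param max_iter,tol Newton-Raphson controls; convergence is declared
#'   at gradient infinity-norm below `tol * max(1, |loglik|)` (the
#'   attainable gradient norm scales with the magnitude of the summed
#'   likelihood terms).
#' @return object of class `cox_fit`: `coefficients`, `se`, `ci` (95%
#'   Wald), `p` (two-sided Wald), `loglik`, `iterations`, `converged`.
#' @export
fit_cox <- function(time, event, X, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(time)
  stopifnot(nrow(X) == n, length(event) == n, all(time > 0))
  event <- as.integer(event)
  stopifnot(all(event %in% 0:1))
  if (sum(event) == 0) stop("no events in the data")
  p <- ncol(X)
  if (qr(X)$rank < p)
    stop("rank-deficient covariate matrix (collinear columns)")
  if (any(apply(X, 2, var) == 0))
    stop("constant covariate: not identifiable in a partial likelihood")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  ## descending-time order: risk sets are prefixes
  ord <- order(-time, -event)
  t_o <- time[ord]; e_o <- event[ord]; X_o <- X[ord, , drop = FALSE]
  blocks <- rle(t_o)
  ends <- cumsum(blocks$lengths)
  starts <- ends - blocks$lengths + 1L

  efron <- function(beta) {
    eta <- drop(X_o %*% beta)
    eta <- eta - mean(eta)            # numerical centering; PL invariant
    w <- exp(eta)
    cs0 <- cumsum(w)
    cs1 <- apply(X_o * w, 2, cumsum)
    cs2 <- array(0, c(n, p, p))
    for (j in seq_len(p)) for (k in j:p) {
      cs <- cumsum(X_o[, j] * X_o[, k] * w)
      cs2[, j, k] <- cs; cs2[, k, j] <- cs
    }
    ll <- 0; gr <- numeric(p); info <- matrix(0, p, p)
    for (b in seq_along(ends)) {
      idx <- starts[b]:ends[b]
      D <- idx[e_o[idx] == 1L]
      d <- length(D)
      if (d == 0) next
      m <- ends[b]
      S0 <- cs0[m]; S1 <- cs1[m, ]; S2 <- cs2[m, , ]
      wD <- w[D]
      S0d <- sum(wD)
      XD <- X_o[D, , drop = FALSE]
      S1d <- colSums(XD * wD)
      S2d <- crossprod(XD, XD * wD)
      ll <- ll + sum(eta[D])
      for (l in seq_len(d) - 1L) {
        f <- l / d
        Z0 <- S0 - f * S0d
        Z1 <- S1 - f * S1d
        Z2 <- S2 - f * S2d
        ll <- ll - log(Z0)
        gr <- gr - Z1 / Z0
        info <- info + Z2 / Z0 - tcrossprod(Z1 / Z0)
      }
      gr <- gr + colSums(XD)
    }
    list(loglik = ll, grad = gr, info = info)
  }

  beta <- numeric(p)
  st <- efron(beta)
  gtol <- tol * max(1, abs(st$loglik))
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    gtol <- tol * max(1, abs(st$loglik))
    if (max(abs(st$grad)) < gtol) { converged <- TRUE; break }
    step <- tryCatch(solve(st$info, st$grad),
                     error = function(e) stop(
                       "singular information matrix; check covariates"))
    halves <- 0
    repeat {
      cand <- beta + step
      st_new <- efron(cand)
      if (is.finite(st_new$loglik) && st_new$loglik >= st$loglik - 1e-12)
        break
      step <- step / 2
      halves <- halves + 1
      if (halves > 30) stop("step-halving failed to improve the ",
                            "partial likelihood")
    }
    beta <- cand; st <- st_new
    if (max(abs(beta)) > 50)
      stop("monotone partial likelihood: a coefficient diverged ",
           "(possible perfect separation)")
  }
  if (!converged && max(abs(st$grad)) < gtol) converged <- TRUE
  if (!converged) warning("Cox fit did not converge in ", max_iter,
                          " iterations")
  ## a coefficient running off to +/-Inf flattens the partial likelihood:
  ## the gradient vanishes but the estimate is meaningless
  x_scale <- apply(X, 2, sd)
  if (any(abs(beta) * x_scale > 10))
    stop("monotone partial likelihood: a coefficient diverged ",
         "(possible perfect separation)")
  vcov <- solve(st$info)
  se <- sqrt(diag(vcov))
  z <- beta / se
  fit <- list(coefficients = setNames(beta, colnames(X)),
              se = setNames(se, colnames(X)),
              ci = cbind(lower = beta - qnorm(0.975) * se,
                         upper = beta + qnorm(0.975) * se),
              p = setNames(2 * pnorm(-abs(z)), colnames(X)),
              vcov = vcov,
              loglik = st$loglik,
              score_norm = max(abs(st$grad)),
              n = n, events = sum(event),
              iterations = iter, converged = converged)
  class(fit) <- "cox_fit"
  fit
}

#' Evaluate the Efron partial log-likelihood at given coefficients
#'
#' Exposed so that independent maximization checks (e.g. grid search) can
#' score candidate coefficient vectors.
#' @inheritParams fit_cox
#' @param beta coefficient vector.
#' @return scalar log partial likelihood.
#' @export
cox_partial_loglik <- function(beta, time, event, X) {
  X <- as.matrix(X)
  ord <- order(-time)
  t_o <- time[ord]; e_o <- as.integer(event)[ord]
  X_o <- X[ord, , drop = FALSE]
  eta <- drop(X_o %*% beta)
  w <- exp(eta)
  cs0 <- cumsum(w)
  blocks <- rle(t_o); ends <- cumsum(blocks$lengths)
  starts <- ends - blocks$lengths + 1L
  ll <- 0
  for (b in seq_along(ends)) {
    idx <- starts[b]:ends[b]
    D <- idx[e_o[idx] == 1L]
    d <- length(D)
    if (d == 0) next
    S0 <- cs0[ends[b]]; S0d <- sum(w[D])
    ll <- ll + sum(eta[D]) -
      sum(log(S0 - (seq_len(d) - 1L) / d * S0d))
  }
  ll
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (Efron ties): n = %d, events = %d\n",
              x$n, x$events))
  tab <- data.frame(coef = x$coefficients, se = x$se,
                    ci_lower = x$ci[, "lower"], ci_upper = x$ci[, "upper"],
                    p = x$p)
  print(round(tab, 4))
  cat(sprintf("log partial likelihood %.4f; %d iteration(s); %s\n",
              x$loglik, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
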