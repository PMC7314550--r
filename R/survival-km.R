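#' Kaplan-Meier product-limit estimator
#'
#' Right-censored product-limit survival estimates, optionally per group.
#'
#' @param time positive event/censoring times.
#' @param event 0/1 event indicators.
#' @param group optional group labels; curves are computed per group.
#' @return object of class `km_curve`: a named list of data.frames with
#'   columns `time` (distinct event times), `n_risk`, `n_event`,
#'   `survival` (non-increasing, in `[0, 1]`).
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.character(group)
  stopifnot(length(time) == length(event), length(group) == length(time))
  curves <- lapply(split(seq_along(time), group), function(idx) {
    if (length(idx) == 0) stop("empty group")
    tt <- time[idx]; ee <- as.integer(event[idx])
    et <- sort(unique(tt[ee == 1]))
    if (length(et) == 0)
      return(data.frame(time = numeric(0), n_risk = integer(0),
                        n_event = integer(0), survival = numeric(0)))
    n_risk <- vapply(et, function(t) sum(tt >= t), integer(1))
    n_event <- vapply(et, function(t) sum(tt == t & ee == 1), integer(1))
    data.frame(time = et, n_risk = n_risk, n_event = n_event,
               survival = cumprod(1 - n_event / n_risk))
  })
  structure(curves, class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  for (g in names(x)) {
    cat(sprintf("Kaplan-Meier curve [%s]: %d event time(s)\n",
                g, nrow(x[[g]])))
    print(head(x[[g]], 10))
  }
  invisible(x)
}

#' Log-rank test for equality of survival curves
#'
#' The standard `sum(O - E)` statistic with hypergeometric variance;
#' for `K` groups the chi-square statistic uses the full `(K-1) x (K-1)`
#' covariance of the observed-minus-expected vector, with `K - 1`
#' degrees of freedom.
#'
#' @param time positive event/censoring times.
#' @param event 0/1 event indicators.
#' @param group group labels (at least two non-empty groups, at least one
#'   event overall).
#' @return object of class `logrank_result`: `statistic`, `df`, `p`,
#'   `observed` and `expected` per group.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(as.character(group))
  event <- as.integer(event)
  stopifnot(length(time) == length(event), length(group) == length(time))
  if (any(table(group) == 0) || nlevels(group) < 2)
    stop("need at least two non-empty groups")
  if (sum(event) == 0) stop("no events")
  K <- nlevels(group)
  et <- sort(unique(time[event == 1]))
  O <- E <- setNames(numeric(K), levels(group))
  V <- matrix(0, K, K, dimnames = list(levels(group), levels(group)))
  for (t in et) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    d_j <- sum(event == 1 & time == t)
    n_kj <- tabulate(group[at_risk], nbins = K)
    d_kj <- tabulate(group[event == 1 & time == t], nbins = K)
    O <- O + d_kj
    E <- E + d_j * n_kj / n_j
    if (n_j > 1) {
      frac <- n_kj / n_j
      vmat <- (diag(frac, K) - tcrossprod(frac)) *
        d_j * (n_j - d_j) / (n_j - 1)
      V <- V + vmat
    }
  }
  u <- (O - E)[-K]
  Vsub <- V[-K, -K, drop = FALSE]
  stat <- tryCatch(drop(t(u) %*% solve(Vsub, u)),
                   error = function(e) 0)
  res <- list(statistic = max(stat, 0), df = K - 1L,
              p = pchisq(max(stat, 0), K - 1L, lower.tail = FALSE),
              observed = O, expected = E, variance = V)
  class(res) <- "logrank_result"
  res
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f on %d df, p = %.3g\n",
              x$statistic, x$df, x$p))
  print(data.frame(observed = x$observed, expected = round(x$expected, 2)))
  invisible(x)
}

#' Pairwise Kolmogorov-Smirnov balance check on assessment ages
#'
#' Verifies that burden strata are age-balanced: every pair of groups is
#' compared with the two-sample KS test, and the minimum p-value is
#' reported. Strata passing at the 1% level are considered balanced.
#'
#' @param ages numeric vector of ages.
#' @param group group labels (each group needs at least 2 members).
#' @return data.frame of pairwise comparisons (`group1`, `group2`,
#'   `statistic`, `p`) with the minimum p-value in attribute `min_p`.
#' @export
ks_age_balance <- function(ages, group) {
  group <- factor(as.character(group))
  stopifnot(length(ages) == length(group))
  if (nlevels(group) < 2) stop("need at least two groups")
  sizes <- table(group)
  if (any(sizes < 2)) stop("every group needs at least 2 members")
  pairs <- utils::combn(levels(group), 2)
  res <- apply(pairs, 2, function(pr) {
    ks <- suppressWarnings(
      ks.test(ages[group == pr[1]], ages[group == pr[2]]))
    c(statistic = unname(ks$statistic), p = ks$p.value)
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    statistic = res["statistic", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  attr(out, "min_p") <- min(out$p)
  out
}

#' Coefficient table of a fitted hazard model
#'
#' One row per covariate with the columns of the standard reporting
#' layout: `term`, `coef`, `ci_lower`, `ci_upper`, `p`, `n`, `events`.
#'
#' @param fit a `cox_fit` or `gompertz_fit`.
#' @return data.frame.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, c("cox_fit", "gompertz_fit")))
  if (length(fit$coefficients) == 0)
    return(data.frame(term = character(0), coef = numeric(0),
                      ci_lower = numeric(0), ci_upper = numeric(0),
                      p = numeric(0), n = integer(0), events = integer(0)))
  data.frame(term = names(fit$coefficients),
             coef = unname(fit$coefficients),
             ci_lower = unname(fit$ci[, "lower"]),
             ci_upper = unname(fit$ci[, "upper"]),
             p = unname(fit$p),
             n = fit$n, events = fit$events,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sex-stratified hazard-model fits
#'
#' Fits the chosen model separately for each sex with sex dropped from
#' the covariates, mirroring the sex-specific association analysis.
#'
#' @param time,event as in [fit_cox()] / [fit_gompertz_ph()].
#' @param X covariate matrix excluding sex.
#' @param sex vector coded 0 = female, 1 = male.
#' @param model `"cox"` or `"gompertz"`.
#' @param ... passed to the fitter.
#' @return list with `fits` (per-sex fit objects, names `female`/`male`)
#'   and `table` (stacked [coef_table()] rows with a `sex` column).
#' @export
fit_sex_stratified <- function(time, event, X, sex,
                               model = c("cox", "gompertz"), ...) {
  model <- match.arg(model)
  sex <- as.integer(sex)
  stopifnot(all(sex %in% 0:1))
  X <- as.matrix(X)
  fits <- lapply(c(female = 0L, male = 1L), function(s) {
    idx <- which(sex == s)
    if (length(idx) == 0) stop("empty sex stratum")
    if (sum(event[idx]) == 0)
      stop("sex stratum with zero events: cannot fit")
    if (model == "cox")
      fit_cox(time[idx], event[idx], X[idx, , drop = FALSE], ...)
    else
      fit_gompertz_ph(time[idx], event[idx], X[idx, , drop = FALSE], ...)
  })
  tabs <- lapply(names(fits), function(s)
    cbind(sex = s, coef_table(fits[[s]])))
  list(fits = fits, table = do.call(rbind, tabs))
}
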