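# Independent oracles used across the suite. These deliberately use
# naive formulations (explicit loops, direct enumeration) and never call
# the package's own computational paths.

# Efron-tied Cox partial log-likelihood, written as an explicit loop
# over risk sets (one covariate or a matrix).
naive_cox_loglik <- function(beta, time, event, xmat) {
  xmat <- as.matrix(xmat)
  eta <- as.vector(xmat %*% beta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum(exp(eta[R])) - (l / d) * sum(exp(eta[D])))
    }
  }
  ll
}

# Two-stage grid search maximizing the naive partial likelihood
# (single covariate); accurate to ~1e-4.
grid_search_cox <- function(time, event, x) {
  coarse <- seq(-4, 4, by = 0.01)
  ll <- vapply(coarse, naive_cox_loglik, numeric(1),
               time = time, event = event, xmat = x)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-4)
  llf <- vapply(fine, naive_cox_loglik, numeric(1),
                time = time, event = event, xmat = x)
  fine[which.max(llf)]
}

# Gompertz-PH log-likelihood written directly from the hazard integral,
# as a per-subject loop.
naive_gompertz_loglik <- function(h0, gamma, beta, time, event, x) {
  ll <- 0
  for (i in seq_along(time)) {
    lh <- log(h0) + gamma * time[i] + beta * x[i]
    H <- (h0 / gamma) * exp(beta * x[i]) * (exp(gamma * time[i]) - 1)
    ll <- ll + event[i] * lh - H
  }
  ll
}

# Two-sided Fisher exact p-value for a 2x2 table by full enumeration of
# the conditional hypergeometric distribution via lchoose (the sum of
# the probabilities of all tables at most as probable as the observed
# one, with the same relative-error guard as R's convention).
fisher_p_enum <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; N <- m1 + m2
  support <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, support) + lchoose(m2, k - support) - lchoose(N, k)
  p_obs <- logp[support == a]
  sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
}

# Drop dimnames/metadata attributes for bare numeric comparison.
strip_mat <- function(m) matrix(as.integer(m), nrow = nrow(m))

# Brute-force burden counting: double loop over individuals x variants.
brute_force_burden <- function(records, individuals, bins = 1:4) {
  m <- matrix(0L, length(individuals), length(bins),
              dimnames = list(individuals, NULL))
  for (i in seq_along(individuals)) {
    for (v in seq_len(nrow(records))) {
      terms <- strsplit(records$effect[v], "&", fixed = TRUE)[[1]]
      truncating <- any(terms %in% c("stop_gained", "frameshift_variant",
                                     "splice_donor_variant",
                                     "splice_acceptor_variant"))
      if (!truncating || !records$canonical[v]) next
      maf <- records$maf[v]
      bin <- if (maf < 1e-4) 1L else if (maf < 1e-3) 2L else
        if (maf < 1e-2) 3L else 4L
      j <- match(bin, bins)
      if (is.na(j)) next
      if (individuals[i] %in% records$carriers[[v]])
        m[i, j] <- m[i, j] + 1L
    }
  }
  m
}

# Empirical log-hazard slope from event ages: person-years method on
# 1-year bins, least-squares slope of log hazard against bin midpoint.
loghazard_slope <- function(ages, lo = 50, hi = 95) {
  breaks <- seq(lo, hi, by = 1)
  mids <- breaks[-length(breaks)] + 0.5
  h <- numeric(length(mids))
  for (b in seq_along(mids)) {
    t0 <- breaks[b]; t1 <- breaks[b + 1]
    at_risk <- ages >= t0
    py <- sum(pmin(ages[at_risk], t1) - t0)
    deaths <- sum(ages >= t0 & ages < t1)
    h[b] <- if (py > 0) deaths / py else NA
  }
  ok <- !is.na(h) & h > 0
  unname(coef(lm(log(h[ok]) ~ mids[ok]))[2])
}

# Lean morbidity-style cohort for parameter-recovery runs: age at first
# disease or censoring at assessment + follow-up, no left truncation.
morbidity_cohort <- function(cfg) {
  sex <- rbinom(cfg$n_individuals, 1, cfg$male_fraction)
  burden <- simulate_burdens(cfg, seed = NA)[, 1]
  ages <- simulate_event_ages(cfg, burden, sex, "healthspan", seed = NA)
  assess <- runif(cfg$n_individuals, cfg$assessment_age_range[1],
                  cfg$assessment_age_range[2])
  cens <- assess + cfg$followup_years
  data.frame(time = pmin(ages, cens), event = as.integer(ages <= cens),
             burden = burden, sex = sex)
}
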