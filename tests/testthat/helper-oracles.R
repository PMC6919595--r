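## Independent oracles and small fixtures shared across the suite. The
## oracles deliberately use direct enumeration / explicit loops rather than
## the package's vectorized code paths.

## Build a ground truth with constant (or supplied) readiness probability.
make_test_truth <- function(country_id = "T01", p = 0.7,
                            shares = c(hospital = 0.6, health_center = 0.4),
                            anc4 = 0.6, hfd = 0.66,
                            live_births = 100000, stillbirths = 1800,
                            maternal = 500, neonatal = 2500,
                            registry = indicator_registry()) {
  ivs <- registry_interventions(registry)$intervention_id
  if (is.matrix(p)) {
    pm <- p
  } else {
    pm <- matrix(p, nrow = length(ivs), ncol = length(shares),
                 dimnames = list(ivs, names(shares)))
  }
  ground_truth(
    country_id, pm, anc4, hfd, shares,
    live_births = live_births, stillbirths = stillbirths,
    deaths = c(maternal = maternal, neonatal = neonatal),
    cause_fractions = list(
      maternal = c(haemorrhage = 0.4, hypertensive_disorders = 0.3,
                   sepsis = 0.2, obstructed_labour = 0.1),
      neonatal = c(prematurity = 0.4, intrapartum = 0.3,
                   sepsis_pneumonia = 0.2, tetanus = 0.1),
      stillbirth = c(antepartum_stillbirth = 0.6,
                     intrapartum_stillbirth = 0.4)))
}

## Exhaustive weighted-conjunction readiness by stratum.
oracle_readiness <- function(records, comps) {
  strata <- unique(records$stratum)
  out <- numeric(length(strata))
  names(out) <- strata
  for (s in strata) {
    num <- den <- 0
    for (i in which(records$stratum == s)) {
      ready <- TRUE
      for (cc in comps) ready <- ready && isTRUE(records[[cc]][i])
      num <- num + records$weight[i] * ready
      den <- den + records$weight[i]
    }
    out[s] <- num / den
  }
  out
}

## Explicit-loop residual-ratio deaths for one cause.
oracle_residual <- function(eff, af, cov) {
  r <- 1
  for (i in seq_along(eff)) r <- r * (1 - eff[i] * af[i] * cov[i])
  r
}

oracle_cause_deaths <- function(d0, eff, af, cov0, covt) {
  d0 * oracle_residual(eff, af, covt) / oracle_residual(eff, af, cov0)
}

## Order-statistic quantile with linear interpolation, written from the
## textbook definition (h = (n - 1) p + 1 on the sorted sample).
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

## A facility record with every registry component present.
all_present_record <- function(registry = indicator_registry()) {
  comps <- registry_components(registry, "SPA")
  stats::setNames(rep(TRUE, length(comps)), comps)
}

## Standard-error of the linked effective-coverage estimator for a truth
## with constant readiness p: U * sum_s share_s * p_hat_s, with p_hat_s a
## binomial proportion over the facilities allocated to stratum s.
coverage_se <- function(truth, intervention_id, period, n_by_stratum) {
  u <- if (period == "antenatal") truth$anc4_plus else truth$hfd
  shares <- truth$stratum_shares
  v <- 0
  for (s in names(shares)) {
    p <- truth$readiness_prob[intervention_id, s]
    v <- v + (shares[[s]]^2) * p * (1 - p) / n_by_stratum[[s]]
  }
  u * sqrt(v)
}
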