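entry <- function(id, eff, af, outcome = "maternal", cause = "haemorrhage") {
  tibble::tibble(intervention_id = id, outcome = outcome, cause = cause,
                 efficacy = eff, affected_fraction = af)
}

## one-country, one-cause epi fixture
mini_epi <- function(d0 = 1000, lb = 100000, sb = 1800) {
  epi_profile("M", 2016, lb, sb, tibble::tibble(
    outcome = c("maternal", "neonatal", "stillbirth"),
    cause = c("haemorrhage", "sepsis_pneumonia", "antepartum_stillbirth"),
    deaths = c(d0, 500, sb)))
}

traj_for <- function(cov0, covt, scenario = "scale_up") {
  dplyr::bind_rows(lapply(names(cov0), function(id) {
    tibble::tibble(intervention_id = id, year = 2016:2020,
                   coverage = seq(cov0[[id]], covt[[id]], length.out = 5),
                   scenario = scenario)
  }))
}

test_that("residual multiplies per-intervention survival factors", {
  expect_equal(residual(entry("a", 0.5, 1)[0, ], c(a = 1)), 1.0)
  expect_equal(residual(entry("a", 0.5, 1), c(a = 0.6)), 0.70)
  two <- dplyr::bind_rows(entry("a", 0.5, 1), entry("b", 0.4, 1))
  expect_equal(residual(two, c(a = 1, b = 1)), 0.30)
  # order invariance
  expect_equal(residual(two[2:1, ], c(a = 1, b = 1)),
               residual(two, c(a = 1, b = 1)))
  expect_error(residual(entry("zz", 0.5, 1), c(a = 0.5)), "zz")
})

test_that("deaths scale by the residual ratio from the baseline envelope", {
  cfg <- entry("a", 0.5, 1)
  tr <- traj_for(c(a = 0.2), c(a = 0.6))
  d <- deaths_under(tr, mini_epi(), cfg, c(a = 0.2))
  mat <- d[d$outcome == "maternal", ]
  expect_equal(mat$deaths[mat$year == 2020], 1000 * 0.70 / 0.90,
               tolerance = 1e-12)
  expect_equal(mat$deaths[mat$year == 2016], 1000, tolerance = 1e-12)
  # untouched causes pass through unchanged
  expect_equal(unique(d$deaths[d$outcome == "neonatal"]), 500)
  # unchanged coverage leaves every cause-year unchanged
  d0 <- deaths_under(traj_for(c(a = 0.2), c(a = 0.2)), mini_epi(), cfg,
                     c(a = 0.2))
  expect_equal(d0$deaths[d0$outcome == "maternal"], rep(1000, 5))
  # full aversion at full coverage
  cfg2 <- entry("a", 1, 1)
  d2 <- deaths_under(traj_for(c(a = 0), c(a = 1)), mini_epi(), cfg2,
                     c(a = 0))
  expect_equal(d2$deaths[d2$outcome == "maternal" & d2$year == 2020], 0)
  # full prevention at baseline contradicts a positive envelope
  expect_error(deaths_under(traj_for(c(a = 1), c(a = 1)), mini_epi(), cfg2,
                            c(a = 1)), "baseline residual")
})

test_that("lives saved are the counterfactual-scenario difference", {
  cfg <- entry("a", 0.5, 1)
  cf <- deaths_under(traj_for(c(a = 0.2), c(a = 0.2)), mini_epi(), cfg,
                     c(a = 0.2))
  su <- deaths_under(traj_for(c(a = 0.2), c(a = 0.6)), mini_epi(), cfg,
                     c(a = 0.2))
  ls <- lives_saved(cf, su)
  expect_equal(ls$lives_saved[ls$outcome == "maternal" & ls$year == 2020],
               1000 - 1000 * 0.70 / 0.90, tolerance = 1e-12)
  expect_true(all(ls$lives_saved >= -1e-12))
  # identical scenarios save nothing
  expect_equal(lives_saved(cf, cf)$lives_saved, rep(0, nrow(ls)))
  # savings bounded by the treatable cause's envelope
  expect_true(all(ls$lives_saved[ls$outcome == "neonatal"] == 0))
  bad <- su
  bad$cause[1] <- "renamed"
  expect_error(lives_saved(cf, bad), "mismatched")
})

test_that("attribution allocates the joint impact proportionally", {
  one <- entry("a", 0.5, 1)
  a1 <- attribute_by_intervention(one, c(a = 0.2), c(a = 0.6), 1000)
  expect_equal(unname(a1), 1000 * (1 - 0.70 / 0.90), tolerance = 1e-12)
  # closed-form proportional split: s = (500, 400), joint = 700
  a2 <- c(700 * 500 / 900, 700 * 400 / 900)
  expect_equal(a2, c(388.888888888889, 311.111111111111), tolerance = 1e-9)
  # zero coverage change -> zero allocations
  two <- dplyr::bind_rows(entry("a", 0.5, 1), entry("b", 0.4, 1))
  a0 <- attribute_by_intervention(two, c(a = .3, b = .4), c(a = .3, b = .4),
                                  1000)
  expect_equal(unname(a0), c(0, 0))
  # conservation: allocations sum to the joint total
  set.seed(9)
  for (i in 1:25) {
    k <- sample(1:3, 1)
    ids <- letters[seq_len(k)]
    ent <- dplyr::bind_rows(lapply(ids, function(id) {
      entry(id, stats::runif(1), stats::runif(1))
    }))
    c0 <- stats::setNames(stats::runif(k, 0, 0.6), ids)
    ct <- c0 + stats::runif(k, 0, 0.4)
    d0 <- stats::runif(1, 10, 5000)
    a <- attribute_by_intervention(ent, c0, ct, d0)
    joint <- d0 * (1 - residual(ent, ct) / residual(ent, c0))
    expect_equal(sum(a), joint, tolerance = 1e-9)
    expect_true(all(a >= -1e-12))
  }
})

test_that("mortality rates use the standard denominators", {
  epi <- mini_epi(lb = 100000, sb = 1800)
  r <- mortality_rates(c(maternal = 150, neonatal = 2000, stillbirth = 1800),
                       epi)
  expect_equal(r[["MMR"]], 150)
  expect_equal(r[["NMR"]], 20)
  expect_equal(r[["SBR"]], 1800 / 101800 * 1000, tolerance = 1e-12)
  bad <- mini_epi(lb = 0, sb = 0)
  expect_error(mortality_rates(c(maternal = 1, neonatal = 1,
                                 stillbirth = 1), bad), "positive")
})

test_that("engine matches a brute-force oracle on random small instances", {
  set.seed(2024)
  causes <- c("c1", "c2", "c3")
  for (trial in 1:200) {
    k <- sample(1:3, 1)   # interventions
    m <- sample(1:3, 1)   # causes
    ids <- paste0("iv", seq_len(k))
    cfg <- dplyr::bind_rows(lapply(seq_len(m), function(ci) {
      keep <- sample(seq_len(k), sample(seq_len(k), 1))
      tibble::tibble(intervention_id = ids[keep], outcome = "neonatal",
                     cause = causes[ci],
                     efficacy = stats::runif(length(keep)),
                     affected_fraction = stats::runif(length(keep)))
    }))
    d0 <- stats::runif(m, 100, 10000)
    epi <- epi_profile("O", 2016, 1e5, 1000,
                       tibble::tibble(outcome = "neonatal",
                                      cause = causes[seq_len(m)],
                                      deaths = d0))
    c0 <- stats::setNames(stats::runif(k, 0, 0.7), ids)
    ct <- pmin(c0 + stats::runif(k, 0, 0.3), 1)
    tr <- traj_for(c0, ct)
    got <- deaths_under(tr, epi, cfg, c0)
    for (ci in seq_len(m)) {
      ent <- cfg[cfg$cause == causes[ci], ]
      for (yi in 1:5) {
        covy <- vapply(ids, function(id) {
          tr$coverage[tr$intervention_id == id][yi]
        }, 0.0)
        # oracle at year yi: baseline cov c0, scenario cov covy
        want <- oracle_cause_deaths(d0[ci], ent$efficacy,
                                    ent$affected_fraction,
                                    c0[ent$intervention_id],
                                    covy[ent$intervention_id])
        have <- got$deaths[got$cause == causes[ci]][yi]
        expect_equal(have, unname(want), tolerance = 1e-9)
      }
    }
  }
})

test_that("impact is monotone and scale-equivariant, without double counting", {
  cfg <- dplyr::bind_rows(entry("a", 0.5, 0.8), entry("b", 0.4, 0.9))
  c0 <- c(a = 0.2, b = 0.3)
  ct <- c(a = 0.6, b = 0.7)
  saved <- function(config, cov0, covt, d0 = 1000) {
    epi <- mini_epi(d0)
    cf <- deaths_under(traj_for(cov0, cov0, "cf"), epi, config, cov0)
    su <- deaths_under(traj_for(cov0, covt), epi, config, cov0)
    ls <- lives_saved(cf, su)
    ls$lives_saved[ls$outcome == "maternal" & ls$year == 2020]
  }
  base <- saved(cfg, c0, ct)
  # higher endline coverage, efficacy or affected fraction -> more saved
  expect_gt(saved(cfg, c0, c(a = 0.7, b = 0.7)), base)
  cfg_eff <- cfg; cfg_eff$efficacy[1] <- 0.6
  expect_gt(saved(cfg_eff, c0, ct), base)
  cfg_af <- cfg; cfg_af$affected_fraction[2] <- 1
  expect_gt(saved(cfg_af, c0, ct), base)
  # doubling the envelope doubles lives saved exactly
  expect_equal(saved(cfg, c0, ct, d0 = 2000), 2 * base, tolerance = 1e-12)
  # joint aversion never exceeds the sum of single-intervention aversions
  s_a <- saved(cfg, c0, c(a = ct[["a"]], b = c0[["b"]]))
  s_b <- saved(cfg, c0, c(a = c0[["a"]], b = ct[["b"]]))
  expect_lt(base, s_a + s_b)
  expect_gt(base, max(s_a, s_b))
})

test_that("country_impact ties deaths, savings, attribution and rates together", {
  cfg <- dplyr::bind_rows(
    entry("a", 0.5, 0.8),
    entry("b", 0.4, 0.9, outcome = "neonatal", cause = "sepsis_pneumonia"))
  traj <- dplyr::bind_rows(traj_for(c(a = 0.2, b = 0.1), c(a = 0.6, b = 0.5)),
                           traj_for(c(a = 0.2, b = 0.1), c(a = 0.2, b = 0.1),
                                    scenario = "counterfactual"))
  res <- country_impact(traj, mini_epi(), cfg)
  # attribution sums to total lives saved per outcome-year
  att <- dplyr::summarise(dplyr::group_by(res$attribution, outcome, year),
                          tot = sum(deaths_averted), .groups = "drop")
  merged <- dplyr::inner_join(att, res$lives_saved, by = c("outcome", "year"))
  expect_equal(merged$tot, merged$lives_saved, tolerance = 1e-9)
  # rate declines mirror death-count declines (fixed denominators)
  r16 <- res$rates[res$rates$scenario == "scale_up" & res$rates$year == 2016, ]
  r20 <- res$rates[res$rates$scenario == "scale_up" & res$rates$year == 2020, ]
  d16 <- sum(res$deaths$deaths[res$deaths$scenario == "scale_up" &
                                 res$deaths$year == 2016 &
                                 res$deaths$outcome == "maternal"])
  d20 <- sum(res$deaths$deaths[res$deaths$scenario == "scale_up" &
                                 res$deaths$year == 2020 &
                                 res$deaths$outcome == "maternal"])
  expect_equal(percent_decline(r16$MMR, r20$MMR),
               percent_decline(d16, d20), tolerance = 1e-9)
})
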