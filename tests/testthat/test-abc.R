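test_that("reference tables have the right bookkeeping and reproduce under a seed", {
  des <- sim_design(n_seq = 4, n_ind = 4, n_loci = 2)
  rt <- build_reference_table(c("S1", "S2", "S3"), default_priors(),
                              n_per_scenario = 20, design = des, seed = 51)
  expect_equal(nrow(rt$stats), 60L)
  expect_equal(as.integer(table(rt$scenario)), rep(20L, 3))
  expect_equal(ncol(rt$stats), 30L)
  rt2 <- build_reference_table(c("S1", "S2", "S3"), default_priors(),
                               n_per_scenario = 20, design = des, seed = 51)
  expect_identical(rt$stats, rt2$stats)
  expect_identical(rt$params, rt2$params)
})

test_that("reference tables round-trip through gzipped TSV bit-identically", {
  des <- sim_design(n_seq = 4, n_ind = 4, n_loci = 2)
  rt <- build_reference_table(c("S1", "S2"), default_priors(),
                              n_per_scenario = 10, design = des, seed = 52)
  f1 <- withr::local_tempfile(fileext = ".tsv.gz")
  write_reftable(rt, f1)
  rt2 <- read_reftable(f1)
  expect_equal(rt2$stats, rt$stats)
  expect_equal(rt2$params, rt$params)
  expect_equal(rt2$scenario, rt$scenario)
  expect_equal(rt2$center, rt$center)
  expect_equal(rt2$scale, rt$scale)
  f2 <- withr::local_tempfile(fileext = ".tsv.gz")
  write_reftable(rt2, f2)
  expect_identical(readLines(gzfile(f1)), readLines(gzfile(f2)))
})

test_that("rejection accepts exactly ceiling(tolerance * rows), closest first", {
  set.seed(53)
  rt <- toy_table(n_per = 334, nstat = 2)  # 1002 rows
  obs <- setNames(as.numeric(rt$stats[5, ]), colnames(rt$stats))
  rej <- rejection_sample(obs, rt, tolerance = 0.01)
  expect_equal(rej$n_accepted, 11L)  # ceiling(0.01 * 1002)
  expect_equal(rej$distance[rej$index[1]], 0)
  expect_true(5L %in% rej$index)
  # tolerance 1 accepts every row
  expect_equal(rejection_sample(obs, rt, 1)$n_accepted, nrow(rt$stats))
  # registry mismatch is an error
  expect_error(rejection_sample(obs[-1], rt, 0.01), "registry mismatch")
})

test_that("posteriors are normalized, rescale-invariant, and match rejection on easy tables", {
  set.seed(54)
  rt <- toy_table(n_per = 400, nstat = 3, noise = 0.6)
  obs <- setNames(c(0, 0, 0), colnames(rt$stats))  # at scenario 1's center
  mc <- suppressWarnings(model_choice(obs, rt, tolerance = 0.05))
  expect_equal(sum(mc$posterior), 1, tolerance = 1e-12)
  expect_gt(mc$posterior[["S1"]], 0.95)
  expect_true(all(mc$ci[, "lower"] <= mc$ci[, "upper"]))
  # logistic and rejection agree on well-separated tables
  expect_lt(max(abs(mc$posterior - mc$rejection_posterior)), 0.1)
  # rescaling a raw statistic is absorbed by the normalization
  rt_scaled <- rt
  rt_scaled$stats[, 2] <- rt_scaled$stats[, 2] * 1000
  rt_scaled <- refugia:::new_ref_table(rt_scaled$scenario, rt_scaled$params,
                                       rt_scaled$stats, rt_scaled$registry)
  obs2 <- obs; obs2[2] <- obs[2] * 1000
  mc2 <- suppressWarnings(model_choice(obs2, rt_scaled, tolerance = 0.05))
  expect_equal(mc2$posterior, mc$posterior, tolerance = 1e-6)
})

test_that("overlapping scenarios give symmetric posteriors near 1/3", {
  set.seed(55)
  rt <- toy_table(n_per = 600, centers = c(S1 = 0, S2 = 0, S3 = 0),
                  nstat = 3, noise = 1)
  obs <- setNames(c(0, 0, 0), colnames(rt$stats))
  mc <- model_choice(obs, rt, tolerance = 0.05)
  # 3 MC standard errors for a proportion around 1/3 with 90 draws
  expect_true(all(abs(mc$posterior - 1 / 3) < 3 * sqrt(1 / 9 * 2 / 90) + 0.15))
  expect_equal(sum(mc$posterior), 1, tolerance = 1e-12)
})

test_that("a single-scenario table yields that scenario with probability one", {
  set.seed(56)
  rt <- toy_table(n_per = 100, centers = c(S2 = 1), nstat = 2)
  obs <- setNames(c(1, 1), colnames(rt$stats))
  mc <- model_choice(obs, rt, tolerance = 0.1)
  expect_equal(unname(mc$posterior[["S2"]]), 1)
})

test_that("local-linear adjustment recovers exact linear relations", {
  # statistics exactly linear in the (log) parameter, no noise
  set.seed(57)
  n <- 300
  logp <- rnorm(n, 10, 1)
  stats <- cbind(st1 = 2 * logp - 5)
  params <- matrix(exp(logp), n, length(refugia:::param_names()),
                   dimnames = list(NULL, refugia:::param_names()))
  reg <- sumstat_registry("combined"); reg$n_stats <- 1
  rt <- refugia:::new_ref_table(rep("S2", n), params, stats, reg,
                                scenarios = list(build_scenario("S2")))
  target <- 9.7
  obs <- setNames(2 * target - 5, "st1")
  est <- estimate_parameters(obs, rt, "S2", tolerance = 0.2)
  expect_equal(unname(est$summary$median[est$summary$parameter == "N_EU"]),
               exp(target), tolerance = 1e-6)
  expect_lt(diff(range(est$adjusted[, "N_EU"])) / exp(target), 1e-6)
})

test_that("a tolerance accepting one row returns a point mass at that row", {
  set.seed(58)
  rt <- toy_table(n_per = 50, centers = c(S2 = 2), nstat = 2)
  obs <- setNames(as.numeric(rt$stats[7, ]), colnames(rt$stats))
  est <- estimate_parameters(obs, rt, "S2", tolerance = 1 / 50)
  expect_equal(est$n_accepted, 1L)
  expect_equal(unname(est$summary$median),
               unname(refugia:::rename_time_params(
                 rt$params[7, , drop = FALSE], rt, "S2")[1, ]))
})

test_that("statistics carrying no signal leave the prior unchanged", {
  set.seed(59)
  n <- 2000
  params <- matrix(exp(rnorm(n * length(refugia:::param_names()))),
                   ncol = length(refugia:::param_names()),
                   dimnames = list(NULL, refugia:::param_names()))
  stats <- cbind(st1 = rnorm(n), st2 = rnorm(n))
  reg <- sumstat_registry("combined"); reg$n_stats <- 2
  rt <- refugia:::new_ref_table(rep("S2", n), params, stats, reg,
                                scenarios = list(build_scenario("S2")))
  obs <- setNames(c(0, 0), c("st1", "st2"))
  est <- estimate_parameters(obs, rt, "S2", tolerance = 0.25)
  ks <- suppressWarnings(stats::ks.test(est$adjusted[, "N_IR"],
                                        params[, "N_IR"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("scenario time symbols are renamed in posterior summaries", {
  des <- sim_design(n_seq = 4, n_ind = 4, n_loci = 2)
  rt <- build_reference_table(c("S2", "S3"), default_priors(),
                              n_per_scenario = 60, design = des, seed = 60)
  obs <- setNames(as.numeric(rt$stats[1, ]), colnames(rt$stats))
  est <- suppressWarnings(estimate_parameters(obs, rt, "S2", tolerance = 0.5))
  expect_true(all(c("T_H", "T_L") %in% est$summary$parameter))
  est3 <- suppressWarnings(estimate_parameters(obs, rt, "S3", tolerance = 0.5))
  expect_true(all(c("T_L", "T_E") %in% est3$summary$parameter))
})

test_that("confidence evaluation separates separable scenarios and not identical ones", {
  # perfectly separable toy scenarios: zero type I and type II error
  set.seed(61)
  rt <- toy_table(n_per = 200, centers = c(S1 = 0, S2 = 10, S3 = 20),
                  noise = 0.3)
  cls <- function(center) {
    obs <- setNames(rnorm(3, center, 0.3), colnames(rt$stats))
    mc <- suppressWarnings(model_choice(obs, rt, 0.05, ci = FALSE))
    names(which.max(mc$posterior))
  }
  hits <- c(mean(replicate(20, cls(0)) == "S1"),
            mean(replicate(20, cls(10)) == "S2"),
            mean(replicate(20, cls(20)) == "S3"))
  expect_equal(hits, c(1, 1, 1))
})

test_that("prior-predictive checks flag misfit and stay calibrated", {
  set.seed(62)
  rt <- toy_table(n_per = 500, centers = c(S1 = 0, S2 = 0.5), nstat = 4,
                  noise = 1)
  # observed from the simulated distribution itself: few flags
  obs <- setNames(as.numeric(rt$stats[3, ]), colnames(rt$stats))
  ppc <- prior_predictive_check(obs, rt)
  expect_equal(nrow(ppc), 8L)  # registry length x scenarios
  expect_true(all(ppc$quantile >= 0 & ppc$quantile <= 1))
  # an impossible observation is flagged at quantile 0 or 1
  obs_far <- setNames(rep(100, 4), colnames(rt$stats))
  ppc2 <- prior_predictive_check(obs_far, rt)
  expect_true(all(ppc2$flagged))
  expect_true(all(ppc2$quantile == 1))
})
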