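test_that("scenario construction encodes the three recolonization histories", {
  s1 <- build_scenario("S1")
  s2 <- build_scenario("S2")
  s3 <- build_scenario("S3")
  expect_equal(s2$time_prior, c("T_H", "T_L"))
  expect_equal(s3$time_prior, c("T_L", "T_E"))
  expect_equal(s1$time_prior, c("T_H", "T_H"))
  expect_equal(s2$merges[[1]]$from, "IR")
  expect_equal(s2$merges[[2]]$from, "TA")
  expect_error(build_scenario("S9"), "unknown scenario")
})

test_that("parameter draws respect priors, ordering and reproducibility", {
  pr <- default_priors()
  sc <- build_scenario("S1")
  set.seed(31)
  draws <- replicate(500, {
    d <- draw_parameters(pr, sc)
    c(d$t1_yr, d$t2_yr, d$N_IR)
  })
  expect_true(all(draws[1, ] < draws[2, ]))
  expect_true(all(draws[1, ] >= 2000 & draws[2, ] <= 11700))
  expect_true(all(draws[3, ] >= 1e2 & draws[3, ] <= 1e6))
  # same seed, same draw
  set.seed(32); d1 <- draw_parameters(pr, build_scenario("S2"))
  set.seed(32); d2 <- draw_parameters(pr, build_scenario("S2"))
  expect_identical(d1, d2)
  # degenerate point priors return the points
  prp <- default_priors(N_EU = list(dist = "unif", min = 500, max = 500),
                        T_H = list(dist = "unif", min = 4000, max = 4000))
  set.seed(33)
  dp <- draw_parameters(prp, build_scenario("S2"))
  expect_equal(dp$N_EU, 500)
  expect_equal(dp$t1_yr, 4000)
  # unsatisfiable ordering raises a prior-specification error
  bad <- default_priors(T_L = list(dist = "unif", min = 100, max = 200))
  expect_error(draw_parameters(bad, build_scenario("S2")),
               "prior-specification")
  # uniform prior mean lands within 3 standard errors of (a + b) / 2
  set.seed(34)
  th <- replicate(10000, draw_parameters(pr, build_scenario("S2"))$t1_yr)
  se <- sd(th) / sqrt(length(th))
  expect_lt(abs(mean(th) - (2000 + 11700) / 2), 3 * se)
})

test_that("pairwise coalescence times match the analytic expectation", {
  sc <- build_scenario("S2")
  dr <- refugia:::table4_medians()
  dr$t1_gen <- 1e12; dr$t2_gen <- 2e12  # effectively a single population
  N <- 1000
  dr$N_EU <- N
  set.seed(35)
  tm <- replicate(5000, {
    tr <- simulate_genealogy(c(2, 0, 0), sc, dr, "autosomal")
    max(tr$time)
  })
  expect_lt(abs(mean(tm) - 2 * N) / (2 * N), 0.05)
  # mtDNA inheritance scalar shrinks the expectation fourfold
  set.seed(36)
  tmh <- replicate(5000, {
    tr <- simulate_genealogy(c(2, 0, 0), sc, dr, "mtdna")
    max(tr$time)
  })
  expect_lt(abs(mean(tmh) - 2 * N * 0.25) / (2 * N * 0.25), 0.05)
})

test_that("zero split times collapse the model to panmixia", {
  sc <- build_scenario("S2")
  dr <- refugia:::table4_medians()
  dr$N_EU <- dr$N_IR <- dr$N_TA <- dr$N_ANC <- 800
  dr$t1_gen <- 0; dr$t2_gen <- 0
  set.seed(37)
  t_struct <- replicate(2000, max(simulate_genealogy(c(2, 2, 2), sc, dr,
                                                     "autosomal")$time))
  # analytic E[TMRCA] for n = 6: 2N * 2 * (1 - 1/6)
  expected <- 2 * 800 * 2 * (1 - 1 / 6)
  expect_lt(abs(mean(t_struct) - expected) / expected, 0.06)
})

test_that("deep splits with small sizes coalesce each group before its event", {
  sc <- build_scenario("S2")
  dr <- refugia:::table4_medians()
  dr$N_EU <- dr$N_IR <- dr$N_TA <- 50
  dr$t1_gen <- 5e5; dr$t2_gen <- 1e6
  set.seed(38)
  for (r in 1:50) {
    tr <- simulate_genealogy(c(4, 4, 4), sc, dr, "autosomal")
    # nodes below the first event: all within-group coalescences done
    below <- sum(tr$time > 0 & tr$time < dr$t1_gen)
    expect_equal(below, 9L)  # (4-1) per group
  }
})

test_that("sequence mutation calibrates against the Watterson expectation", {
  sc <- build_scenario("S2")
  dr <- refugia:::table4_medians()
  # L is large relative to the expected mutation count so that finite-site
  # collisions do not bias S against the infinite-sites expectation
  N <- 1500; n <- 20L; L <- 2000L
  theta <- 5
  mu_gen <- theta / (2 * (2 * N * 0.25) * L)  # per site per generation
  dr$N_EU <- N; dr$t1_gen <- 1e9; dr$t2_gen <- 2e9
  set.seed(39)
  S <- replicate(2000, {
    tr <- simulate_genealogy(c(n, 0, 0), sc, dr, "mtdna")
    a <- mutate_sequence(tr, L, mu_gen / dr$gen_time, dr$gen_time)
    nucleotide_diversity(a)$S
  })
  a1 <- sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(S) - theta * a1) / (theta * a1), 0.05)
  # mu = 0 leaves every sequence identical
  set.seed(40)
  tr <- simulate_genealogy(c(6, 0, 0), sc, dr, "mtdna")
  a0 <- mutate_sequence(tr, 50L, 0, dr$gen_time)
  expect_equal(collapse_haplotypes(a0)$H_n, 1L)
  # doubling mu doubles the expected pairwise difference
  set.seed(41)
  k1 <- mean(replicate(800, {
    tr <- simulate_genealogy(c(8, 0, 0), sc, dr, "mtdna")
    nucleotide_diversity(mutate_sequence(tr, L, mu_gen / 2, dr$gen_time))$k
  }))
  set.seed(41)
  k2 <- mean(replicate(800, {
    tr <- simulate_genealogy(c(8, 0, 0), sc, dr, "mtdna")
    nucleotide_diversity(mutate_sequence(tr, L, mu_gen, dr$gen_time))$k
  }))
  expect_lt(abs(k2 / k1 - 2), 0.25)
})

test_that("the stepwise model reaches Ohta-Kimura equilibrium homozygosity", {
  sc <- build_scenario("S2")
  dr <- refugia:::table4_medians()
  N <- 1e4; mu <- 1e-4
  dr$N_EU <- N; dr$mu_ms <- mu; dr$gsm_p <- 0
  dr$t1_gen <- 1e9; dr$t2_gen <- 2e9
  set.seed(42)
  Fhat <- replicate(2000, {
    tr <- simulate_genealogy(c(50, 0, 0), sc, dr, "autosomal")
    sizes <- mutate_microsat(tr, mu, 0)
    cnt <- tabulate(match(sizes, unique(sizes)))
    n <- sum(cnt); p <- cnt / n
    1 - n * (1 - sum(p^2)) / (n - 1)  # unbiased homozygosity
  })
  expected <- 1 / sqrt(1 + 8 * N * mu)
  expect_lt(abs(mean(Fhat) - expected) / expected, 0.10)
  # mu = 0 keeps every allele at the root size
  tr <- simulate_genealogy(c(10, 0, 0), sc, dr, "autosomal")
  expect_true(all(mutate_microsat(tr, 0, 0) == 200L))
  # same seed, same allele table
  set.seed(43); s1 <- mutate_microsat(simulate_genealogy(c(8, 0, 0), sc, dr,
                                                         "autosomal"), mu, 0.3)
  set.seed(43); s2 <- mutate_microsat(simulate_genealogy(c(8, 0, 0), sc, dr,
                                                         "autosomal"), mu, 0.3)
  expect_identical(s1, s2)
})

test_that("simulated datasets have the requested shape and are reproducible", {
  sc <- build_scenario("S2")
  pr <- default_priors()
  set.seed(44)
  dr <- draw_parameters(pr, sc)
  ds <- simulate_dataset(sc, dr, sim_design(20, 20, 9))
  expect_length(ds$aln$ids, 60L)
  expect_equal(ds$aln$length, 1029L)
  expect_equal(dim(ds$ms$allele1), c(60L, 9L))
  expect_equal(nrow(ds$map), 60L)
  # mtDNA-only design has no microsatellite component
  ds2 <- simulate_dataset(sc, dr, sim_design(5, 5, n_loci = 0))
  expect_null(ds2$ms)
  # byte-identical regeneration under a fixed seed
  set.seed(45); a <- simulate_dataset(sc, draw_parameters(pr, sc))
  set.seed(45); b <- simulate_dataset(sc, draw_parameters(pr, sc))
  expect_identical(a, b)
})

test_that("summary statistics are exchangeable and scale with inheritance", {
  sc <- build_scenario("S2")
  dr <- refugia:::table4_medians()
  dr$N_EU <- dr$N_IR <- dr$N_TA <- dr$N_ANC <- 2000
  dr$t1_gen <- 1e9; dr$t2_gen <- 2e9
  L <- 300L; mu_gen <- 1e-5
  # mtDNA mean k is ~1/4 of the autosomal-mode mean k at matched N and mu
  set.seed(46)
  k_mt <- mean(replicate(600, {
    tr <- simulate_genealogy(c(10, 0, 0), sc, dr, "mtdna")
    nucleotide_diversity(mutate_sequence(tr, L, mu_gen / dr$gen_time,
                                         dr$gen_time))$k
  }))
  k_auto <- mean(replicate(600, {
    tr <- simulate_genealogy(c(10, 0, 0), sc, dr, "autosomal")
    nucleotide_diversity(mutate_sequence(tr, L, mu_gen / dr$gen_time,
                                         dr$gen_time))$k
  }))
  expect_lt(abs(k_mt / k_auto - 0.25) / 0.25, 0.25)
})

test_that("nested scenarios collapse when their times coincide", {
  # S2 with T_L forced to T_H is S1 with both merges at that point: the
  # summary-statistic distributions coincide at matched parameters
  des <- sim_design(n_seq = 10, n_ind = 10, n_loci = 4)
  dr <- refugia:::table4_medians()
  dr$t1_gen <- 4000; dr$t2_gen <- 4000.005  # effectively simultaneous
  stat_reps <- function(scen, nrep) {
    sc <- build_scenario(scen)
    t(replicate(nrep, {
      ds <- simulate_dataset(sc, dr, des)
      assemble_sumstats(ds$aln, ds$ms, ds$map)
    }))
  }
  set.seed(47)
  r2 <- stat_reps("S2", 300)
  set.seed(48)
  r1 <- stat_reps("S1", 300)
  for (stat in c("fst.EU.TA", "fstw.EU.TA", "kb.EU.IR", "He.IR")) {
    se <- sqrt(var(r1[, stat]) / nrow(r1) + var(r2[, stat]) / nrow(r2))
    expect_lt(abs(mean(r2[, stat]) - mean(r1[, stat])), 5 * se)
  }
})
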