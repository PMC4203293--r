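test_that("haplotype collapsing counts exact string classes", {
  a <- alignment(sprintf("s%d", 1:4), rep("AAAA", 4))
  ht <- collapse_haplotypes(a)
  expect_equal(ht$H_n, 1L)
  expect_equal(ht$counts, 4L)

  b <- alignment(sprintf("s%d", 1:3), c("AAA", "AAA", "AAT"))
  ht2 <- collapse_haplotypes(b)
  expect_equal(ht2$H_n, 2L)
  expect_equal(sort(ht2$counts), c(1L, 2L))

  set.seed(21)
  cc <- rand_alignment(10, L = 40)
  cc$seq <- vapply(1:10, function(i) {
    s <- cc$seq[i]; substr(s, 1, 2) <- c("AA", "AC", "AG", "AT", "CA",
                                         "CC", "CG", "CT", "GA", "GC")[i]; s
  }, "")
  expect_equal(collapse_haplotypes(cc)$H_n, 10L)

  # per-deme counts sum to the totals
  map <- two_deme_map(b$ids, 2)
  ht3 <- collapse_haplotypes(b, map)
  expect_equal(rowSums(ht3$deme_counts), ht3$counts)
})

test_that("nucleotide diversity matches hand-enumerated examples", {
  a <- alignment(c("x", "y"), c("AAAAAAAAAA", "AATTAAAAAA"))
  nd <- nucleotide_diversity(a)
  expect_equal(nd$k, 2)
  expect_equal(nd$pi, 0.2)
  expect_equal(nd$S, 2L)

  mono <- generate_null_fixture("monomorphic", 6)
  ndm <- nucleotide_diversity(mono$aln)
  expect_equal(ndm$k, 0)
  expect_equal(ndm$pi, 0)
  expect_equal(ndm$S, 0L)

  b <- alignment(c("x", "y", "z"), c("AAAA", "AAAT", "AATA"))
  expect_equal(nucleotide_diversity(b)$k, 4 / 3)
  expect_error(nucleotide_diversity(alignment("x", "AC")), "at least two")
})

test_that("haplotype diversity hits its boundary values and Nei's formula", {
  mono <- generate_null_fixture("monomorphic", 8)
  expect_equal(haplotype_diversity(mono$aln)$HD, 0)
  uniq <- generate_null_fixture("all_unique", 8)
  expect_equal(haplotype_diversity(uniq$aln)$HD, 1)
  hd <- haplotype_diversity(c(2, 2))
  expect_equal(hd$HD, 2 / 3)
  expect_equal(hd$sd, o_HD_sd(c(2, 2)))
})

test_that("sequence statistics match brute-force oracles on random data", {
  set.seed(22)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    a <- rand_alignment(n, L = sample(30:80, 1))
    nd <- nucleotide_diversity(a)
    ora <- o_pi_k_S(a$seq)
    expect_equal(nd$k, ora$k, tolerance = 1e-12)
    expect_equal(nd$S, ora$S)
    expect_equal(haplotype_diversity(a)$HD, o_HD(o_hap_counts(a$seq)),
                 tolerance = 1e-12)
    expect_equal(tajimas_D(a), o_tajima(a$seq), tolerance = 1e-10)
    expect_equal(fu_li_F(a), o_fu_li_Fstar(a$seq), tolerance = 1e-10)
  }
})

test_that("neutrality tests return an undefined sentinel without polymorphism", {
  mono <- generate_null_fixture("monomorphic", 6)$aln
  expect_warning(D <- tajimas_D(mono), "undefined")
  expect_true(is.nan(D))
  expect_warning(FF <- fu_li_F(mono), "undefined")
  expect_true(is.nan(FF))
})

test_that("an excess of singletons forces D and F* negative", {
  n <- 30
  base <- strrep("A", 60)
  seqs <- rep(base, n)
  for (i in 1:12) substr(seqs[i], i, i) <- "T"  # every variant a singleton
  a <- alignment(sprintf("s%d", 1:n), seqs)
  expect_lt(tajimas_D(a), 0)
  expect_lt(fu_li_F(a), 0)
})

test_that("the outgroup variant of Fu & Li's F polarizes singletons", {
  # two singletons, one matching the outgroup state (ancestral, not counted)
  seqs <- c("AAAA", "TAAA", "AAAC", "AAAA", "AAAA")
  a <- alignment(sprintf("s%d", 1:5), seqs)
  f_all <- fu_li_F(a, "outgroup", outgroup = "AAAA")
  # with outgroup TAAA the first singleton is ancestral: eta_e drops by 1
  f_anc <- fu_li_F(a, "outgroup", outgroup = "TAAA")
  expect_false(isTRUE(all.equal(f_all, f_anc)))
  expect_error(fu_li_F(a, "outgroup"), "outgroup")
})

test_that("Hudson FST behaves at its anchors and matches hand computation", {
  set.seed(23)
  pool <- rand_alignment(12, L = 50)
  map <- two_deme_map(pool$ids, 6)
  expect_lt(abs(hudson_fst(pool, map, c("d1", "d2"))), 0.35)

  fixed <- generate_null_fixture("two_group_fixed", 5)
  expect_equal(hudson_fst(fixed$aln, fixed$map, c("d1", "d2")), 1)

  toy <- alignment(c("a1", "a2", "b1", "b2"),
                   c("AAAA", "AAAT", "TTAA", "TTAT"))
  tmap <- two_deme_map(toy$ids, 2)
  expect_equal(hudson_fst(toy, tmap, c("d1", "d2")),
               o_hudson_fst(toy$seq[1:2], toy$seq[3:4]), tolerance = 1e-12)
  expect_error(hudson_fst(toy, tmap, c("d1", "d9")), "absent")
})

test_that("microsatellite statistics match their definitions", {
  ids <- sprintf("i%d", 1:4)
  ms <- microsat_dataset(ids, "loc1",
                         matrix(c(100L, 104L, 100L, 100L), 4, 1),
                         matrix(c(100L, 104L, 100L, 100L), 4, 1))
  map <- popmap(ids, c("d1", "d1", "d2", "d2"))
  st <- microsat_stats(ms, map)
  # two copies of 100 and two of 104 in d1: sample variance over 4 copies
  expect_equal(st$per_deme$mean_size_var[1], var(c(100, 100, 104, 104)))
  expect_equal(st$per_deme$mean_alleles[2], 1)
  expect_equal(st$per_deme$mean_He[2], 0)
  expect_equal(st$per_deme$mean_size_var[2], 0)
  # two copies of sizes 100 and 104 give sample variance 8
  ms2 <- microsat_dataset("i1", "loc1", matrix(100L), matrix(104L))
  st2 <- microsat_stats(ms2, popmap("i1", "d1"))
  expect_equal(st2$per_deme$mean_size_var, 8)
})

test_that("Weir-Cockerham FST matches the oracle and its null anchor", {
  set.seed(24)
  for (rep in 1:20) {
    ms <- rand_msat(14, nloc = 3, nalleles = 4, miss = 0.05)
    map <- two_deme_map(ms$ids, 7)
    st <- microsat_stats(ms, map)
    idx1 <- 1:7; idx2 <- 8:14
    g <- function(idx) lapply(1:3, function(l) {
      m <- cbind(ms$allele1[idx, l], ms$allele2[idx, l])
      m[stats::complete.cases(m), , drop = FALSE]
    })
    expect_equal(st$per_pair$fst_wc, o_wc_fst(g(idx1), g(idx2)),
                 tolerance = 1e-9)
  }
  # identical allele-frequency pools: multilocus FST near zero
  set.seed(25)
  a1 <- matrix(sample(c(100L, 102L), 8 * 40, TRUE), 8, 40)
  a2 <- matrix(sample(c(100L, 102L), 8 * 40, TRUE), 8, 40)
  msp <- microsat_dataset(sprintf("i%d", 1:8), sprintf("l%d", 1:40), a1, a2)
  stp <- microsat_stats(msp, two_deme_map(msp$ids, 4))
  expect_lt(abs(stp$per_pair$fst_wc), 0.1)
})

test_that("registry vectors have fixed length and deme-order invariance", {
  set.seed(26)
  sc <- build_scenario("S2")
  dr <- draw_parameters(default_priors(), sc)
  ds <- simulate_dataset(sc, dr, sim_design(n_seq = 5, n_ind = 5, n_loci = 3))
  ss <- assemble_sumstats(ds$aln, ds$ms, ds$map)
  expect_length(ss, 30L)
  # the registry's microsatellite block agrees with microsat_stats()
  st <- suppressWarnings(microsat_stats(ds$ms, ds$map, "lineage"))
  pd <- st$per_deme[match(c("EU", "IR", "TA"), st$per_deme$deme), ]
  ref <- c(t(as.matrix(pd[, c("mean_alleles", "mean_He")])),
           rbind(st$per_pair$fst_wc, st$per_pair$dmu2))
  expect_equal(unname(ss[19:30]), as.numeric(ref), tolerance = 1e-9)
  expect_length(assemble_sumstats(ds$aln, NULL, ds$map,
                                  sumstat_registry("mtdna")), 15L)
  expect_length(assemble_sumstats(NULL, ds$ms, ds$map,
                                  sumstat_registry("microsat")), 12L)
  expect_error(assemble_sumstats(NULL, ds$ms, ds$map,
                                 sumstat_registry("mtdna")),
               "requires a sequence alignment")
  # permuting sample order leaves the vector unchanged
  perm <- sample(length(ds$aln$ids))
  aln_p <- alignment(ds$aln$ids[perm], ds$aln$seq[perm])
  permi <- sample(length(ds$ms$ids))
  ms_p <- microsat_dataset(ds$ms$ids[permi], ds$ms$loci,
                           ds$ms$allele1[permi, ], ds$ms$allele2[permi, ])
  map_p <- ds$map[sample(nrow(ds$map)), ]
  expect_equal(assemble_sumstats(aln_p, ms_p, map_p), ss, tolerance = 1e-12)
})

test_that("degenerate statistics map to the documented ABC sentinels", {
  # three monomorphic groups fixed for different haplotypes
  L <- 24
  haps <- c(strrep("A", L), strrep("C", L), strrep("G", L))
  ids <- sprintf("s%d", 1:12)
  aln <- alignment(ids, rep(haps, each = 4))
  grp <- rep(c("EU", "IR", "TA"), each = 4)
  a1 <- matrix(rep(c(100L, 120L, 140L), each = 4), 12, 2)
  ms <- microsat_dataset(ids, c("l1", "l2"), a1, a1)
  map <- popmap(ids, grp, lineage = grp)
  ss <- assemble_sumstats(aln, ms, map)
  expect_equal(unname(ss[c("D.EU", "D.IR", "D.TA")]), c(0, 0, 0))
  expect_equal(unname(ss[c("fst.EU.IR", "fst.EU.TA", "fst.IR.TA")]),
               c(1, 1, 1))
  expect_true(all(is.finite(ss)))
})

test_that("under a constant-size neutral coalescent the median Tajima's D is near zero", {
  set.seed(27)
  sc <- build_scenario("S2")
  dr <- refugia:::table4_medians()
  dr$N_EU <- 5000; dr$mu_mt <- 5 / (2 * (2 * 5000 * 0.25) * 2 * 20)
  # theta_locus = 2 * (2 N x) * mu_locus_per_gen = 5 over 20 sites... use
  # direct single-population simulation via huge split times instead
  n <- 20L; L <- 100L
  theta <- 5
  N <- 2000
  mu_site_gen <- theta / (2 * (2 * N * 0.25) * L)
  dr$N_EU <- N; dr$t1_gen <- 1e9; dr$t2_gen <- 2e9
  Ds <- replicate(2000, {
    tr <- simulate_genealogy(c(20, 0, 0), sc, dr, "mtdna")
    a <- mutate_sequence(tr, L, mu_site_gen / dr$gen_time, dr$gen_time)
    suppressWarnings(tajimas_D(a))
  })
  expect_gt(median(Ds, na.rm = TRUE), -0.5)
  expect_lt(median(Ds, na.rm = TRUE), 0.5)
})
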