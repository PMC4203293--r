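# random small datasets used across tests (always under a caller-set seed)

rand_alignment <- function(n, L = 60, poly = 0.2) {
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(rep(base, each = n), n, L)
  npoly <- max(1L, rpois(1, poly * L))
  for (s in sample(L, min(npoly, L))) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), base[s]), 1)
    carriers <- sample(n, sample(1:(n - 1), 1))
    m[carriers, s] <- alt
  }
  alignment(sprintf("s%03d", seq_len(n)),
            apply(m, 1, paste0, collapse = ""))
}

rand_msat <- function(n, nloc = 4, nalleles = 5, miss = 0) {
  a1 <- matrix(sample(100:(99 + nalleles), n * nloc, replace = TRUE), n, nloc)
  a2 <- matrix(sample(100:(99 + nalleles), n * nloc, replace = TRUE), n, nloc)
  if (miss > 0) {
    drop <- matrix(runif(n * nloc) < miss, n, nloc)
    a1[drop] <- NA; a2[drop] <- NA
  }
  microsat_dataset(sprintf("i%03d", seq_len(n)),
                   sprintf("loc%d", seq_len(nloc)), a1, a2)
}

two_deme_map <- function(ids, n1) {
  popmap(ids, rep(c("d1", "d2"), c(n1, length(ids) - n1)))
}

# a toy reference table with hand-made statistics (no simulation):
# statistic block centered at `centers[scenario]` with small noise
toy_table <- function(n_per = 200, centers = c(S1 = 0, S2 = 4, S3 = 8),
                      nstat = 3, noise = 0.5) {
  scen <- rep(names(centers), each = n_per)
  stats <- do.call(rbind, lapply(names(centers), function(s)
    matrix(rnorm(n_per * nstat, centers[[s]], noise), n_per, nstat)))
  colnames(stats) <- paste0("st", seq_len(nstat))
  params <- matrix(exp(rnorm(length(scen) * length(refugia:::param_names()))),
                   ncol = length(refugia:::param_names()),
                   dimnames = list(NULL, refugia:::param_names()))
  reg <- sumstat_registry("combined")
  reg$n_stats <- nstat
  refugia:::new_ref_table(scen, params, stats, reg,
                          scenarios = lapply(names(centers), build_scenario))
}
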