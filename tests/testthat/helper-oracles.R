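# Brute-force oracle implementations, written directly from the published
# formulas with naive loops. They deliberately share no code with the
# package internals.

o_charmat <- function(seqs) {
  do.call(rbind, strsplit(toupper(seqs), ""))
}

# mean pairwise differences, per-site diversity and segregating sites
o_pi_k_S <- function(seqs) {
  m <- o_charmat(seqs)
  n <- nrow(m)
  tot <- 0
  np <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(m[i, ] != m[j, ])
      np <- np + 1
    }
  }
  S <- 0
  for (s in seq_len(ncol(m))) {
    if (length(unique(m[, s])) > 1) S <- S + 1
  }
  k <- tot / np
  list(k = k, pi = k / ncol(m), S = S)
}

o_hap_counts <- function(seqs) as.integer(table(seqs))

o_HD <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

o_HD_sd <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  J2 <- sum(p^2); J3 <- sum(p^3)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (J3 - J2^2) + J2 - J2^2)
  sqrt(max(v, 0))
}

o_tajima <- function(seqs) {
  pk <- o_pi_k_S(seqs)
  n <- length(seqs)
  S <- pk$S
  if (S == 0) return(NaN)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (pk$k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# number of mutations (minimum, alleles - 1 per column) and singleton
# mutations (alleles observed exactly once)
o_eta <- function(seqs) {
  m <- o_charmat(seqs)
  eta <- 0; eta_s <- 0
  for (s in seq_len(ncol(m))) {
    tb <- table(m[, s])
    eta <- eta + length(tb) - 1
    eta_s <- eta_s + sum(tb == 1)
  }
  list(eta = eta, eta_s = eta_s)
}

o_fu_li_Fstar <- function(seqs) {
  n <- length(seqs)
  e <- o_eta(seqs)
  if (e$eta == 0) return(NaN)
  k <- o_pi_k_S(seqs)$k
  an <- sum(1 / seq_len(n - 1))
  bn <- sum(1 / seq_len(n - 1)^2)
  an1 <- an + 1 / n
  vf <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           (2 * (n - 1) * an) / n^2 - (8 * bn) / n) / (an^2 + bn)
  uf <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
           (3 * n * (n - 1))) / an - vf
  (k - ((n - 1) / n) * e$eta_s) / sqrt(uf * e$eta + vf * e$eta^2)
}

o_hudson_fst <- function(seqs1, seqs2) {
  pd <- function(a, b) sum(o_charmat(c(a, b))[1, ] != o_charmat(c(a, b))[2, ])
  wpairs <- function(ss) {
    n <- length(ss); tot <- 0; np <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      tot <- tot + pd(ss[i], ss[j]); np <- np + 1
    }
    tot / np
  }
  hw <- (wpairs(seqs1) + wpairs(seqs2)) / 2
  hb <- 0; np <- 0
  for (i in seq_along(seqs1)) for (j in seq_along(seqs2)) {
    hb <- hb + pd(seqs1[i], seqs2[j]); np <- np + 1
  }
  hb <- hb / np
  if (hb == 0) 0 else 1 - hw / hb
}

# Weir & Cockerham (1984) theta for two demes over several loci.
# geno1/geno2: lists (one entry per locus) of n x 2 allele matrices
# (complete genotypes only).
o_wc_fst <- function(geno1, geno2) {
  num <- 0; den <- 0
  for (l in seq_along(geno1)) {
    g1 <- geno1[[l]]; g2 <- geno2[[l]]
    n1 <- nrow(g1); n2 <- nrow(g2)
    if (n1 < 1 || n2 < 1) next
    nbar <- mean(c(n1, n2))
    if (nbar <= 1) next
    r <- 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    for (al in unique(c(g1, g2))) {
      p1 <- mean(g1 == al); p2 <- mean(g2 == al)
      h1 <- mean(xor(g1[, 1] == al, g1[, 2] == al))
      h2 <- mean(xor(g2[, 1] == al, g2[, 2] == al))
      pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
      a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                            (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                    ((2 * nbar - 1) / (4 * nbar)) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  if (den == 0) 0 else num / den
}

# Three-level AMOVA oracle for one locus from the full O(N^2) distance
# matrix (0/1 allele mismatch), solving the expected-mean-square system
# with solve(). alleles: gene-copy values; deme, grp: parallel labels.
o_amova_locus <- function(alleles, deme, grp) {
  N <- length(alleles)
  if (length(unique(deme)) - length(unique(grp)) <= 0 ||
      length(unique(grp)) < 2 || N - length(unique(deme)) <= 0)
    return(NULL)
  d2 <- outer(alleles, alleles, "!=") * 1
  ssd <- function(sel) sum(d2[sel, sel][upper.tri(d2[sel, sel])]) / sum(sel)
  ss_t <- sum(d2[upper.tri(d2)]) / N
  demes <- unique(deme); groups <- unique(grp)
  P <- length(demes); G <- length(groups)
  ss_wp <- sum(sapply(demes, function(p) ssd(deme == p)))
  ss_wg <- sum(sapply(groups, function(g) ssd(grp == g)))
  df <- c(G - 1, P - G, N - P)
  ssd3 <- c(ss_t - ss_wg, ss_wg - ss_wp, ss_wp)
  ms <- ssd3 / df
  n_p <- sapply(demes, function(p) sum(deme == p))
  n_g <- sapply(groups, function(g) sum(grp == g))
  grp_of_deme <- sapply(demes, function(p) grp[deme == p][1])
  sgd <- sapply(groups, function(g) sum(n_p[grp_of_deme == g]^2) /
                  n_g[groups == g])
  n1 <- (N - sum(sgd)) / df[2]
  n2 <- (sum(sgd) - sum(n_p^2) / N) / df[1]
  n3 <- (N - sum(n_g^2) / N) / df[1]
  # E[MS] = C sigma with sigma = (a, b, c)
  C <- rbind(c(n3, n2, 1),
             c(0, n1, 1),
             c(0, 0, 1))
  sigma <- solve(C, ms)
  names(sigma) <- c("a", "b", "c")
  sigma
}

o_amova <- function(ms_obj, deme_of_ind, grp_of_deme) {
  sig <- c(a = 0, b = 0, c = 0)
  for (l in seq_along(ms_obj$loci)) {
    al <- c(ms_obj$allele1[, l], ms_obj$allele2[, l])
    ind <- rep(seq_along(ms_obj$ids), 2)
    keep <- !is.na(al)
    deme <- deme_of_ind[ind[keep]]
    res <- o_amova_locus(al[keep], deme, unname(grp_of_deme[deme]))
    if (!is.null(res)) sig <- sig + res
  }
  sig
}

# expected rarefied haplotype richness by exhaustive enumeration
o_rarefy_exact <- function(hap_ids, m) {
  subsets <- combn(length(hap_ids), m)
  mean(apply(subsets, 2, function(ix) length(unique(hap_ids[ix]))))
}
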