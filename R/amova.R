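# Per-locus three-level AMOVA machinery on gene copies with the
# allele-identity (0/1 mismatch) distance. With that distance the sum of
# pairwise squared distances within a set of copies is
# (n^2 - sum_a c_a^2) / 2, which lets every SSD be computed from allele
# counts rather than an O(N^2) distance matrix.

sum_pairs_mismatch <- function(counts) {
  n <- sum(counts)
  (n^2 - sum(counts^2)) / 2
}

# variance components for one locus.
# alleles: integer codes per gene copy (no NA); deme, grp: parallel labels.
amova_locus <- function(alleles, deme, grp) {
  N <- length(alleles)
  demes <- unique(deme)
  P <- length(demes)
  groups <- unique(grp)
  G <- length(groups)
  cnt_tot <- tabulate(match(alleles, unique(alleles)))
  ss_t <- sum_pairs_mismatch(cnt_tot) / N
  ss_wp <- 0
  n_p <- numeric(P)
  grp_of_deme <- character(P)
  for (pi in seq_len(P)) {
    sel <- deme == demes[[pi]]
    n_p[[pi]] <- sum(sel)
    grp_of_deme[[pi]] <- grp[sel][[1L]]
    a <- alleles[sel]
    ss_wp <- ss_wp + sum_pairs_mismatch(tabulate(match(a, unique(a)))) /
      n_p[[pi]]
  }
  ss_wg <- 0
  n_g <- numeric(G)
  for (gi in seq_len(G)) {
    sel <- grp == groups[[gi]]
    n_g[[gi]] <- sum(sel)
    a <- alleles[sel]
    ss_wg <- ss_wg + sum_pairs_mismatch(tabulate(match(a, unique(a)))) /
      n_g[[gi]]
  }
  ssd_ag <- ss_t - ss_wg
  ssd_ap <- ss_wg - ss_wp
  ssd_wp <- ss_wp
  df_ag <- G - 1L
  df_ap <- P - G
  df_wp <- N - P
  if (df_ap <= 0L || df_wp <= 0L || df_ag <= 0L) return(NULL)
  # expected-mean-square coefficients for the unbalanced nested design
  sum_np2_by_g <- vapply(groups, function(g) {
    sel <- grp_of_deme == g
    sum(n_p[sel]^2) / n_g[[match(g, groups)]]
  }, 0)
  n1 <- (N - sum(sum_np2_by_g)) / df_ap
  n2 <- (sum(sum_np2_by_g) - sum(n_p^2) / N) / df_ag
  n3 <- (N - sum(n_g^2) / N) / df_ag
  ms_ag <- ssd_ag / df_ag
  ms_ap <- ssd_ap / df_ap
  ms_wp <- ssd_wp / df_wp
  sig_c <- ms_wp
  sig_b <- (ms_ap - sig_c) / n1
  sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
  list(sigma = c(a = sig_a, b = sig_b, c = sig_c),
       df = c(ag = df_ag, ap = df_ap, wp = df_wp),
       ssd = c(ag = ssd_ag, ap = ssd_ap, wp = ssd_wp))
}

# multilocus components: per-locus components summed over loci.
# deme_of_ind: deme label per individual; grp_map: group label named by deme.
amova_components <- function(loci_alleles, deme_of_ind, grp_map) {
  sig <- c(a = 0, b = 0, c = 0)
  df <- c(ag = 0, ap = 0, wp = 0)
  ssd <- c(ag = 0, ap = 0, wp = 0)
  any_locus <- FALSE
  for (la in loci_alleles) {
    keep <- !is.na(la$alleles)
    deme <- deme_of_ind[la$ind[keep]]
    res <- amova_locus(la$alleles[keep], deme,
                       unname(grp_map[deme]))
    if (is.null(res)) next
    sig <- sig + res$sigma
    df <- df + res$df
    ssd <- ssd + res$ssd
    any_locus <- TRUE
  }
  if (!any_locus) stop("no locus with a valid AMOVA design")
  list(sigma = sig, df = df, ssd = ssd)
}

amova_phi <- function(sigma) {
  tot <- sum(sigma)
  c(phi_CT = sigma[["a"]] / tot,
    phi_SC = sigma[["b"]] / (sigma[["b"]] + sigma[["c"]]),
    phi_ST = (sigma[["a"]] + sigma[["b"]]) / tot)
}

#' Three-level analysis of molecular variance (AMOVA)
#'
#' Partitions microsatellite variance among groups, among demes within
#' groups, and within demes, using the allele-identity (0/1 mismatch)
#' distance between gene copies. Phi statistics follow the standard
#' definitions: `phi_CT` (groups vs total), `phi_SC` (demes within groups)
#' and `phi_ST` (demes vs total), with the identity
#' `(1 - phi_CT)(1 - phi_SC) = (1 - phi_ST)`. Loci are analyzed separately
#' (gene copies missing at a locus dropped for that locus) and covariance
#' components summed over loci. Permutation p-values, each
#' `(exceedances + 1) / (permutations + 1)`:
#' `phi_CT` permutes whole demes among groups, `phi_SC` permutes
#' individuals among demes within groups, `phi_ST` permutes individuals
#' among all demes.
#'
#' @param ms a [microsat_dataset()].
#' @param map a [popmap()] with the deme assignment and the grouping axis.
#' @param group_by column of `map` assigning demes to groups.
#' @param n_permutations permutations per test (default 10,000; 0 disables
#'   the tests).
#' @return An object of class `amova` with the variance-component table,
#'   Phi statistics and p-values.
#' @export
amova <- function(ms, map, group_by, n_permutations = 10000L) {
  stopifnot(inherits(ms, "microsat_dataset"))
  deme_all <- map_groups(map, "deme_id")
  grp_all <- map_groups(map, group_by)
  if (!all(ms$ids %in% names(deme_all)))
    stop("population map does not cover all individuals")
  n_ind <- length(ms$ids)
  deme_of_ind <- unname(deme_all[ms$ids])
  demes <- unique(deme_of_ind)
  grp_of_deme <- vapply(demes, function(d)
    unname(grp_all[ms$ids])[deme_of_ind == d][[1L]], "")
  if (length(unique(grp_of_deme)) < 2L)
    stop("need at least two groups")
  grp_map <- setNames(grp_of_deme, demes)
  # per-locus gene copies with their individual of origin
  loci_alleles <- lapply(seq_along(ms$loci), function(l) {
    list(alleles = c(ms$allele1[, l], ms$allele2[, l]),
         ind = rep(seq_len(n_ind), 2L))
  })
  obs <- amova_components(loci_alleles, deme_of_ind, grp_map)
  if (sum(obs$sigma) == 0)
    stop("zero total variance: all gene copies identical")
  phi <- amova_phi(obs$sigma)
  pvals <- c(phi_CT = NA_real_, phi_SC = NA_real_, phi_ST = NA_real_)
  if (n_permutations > 0L) {
    exceed <- c(0L, 0L, 0L)
    for (b in seq_len(n_permutations)) {
      # phi_ST: individuals permuted among all demes
      p_st <- amova_phi(amova_components(
        loci_alleles, sample(deme_of_ind), grp_map)$sigma)[["phi_ST"]]
      # phi_SC: individuals permuted among demes within groups
      deme_sc <- deme_of_ind
      for (g in unique(grp_of_deme)) {
        sel <- grp_map[deme_of_ind] == g
        deme_sc[sel] <- sample(deme_of_ind[sel])
      }
      p_sc <- amova_phi(amova_components(
        loci_alleles, deme_sc, grp_map)$sigma)[["phi_SC"]]
      # phi_CT: whole demes permuted among groups
      grp_perm <- setNames(sample(grp_of_deme), demes)
      p_ct <- amova_phi(amova_components(
        loci_alleles, deme_of_ind, grp_perm)$sigma)[["phi_CT"]]
      exceed <- exceed + c(p_ct >= phi[["phi_CT"]],
                           p_sc >= phi[["phi_SC"]],
                           p_st >= phi[["phi_ST"]])
    }
    pvals <- (exceed + 1) / (n_permutations + 1)
    names(pvals) <- c("phi_CT", "phi_SC", "phi_ST")
  }
  pct <- 100 * obs$sigma / sum(obs$sigma)
  tab <- data.frame(
    level = c("among groups", "among demes within groups", "within demes"),
    df = as.integer(obs$df),
    ssd = as.numeric(obs$ssd),
    sigma = as.numeric(obs$sigma),
    percent = as.numeric(pct),
    stringsAsFactors = FALSE)
  structure(list(table = tab, phi = phi, p_values = pvals,
                 n_permutations = n_permutations, group_by = group_by),
            class = "amova")
}

#' @export
print.amova <- function(x, ...) {
  cat("<amova> grouping axis: ", x$group_by, "\n", sep = "")
  print(x$table, digits = 4L)
  cat(sprintf("phi_CT = %.4f (P = %s), phi_SC = %.4f (P = %s), phi_ST = %.4f (P = %s)\n",
              x$phi[["phi_CT"]], format(x$p_values[["phi_CT"]]),
              x$phi[["phi_SC"]], format(x$p_values[["phi_SC"]]),
              x$phi[["phi_ST"]], format(x$p_values[["phi_ST"]])))
  invisible(x)
}
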