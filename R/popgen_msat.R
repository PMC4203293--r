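# unbiased expected heterozygosity from gene-copy counts
he_unbiased <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  n * (1 - sum(p^2)) / (n - 1)
}

# Weir & Cockerham (1984) variance components for one locus and two demes.
# g1, g2: individuals x 2 allele matrices with complete genotypes.
# Returns c(a, b, c) summed over alleles, or NULL when undefined.
wc_components_locus <- function(g1, g2) {
  n1 <- nrow(g1); n2 <- nrow(g2)
  r <- 2
  nbar <- (n1 + n2) / 2
  if (nbar <= 1) return(NULL)
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  alleles <- sort(unique(c(g1, g2)))
  suma <- 0; sumb <- 0; sumc <- 0
  for (al in alleles) {
    c1 <- sum(g1 == al); c2 <- sum(g2 == al)
    p1 <- c1 / (2 * n1); p2 <- c2 / (2 * n2)
    h1 <- sum((g1[, 1L] == al) != (g1[, 2L] == al)) / n1
    h2 <- sum((g2[, 1L] == al) != (g2[, 2L] == al)) / n2
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    suma <- suma + a; sumb <- sumb + b; sumc <- sumc + cc
  }
  c(a = suma, b = sumb, c = sumc)
}

# multilocus Weir-Cockerham theta (ratio of sums) for two demes;
# idx1/idx2 index individuals in ms
wc_fst_pair <- function(ms, idx1, idx2) {
  suma <- 0; sumall <- 0
  for (l in seq_along(ms$loci)) {
    g1 <- cbind(ms$allele1[idx1, l], ms$allele2[idx1, l])
    g2 <- cbind(ms$allele1[idx2, l], ms$allele2[idx2, l])
    g1 <- g1[stats::complete.cases(g1), , drop = FALSE]
    g2 <- g2[stats::complete.cases(g2), , drop = FALSE]
    if (nrow(g1) < 1L || nrow(g2) < 1L) next
    comp <- wc_components_locus(g1, g2)
    if (is.null(comp)) next
    suma <- suma + comp[["a"]]
    sumall <- sumall + sum(comp)
  }
  if (sumall == 0) return(0)
  suma / sumall
}

#' One- and two-sample microsatellite statistics
#'
#' Per deme: mean (over loci) number of alleles, unbiased expected
#' heterozygosity `He = n (1 - sum p_i^2) / (n - 1)`, and allele-size
#' variance (sample variance over gene copies). Per deme pair: the
#' multilocus Weir-Cockerham FST (ratio of sums over loci and alleles) and
#' the mean squared allele-size difference (delta mu)^2. Loci with fewer
#' than two gene copies in a deme are dropped for that deme's statistics,
#' with a warning when a deme has an all-missing locus.
#'
#' @param ms a [microsat_dataset()].
#' @param map a [popmap()] covering the individuals.
#' @param group_by column of `map` defining the demes (default `deme_id`).
#' @return A list with `per_deme` and `per_pair` data.frames.
#' @export
microsat_stats <- function(ms, map, group_by = "deme_id") {
  stopifnot(inherits(ms, "microsat_dataset"))
  grp <- map_groups(map, group_by)
  if (!all(ms$ids %in% names(grp)))
    stop("population map does not cover all individuals")
  dm <- grp[ms$ids]
  demes <- unique(dm)
  per_deme <- data.frame(deme = demes, mean_alleles = NA_real_,
                         mean_He = NA_real_, mean_size_var = NA_real_,
                         stringsAsFactors = FALSE)
  for (di in seq_along(demes)) {
    idx <- which(dm == demes[[di]])
    A <- He <- V <- rep(NA_real_, length(ms$loci))
    for (l in seq_along(ms$loci)) {
      cp <- gene_copies(ms, idx, l)
      if (length(cp) == 0L) {
        warning("deme ", demes[[di]], " has no data at locus ",
                ms$loci[[l]], "; locus dropped")
        next
      }
      if (length(cp) < 2L) next
      A[[l]] <- length(unique(cp))
      He[[l]] <- he_unbiased(tabulate(match(cp, unique(cp))))
      V[[l]] <- var(cp)
    }
    per_deme$mean_alleles[[di]] <- mean(A, na.rm = TRUE)
    per_deme$mean_He[[di]] <- mean(He, na.rm = TRUE)
    per_deme$mean_size_var[[di]] <- mean(V, na.rm = TRUE)
  }
  pairs <- if (length(demes) >= 2L) combn(demes, 2L) else
    matrix(character(), 2L, 0L)
  per_pair <- data.frame(deme1 = character(0), deme2 = character(0),
                         fst_wc = numeric(0), dmu2 = numeric(0),
                         stringsAsFactors = FALSE)
  for (p in seq_len(ncol(pairs))) {
    i1 <- which(dm == pairs[1L, p]); i2 <- which(dm == pairs[2L, p])
    fst <- wc_fst_pair(ms, i1, i2)
    dd <- vapply(seq_along(ms$loci), function(l) {
      c1 <- gene_copies(ms, i1, l); c2 <- gene_copies(ms, i2, l)
      if (length(c1) == 0L || length(c2) == 0L) return(NA_real_)
      (mean(c1) - mean(c2))^2
    }, 0)
    per_pair <- rbind(per_pair, data.frame(
      deme1 = pairs[1L, p], deme2 = pairs[2L, p],
      fst_wc = fst, dmu2 = mean(dd, na.rm = TRUE),
      stringsAsFactors = FALSE))
  }
  list(per_deme = per_deme, per_pair = per_pair)
}
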