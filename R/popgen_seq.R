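# --- core machinery shared by all sequence statistics ---------------------

# pairwise Hamming differences + segregating columns of an alignment;
# returns list(d, varsites, n, L)
seq_core <- function(aln) {
  m <- aln_raw(aln)
  res <- seq_pairdiff_cpp(m)
  list(d = res$d, varsites = res$varsites, n = nrow(m), L = ncol(m), mat = m)
}

# per-column allele counts at the segregating columns: list of integer
# count vectors
site_allele_counts <- function(mat, varsites) {
  lapply(varsites, function(s) {
    col <- as.integer(mat[, s])
    tabulate(match(col, unique(col)))
  })
}

# Watterson / Tajima constants for sample size n
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

# Tajima's D from sufficient statistics; NaN when S == 0
tajima_D_core <- function(n, S, k) {
  if (S == 0L) return(NaN)
  cc <- tajima_constants(n)
  (k - S / cc$a1) / sqrt(cc$e1 * S + cc$e2 * S * (S - 1))
}

# Fu & Li's F* from sufficient statistics (eta = total mutations, eta_s =
# singleton mutations), with the corrected u/v weights (Simonsen et al. 1995)
fu_li_Fstar_core <- function(n, eta, eta_s, k) {
  if (eta == 0) return(NaN)
  i <- seq_len(n - 1L)
  an <- sum(1 / i)
  bn <- sum(1 / i^2)
  an1 <- an + 1 / n
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           2 * (n - 1) * an / n^2 - 8 * bn / n) / (an^2 + bn)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
           (3 * n * (n - 1))) / an - vF
  (k - ((n - 1) / n) * eta_s) / sqrt(uF * eta + vF * eta^2)
}

# Fu & Li's F (outgroup variant) from sufficient statistics; eta_e = derived
# singleton mutations polarized by the outgroup
fu_li_F_outgroup_core <- function(n, eta, eta_e, k) {
  if (eta == 0) return(NaN)
  i <- seq_len(n - 1L)
  an <- sum(1 / i)
  bn <- sum(1 / i^2)
  an1 <- an + 1 / n
  cn <- if (n == 2L) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) /
    (an^2 + bn)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
           4 * ((n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / an - vF
  (k - eta_e) / sqrt(uF * eta + vF * eta^2)
}

# --- user-facing operations ------------------------------------------------

#' Collapse an alignment into haplotypes
#'
#' Exact string identity defines a haplotype. When a population map is
#' supplied, per-deme haplotype counts are returned as well.
#'
#' @param aln a [alignment()], already filtered of ambiguity codes.
#' @param map optional [popmap()] covering the alignment samples.
#' @return An object of class `haplotype_table`: `haplotypes` (sequences in
#'   order of first appearance), `counts` (total count per haplotype),
#'   `deme_counts` (haplotype x deme matrix or `NULL`), `H_n`, `H_ind`.
#' @export
collapse_haplotypes <- function(aln, map = NULL) {
  stopifnot(inherits(aln, "sequence_alignment"))
  if (length(aln$ids) == 0L) stop("empty alignment")
  haps <- unique(aln$seq)
  hid <- match(aln$seq, haps)
  counts <- tabulate(hid, nbins = length(haps))
  deme_counts <- NULL
  if (!is.null(map)) {
    grp <- map_groups(map, "deme_id")
    if (!all(aln$ids %in% names(grp)))
      stop("population map does not cover all alignment samples")
    dm <- grp[aln$ids]
    demes <- unique(dm)
    deme_counts <- vapply(demes, function(d)
      tabulate(hid[dm == d], nbins = length(haps)),
      integer(length(haps)))
    if (is.null(dim(deme_counts)))
      deme_counts <- matrix(deme_counts, ncol = length(demes))
    colnames(deme_counts) <- demes
  }
  structure(list(haplotypes = haps, counts = counts,
                 deme_counts = deme_counts,
                 H_n = length(haps), H_ind = length(aln$ids)),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("<haplotype_table> H_n = ", x$H_n, " haplotypes among H_ind = ",
      x$H_ind, " individuals\n", sep = "")
  invisible(x)
}

#' Nucleotide diversity, mean pairwise differences and segregating sites
#'
#' `k` is the average number of nucleotide differences over all unordered
#' sequence pairs, `pi = k / L` the per-site nucleotide diversity, and `S`
#' the number of polymorphic columns. The standard deviation of `pi` is the
#' total (sampling + evolutionary) variance under the neutral
#' no-recombination model.
#'
#' @param aln a [alignment()] with at least two sequences.
#' @return A list with `pi`, `k`, `S`, `pi_sd`, `n` and `length`.
#' @export
nucleotide_diversity <- function(aln) {
  stopifnot(inherits(aln, "sequence_alignment"))
  n <- length(aln$ids)
  if (n < 2L) stop("need at least two sequences")
  core <- seq_core(aln)
  k <- sum(core$d) / (n * (n - 1))
  pi <- k / aln$length
  S <- length(core$varsites)
  v <- (n + 1) * pi / (3 * (n - 1) * aln$length) +
    2 * (n^2 + n + 3) * pi^2 / (9 * n * (n - 1))
  list(pi = pi, k = k, S = S, pi_sd = sqrt(v), n = n, length = aln$length)
}

#' Haplotype diversity (Nei's unbiased gene diversity)
#'
#' `HD = n (1 - sum p_i^2) / (n - 1)` with sampling standard deviation from
#' Nei (1987).
#'
#' @param x a [alignment()], a [collapse_haplotypes()] table, or a vector of
#'   haplotype counts.
#' @return A list with `HD`, `sd` and `n`.
#' @export
haplotype_diversity <- function(x) {
  counts <- if (inherits(x, "sequence_alignment")) {
    collapse_haplotypes(x)$counts
  } else if (inherits(x, "haplotype_table")) {
    x$counts
  } else {
    as.numeric(x)
  }
  n <- sum(counts)
  if (n < 2) stop("need at least two individuals")
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  HD <- n * (1 - s2) / (n - 1)
  v <- (2 / (n * (n - 1))) *
    (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(HD = HD, sd = sqrt(max(v, 0)), n = n)
}

#' Tajima's D
#'
#' Mutation-drift equilibrium test contrasting mean pairwise differences
#' against the Watterson estimate from segregating sites.
#'
#' @param aln a [alignment()]; at least 4 sequences recommended.
#' @return The D statistic; `NaN` (with a warning) when there is no
#'   polymorphism.
#' @export
tajimas_D <- function(aln) {
  stopifnot(inherits(aln, "sequence_alignment"))
  n <- length(aln$ids)
  if (n < 2L) stop("need at least two sequences")
  core <- seq_core(aln)
  S <- length(core$varsites)
  if (S == 0L) {
    warning("no segregating sites: Tajima's D undefined")
    return(NaN)
  }
  k <- sum(core$d) / (n * (n - 1))
  tajima_D_core(n, S, k)
}

#' Fu and Li's F
#'
#' Contrasts mean pairwise differences against the number of singleton
#' mutations. The default `star` variant (F*) needs no outgroup and counts
#' alleles carried by a single sequence; the `outgroup` variant polarizes
#' singletons against a supplied outgroup sequence.
#'
#' @param aln a [alignment()].
#' @param variant `"star"` (default) or `"outgroup"`.
#' @param outgroup a single DNA string of alignment length (required for the
#'   outgroup variant; the outgroup is not part of `aln`).
#' @return The F (or F*) statistic; `NaN` with a warning when there is no
#'   polymorphism.
#' @export
fu_li_F <- function(aln, variant = c("star", "outgroup"), outgroup = NULL) {
  stopifnot(inherits(aln, "sequence_alignment"))
  variant <- match.arg(variant)
  n <- length(aln$ids)
  if (n < 2L) stop("need at least two sequences")
  core <- seq_core(aln)
  counts <- site_allele_counts(core$mat, core$varsites)
  eta <- sum(vapply(counts, function(cc) length(cc) - 1L, 0L))
  if (eta == 0L) {
    warning("no segregating sites: Fu & Li's F undefined")
    return(NaN)
  }
  k <- sum(core$d) / (n * (n - 1))
  if (variant == "star") {
    eta_s <- sum(vapply(counts, function(cc) sum(cc == 1L), 0L))
    return(fu_li_Fstar_core(n, eta, eta_s, k))
  }
  if (is.null(outgroup))
    stop("outgroup sequence required for the outgroup variant")
  outgroup <- toupper(outgroup)
  if (nchar(outgroup) != aln$length)
    stop("outgroup length does not match the alignment")
  eta_e <- 0L
  for (s in core$varsites) {
    col <- rawToChar(core$mat[, s], multiple = TRUE)
    tab <- table(col)
    singles <- names(tab)[tab == 1L]
    anc <- substr(outgroup, s, s)
    eta_e <- eta_e + sum(singles != anc)
  }
  fu_li_F_outgroup_core(n, eta, eta_e, k)
}

#' Hudson's FST for sequence data
#'
#' `1 - Hw / Hb` where `Hw` is the mean within-deme pairwise difference
#' (averaged over the two demes) and `Hb` the mean between-deme pairwise
#' difference. Slightly negative values can arise by sampling; the raw value
#' is returned here, and clamped to \[0, 1\] only inside the ABC statistic
#' registry.
#'
#' @param aln a [alignment()].
#' @param map a [popmap()] covering the alignment samples.
#' @param demes character vector of two deme ids.
#' @return The FST estimate (0 when both demes carry identical monomorphic
#'   pools).
#' @export
hudson_fst <- function(aln, map, demes) {
  stopifnot(inherits(aln, "sequence_alignment"), length(demes) == 2L)
  grp <- map_groups(map, "deme_id")
  dm <- grp[aln$ids]
  i1 <- which(dm == demes[[1L]])
  i2 <- which(dm == demes[[2L]])
  if (length(i1) == 0L || length(i2) == 0L)
    stop("deme absent from alignment: ", demes[[1L]], " / ", demes[[2L]])
  if (length(i1) < 2L || length(i2) < 2L)
    stop("both demes need at least two sequences")
  d <- seq_core(aln)$d
  hudson_fst_core(d, i1, i2)
}

hudson_fst_core <- function(d, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  hw <- (sum(d[i1, i1]) / (n1 * (n1 - 1)) +
           sum(d[i2, i2]) / (n2 * (n2 - 1))) / 2
  hb <- mean(d[i1, i2])
  if (hb == 0) return(0)
  1 - hw / hb
}
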