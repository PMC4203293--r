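# null distribution of (D, F*) conditional on the number of segregating
# sites: neutral constant-size coalescent trees with S mutations placed
# multinomially on branches by length. Returns a reps x 2 matrix.
neutrality_null <- function(n, S, reps = 1000L) {
  out <- matrix(NA_real_, reps, 2L, dimnames = list(NULL, c("D", "Fstar")))
  for (r in seq_len(reps)) {
    tr <- coal_tree_cpp(n, 1, 1, numeric(0), integer(0), integer(0),
                        numeric(0))
    parent <- tr$parent; tt <- tr$time
    nn <- length(parent)
    blen <- ifelse(parent >= 0L, tt[parent + 1L] - tt, 0)
    # subtree tip counts per node (nodes are created in time order, so a
    # single pastward pass accumulates children before parents)
    sz <- c(rep(1L, n), integer(nn - n))
    for (i in seq_len(nn)) {
      if (parent[[i]] >= 0L) sz[parent[[i]] + 1L] <- sz[parent[[i]] + 1L] + sz[[i]]
    }
    branches <- which(parent >= 0L)
    muts <- as.integer(stats::rmultinom(1L, S,
                                        prob = blen[branches]))
    xi <- tabulate(rep(sz[branches], muts), nbins = n - 1L)
    k <- sum(xi * seq_len(n - 1L) * (n - seq_len(n - 1L))) / choose(n, 2L)
    eta_s <- xi[[1L]] + if (n > 2L) xi[[n - 1L]] else 0L
    out[r, 1L] <- tajima_D_core(n, S, k)
    out[r, 2L] <- fu_li_Fstar_core(n, S, eta_s, k)
  }
  out
}

sim_pvalue <- function(obs, null) {
  lo <- (sum(null <= obs) + 1) / (length(null) + 1)
  hi <- (sum(null >= obs) + 1) / (length(null) + 1)
  min(1, 2 * min(lo, hi))
}

# two-sided p for Tajima's D via the beta approximation over [Dmin, Dmax]
tajima_beta_p <- function(D, n) {
  cc <- tajima_constants(n)
  Dmin <- (2 / n - 1 / cc$a1) / sqrt(cc$e2)
  Dmax <- ((n + 1) / (2 * n) - 1 / cc$a1) / sqrt(cc$e2)
  tmp1 <- 1 + Dmin * Dmax
  tmp2 <- Dmax - Dmin
  a <- -tmp1 * Dmax / tmp2
  b <- tmp1 * Dmin / tmp2
  p <- pbeta((D - Dmin) / tmp2, b, a)
  min(1, 2 * min(p, 1 - p))
}

stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Diversity table by grouping axis
#'
#' One row per group plus a pooled `All` row, mirroring the layout of
#' lineage/region diversity tables: nucleotide diversity with SD, sample
#' size, haplotype number, haplotype diversity with SD, mean pairwise
#' differences, Tajima's D and Fu & Li's F* with significance stars
#' (`*` P < 0.05, `**` P < 0.01). D significance uses the beta
#' approximation; F* uses a coalescent null conditional on the observed
#' number of segregating sites. Every cell is a composition of the
#' package's statistic functions. Groups with fewer than two sequences are
#' skipped with a warning.
#'
#' @param aln a filtered, concatenated [alignment()].
#' @param map a [popmap()] covering the samples.
#' @param group_by grouping axis column of `map`.
#' @param f_reps replicates for the F* null (0 disables significance for
#'   F*).
#' @return A data.frame of class `diversity_report`.
#' @export
diversity_table <- function(aln, map, group_by = "deme_id",
                            f_reps = 1000L) {
  grp <- map_groups(map, group_by)
  if (!all(aln$ids %in% names(grp)))
    stop("population map does not cover all alignment samples")
  dm <- grp[aln$ids]
  groups <- unique(dm)
  rows <- list()
  for (g in c(as.list(groups), list(NULL))) {
    idx <- if (is.null(g)) seq_along(aln$ids) else which(dm == g)
    label <- if (is.null(g)) "All" else g
    if (length(idx) < 2L) {
      warning("group ", label, " has fewer than two sequences; skipped")
      next
    }
    sub <- subset_alignment(aln, idx)
    nd <- nucleotide_diversity(sub)
    hd <- haplotype_diversity(sub)
    hn <- collapse_haplotypes(sub)$H_n
    D <- suppressWarnings(tajimas_D(sub))
    FF <- suppressWarnings(fu_li_F(sub))
    Dp <- if (is.finite(D)) tajima_beta_p(D, nd$n) else NA_real_
    Fp <- NA_real_
    if (is.finite(FF) && f_reps > 0L) {
      null <- neutrality_null(nd$n, nd$S, f_reps)
      Fp <- sim_pvalue(FF, null[, "Fstar"])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group = label, pi = nd$pi, pi_sd = nd$pi_sd, H_ind = nd$n, H_n = hn,
      HD = hd$HD, HD_sd = hd$sd, k = nd$k,
      tajima_D = D, tajima_sig = stars(Dp),
      fu_li_F = FF, fu_li_sig = stars(Fp),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diversity_report", "data.frame")
  out
}

#' Haplotype rarefaction
#'
#' Mean and SD of the number of distinct haplotypes among `n_subsample`
#' individuals drawn without replacement, over `n_permutations` draws. Used
#' to compare haplotype richness with studies of smaller sample size.
#'
#' @param aln a [alignment()].
#' @param n_subsample individuals per draw (at most the sample size).
#' @param n_permutations number of draws (default 10,000).
#' @return A list with `mean`, `sd`, `n_subsample`, `n_permutations`.
#' @export
rarefy_haplotypes <- function(aln, n_subsample, n_permutations = 10000L) {
  stopifnot(inherits(aln, "sequence_alignment"))
  n <- length(aln$ids)
  if (n_subsample < 1L) stop("n_subsample must be at least 1")
  if (n_subsample > n) stop("n_subsample exceeds the sample size")
  hid <- match(aln$seq, unique(aln$seq))
  counts <- vapply(seq_len(n_permutations), function(r)
    length(unique(hid[sample.int(n, n_subsample)])), 0L)
  list(mean = mean(counts), sd = sd(counts),
       n_subsample = n_subsample, n_permutations = n_permutations)
}

parse_windows <- function(windows) {
  if (is.character(windows)) {
    parts <- strsplit(windows, ",", fixed = TRUE)[[1L]]
    m <- do.call(rbind, lapply(parts, function(p) {
      ab <- as.integer(strsplit(trimws(p), "-", fixed = TRUE)[[1L]])
      if (length(ab) != 2L || anyNA(ab)) stop("malformed window: ", p)
      ab
    }))
  } else {
    m <- as.matrix(windows)
  }
  if (ncol(m) != 2L || any(m[, 1L] > m[, 2L]))
    stop("windows must be start-end pairs with start <= end")
  m
}

#' Trim sequences to fragment windows and count lost haplotypes
#'
#' Cuts every sequence to the concatenation of 1-based inclusive windows on
#' the reference alignment, collapses to haplotypes, and reports how many
#' haplotypes are lost relative to the full-length alignment. This is the
#' in-silico check that a shorter sequenced fragment retains the power to
#' distinguish published haplotypes.
#'
#' @param aln the reference [alignment()] (typically one sequence per
#'   published haplotype).
#' @param windows `"start-end,start-end"` string or a two-column matrix of
#'   1-based inclusive coordinates.
#' @return A list with `n_before`, `n_after`, `n_lost` and `trimmed` (the
#'   trimmed alignment).
#' @export
trim_and_collapse <- function(aln, windows) {
  stopifnot(inherits(aln, "sequence_alignment"))
  w <- parse_windows(windows)
  if (any(w < 1L) || any(w > aln$length))
    stop("window out of range for alignment of length ", aln$length)
  trim <- vapply(aln$seq, function(s)
    paste0(substring(s, w[, 1L], w[, 2L]), collapse = ""), "",
    USE.NAMES = FALSE)
  before <- length(unique(aln$seq))
  after <- length(unique(trim))
  list(n_before = before, n_after = after, n_lost = before - after,
       trimmed = alignment(aln$ids, trim))
}

#' Convert isolation-with-migration outputs to natural units
#'
#' Converts a mutation-scaled population parameter and divergence time to
#' effective size and years: `N_e = theta / (4 u)` and `t_years = t / u`,
#' with `u` the per-locus per-year mutation rate.
#'
#' @param theta mutation-scaled population size(s).
#' @param t divergence time(s) in coalescent (mutation) units; `NA` when
#'   not applicable.
#' @param u per-locus per-year mutation rate (> 0).
#' @return A data.frame with `theta`, `t`, `u`, `N_e`, `t_years`.
#' @export
convert_ima2 <- function(theta, t = NA_real_, u) {
  if (any(u <= 0)) stop("mutation rate u must be positive")
  if (any(theta < 0, na.rm = TRUE)) stop("theta must be non-negative")
  data.frame(theta = theta, t = t, u = u,
             N_e = theta / (4 * u), t_years = t / u)
}
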