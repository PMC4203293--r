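#' Summary-statistic registry
#'
#' The ABC reference table and observed data are summarized with a fixed,
#' versioned vector of statistics over the three analysis groups (and their
#' three pairs). The combined registry has exactly 30 components:
#'
#' * mtDNA, per group: haplotype number `Hn`, haplotype diversity `HD`,
#'   nucleotide diversity `pi`, Tajima's `D` (12 statistics);
#' * mtDNA, per pair: between-group mean pairwise differences `kb` and
#'   Hudson `fst` (6);
#' * microsatellites, per group: mean allele count `A` and expected
#'   heterozygosity `He` (6);
#' * microsatellites, per pair: Weir-Cockerham `fstw` and Goldstein's
#'   `(delta mu)^2` mean squared allele-size difference `dmu2` (6).
#'
#' The two-sample microsatellite pair combines a drift-sensitive statistic
#' (FST) with a mutation-clock statistic: under stepwise mutation the
#' expectation of `(delta mu)^2` grows linearly with divergence time
#' regardless of population size, which is what separates scenarios that
#' differ only in when a lineage split.
#'
#' The mtDNA-only registry drops the microsatellite block and the three
#' between-group `kb` statistics (15 components); the microsatellite-only
#' registry is the 12-component block.
#'
#' @param type `"combined"` (30 statistics), `"mtdna"` (15) or
#'   `"microsat"` (12).
#' @return An object of class `sumstat_registry` with `id`, `type`,
#'   `needs_seq`, `needs_ms` and `n_stats`.
#' @export
sumstat_registry <- function(type = c("combined", "mtdna", "microsat")) {
  type <- match.arg(type)
  structure(list(id = paste0(type, "-v1"), type = type,
                 needs_seq = type != "microsat",
                 needs_ms = type != "mtdna",
                 n_stats = c(combined = 30L, mtdna = 15L,
                             microsat = 12L)[[type]]),
            class = "sumstat_registry")
}

registry_names <- function(registry, groups) {
  g <- sort(groups)
  pr <- combn(g, 2L)
  pn <- paste(pr[1L, ], pr[2L, ], sep = ".")
  nm <- character(0)
  if (registry$needs_seq) {
    nm <- c(nm, as.vector(outer(c("Hn", "HD", "pi", "D"), g, paste,
                                sep = ".")))
    if (registry$type == "combined")
      nm <- c(nm, as.vector(rbind(paste0("kb.", pn), paste0("fst.", pn))))
    else
      nm <- c(nm, paste0("fst.", pn))
  }
  if (registry$needs_ms) {
    nm <- c(nm, as.vector(outer(c("A", "He"), g, paste, sep = ".")))
    nm <- c(nm, as.vector(rbind(paste0("fstw.", pn), paste0("dmu2.", pn))))
  }
  nm
}

# degenerate-case sentinels used only inside ABC vectors: an undefined
# neutrality statistic (S = 0) maps to 0, Hudson FST is clamped to [0, 1]
abc_sentinel_D <- function(x) if (is.finite(x)) x else 0
abc_clamp01 <- function(x) min(max(x, 0), 1)

#' Assemble the ABC summary-statistic vector
#'
#' Computes the registry's statistics over the three analysis groups of a
#' dataset. Group slots are determined by sorted group labels, so permuting
#' the input order of demes leaves the vector unchanged. Degenerate
#' statistics are mapped to defined sentinels (monomorphic Tajima's D to 0;
#' Hudson FST clamped to \[0, 1\]) so that ABC distances stay finite.
#'
#' @param aln a [alignment()] (required unless the registry is
#'   microsatellite-only).
#' @param ms a [microsat_dataset()] (required unless the registry is
#'   mtDNA-only).
#' @param map a [popmap()] covering all samples.
#' @param registry a [sumstat_registry()].
#' @param group_by column of `map` assigning samples to the three analysis
#'   groups (default `"lineage"` when present, else `"deme_id"`).
#' @return A named numeric vector of length `registry$n_stats`.
#' @export
assemble_sumstats <- function(aln = NULL, ms = NULL, map,
                              registry = sumstat_registry("combined"),
                              group_by = NULL) {
  stopifnot(inherits(registry, "sumstat_registry"))
  if (is.null(group_by))
    group_by <- if ("lineage" %in% names(map)) "lineage" else "deme_id"
  if (registry$needs_seq && is.null(aln))
    stop("registry '", registry$id, "' requires a sequence alignment")
  if (registry$needs_ms && is.null(ms))
    stop("registry '", registry$id, "' requires microsatellite data")
  grp <- map_groups(map, group_by)
  groups <- sort(unique(grp))
  if (length(groups) != 3L)
    stop("expected exactly three analysis groups, found ", length(groups))
  pr <- combn(groups, 2L)
  out <- numeric(0)
  if (registry$needs_seq) {
    dm <- grp[aln$ids]
    core <- seq_core(aln)
    idx <- lapply(groups, function(g) which(dm == g))
    if (any(vapply(idx, length, 0L) < 2L))
      stop("every group needs at least two sequences")
    for (gi in seq_along(groups)) {
      i <- idx[[gi]]
      ng <- length(i)
      sub <- core$mat[i, , drop = FALSE]
      vs <- seq_pairdiff_cpp(sub)
      Sg <- length(vs$varsites)
      kg <- sum(core$d[i, i]) / (ng * (ng - 1))
      seqs_g <- aln$seq[i]
      cnt <- tabulate(match(seqs_g, unique(seqs_g)))
      out <- c(out, length(cnt),
               he_unbiased(cnt),
               kg / aln$length,
               abc_sentinel_D(tajima_D_core(ng, Sg, kg)))
    }
    for (p in seq_len(ncol(pr))) {
      i1 <- idx[[match(pr[1L, p], groups)]]
      i2 <- idx[[match(pr[2L, p], groups)]]
      kb <- mean(core$d[i1, i2])
      fst <- abc_clamp01(hudson_fst_core(core$d, i1, i2))
      out <- if (registry$type == "combined") c(out, kb, fst) else c(out, fst)
    }
  }
  if (registry$needs_ms) {
    gidx <- match(unname(grp[ms$ids]), groups) - 1L
    if (anyNA(gidx)) stop("population map does not cover all individuals")
    st <- msat_sumstats_cpp(ms$allele1, ms$allele2, gidx, 3L)
    block <- c(as.vector(t(st$per_group[, 1:2, drop = FALSE])),
               as.vector(rbind(st$fst, st$dmu2)))
    block[!is.finite(block)] <- 0  # degenerate (no-data) sentinel
    out <- c(out, block)
  }
  names(out) <- registry_names(registry, groups)
  stopifnot(length(out) == registry$n_stats)
  out
}
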