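# posterior medians of the two-source scenario, used as the default truth
# for study-shaped synthetic data
table4_medians <- function(gen_time = 2) {
  structure(list(N_EU = 1.05e6, N_IR = 2.48e4, N_TA = 1.0e5,
                 N_ANC = 4.88e4, mu_mt = 6.37e-8, mu_ms = 1.0e-4,
                 gsm_p = 0.22, t1_yr = 8320, t2_yr = 14500,
                 gen_time = gen_time, t1_gen = 8320 / gen_time,
                 t2_gen = 14500 / gen_time),
            class = "parameter_draw")
}

#' Generate a study-shaped dataset with known ground truth
#'
#' Emulates the shape of the empirical study: three lineages sampled over
#' many small demes, with mtDNA sequenced for a random half of the
#' genotyped individuals (mirroring partial overlap of the two marker
#' sets). Data are simulated under the two-source scenario at its posterior
#' medians unless overridden. At `small` scale: 12 demes (4 per lineage) of
#' 10 individuals, 9 loci, 120 genotyped and 60 sequenced individuals. At
#' `paper` scale: 69 demes with 4-30 individuals each.
#'
#' @param seed integer seed; the same seed regenerates the dataset
#'   byte-identically.
#' @param scale `"small"` or `"paper"`.
#' @param scenario scenario label for the truth (default `"S2"`).
#' @param params optional `parameter_draw` overriding the default truth.
#' @return A list with `data` (a `simulated_dataset` whose map has `deme_id`
#'   and `lineage` axes and a `sequenced` flag) and `truth` (scenario,
#'   parameters, seed, design).
#' @export
generate_study_like <- function(seed = 1L, scale = c("small", "paper"),
                                scenario = "S2", params = NULL) {
  scale <- match.arg(scale)
  set.seed(seed)
  sc <- build_scenario(scenario)
  dr <- if (is.null(params)) table4_medians() else params
  if (scale == "small") {
    demes_per_group <- 4L
    deme_sizes <- rep(10L, 3L * demes_per_group)
  } else {
    demes_per_group <- 23L
    deme_sizes <- sample(4:30, 3L * demes_per_group, replace = TRUE)
  }
  groups <- c("EU", "IR", "TA")
  deme_group <- rep(groups, each = length(deme_sizes) / 3L)
  n_ind <- vapply(groups, function(g) sum(deme_sizes[deme_group == g]), 0L)
  seq_flag <- unlist(lapply(deme_sizes, function(k) {
    f <- rep(FALSE, k)
    f[sample.int(k, k %/% 2L)] <- TRUE
    f
  }))
  n_seq <- vapply(groups, function(g)
    sum(seq_flag[rep(deme_group, deme_sizes) == g]), 0L)
  design <- sim_design(n_seq = n_seq, n_ind = n_ind)
  ds <- simulate_dataset(sc, dr, design)
  # reassign individuals to demes within their group and rename
  deme_id <- character(sum(n_ind))
  new_ids <- character(sum(n_ind))
  grp_of <- rep(deme_group, deme_sizes)
  pos <- 1L
  for (di in seq_along(deme_sizes)) {
    k <- deme_sizes[[di]]
    deme <- sprintf("%s%02d", deme_group[[di]], ((di - 1L) %%
                                                   (length(deme_sizes) / 3L)) + 1L)
    deme_id[pos:(pos + k - 1L)] <- deme
    new_ids[pos:(pos + k - 1L)] <- sprintf("%s_i%02d", deme, seq_len(k))
    pos <- pos + k
  }
  # order individuals by group to line up with the simulated dataset
  ord <- order(match(grp_of, groups))
  map <- popmap(new_ids[ord], deme_id[ord], lineage = grp_of[ord],
                sequenced = as.character(seq_flag[ord]))
  old_ids <- ds$map$sample_id
  ds$ms$ids <- map$sample_id
  rownames(ds$ms$allele1) <- rownames(ds$ms$allele2) <- map$sample_id
  # sequenced individuals take the simulated sequences, in group order
  seq_ids <- map$sample_id[map$sequenced == "TRUE"]
  ds$aln <- alignment(seq_ids, ds$aln$seq)
  ds$map <- map
  truth <- list(scenario = scenario, params = dr, seed = seed,
                design = design, deme_sizes = deme_sizes,
                deme_group = deme_group)
  list(data = ds, truth = truth)
}

#' Deterministic edge-case fixtures
#'
#' Small datasets hitting statistic boundaries: a monomorphic sample
#' (`HD = 0`, `pi = 0`), an all-unique sample (`HD = 1`), or two demes
#' fixed for different haplotypes and alleles (`Hudson FST = 1`,
#' `phi_ST = 1`).
#'
#' @param kind `"monomorphic"`, `"all_unique"` or `"two_group_fixed"`.
#' @param n individuals (per deme for `two_group_fixed`); at least 2.
#' @return A list with `aln`, `ms` and `map` (as in `simulated_dataset`).
#' @export
generate_null_fixture <- function(kind = c("monomorphic", "all_unique",
                                           "two_group_fixed"), n = 10L) {
  kind <- match.arg(kind)
  if (n < 2L) stop("n must be at least 2")
  L <- 40L
  base <- strrep("ACGT", L / 4L)
  if (kind == "monomorphic") {
    ids <- sprintf("m%02d", seq_len(n))
    aln <- alignment(ids, rep(base, n))
    ms <- microsat_dataset(ids, c("loc1", "loc2"),
                           matrix(150L, n, 2L), matrix(150L, n, 2L))
    map <- popmap(ids, rep("d1", n))
  } else if (kind == "all_unique") {
    ids <- sprintf("u%02d", seq_len(n))
    seqs <- vapply(seq_len(n), function(i) {
      s <- base
      substr(s, i, i) <- chartr("ACGT", "CGTA", substr(s, i, i))
      s
    }, "")
    aln <- alignment(ids, seqs)
    ms <- microsat_dataset(ids, c("loc1", "loc2"),
                           matrix(100L + seq_len(n), n, 2L),
                           matrix(100L + seq_len(n), n, 2L))
    map <- popmap(ids, rep("d1", n))
  } else {
    ids <- c(sprintf("a%02d", seq_len(n)), sprintf("b%02d", seq_len(n)))
    alt <- chartr("ACGT", "TGCA", base)
    aln <- alignment(ids, c(rep(base, n), rep(alt, n)))
    ms <- microsat_dataset(ids, c("loc1", "loc2"),
                           matrix(rep(c(100L, 200L), each = n), 2L * n, 2L),
                           matrix(rep(c(100L, 200L), each = n), 2L * n, 2L))
    map <- popmap(ids, rep(c("d1", "d2"), each = n))
  }
  structure(list(aln = aln, ms = ms, map = map),
            class = "simulated_dataset")
}
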