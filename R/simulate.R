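#' Sampling design for simulated datasets
#'
#' @param n_seq mtDNA sequences per group (length 1 or 3; order EU, IR, TA).
#' @param n_ind microsatellite-genotyped individuals per group.
#' @param n_loci number of microsatellite loci.
#' @param seq_length mtDNA alignment length in bp (composite cyt B +
#'   control region default).
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_seq = 20L, n_ind = 20L, n_loci = 9L,
                       seq_length = 1029L) {
  out <- list(n_seq = rep(as.integer(n_seq), length.out = 3L),
              n_ind = rep(as.integer(n_ind), length.out = 3L),
              n_loci = as.integer(n_loci),
              seq_length = as.integer(seq_length))
  names(out$n_seq) <- names(out$n_ind) <- c("EU", "IR", "TA")
  stopifnot(all(out$n_seq >= 0L), all(out$n_ind >= 0L))
  structure(out, class = "sim_design")
}

#' Simulate a coalescent genealogy under a scenario
#'
#' Standard n-coalescent within each branch, with pairwise coalescence rate
#' `choose(j, 2) / (2 N x)` per generation, where `x` is the inheritance
#' scalar: 0.25 for mtDNA (maternally inherited, effectively haploid) and 1
#' for autosomal microsatellite loci. Lineage groups are merged pastward at
#' the scenario's event times. Uses R's RNG stream.
#'
#' @param samples_per_group number of sampled lineages (gene copies) per
#'   group; length 1 or 3 in order EU, IR, TA.
#' @param scenario a [build_scenario()] object.
#' @param draw a [draw_parameters()] draw.
#' @param locus_mode `"mtdna"` or `"autosomal"`.
#' @return A list of class `coal_tree`: `parent` and `time` arrays over the
#'   `2n - 1` nodes (times in generations, tips at 0), `tip_group` labels,
#'   `n_tip`.
#' @export
simulate_genealogy <- function(samples_per_group, scenario, draw,
                               locus_mode = c("mtdna", "autosomal")) {
  locus_mode <- match.arg(locus_mode)
  stopifnot(inherits(scenario, "demographic_scenario"),
            inherits(draw, "parameter_draw"))
  n <- rep(as.integer(samples_per_group), length.out = 3L)
  if (any(n < 0L) || sum(n) < 2L)
    stop("need at least two sampled lineages in total")
  x <- if (locus_mode == "mtdna") 0.25 else 1
  groups <- scenario$groups
  N <- c(draw$N_EU, draw$N_IR, draw$N_TA)
  ev_time <- c(draw$t1_gen, draw$t2_gen)
  ev_from <- ev_to <- integer(2L)
  ev_newN <- numeric(2L)
  for (i in 1:2) {
    mg <- scenario$merges[[i]]
    ev_from[[i]] <- match(mg$from, groups) - 1L
    ev_to[[i]] <- match(mg$to, groups) - 1L
    ev_newN[[i]] <- if (is.na(mg$newN)) -1 else draw[[mg$newN]]
  }
  tr <- coal_tree_cpp(n, N, x, ev_time, ev_from, ev_to, ev_newN)
  structure(list(parent = tr$parent, time = tr$time,
                 tip_group = groups[tr$tip_group + 1L],
                 n_tip = tr$n_tip, locus_mode = locus_mode),
            class = "coal_tree")
}

#' Drop mutations on a genealogy and return tip sequences
#'
#' Mutations fall as a Poisson process at rate `mu_site_year * length` per
#' branch-year; each applies a two-parameter substitution kernel with
#' transition/transversion ratio `kappa` over a uniform stationary base
#' composition.
#'
#' @param tree a [simulate_genealogy()] tree (times in generations).
#' @param length sequence length in bp.
#' @param mu_site_year mutation rate per site per year.
#' @param gen_time generation time in years used to convert branch lengths.
#' @param kappa transition/transversion rate ratio (default 3).
#' @param ids sample identifiers for the tips (defaults to group-numbered
#'   labels).
#' @return A [alignment()] of the tip sequences.
#' @export
mutate_sequence <- function(tree, length = 1029L, mu_site_year, gen_time = 2,
                            kappa = 3, ids = NULL) {
  stopifnot(inherits(tree, "coal_tree"))
  if (mu_site_year < 0) stop("mutation rate must be non-negative")
  m <- mutate_sequence_cpp(tree$parent, tree$time, tree$n_tip,
                           as.integer(length), mu_site_year * gen_time,
                           kappa)
  if (is.null(ids)) ids <- tip_ids(tree$tip_group)
  # sequences from the simulator are already upper-case and rectangular,
  # so the validating constructor can be bypassed
  structure(list(ids = as.character(ids), seq = apply_raw_to_strings(m),
                 length = ncol(m)),
            class = "sequence_alignment")
}

apply_raw_to_strings <- function(m) {
  vapply(seq_len(nrow(m)), function(i) rawToChar(m[i, ]), "")
}

tip_ids <- function(tip_group) {
  idx <- stats::ave(seq_along(tip_group), tip_group, FUN = seq_along)
  sprintf("%s_%03d", tip_group, idx)
}

#' Drop stepwise mutations on a genealogy and return tip allele sizes
#'
#' Generalized stepwise model: each mutation changes the allele size by
#' `+/- (1 + G)` with `G ~ Geometric(P)`; `P = 0` gives the strict
#' single-step model. The allele range is unconstrained, starting from the
#' root size.
#'
#' @param tree a [simulate_genealogy()] tree in autosomal mode.
#' @param mu_locus_gen mutation rate per locus per generation.
#' @param gsm_p geometric parameter `P` of the GSM.
#' @param root_size ancestral allele size in repeat units (default 200).
#' @return Integer vector of tip allele sizes.
#' @export
mutate_microsat <- function(tree, mu_locus_gen, gsm_p = 0, root_size = 200L) {
  stopifnot(inherits(tree, "coal_tree"))
  mutate_microsat_cpp(tree$parent, tree$time, tree$n_tip, mu_locus_gen,
                      gsm_p, as.integer(root_size))
}

#' Simulate one combined mtDNA + microsatellite dataset
#'
#' One mtDNA alignment and `n_loci` microsatellite loci share the parameter
#' draw but have independent genealogies per locus. mtDNA is sampled one
#' copy per sequenced individual; microsatellites two gene copies per
#' individual.
#'
#' @param scenario a [build_scenario()] object.
#' @param draw a [draw_parameters()] draw.
#' @param design a [sim_design()]; set `n_seq = 0` or `n_loci = 0` for
#'   single-marker datasets.
#' @param kappa transition/transversion ratio of the sequence kernel.
#' @return A list of class `simulated_dataset` with `aln` (or `NULL`),
#'   `ms` (or `NULL`) and `map`.
#' @export
simulate_dataset <- function(scenario, draw, design = sim_design(),
                             kappa = 3) {
  stopifnot(inherits(design, "sim_design"))
  groups <- scenario$groups
  n_ind <- design$n_ind
  ids <- unlist(lapply(groups, function(g)
    sprintf("%s_%03d", g, seq_len(n_ind[[g]]))))
  grp_of <- rep(groups, n_ind)
  map <- popmap(ids, grp_of, lineage = grp_of)
  aln <- NULL
  if (sum(design$n_seq) >= 2L) {
    seq_ids <- unlist(lapply(groups, function(g)
      sprintf("%s_%03d", g, seq_len(design$n_seq[[g]]))))
    tr <- simulate_genealogy(design$n_seq, scenario, draw, "mtdna")
    aln <- mutate_sequence(tr, design$seq_length, draw$mu_mt,
                           draw$gen_time, kappa, ids = seq_ids)
    extra <- setdiff(seq_ids, ids)
    if (length(extra) > 0L)
      stop("design has more sequenced than genotyped individuals")
  }
  ms <- NULL
  if (design$n_loci > 0L && sum(n_ind) > 0L) {
    copies <- 2L * n_ind
    a1 <- matrix(NA_integer_, sum(n_ind), design$n_loci)
    a2 <- matrix(NA_integer_, sum(n_ind), design$n_loci)
    for (l in seq_len(design$n_loci)) {
      tr <- simulate_genealogy(copies, scenario, draw, "autosomal")
      sizes <- mutate_microsat(tr, draw$mu_ms, draw$gsm_p)
      a1[, l] <- sizes[seq(1L, length(sizes), by = 2L)]
      a2[, l] <- sizes[seq(2L, length(sizes), by = 2L)]
    }
    a1[a1 < 1L] <- 1L; a2[a2 < 1L] <- 1L  # size floor: alleles stay positive
    ms <- microsat_dataset(ids, sprintf("loc%d", seq_len(design$n_loci)),
                           a1, a2)
  }
  structure(list(aln = aln, ms = ms, map = map), class = "simulated_dataset")
}
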