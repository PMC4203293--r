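#' Build an ABC reference table
#'
#' Simulates `n_per_scenario` datasets under each scenario with parameters
#' drawn from the priors, summarizes each with the registry, and stores
#' per-statistic normalization constants (median and MAD over the whole
#' table; the standard deviation is used when the MAD is zero, and a
#' statistic with zero spread is excluded from distance computations with a
#' warning but retained in the table).
#'
#' @param scenarios list of [build_scenario()] objects or character labels.
#' @param priors a [default_priors()] prior set.
#' @param n_per_scenario simulations per scenario.
#' @param design a [sim_design()].
#' @param registry a [sumstat_registry()].
#' @param gen_time generation time in years.
#' @param seed optional integer; when given, `set.seed(seed)` is called and
#'   the seed recorded in the table (and its file header on write).
#' @param verbose print progress every 1,000 rows.
#' @return An object of class `ref_table`.
#' @export
build_reference_table <- function(scenarios, priors = default_priors(),
                                  n_per_scenario, design = sim_design(),
                                  registry = sumstat_registry("combined"),
                                  gen_time = 2, seed = NULL,
                                  verbose = FALSE) {
  scenarios <- lapply(scenarios, function(s)
    if (inherits(s, "demographic_scenario")) s else build_scenario(s))
  stopifnot(n_per_scenario >= 1L)
  if (!is.null(seed)) set.seed(seed)
  ns <- length(scenarios)
  ntot <- ns * n_per_scenario
  stats_m <- matrix(NA_real_, ntot, registry$n_stats)
  params_m <- matrix(NA_real_, ntot, length(param_names()),
                     dimnames = list(NULL, param_names()))
  scen_lab <- character(ntot)
  row <- 0L
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    for (r in seq_len(n_per_scenario)) {
      row <- row + 1L
      dr <- draw_parameters(priors, sc, gen_time = gen_time)
      ds <- simulate_dataset(sc, dr, design)
      ss <- assemble_sumstats(ds$aln, ds$ms, ds$map, registry)
      stats_m[row, ] <- ss
      params_m[row, ] <- draw_as_vector(dr)
      scen_lab[[row]] <- sc$label
      if (verbose && row %% 1000L == 0L)
        message("  reference table: ", row, " / ", ntot)
      if (row == 1L) colnames(stats_m) <- names(ss)
    }
  }
  new_ref_table(scen_lab, params_m, stats_m, registry, design,
                scenarios = scenarios, seed = seed,
                n_per_scenario = n_per_scenario)
}

# assemble a ref_table from parts; normalization constants are recomputed
# here so that tables rebuilt from file are identical
new_ref_table <- function(scenario, params, stats, registry, design = NULL,
                          scenarios = NULL, seed = NULL,
                          n_per_scenario = NULL) {
  center <- apply(stats, 2L, median)
  scale <- apply(stats, 2L, mad)
  fallback <- scale == 0
  if (any(fallback))
    scale[fallback] <- apply(stats[, fallback, drop = FALSE], 2L, sd)
  included <- scale > 0
  if (any(!included))
    warning("statistic(s) with zero spread excluded from distances: ",
            paste(colnames(stats)[!included], collapse = ", "))
  time_names <- NULL
  if (!is.null(scenarios))
    time_names <- setNames(lapply(scenarios, `[[`, "time_name"),
                           vapply(scenarios, `[[`, "", "label"))
  out <- structure(list(scenario = scenario, params = params, stats = stats,
                        registry = registry, center = center, scale = scale,
                        included = included, design = design,
                        time_names = time_names, seed = seed,
                        n_per_scenario = n_per_scenario),
                   class = "ref_table")
  out$znorm <- normalize_stats(out, stats)  # cached for repeated rejection
  out
}

#' @export
print.ref_table <- function(x, ...) {
  cat("<ref_table> ", nrow(x$stats), " simulations (",
      paste(unique(x$scenario), collapse = ", "), "), registry ",
      x$registry$id, " (", x$registry$n_stats, " statistics)\n", sep = "")
  if (!is.null(x$seed)) cat("  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

# normalized statistics (included columns only)
normalize_stats <- function(table, stats) {
  inc <- which(table$included)
  if (is.null(dim(stats)))
    stats <- matrix(stats, 1L, length(stats),
                    dimnames = list(NULL, names(stats)))
  sweep(sweep(stats[, inc, drop = FALSE], 2L, table$center[inc]),
        2L, table$scale[inc], "/")
}

#' Write a reference table to gzip-compressed TSV
#'
#' Header comment lines record the registry, design and seed; then one row
#' per simulation with scenario label, parameter draw and statistics.
#'
#' @param table a [build_reference_table()] object.
#' @param path output path (conventionally `.tsv.gz`).
#' @return `path`, invisibly.
#' @export
write_reftable <- function(table, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  hdr <- c("#refugia_reftable v1",
           paste0("#registry=", table$registry$type),
           paste0("#seed=", if (is.null(table$seed)) "NA" else table$seed),
           paste0("#n_per_scenario=",
                  if (is.null(table$n_per_scenario)) "NA" else
                    table$n_per_scenario),
           if (!is.null(table$design))
             paste0("#design=", paste(table$design$n_seq, collapse = ","),
                    ";", paste(table$design$n_ind, collapse = ","),
                    ";", table$design$n_loci, ";", table$design$seq_length))
  writeLines(hdr, con)
  df <- data.frame(scenario = table$scenario, table$params, table$stats,
                   check.names = FALSE)
  num <- vapply(df, is.numeric, NA)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  invisible(path)
}

#' Read a reference table written by [write_reftable()]
#'
#' Normalization constants are recomputed from the data, reproducing the
#' original table exactly.
#'
#' @param path path to the `.tsv.gz` file.
#' @return A `ref_table` object.
#' @export
read_reftable <- function(path) {
  lines <- readLines(gzfile(path))
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_hdr <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, "="))]
    if (length(ln) == 0L) return(NULL)
    sub(paste0("#", key, "="), "", ln[[1L]], fixed = TRUE)
  }
  cols <- strsplit(body[[1L]], "\t", fixed = TRUE)[[1L]]
  cells <- strsplit(body[-1L], "\t", fixed = TRUE)
  m <- do.call(rbind, cells)
  colnames(m) <- cols
  scen <- m[, "scenario"]
  pn <- param_names()
  params <- matrix(as.numeric(m[, pn]), ncol = length(pn),
                   dimnames = list(NULL, pn))
  stat_cols <- setdiff(cols, c("scenario", pn))
  stats <- matrix(as.numeric(m[, stat_cols]), ncol = length(stat_cols),
                  dimnames = list(NULL, stat_cols))
  registry <- sumstat_registry(get_hdr("registry"))
  seed <- get_hdr("seed")
  seed <- if (is.null(seed) || seed == "NA") NULL else as.integer(seed)
  nps <- get_hdr("n_per_scenario")
  nps <- if (is.null(nps) || nps == "NA") NULL else as.integer(nps)
  design <- NULL
  dtxt <- get_hdr("design")
  if (!is.null(dtxt)) {
    parts <- strsplit(dtxt, ";", fixed = TRUE)[[1L]]
    design <- sim_design(
      n_seq = as.integer(strsplit(parts[[1L]], ",")[[1L]]),
      n_ind = as.integer(strsplit(parts[[2L]], ",")[[1L]]),
      n_loci = as.integer(parts[[3L]]),
      seq_length = as.integer(parts[[4L]]))
  }
  scenarios <- lapply(unique(scen), build_scenario)
  suppressWarnings(
    new_ref_table(scen, params, stats, registry, design,
                  scenarios = scenarios, seed = seed, n_per_scenario = nps))
}
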