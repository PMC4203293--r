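#' Construct a microsatellite dataset
#'
#' Diploid allele-size genotypes over a set of loci. Genotypes are stored as
#' two integer matrices (one per allele copy) with `NA` as the single missing
#' sentinel; individuals with missing loci are retained and handled
#' per-statistic by pairwise deletion.
#'
#' @param ids character vector of unique individual identifiers.
#' @param loci character vector of locus names (9 in the default study
#'   design).
#' @param allele1,allele2 integer matrices, individuals x loci, of allele
#'   sizes in repeat-scaled units; `NA` marks a missing allele.
#' @return An object of class `microsat_dataset`.
#' @export
microsat_dataset <- function(ids, loci, allele1, allele2) {
  ids <- as.character(ids)
  loci <- as.character(loci)
  allele1 <- as.matrix(allele1); storage.mode(allele1) <- "integer"
  allele2 <- as.matrix(allele2); storage.mode(allele2) <- "integer"
  if (anyDuplicated(ids)) stop("duplicate individual ids")
  if (!all(dim(allele1) == c(length(ids), length(loci))) ||
      !all(dim(allele2) == c(length(ids), length(loci))))
    stop("allele matrices must be individuals x loci")
  if (any(allele1 <= 0L, na.rm = TRUE) || any(allele2 <= 0L, na.rm = TRUE))
    stop("allele sizes must be positive integers")
  dimnames(allele1) <- dimnames(allele2) <- list(ids, loci)
  structure(list(ids = ids, loci = loci, allele1 = allele1,
                 allele2 = allele2),
            class = "microsat_dataset")
}

#' @export
print.microsat_dataset <- function(x, ...) {
  nmiss <- sum(is.na(x$allele1) | is.na(x$allele2))
  cat("<microsat_dataset> ", length(x$ids), " individuals x ",
      length(x$loci), " loci (", nmiss, " missing genotypes)\n", sep = "")
  invisible(x)
}

# gene copies (allele sizes) for a set of individuals at one locus,
# missing copies dropped
gene_copies <- function(ms, idx, locus) {
  v <- c(ms$allele1[idx, locus], ms$allele2[idx, locus])
  v[!is.na(v)]
}

#' Read a Genepop file
#'
#' Parses the standard Genepop dialect: a title line, one locus name per
#' line (or a single comma-separated line), `Pop` separators, and individual
#' lines `name , 120120 095097 ...` with 2- or 3-digit allele codes; `000`
#' (or `00`) encodes a missing allele. Demes are assigned in file order and
#' named `pop1`, `pop2`, ...
#'
#' @param path path to the Genepop file.
#' @return A list with `data` (a [microsat_dataset()]) and `map` (a
#'   [popmap()] assigning each individual to its deme).
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L) stop("not a Genepop file: ", path)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("no 'Pop' separator found in ", path)
  loc_lines <- trimws(lines[2:(first_pop - 1L)])
  loci <- unlist(strsplit(loc_lines[nzchar(loc_lines)], ",", fixed = TRUE))
  loci <- trimws(loci)
  nloc <- length(loci)
  ids <- character(); deme <- character()
  a1 <- list(); a2 <- list()
  pop_i <- 0L
  cur <- ""
  seen_in_pop <- 0L
  for (i in seq(first_pop, length(lines))) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    if (toupper(line) == "POP") {
      if (pop_i > 0L && seen_in_pop == 0L)
        warning("empty Pop block (deme ", cur, ") in ", path)
      pop_i <- pop_i + 1L
      cur <- paste0("pop", pop_i)
      seen_in_pop <- 0L
      next
    }
    halves <- strsplit(line, ",", fixed = TRUE)[[1L]]
    if (length(halves) != 2L)
      stop("format error on line ", i, ": expected 'name , genotypes'")
    nm <- trimws(halves[[1L]])
    toks <- strsplit(trimws(halves[[2L]]), "[[:space:]]+")[[1L]]
    if (length(toks) != nloc)
      stop("format error on line ", i, ": expected ", nloc,
           " genotype tokens, found ", length(toks))
    g1 <- integer(nloc); g2 <- integer(nloc)
    for (l in seq_len(nloc)) {
      tok <- toks[[l]]
      if (!grepl("^[0-9]+$", tok) || !(nchar(tok) %in% c(4L, 6L)))
        stop("format error on line ", i, ": malformed genotype token '",
             tok, "'")
      w <- nchar(tok) / 2L
      x1 <- as.integer(substr(tok, 1L, w))
      x2 <- as.integer(substr(tok, w + 1L, 2L * w))
      g1[[l]] <- if (x1 == 0L) NA_integer_ else x1
      g2[[l]] <- if (x2 == 0L) NA_integer_ else x2
    }
    ids <- c(ids, nm); deme <- c(deme, cur)
    a1[[length(a1) + 1L]] <- g1
    a2[[length(a2) + 1L]] <- g2
    seen_in_pop <- seen_in_pop + 1L
  }
  if (pop_i > 0L && seen_in_pop == 0L)
    warning("empty Pop block (deme ", cur, ") in ", path)
  m1 <- do.call(rbind, a1); m2 <- do.call(rbind, a2)
  list(data = microsat_dataset(ids, loci, m1, m2),
       map = popmap(ids, deme))
}

#' Write a Genepop file
#'
#' Writes 3-digit allele codes with `000` for missing alleles, one `Pop`
#' block per deme in the order demes first appear in `map`.
#'
#' @param ms a [microsat_dataset()].
#' @param map a [popmap()] covering every individual in `ms`.
#' @param path output path.
#' @param title title line written as the first line of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(ms, map, path, title = "refugia microsatellite export") {
  stopifnot(inherits(ms, "microsat_dataset"))
  grp <- map_groups(map, "deme_id")
  if (!all(ms$ids %in% names(grp)))
    stop("population map does not cover all individuals")
  fmt <- function(v) sprintf("%03d", ifelse(is.na(v), 0L, v))
  out <- c(title, ms$loci)
  for (d in unique(grp[ms$ids])) {
    out <- c(out, "Pop")
    for (i in which(grp[ms$ids] == d)) {
      gen <- paste0(fmt(ms$allele1[i, ]), fmt(ms$allele2[i, ]))
      out <- c(out, paste(ms$ids[[i]], ",", paste(gen, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}
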