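#' Construct a sequence alignment
#'
#' An alignment is the substrate for every mtDNA statistic in the package:
#' equal-length DNA sequences with unique sample identifiers. Sequences are
#' case-normalized to upper case on construction.
#'
#' @param ids character vector of unique sample identifiers.
#' @param seqs character vector of DNA sequences (one string per sample),
#'   all of identical length.
#' @return An object of class `sequence_alignment` with elements `ids`,
#'   `seq` and `length` (alignment length in bp).
#' @examples
#' alignment(c("a", "b"), c("ACGT", "ACGA"))
#' @export
alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("`ids` and `seqs` must have the same length")
  if (length(seqs) == 0L)
    stop("empty alignment")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequences differ in length")
  if (lens[[1L]] == 0L)
    stop("alignment length must be positive")
  if (anyDuplicated(ids))
    stop("duplicate sample ids in alignment")
  structure(list(ids = ids, seq = unname(seqs), length = lens[[1L]]),
            class = "sequence_alignment")
}

#' @export
print.sequence_alignment <- function(x, ...) {
  cat("<sequence_alignment> ", length(x$ids), " sequences x ", x$length,
      " bp\n", sep = "")
  show <- head(x$ids, 5L)
  cat("  samples: ", paste(show, collapse = ", "),
      if (length(x$ids) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.sequence_alignment <- function(x) length(x$ids)

#' @export
as.character.sequence_alignment <- function(x, ...) setNames(x$seq, x$ids)

# alignment as raw byte matrix (rows = sequences); internal workhorse for
# all sequence statistics
aln_raw <- function(aln) {
  t(vapply(aln$seq, charToRaw, raw(aln$length), USE.NAMES = FALSE))
}

subset_alignment <- function(aln, idx) {
  alignment(aln$ids[idx], aln$seq[idx])
}

#' Read a FASTA alignment
#'
#' Records are kept in file order and sequences are upper-cased. All records
#' must have the same length; a ragged file is an error, as are duplicated
#' record names.
#'
#' @param path path to a FASTA file.
#' @return A [alignment()] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no FASTA records in ", path)
  chars <- as.character(dna)
  seqs <- vapply(chars, function(v) paste0(v, collapse = ""), "")
  alignment(names(dna), seqs)
}

#' Write a FASTA alignment
#'
#' @param aln a [alignment()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "sequence_alignment"))
  dna <- ape::as.DNAbin(setNames(strsplit(tolower(aln$seq), ""), aln$ids))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Concatenate aligned regions into a composite alignment
#'
#' Joins several single-region alignments (for example an 858 bp cytochrome B
#' fragment and a 171 bp control-region fragment) into one composite
#' haplotype alignment. Every region must contain exactly the same sample
#' set; samples are concatenated in the order of the first region.
#'
#' @param alignments list of [alignment()] objects sharing one sample set.
#' @return A [alignment()] whose length is the sum of the region lengths.
#' @export
concatenate_regions <- function(alignments) {
  stopifnot(is.list(alignments), length(alignments) >= 1L)
  for (a in alignments) stopifnot(inherits(a, "sequence_alignment"))
  ref <- alignments[[1L]]
  if (length(alignments) == 1L) return(ref)
  out <- ref$seq
  for (a in alignments[-1L]) {
    if (!setequal(a$ids, ref$ids))
      stop("missing-sample error: regions do not share the same sample set")
    out <- paste0(out, a$seq[match(ref$ids, a$ids)])
  }
  alignment(ref$ids, out)
}

#' Drop sequences containing ambiguity codes
#'
#' Samples whose sequence contains anything outside {A,C,G,T} (N, IUPAC
#' ambiguity codes, gaps) are excluded, mirroring the practice of removing
#' ambiguous reads before haplotype collapsing.
#'
#' @param aln a [alignment()] object.
#' @return A list with `alignment` (the retained sequences) and `excluded`
#'   (character vector of excluded sample ids).
#' @export
filter_ambiguous <- function(aln) {
  stopifnot(inherits(aln, "sequence_alignment"))
  bad <- grepl("[^ACGT]", aln$seq)
  if (all(bad)) stop("empty alignment: all sequences contain ambiguity codes")
  if (any(bad))
    message("excluding ", sum(bad), " sequence(s) with ambiguity codes: ",
            paste(aln$ids[bad], collapse = ", "))
  list(alignment = subset_alignment(aln, !bad), excluded = aln$ids[bad])
}

#' Construct a population map
#'
#' Maps samples to demes, with optional additional grouping axes (region,
#' habitat, marine drainage, lineage, cluster) as extra columns.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param deme_id character vector assigning each sample to a deme.
#' @param ... further equal-length vectors, one per grouping axis.
#' @return A data.frame of class `popmap`.
#' @export
popmap <- function(sample_id, deme_id, ...) {
  df <- data.frame(sample_id = as.character(sample_id),
                   deme_id = as.character(deme_id),
                   ..., stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in population map")
  class(df) <- c("popmap", "data.frame")
  df
}

#' Read a population map from TSV
#'
#' Format: a header line `sample_id<TAB>deme_id`, then one line per sample.
#' Additional grouping axes are carried as `axis=value` tokens in columns
#' three onward.
#'
#' @param path path to the TSV file.
#' @return A [popmap()] data.frame.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  sid <- vapply(parts, `[[`, "", 1L)
  did <- vapply(parts, `[[`, "", 2L)
  axes <- list()
  for (i in seq_along(parts)) {
    extra <- parts[[i]][-(1:2)]
    for (tok in extra) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L)
        stop("malformed axis token '", tok, "' on line ", i + 1L)
      if (is.null(axes[[kv[[1L]]]])) axes[[kv[[1L]]]] <- rep(NA_character_, length(parts))
      axes[[kv[[1L]]]][i] <- kv[[2L]]
    }
  }
  do.call(popmap, c(list(sample_id = sid, deme_id = did), axes))
}

#' Write a population map to TSV
#'
#' @param map a [popmap()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(map, path) {
  axes <- setdiff(names(map), c("sample_id", "deme_id"))
  lines <- paste(map$sample_id, map$deme_id, sep = "\t")
  for (ax in axes)
    lines <- paste0(lines, "\t", ax, "=", map[[ax]])
  writeLines(c("sample_id\tdeme_id", lines), path)
  invisible(path)
}

# resolve a grouping axis of a popmap into a named sample -> group vector
map_groups <- function(map, group_by = "deme_id") {
  if (!group_by %in% names(map))
    stop("grouping axis '", group_by, "' not present in population map")
  setNames(as.character(map[[group_by]]), map$sample_id)
}
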