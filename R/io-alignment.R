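#' Read a FASTA multiple sequence alignment
#'
#' Reads an aligned nucleotide FASTA file into a `seq_alignment` object: a
#' character matrix with one row per taxon and one column per site.
#' Sequences are upper-cased and RNA `U` is normalised to `T`.  All rows
#' must have identical length and taxon ids must be unique.
#'
#' @param path Path to a FASTA file with at least two records.
#' @return A `seq_alignment`: character matrix (taxa x sites) with rownames
#'   giving the taxon ids.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  if (length(recs) < 2L) stop("alignment must contain at least 2 records: ", path)
  ids <- unname(vapply(recs, function(r) attr(r, "name"), character(1)))
  seqs <- toupper(unname(vapply(recs, as.character, character(1))))
  seqs <- chartr("U", "T", seqs)
  new_alignment(seqs, ids)
}

#' Construct an alignment from named sequence strings
#'
#' @param seqs Character vector of equal-length sequence strings.
#' @param ids Taxon ids (defaults to `names(seqs)`).
#' @return A `seq_alignment` matrix.
#' @export
new_alignment <- function(seqs, ids = names(seqs)) {
  if (is.null(ids) || any(!nzchar(ids))) stop("taxon ids must be non-empty")
  if (anyDuplicated(ids)) {
    stop("duplicate taxon id in alignment: ", ids[duplicated(ids)][1])
  }
  lens <- nchar(seqs)
  if (lens[1] == 0L) stop("alignment has zero length")
  if (any(lens != lens[1])) {
    bad <- ids[which(lens != lens[1])[1]]
    stop("alignment rows have unequal lengths (offending taxon: ", bad, ")")
  }
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(m) <- as.character(unname(ids))
  class(m) <- c("seq_alignment", class(m))
  m
}

#' Write an alignment to FASTA
#'
#' @param aln A `seq_alignment`.
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = rownames(aln), file.out = path)
  invisible(path)
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("seq_alignment:", nrow(x), "taxa x", ncol(x), "sites\n")
  invisible(x)
}

#' Read a taxon-to-group partition table
#'
#' Two-column TSV (`taxon`, `group`).  A header row is detected by the
#' literal string `taxon` in the first field.
#'
#' @param path Path to the TSV file.
#' @return A `taxon_partition`: named character vector mapping taxon id to
#'   group id.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("partition file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^taxon\\b", lines[1])) lines <- lines[-1]
  if (!length(lines)) stop("partition file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  taxa <- vapply(parts, `[`, character(1), 1L)
  grps <- trimws(vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1)))
  if (any(!nzchar(grps))) {
    stop("empty group field for taxon: ", taxa[!nzchar(grps)][1])
  }
  new_partition(stats::setNames(grps, taxa))
}

#' Construct a taxon partition
#'
#' @param assignment Named character vector: taxon id -> group id.
#' @return A `taxon_partition`.
#' @export
new_partition <- function(assignment) {
  taxa <- names(assignment)
  if (is.null(taxa) || any(!nzchar(taxa))) stop("taxon ids must be non-empty")
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon in partition: ", taxa[duplicated(taxa)][1])
  }
  if (any(!nzchar(assignment))) stop("group ids must be non-empty")
  structure(assignment, class = "taxon_partition")
}

#' Groups of a partition
#' @param part A `taxon_partition`.
#' @return Named list: group id -> character vector of member taxa.
#' @export
partition_groups <- function(part) {
  split(names(part), unname(unclass(part)))
}

#' Write a partition table
#' @param part A `taxon_partition`.
#' @param path Output path.
#' @export
write_partition <- function(part, path) {
  utils::write.table(
    data.frame(taxon = names(part), group = unname(unclass(part))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxon-to-area range table
#'
#' Two-column TSV (`taxon`, area string such as `"AC"`).  Area letters are
#' validated against `areas`; repeated letters are collapsed with a warning.
#'
#' @param path Path to the TSV file.
#' @param areas Ordered character vector of one-letter area codes.
#' @return A `range_matrix`: logical matrix (taxa x areas).
#' @export
read_ranges <- function(path, areas = LETTERS[1:6]) {
  if (!file.exists(path)) stop("range file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^taxon\\b", lines[1])) lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  taxa <- vapply(parts, `[`, character(1), 1L)
  rng <- trimws(vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1)))
  ranges <- lapply(seq_along(taxa), function(i) {
    a <- strsplit(rng[i], "", fixed = TRUE)[[1]]
    if (!length(a)) stop("empty area string for taxon: ", taxa[i])
    bad <- setdiff(a, areas)
    if (length(bad)) {
      stop("unknown area code '", bad[1], "' for taxon: ", taxa[i])
    }
    if (anyDuplicated(a)) {
      warning("repeated area letters for taxon ", taxa[i], "; collapsed")
      a <- unique(a)
    }
    a
  })
  new_range_matrix(stats::setNames(ranges, taxa), areas)
}

#' Construct a range matrix from per-taxon area sets
#'
#' @param ranges Named list: taxon id -> character vector of area codes.
#' @param areas Ordered area codes.
#' @return A `range_matrix` (logical taxa x areas matrix).
#' @export
new_range_matrix <- function(ranges, areas = LETTERS[1:6]) {
  if (!length(areas)) stop("area list must be non-empty")
  taxa <- names(ranges)
  if (anyDuplicated(taxa)) stop("duplicate taxon in range table: ",
                                taxa[duplicated(taxa)][1])
  m <- t(vapply(ranges, function(a) areas %in% a, logical(length(areas))))
  if (length(areas) == 1L) m <- matrix(m, ncol = 1L, dimnames = list(taxa, NULL))
  colnames(m) <- areas
  rownames(m) <- taxa
  if (any(rowSums(m) == 0L)) {
    stop("empty range for taxon: ", taxa[rowSums(m) == 0L][1])
  }
  structure(m, class = c("range_matrix", class(m)), areas = areas)
}

#' Write a range table
#' @param rm A `range_matrix`.
#' @param path Output path.
#' @export
write_ranges <- function(rm, path) {
  areas <- attr(rm, "areas")
  strs <- apply(rm, 1, function(r) paste(areas[r], collapse = ""))
  utils::write.table(data.frame(taxon = rownames(rm), range = strs),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
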