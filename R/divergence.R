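#' Distance configuration
#'
#' Settings for pairwise nucleotide distances in the divergence screen.
#' The default — uncorrected p-distance with pairwise deletion of
#' non-comparable sites — is the common default for published
#' within/between group divergence tables; the Kimura two-parameter
#' correction and complete deletion are available as alternates.
#' Ambiguity codes (including `N`) and gaps are always treated as
#' non-comparable.
#'
#' @param model `"p_distance"` or `"k2p"`.
#' @param gap_policy `"pairwise_deletion"` (exclude a site per pair when
#'   either residue is not A/C/G/T) or `"complete_deletion"` (exclude any
#'   site that is not A/C/G/T in every row of the alignment).
#' @return A `distance_config` list.
#' @export
distance_config <- function(model = c("p_distance", "k2p"),
                            gap_policy = c("pairwise_deletion",
                                           "complete_deletion")) {
  structure(list(model = match.arg(model), gap_policy = match.arg(gap_policy)),
            class = "distance_config")
}

BASES <- c("A", "C", "G", "T")

#' Pairwise distance between two aligned sequences
#'
#' Comparable sites are those where both residues are in `{A,C,G,T}`
#' (pairwise deletion) or, under complete deletion, sites that are
#' unambiguous in the whole alignment (the caller pre-filters; for the
#' two-sequence kernel both policies coincide).  The p-distance is the
#' proportion of comparable sites that differ.  The K2P distance is
#' `-0.5 * log(1 - 2P - Q) - 0.25 * log(1 - 2Q)` with `P` and `Q` the
#' transition and transversion proportions.
#'
#' @param a,b Character vectors (one residue per element) or single strings
#'   of equal length.
#' @param config A [distance_config()].
#' @return A proportion (p-distance) or corrected distance (K2P).
#' @export
pairwise_distance <- function(a, b, config = distance_config()) {
  if (length(a) == 1L && nchar(a[1]) > 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L && nchar(b[1]) > 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  a <- toupper(a); b <- toupper(b)
  ok <- a %in% BASES & b %in% BASES
  n <- sum(ok)
  if (n == 0L) stop("undefined distance: no comparable sites")
  a <- a[ok]; b <- b[ok]
  if (config$model == "p_distance") {
    return(sum(a != b) / n)
  }
  purine <- function(x) x %in% c("A", "G")
  diff <- a != b
  ts <- diff & (purine(a) == purine(b))     # A<->G or C<->T
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("K2P saturation: log argument <= 0 for pair (P=", P, ", Q=", Q, ")")
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Full pairwise distance matrix of an alignment
#'
#' Vectorised (indicator cross-product) computation giving results
#' identical to looping [pairwise_distance()] over all pairs.
#'
#' @param aln A `seq_alignment`.
#' @param config A [distance_config()].
#' @return Symmetric numeric matrix with taxon dimnames.
#' @export
distance_matrix <- function(aln, config = distance_config()) {
  m <- toupper(unclass(aln))
  if (config$gap_policy == "complete_deletion") {
    keep <- colSums(matrix(m %in% BASES, nrow = nrow(m))) == nrow(m)
    if (!any(keep)) stop("undefined distance: no comparable sites after complete deletion")
    m <- m[, keep, drop = FALSE]
  }
  X <- lapply(BASES, function(b) (m == b) * 1)
  C <- Reduce(`+`, X)                       # 1 where residue comparable
  N <- tcrossprod(C)                        # comparable sites per pair
  M <- Reduce(`+`, lapply(X, tcrossprod))   # matching sites per pair
  if (any(N[upper.tri(N)] == 0)) {
    ij <- which(N == 0 & upper.tri(N), arr.ind = TRUE)[1, ]
    stop("undefined distance: no comparable sites for pair (",
         rownames(m)[ij[1]], ", ", rownames(m)[ij[2]], ")")
  }
  if (config$model == "p_distance") {
    D <- 1 - M / N
  } else {
    TS <- tcrossprod(X[[1]], X[[3]]) + tcrossprod(X[[3]], X[[1]]) +
      tcrossprod(X[[2]], X[[4]]) + tcrossprod(X[[4]], X[[2]])
    P <- TS / N
    Q <- (N - M - TS) / N
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    bad <- (w1 <= 0 | w2 <= 0) & upper.tri(N)
    if (any(bad)) {
      ij <- which(bad, arr.ind = TRUE)[1, ]
      stop("K2P saturation: log argument <= 0 for pair (",
           rownames(m)[ij[1]], ", ", rownames(m)[ij[2]], ")")
    }
    D <- -0.5 * log(w1) - 0.25 * log(w2)
  }
  diag(D) <- 0
  dimnames(D) <- list(rownames(aln), rownames(aln))
  D
}

#' Mean within- and between-group divergence
#'
#' Arithmetic means of all constituent pairwise distances, within each
#' group (for groups of two or more sequences) and between each unordered
#' group pair — the layout of a MEGA "average evolutionary divergence over
#' sequence pairs within/between groups" table.
#'
#' @param aln A `seq_alignment`.
#' @param part A `taxon_partition` whose taxa all occur in `aln`.
#' @param config A [distance_config()].
#' @return A `divergence_table`: list with data frames `within` (`group`,
#'   `mean`, `n_pairs`), `between` (`group1`, `group2`, `mean`, `n_pairs`),
#'   integer vector `sizes`, and the `config`.
#' @export
group_divergence <- function(aln, part, config = distance_config()) {
  groups <- partition_groups(part)
  for (g in names(groups)) {
    present <- groups[[g]] %in% rownames(aln)
    if (!any(present)) stop("group absent from alignment: ", g)
    if (!all(present)) {
      stop("taxon missing from alignment: ", groups[[g]][!present][1])
    }
  }
  D <- distance_matrix(aln, config)
  gn <- sort(names(groups))
  within <- data.frame(group = character(0), mean = numeric(0),
                       n_pairs = integer(0), stringsAsFactors = FALSE)
  for (g in gn) {
    mem <- groups[[g]]
    if (length(mem) < 2L) next
    sub <- D[mem, mem, drop = FALSE]
    vals <- sub[upper.tri(sub)]
    within <- rbind(within, data.frame(group = g, mean = mean(vals),
                                       n_pairs = length(vals),
                                       stringsAsFactors = FALSE))
  }
  between <- data.frame(group1 = character(0), group2 = character(0),
                        mean = numeric(0), n_pairs = integer(0),
                        stringsAsFactors = FALSE)
  if (length(gn) >= 2L) {
    for (i in seq_len(length(gn) - 1L)) {
      for (j in (i + 1L):length(gn)) {
        vals <- D[groups[[gn[i]]], groups[[gn[j]]], drop = FALSE]
        between <- rbind(between, data.frame(
          group1 = gn[i], group2 = gn[j], mean = mean(vals),
          n_pairs = length(vals), stringsAsFactors = FALSE))
      }
    }
  }
  new_divergence_table(within, between,
                       sizes = vapply(groups, length, integer(1))[gn],
                       config = config)
}

#' Assemble a divergence table from precomputed statistics
#'
#' Used both by [group_divergence()] and to load published summary tables
#' (within/between group means) directly.
#'
#' @param within Data frame `group`, `mean`, `n_pairs`.
#' @param between Data frame `group1`, `group2`, `mean`, `n_pairs`.
#' @param sizes Named integer vector of group sizes.
#' @param config The [distance_config()] in force.
#' @return A `divergence_table`.
#' @export
new_divergence_table <- function(within, between, sizes,
                                 config = distance_config()) {
  structure(list(within = within, between = between, sizes = sizes,
                 config = config), class = "divergence_table")
}

#' @export
print.divergence_table <- function(x, ...) {
  cat("divergence_table:", length(x$sizes), "groups;",
      nrow(x$within), "within,", nrow(x$between), "between entries\n")
  invisible(x)
}

#' Calibrate the species-delimitation cutoff from reference species
#'
#' The cutoff is the highest mean intraspecific divergence observed among a
#' set of well-studied reference species, taken as a conservative upper
#' bound on within-species variation.
#'
#' @param table A `divergence_table`.
#' @param reference_groups Group ids to calibrate from; each must have at
#'   least two sequences (a within-group mean).
#' @return A `cutoff_result`: list with `cutoff`, `source_group`,
#'   `per_reference` (named numeric).
#' @export
calibrate_cutoff <- function(table, reference_groups) {
  w <- table$within
  missing <- setdiff(reference_groups, w$group)
  if (length(missing)) {
    stop("reference group without a within-group divergence (needs >= 2 ",
         "sequences): ", missing[1])
  }
  per <- stats::setNames(w$mean[match(reference_groups, w$group)],
                         reference_groups)
  src <- reference_groups[which.max(per)]
  structure(list(cutoff = max(per), source_group = src, per_reference = per),
            class = "cutoff_result")
}

#' Apply the distance-cutoff species decision rule
#'
#' Each provisional group is accepted as a species if its divergence from
#' the closest other group (minimal mean between-group distance) exceeds
#' the cutoff, and merged with that group otherwise.  Independently, a
#' group whose *within*-group mean exceeds the cutoff is flagged as
#' potentially comprising multiple species.  Singleton groups carry no
#' within-group divergence and are routed to the GCPSR singleton rule
#' (status `singleton_untested`).  Ties for the nearest group break
#' lexicographically.
#'
#' @param table A `divergence_table` with at least two groups.
#' @param cutoff Numeric cutoff (a proportion), e.g. from
#'   [calibrate_cutoff()].
#' @return Data frame with columns `group`, `status` (`accepted`, `merged`,
#'   `singleton_untested`), `merged_with`, `nearest_group`,
#'   `nearest_divergence`, `delta_w`, `flagged_multiple`.
#' @export
decide_species <- function(table, cutoff) {
  gn <- sort(names(table$sizes))
  if (length(gn) < 2L) stop("decision rule needs at least two groups")
  bt <- table$between
  res <- lapply(gn, function(g) {
    rows <- bt[bt$group1 == g | bt$group2 == g, , drop = FALSE]
    other <- ifelse(rows$group1 == g, rows$group2, rows$group1)
    o <- order(rows$mean, other)            # lexicographic tie-break
    nearest <- other[o[1]]
    ndiv <- rows$mean[o[1]]
    dw <- table$within$mean[match(g, table$within$group)]
    singleton <- table$sizes[[g]] < 2L
    status <- if (singleton) "singleton_untested"
              else if (ndiv > cutoff) "accepted" else "merged"
    data.frame(group = g, status = status,
               merged_with = if (status == "merged") nearest else NA_character_,
               nearest_group = nearest, nearest_divergence = ndiv,
               delta_w = if (singleton) NA_real_ else dw,
               flagged_multiple = !singleton && !is.na(dw) && dw > cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
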