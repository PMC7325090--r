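#' GCPSR configuration
#'
#' Thresholds for genealogical concordance phylogenetic species
#' recognition.  A clade counts as well supported when its maximum
#' likelihood bootstrap is at least `mlb_threshold` percent or its Bayesian
#' posterior probability is at least `bpp_threshold` (combiner `"any"`,
#' the default); combiner `"all"` instead requires every support kind
#' present on the node to pass.  `majority_fraction` is the fraction of
#' testable single-locus genealogies that must support a clade under the
#' majority criterion (3/4 by default).
#'
#' @param mlb_threshold Bootstrap percentage threshold (default 70).
#' @param bpp_threshold Posterior probability threshold (default 0.95).
#' @param majority_fraction Proportion in (0, 1] (default 0.75).
#' @param support_combiner `"any"` or `"all"`.
#' @return A `concordance_config` list.
#' @export
concordance_config <- function(mlb_threshold = 70, bpp_threshold = 0.95,
                               majority_fraction = 0.75,
                               support_combiner = c("any", "all")) {
  stopifnot(mlb_threshold >= 0, mlb_threshold <= 100,
            bpp_threshold >= 0, bpp_threshold <= 1,
            majority_fraction > 0, majority_fraction <= 1)
  structure(list(mlb_threshold = mlb_threshold,
                 bpp_threshold = bpp_threshold,
                 majority_fraction = majority_fraction,
                 support_combiner = match.arg(support_combiner)),
            class = "concordance_config")
}

#' Is a node's support map above threshold?
#'
#' @param support Named list with any of `mlb`, `bpp` (e.g. from
#'   [node_support()]).  An empty map is never well supported.
#' @param config A [concordance_config()].
#' @return Logical.
#' @export
clade_well_supported <- function(support, config = concordance_config()) {
  has_mlb <- !is.null(support$mlb)
  has_bpp <- !is.null(support$bpp)
  if (!has_mlb && !has_bpp) return(FALSE)
  mlb_ok <- has_mlb && support$mlb >= config$mlb_threshold
  bpp_ok <- has_bpp && support$bpp >= config$bpp_threshold
  if (config$support_combiner == "any") {
    mlb_ok || bpp_ok
  } else {
    (!has_mlb || mlb_ok) && (!has_bpp || bpp_ok)
  }
}

#' Verdict of one gene tree on one candidate species
#'
#' With `S` the candidate members present in the tree: fewer than two
#' members make the tree `untestable`; the tree `supports` the candidate
#' when `S` is monophyletic and its MRCA node is well supported;
#' it `contradicts` the candidate when some *well-supported* clade
#' partially overlaps `S` (shares members with it and with its complement
#' while not containing all of `S`), which is incompatible with the
#' monophyly of `S` at the same level of support; otherwise the tree is
#' `uninformative`.  Clades of a single tree are nested or disjoint, so
#' `supports` and `contradicts` are mutually exclusive.
#'
#' @param tree A rooted tree from [read_tree()].
#' @param members Character vector of candidate species members.
#' @param config A [concordance_config()].
#' @return List with `verdict` (one of `supports`, `contradicts`,
#'   `uninformative`, `untestable`) and `mrca_support` (support map of the
#'   MRCA when `S` is monophyletic, else `NULL`).
#' @export
assess_candidate_in_tree <- function(tree, members,
                                     config = concordance_config()) {
  S <- intersect(members, tree$tip.label)
  if (length(S) < 2L) {
    return(list(verdict = "untestable", mrca_support = NULL))
  }
  sets <- clade_leafsets(tree)
  mrca_support <- NULL
  mono_node <- NULL
  for (nm in names(sets)) {
    C <- sets[[nm]]
    if (length(C) == length(S) && setequal(C, S)) {
      mono_node <- as.integer(nm)
      break
    }
  }
  if (!is.null(mono_node)) {
    mrca_support <- node_support(tree, mono_node)
    if (clade_well_supported(mrca_support, config)) {
      return(list(verdict = "supports", mrca_support = mrca_support))
    }
  }
  for (nm in names(sets)) {
    C <- sets[[nm]]
    inS <- sum(C %in% S)
    if (inS > 0L && inS < length(C) && inS < length(S) &&
        clade_well_supported(node_support(tree, as.integer(nm)), config)) {
      return(list(verdict = "contradicts", mrca_support = mrca_support))
    }
  }
  list(verdict = "uninformative", mrca_support = mrca_support)
}

#' Evaluate GCPSR over a set of single-locus gene trees
#'
#' Applies two criteria per candidate group: (a) the clade is well
#' supported in at least `majority_fraction` of the *testable* genealogies
#' (those containing at least two of its members); (b) the clade is well
#' supported by at least one genealogy and contradicted by none.  A group
#' is accepted if either criterion holds.  Groups are binned by the number
#' of supporting genealogies into tiers `gt30`, `gt20`, `gt10`, `le10`;
#' groups testable in no tree get tier `singleton` and are routed to
#' [singleton_rule()].
#'
#' @param trees Named list of trees (names = locus ids).
#' @param part A `taxon_partition` of candidate species.
#' @param config A [concordance_config()].
#' @return A `concordance_report`: list with `report` (one row per group:
#'   `group`, `n_testable`, `n_supporting`, `n_contradicting`,
#'   `criterion_a`, `criterion_b`, `accepted`, `tier`) and `verdicts`
#'   (locus x group long table).
#' @export
evaluate_gcpsr <- function(trees, part, config = concordance_config()) {
  stopifnot(length(trees) >= 1L, length(part) >= 1L)
  groups <- partition_groups(part)
  loci <- names(trees)
  if (is.null(loci)) loci <- sprintf("locus%03d", seq_along(trees))
  verdicts <- do.call(rbind, lapply(seq_along(trees), function(i) {
    data.frame(locus = loci[i], group = names(groups),
               verdict = vapply(groups, function(mem) {
                 assess_candidate_in_tree(trees[[i]], mem, config)$verdict
               }, character(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(verdicts) <- NULL
  report <- do.call(rbind, lapply(names(groups), function(g) {
    v <- verdicts$verdict[verdicts$group == g]
    n_test <- sum(v != "untestable")
    n_sup <- sum(v == "supports")
    n_con <- sum(v == "contradicts")
    crit_a <- n_test >= 1L && n_sup >= config$majority_fraction * n_test
    crit_b <- n_sup >= 1L && n_con == 0L
    tier <- if (n_test == 0L) "singleton"
            else if (n_sup > 30L) "gt30"
            else if (n_sup > 20L) "gt20"
            else if (n_sup > 10L) "gt10" else "le10"
    data.frame(group = g, n_testable = n_test, n_supporting = n_sup,
               n_contradicting = n_con, criterion_a = crit_a,
               criterion_b = crit_b, accepted = crit_a || crit_b,
               tier = tier, stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  structure(list(report = report, verdicts = verdicts, config = config),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("concordance_report over", length(unique(x$verdicts$locus)),
      "loci:", sum(x$report$accepted), "of", nrow(x$report),
      "groups accepted\n")
  print(x$report)
  invisible(x)
}

#' Singleton rule for groups with a single multilocus sample
#'
#' A candidate represented by one sample cannot be tested for monophyly;
#' it is accepted as a provisional independent lineage when it is more
#' divergent from every other group than the distance cutoff *and* shows a
#' stable morphological difference (supplied as a flag).
#'
#' @param group Group id (must have exactly one sample in `table`).
#' @param table A `divergence_table`.
#' @param cutoff Distance cutoff (proportion).
#' @param morphology_flag Logical: stable morphological difference?
#' @return `"provisional_lineage"` or `"undetermined"`.
#' @export
singleton_rule <- function(group, table, cutoff, morphology_flag) {
  size <- table$sizes[[group]]
  if (is.null(size) || size != 1L) {
    stop("singleton_rule applies only to groups with exactly one sample: ",
         group)
  }
  bt <- table$between
  rows <- bt[bt$group1 == group | bt$group2 == group, , drop = FALSE]
  if (!nrow(rows)) stop("no between-group divergence for group: ", group)
  if (min(rows$mean) > cutoff && isTRUE(morphology_flag)) {
    "provisional_lineage"
  } else {
    "undetermined"
  }
}
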