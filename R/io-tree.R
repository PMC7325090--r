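#' Read a rooted Newick tree with node support
#'
#' Trees are returned as [ape::read.tree()] `phylo` objects augmented with a
#' `support` data frame (one row per annotated internal node, columns
#' `node`, `mlb`, `bpp`, `primary`).  Two support dialects are understood:
#'
#' * `label_as_primary`: a numeric internal-node label `v` is stored as the
#'   primary support and classified as a maximum-likelihood bootstrap
#'   percentage (`mlb`) if `1 < v <= 100` or a Bayesian posterior
#'   probability (`bpp`) if `0 <= v <= 1`.  A label of exactly 1 is
#'   ambiguous between the two scales and is taken as `bpp = 1` with a
#'   warning.  Labels outside `[0, 100]` are an error.
#' * `annotated`: comment blocks of the form `[&mlb=97,bpp=0.99]` in the
#'   node-label position populate the support map directly.
#'
#' Missing branch lengths default to 0 with a warning (support-only gene
#' trees are legitimate inputs).  The tree is used as rooted as written; no
#' implicit re-rooting is performed.
#'
#' @param path Path to a Newick file (ignored when `text` is given).
#' @param support_dialect `"label_as_primary"` or `"annotated"`.
#' @param text Optional Newick string instead of a file.
#' @return A `phylo` object with a `support` data frame element.
#' @export
read_tree <- function(path, support_dialect = c("label_as_primary", "annotated"),
                      text = NULL) {
  support_dialect <- match.arg(support_dialect)
  nwk <- if (is.null(text)) paste(readLines(path), collapse = "") else text
  nwk <- trimws(nwk)
  check_newick_syntax(nwk)

  ann <- character(0)
  if (support_dialect == "annotated") {
    m <- gregexpr("\\[&[^]]*\\]", nwk)[[1]]
    if (m[1] != -1L) {
      ann <- regmatches(nwk, gregexpr("\\[&[^]]*\\]", nwk))[[1]]
      for (i in seq_along(ann)) {
        nwk <- sub(ann[i], sprintf("@ANN%d@", i), nwk, fixed = TRUE)
      }
    }
  }
  tree <- tryCatch(ape::read.tree(text = nwk),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("Newick parse error in: ", substr(nwk, 1, 60))

  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }

  ntip <- length(tree$tip.label)
  labs <- tree$node.label
  sup <- data.frame(node = integer(0), mlb = numeric(0), bpp = numeric(0),
                    primary = character(0), stringsAsFactors = FALSE)
  if (!is.null(labs)) {
    for (i in seq_along(labs)) {
      lab <- labs[i]
      if (is.na(lab) || !nzchar(lab)) next
      node <- ntip + i
      if (support_dialect == "annotated" && grepl("^@ANN[0-9]+@$", lab)) {
        k <- as.integer(sub("^@ANN([0-9]+)@$", "\\1", lab))
        kv <- parse_annotation(ann[k])
        sup <- rbind(sup, data.frame(
          node = node,
          mlb = if (!is.null(kv$mlb)) kv$mlb else NA_real_,
          bpp = if (!is.null(kv$bpp)) kv$bpp else NA_real_,
          primary = NA_character_, stringsAsFactors = FALSE))
        tree$node.label[i] <- ""
      } else {
        v <- suppressWarnings(as.numeric(lab))
        if (is.na(v)) next   # non-numeric label: kept verbatim, no support
        cls <- classify_support(v)
        sup <- rbind(sup, data.frame(node = node, mlb = cls$mlb, bpp = cls$bpp,
                                     primary = lab, stringsAsFactors = FALSE))
      }
    }
  }
  tree$support <- sup
  tree
}

# Cheap structural validation so parse failures carry a character offset.
check_newick_syntax <- function(nwk) {
  chars <- strsplit(nwk, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("Newick parse error at character ", i,
                           ": unbalanced ')'")
    }
  }
  if (depth != 0L) stop("Newick parse error at character ", length(chars),
                        ": ", depth, " unclosed '('")
  if (!grepl(";\\s*$", nwk)) stop("Newick parse error at character ",
                                  nchar(nwk), ": missing terminal ';'")
  invisible(TRUE)
}

# Classify a bare numeric node label onto the MLB or BPP scale.
classify_support <- function(v) {
  if (v < 0 || v > 100) stop("support value out of range [0, 100]: ", v)
  if (v == 1) {
    warning("node label 1 is ambiguous between MLB and BPP scales; ",
            "treated as BPP = 1")
    return(list(mlb = NA_real_, bpp = 1))
  }
  if (v > 1) list(mlb = v, bpp = NA_real_) else list(mlb = NA_real_, bpp = v)
}

parse_annotation <- function(s) {
  body <- sub("^\\[&", "", sub("\\]$", "", s))
  kv <- strsplit(strsplit(body, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    val <- as.numeric(p[2])
    key <- trimws(p[1])
    if (key == "mlb" && (val < 0 || val > 100)) {
      stop("support value out of range [0, 100]: ", val)
    }
    if (key == "bpp" && (val < 0 || val > 1)) {
      stop("bpp value out of range [0, 1]: ", val)
    }
    out[[key]] <- val
  }
  out
}

#' Support map of one internal node
#'
#' @param tree A tree from [read_tree()] (or with a `support` element).
#' @param node Internal node number (ape numbering).
#' @return Named list with any of `mlb`, `bpp`, `primary`; empty list if the
#'   node carries no support.
#' @export
node_support <- function(tree, node) {
  sup <- tree$support
  if (is.null(sup) || !nrow(sup)) return(list())
  r <- sup[sup$node == node, , drop = FALSE]
  if (!nrow(r)) return(list())
  out <- list()
  if (!is.na(r$mlb[1])) out$mlb <- r$mlb[1]
  if (!is.na(r$bpp[1])) out$bpp <- r$bpp[1]
  if (!is.na(r$primary[1])) out$primary <- r$primary[1]
  out
}

#' Write a tree to Newick, preserving supports
#'
#' Round-trips with [read_tree()]: identical topology, branch lengths to 10
#' significant digits, identical support maps.  Nodes without support get no
#' label.
#'
#' @param tree A `phylo` with optional `support` element.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @param support_dialect As in [read_tree()].
#' @return The Newick string, invisibly when written to a file.
#' @export
write_tree <- function(tree, path = NULL,
                       support_dialect = c("label_as_primary", "annotated")) {
  support_dialect <- match.arg(support_dialect)
  ntip <- length(tree$tip.label)
  kids <- children_list(tree)
  el <- tree$edge.length
  if (is.null(el)) el <- rep(0, nrow(tree$edge))
  edge_of <- integer(ntip + tree$Nnode)
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))

  lab_of <- function(node) {
    s <- node_support(tree, node)
    if (!length(s)) return("")
    if (support_dialect == "annotated") {
      parts <- character(0)
      if (!is.null(s$mlb)) parts <- c(parts, sprintf("mlb=%.10g", s$mlb))
      if (!is.null(s$bpp)) parts <- c(parts, sprintf("bpp=%.10g", s$bpp))
      if (!length(parts)) return("")
      paste0("[&", paste(parts, collapse = ","), "]")
    } else {
      if (!is.null(s$primary)) return(s$primary)
      if (!is.null(s$mlb)) return(sprintf("%.10g", s$mlb))
      if (!is.null(s$bpp)) return(sprintf("%.10g", s$bpp))
      ""
    }
  }
  rec <- function(node) {
    if (node <= ntip) {
      tree$tip.label[node]
    } else {
      inner <- paste(vapply(kids[[node]], function(ch) {
        paste0(rec(ch), ":", sprintf("%.10g", el[edge_of[ch]]))
      }, character(1)), collapse = ",")
      paste0("(", inner, ")", lab_of(node))
    }
  }
  root <- ntip + 1L
  out <- paste0(rec(root), ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

# Adjacency list: node number -> child node numbers.
children_list <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
  }
  kids
}

#' Node ages of an ultrametric tree
#'
#' Ages are measured backward from the present: tips at age 0, crown age at
#' the root.
#'
#' @param tree A `phylo`.
#' @return Numeric vector of length `Ntip + Nnode`, age per node.
#' @export
node_ages <- function(tree) {
  d <- ape::node.depth.edgelength(tree)    # distance from root
  max(d[seq_along(tree$tip.label)]) - d
}

#' Validate a tree as an ultrametric chronogram
#'
#' All root-to-tip path lengths must agree within relative tolerance
#' `tol` of the tree depth.
#'
#' @param tree A `phylo`.
#' @param tol Relative tolerance (default 1e-6).
#' @return The tree with attribute `is_chronogram = TRUE`.
#' @export
as_chronogram <- function(tree, tol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  depth <- max(d)
  if (depth <= 0) stop("chronogram has zero depth")
  if (max(d) - min(d) > tol * depth) {
    stop("tree is not ultrametric: root-to-tip spread ",
         signif(max(d) - min(d), 4), " exceeds tolerance")
  }
  attr(tree, "is_chronogram") <- TRUE
  tree
}

#' Is a tree flagged as a chronogram?
#' @param tree A `phylo`.
#' @return Logical.
#' @export
is_chronogram <- function(tree) isTRUE(attr(tree, "is_chronogram"))

#' Leaf sets of all internal nodes
#'
#' @param tree A `phylo`.
#' @return Named list: internal node number (as character) -> character
#'   vector of descendant tip labels.
#' @export
clade_leafsets <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, (ntip + 1L):(ntip + tree$Nnode), "tips")
  out <- lapply(desc, function(ix) tree$tip.label[ix])
  names(out) <- as.character((ntip + 1L):(ntip + tree$Nnode))
  out
}
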