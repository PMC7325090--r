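# Independent brute-force oracles and random-instance generators used
# across the suite.  These deliberately avoid the package's optimised code
# paths.

# Brute-force per-pair p-distance / K2P on two character vectors.
oracle_pair_distance <- function(a, b, model = "p_distance") {
  bases <- c("A", "C", "G", "T")
  keep <- a %in% bases & b %in% bases
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (model == "p_distance") return(sum(a != b) / n)
  pur <- function(x) x %in% c("A", "G")
  ts <- sum(a != b & pur(a) == pur(b)) / n
  tv <- sum(a != b & pur(a) != pur(b)) / n
  -0.5 * log(1 - 2 * ts - tv) - 0.25 * log(1 - 2 * tv)
}

# Brute-force within/between group means by explicit double loops.
oracle_group_divergence <- function(aln, part, model = "p_distance") {
  m <- unclass(aln)
  groups <- split(names(part), unname(unclass(part)))
  gn <- sort(names(groups))
  within <- list(); between <- list()
  for (g in gn) {
    mem <- groups[[g]]
    if (length(mem) < 2) next
    vals <- c()
    for (i in seq_along(mem)) for (j in seq_along(mem)) if (i < j) {
      vals <- c(vals, oracle_pair_distance(m[mem[i], ], m[mem[j], ], model))
    }
    within[[g]] <- mean(vals)
  }
  for (i in seq_along(gn)) for (j in seq_along(gn)) if (i < j) {
    vals <- c()
    for (x in groups[[gn[i]]]) for (y in groups[[gn[j]]]) {
      vals <- c(vals, oracle_pair_distance(m[x, ], m[y, ], model))
    }
    between[[paste(gn[i], gn[j], sep = "|")]] <- mean(vals)
  }
  list(within = within, between = between)
}

# Random aligned sequences with occasional gaps/ambiguities.
random_alignment <- function(ntaxa, nsites, gap_frac = 0.05) {
  taxa <- sprintf("x%02d", seq_len(ntaxa))
  pool <- c("A", "C", "G", "T")
  seqs <- vapply(taxa, function(t) {
    s <- sample(pool, nsites, replace = TRUE)
    k <- rbinom(1, nsites, gap_frac)
    if (k > 0) s[sample.int(nsites, k)] <- sample(c("-", "N"), k, replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  new_alignment(seqs, taxa)
}

# Brute-force monophyly check: enumerate every internal node's leaf set.
oracle_is_monophyletic <- function(tree, S) {
  for (leafs in clade_leafsets(tree)) {
    if (length(leafs) == length(S) && setequal(leafs, S)) return(TRUE)
  }
  FALSE
}

# Brute-force GCPSR verdict: exhaustive clade enumeration.
oracle_verdict <- function(tree, members, config = concordance_config()) {
  S <- intersect(members, tree$tip.label)
  if (length(S) < 2) return("untestable")
  sets <- clade_leafsets(tree)
  supported <- vapply(names(sets), function(nm) {
    clade_well_supported(node_support(tree, as.integer(nm)), config)
  }, logical(1))
  mono <- FALSE; mono_sup <- FALSE
  for (k in seq_along(sets)) {
    C <- sets[[k]]
    if (length(C) == length(S) && setequal(C, S)) {
      mono <- TRUE
      mono_sup <- supported[k]
    }
  }
  if (mono && mono_sup) return("supports")
  for (k in seq_along(sets)) {
    C <- sets[[k]]
    ov <- length(intersect(C, S))
    if (supported[k] && ov > 0 && length(setdiff(C, S)) > 0 &&
        length(setdiff(S, C)) > 0) {
      return("contradicts")
    }
  }
  "uninformative"
}

# Random rooted binary tree with random numeric supports on internal nodes.
random_supported_tree <- function(ntips) {
  tr <- ape::rtree(ntips, rooted = TRUE)
  # omit 1, which is deliberately ambiguous between the MLB and BPP scales
  tr$node.label <- c("", as.character(sample(c(0, 2:100), tr$Nnode - 1,
                                             replace = TRUE)))
  read_tree(text = ape::write.tree(tr))
}

# Exhaustive DEC likelihood + node marginals on a 3-tip caterpillar
# ((a,b),c) by summing over every node state and cladogenetic outcome.
oracle_dec_3tip <- function(tr, tips, d, e, max_range_size = NULL) {
  areas <- attr(tips, "areas")
  if (is.null(max_range_size)) max_range_size <- length(areas)
  st <- enumerate_ranges(areas, max_range_size)
  model <- dec_model(areas, d, e, max_range_size)
  Q <- build_dec_q(model)
  oc <- gcpsr:::clado_outcomes(st)
  nobs <- st$n_observable
  ages <- node_ages(tr)
  kids <- gcpsr:::children_list(tr)
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  inner <- setdiff(kids[[root]], seq_len(ntip))
  leaf_state <- function(i) {
    match(paste(areas[tips[tr$tip.label[i], ]], collapse = ""), st$labels)
  }
  P <- function(t) as.matrix(Matrix::expm(Q * t))
  edge_of <- integer(ntip + tr$Nnode)
  edge_of[tr$edge[, 2]] <- seq_len(nrow(tr$edge))
  blen <- function(v) tr$edge.length[edge_of[v]]
  c_tip <- setdiff(kids[[root]], inner)
  ab <- kids[[inner]]
  P_c <- P(blen(c_tip)); P_in <- P(blen(inner))
  P_a <- P(blen(ab[1])); P_b <- P(blen(ab[2]))
  tot <- 0
  marg_root <- numeric(nobs); marg_in <- numeric(nobs)
  for (r in seq_len(nobs)) {
    ocr <- oc[[r]]
    for (i in seq_len(nrow(ocr))) {
      # two assignments of the ordered pair to (inner, c) both appear in ocr
      p_c <- P_c[ocr[i, 2], leaf_state(c_tip)]
      for (s1 in seq_len(nobs)) {
        p_in <- P_in[ocr[i, 1], s1]
        oci <- oc[[s1]]
        for (j in seq_len(nrow(oci))) {
          w <- p_c * p_in / nrow(ocr) / nrow(oci) *
            P_a[oci[j, 1], leaf_state(ab[1])] *
            P_b[oci[j, 2], leaf_state(ab[2])]
          tot <- tot + w
          marg_root[r] <- marg_root[r] + w
          marg_in[s1] <- marg_in[s1] + w
        }
      }
    }
  }
  list(logL = log(tot), root = marg_root / tot, inner = marg_in / tot,
       root_node = root, inner_node = inner)
}

# Exhaustive two-state marginals on any small tree (<= 6 nodes): sum over
# all internal-state assignments.
oracle_two_state <- function(tree, x, q01, q10) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  kids <- gcpsr:::children_list(tree)
  edge_of <- integer(nn)
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  s <- q01 + q10
  pm <- function(t) {
    et <- exp(-s * t)
    matrix(c(q10 + q01 * et, q10 - q10 * et,
             q01 - q01 * et, q01 + q10 * et), 2, 2) / s
  }
  internals <- (ntip + 1L):nn
  grids <- rev(expand.grid(rep(list(0:1), length(internals))))
  tot <- 0
  marg <- matrix(0, length(internals), 2)
  for (g in seq_len(nrow(grids))) {
    st <- integer(nn)
    st[seq_len(ntip)] <- x
    st[internals] <- as.integer(grids[g, ])
    w <- 0.5
    for (ed in seq_len(nrow(tree$edge))) {
      p <- tree$edge[ed, 1]; ch <- tree$edge[ed, 2]
      w <- w * pm(tree$edge.length[ed])[st[p] + 1L, st[ch] + 1L]
    }
    tot <- tot + w
    for (k in seq_along(internals)) {
      marg[k, st[internals[k]] + 1L] <- marg[k, st[internals[k]] + 1L] + w
    }
  }
  list(logL = log(tot), marginal = marg / tot)
}
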