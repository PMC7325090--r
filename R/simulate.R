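#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generators.  The deep- and
#' shallow-divergence presets ([deep_preset()], [shallow_preset()]) mirror
#' a multilocus species-complex study design: a handful of species with a
#' few specimens each, genotyped at 40 loci.
#'
#' @param seed Integer seed; when non-`NULL` each generator seeds the RNG
#'   on entry so outputs are bit-reproducible.
#' @param n_species Number of extant species in the species tree.
#' @param samples_per_species Specimens sampled per species.
#' @param lambda,mu Speciation and extinction rates (per Ma); `lambda > mu`.
#' @param shift Optional rate shift: `list(t = <forward time from the crown
#'   at which rates switch>, lambda2 = <post-shift speciation rate>)`.
#' @param crown_age Age the simulated chronogram is rescaled to (Ma).
#' @param theta Coalescent population parameter, same units as the species
#'   tree; pairwise coalescence rate `2 / theta`.
#' @param loci Number of loci.
#' @param sites Alignment length per locus.
#' @param kappa HKY transition/transversion rate ratio.
#' @param pi Base frequencies (A, C, G, T), summing to 1.
#' @param rate Substitutions per site per Ma used to rescale coalescent
#'   branch lengths before sequence simulation.
#' @param bootstrap Bootstrap replicate count for [nj_with_bootstrap()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = NULL, n_species = 8, samples_per_species = 3,
                       lambda = 0.4, mu = 0, shift = NULL, crown_age = 10,
                       theta = 0.05, loci = 40, sites = 500, kappa = 2,
                       pi = rep(0.25, 4), rate = 0.005, bootstrap = 100) {
  stopifnot(lambda > mu, mu >= 0, is.na(theta) || theta > 0,
            abs(sum(pi) - 1) < 1e-9)
  structure(list(seed = seed, n_species = n_species,
                 samples_per_species = samples_per_species, lambda = lambda,
                 mu = mu, shift = shift, crown_age = crown_age,
                 theta = theta, loci = loci, sites = sites, kappa = kappa,
                 pi = pi, rate = rate, bootstrap = bootstrap,
                 preset = NA_character_),
            class = "sim_config")
}

#' @rdname sim_config
#' @details
#' The presets fix the coalescent parameter relative to the *realized*
#' species tree so that their defining property holds by construction:
#' under `deep_preset()` every species divergence depth is at least
#' `10 * theta` (theta is set to one tenth of the shallowest species
#' split), while under `shallow_preset()` the whole tree is about one
#' coalescent unit deep (`theta = crown_age`), giving pervasive incomplete
#' lineage sorting.
#' @export
deep_preset <- function(seed = NULL) {
  cfg <- sim_config(seed = seed, theta = NA, crown_age = 10, rate = 0.01)
  cfg$preset <- "deep"
  cfg
}

#' @rdname sim_config
#' @export
shallow_preset <- function(seed = NULL) {
  cfg <- sim_config(seed = seed, theta = NA, crown_age = 10, rate = 0.01)
  cfg$preset <- "shallow"
  cfg
}

maybe_seed <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  invisible(NULL)
}

#' Simulate a birth-death chronogram with n extant species
#'
#' Forward-time constant-rate (or two-rate, with a speciation-rate shift at
#' a fixed time after the crown) birth-death simulation.  The process runs
#' until the `(n+1)`-th extant lineage would arise; the present is then
#' drawn uniformly within that final waiting interval, extinct lineages are
#' pruned, and the reconstructed tree is returned — an approximate
#' conditioning on the extant tip count.  Replicates in which the clade
#' dies are rejected (up to 1000 retries).  When `cfg$crown_age` is set the
#' tree is rescaled to that crown age.
#'
#' @param cfg A [sim_config()].
#' @return An ultrametric `phylo` with `n_species` tips labelled
#'   `t1..tn`, flagged as a chronogram.
#' @export
simulate_chronogram <- function(cfg = sim_config()) {
  maybe_seed(cfg)
  n <- cfg$n_species
  stopifnot(n >= 2, cfg$lambda > 0)
  lam2 <- if (!is.null(cfg$shift)) cfg$shift$lambda2 else cfg$lambda
  tshift <- if (!is.null(cfg$shift)) cfg$shift$t else Inf
  for (try in seq_len(1000L)) {
    birth <- c(0, 0); death <- c(NA_real_, NA_real_); parent <- c(0L, 0L)
    alive <- c(TRUE, TRUE)
    t <- 0; present <- NA_real_
    repeat {
      k <- sum(alive)
      if (k == 0L) break
      lam <- if (t < tshift) cfg$lambda else lam2
      tot <- k * (lam + cfg$mu)
      wait <- stats::rexp(1, tot)
      # a rate shift inside the waiting interval invalidates the draw:
      # restart the clock from the shift (memoryless in each regime)
      if (t < tshift && t + wait > tshift) {
        t <- tshift
        next
      }
      t_ev <- t + wait
      is_birth <- stats::runif(1) < lam / (lam + cfg$mu)
      if (is_birth && k == n) {
        present <- t + stats::runif(1) * wait
        break
      }
      who <- sample(which(alive), 1L)
      if (is_birth) {
        birth <- c(birth, t_ev); death <- c(death, NA_real_)
        parent <- c(parent, who); alive <- c(alive, TRUE)
      } else {
        death[who] <- t_ev; alive[who] <- FALSE
      }
      t <- t_ev
    }
    if (is.na(present)) next
    tree <- reconstruct_tree(birth, death, parent, present)
    if (is.null(tree) || length(tree$tip.label) != n) next
    if (!is.null(cfg$crown_age)) {
      tree$edge.length <- tree$edge.length *
        (cfg$crown_age / max(node_ages(tree)))
    }
    tree$tip.label <- sprintf("t%d", seq_len(n))
    return(as_chronogram(tree))
  }
  stop("birth-death simulation failed 1000 times (whole-clade extinction)")
}

# Build the reconstructed (extinct-pruned) tree from forward-time lineage
# records; lineages alive at `present` become tips.
reconstruct_tree <- function(birth, death, parent, present) {
  end_time <- pmin(ifelse(is.na(death), present, death), present)
  extant <- is.na(death) | death >= present
  nwk_of <- function(l, t0) {
    evs <- which(parent == l & birth > t0 & birth < end_time[l])
    evs <- evs[order(birth[evs])]
    if (!length(evs)) {
      lab <- if (extant[l]) sprintf("L%d", l) else sprintf("X%d", l)
      return(sprintf("%s:%.12g", lab, end_time[l] - t0))
    }
    ev <- evs[1]
    sprintf("(%s,%s):%.12g", nwk_of(l, birth[ev]), nwk_of(ev, birth[ev]),
            birth[ev] - t0)
  }
  left <- nwk_of(1L, 0); right <- nwk_of(2L, 0)
  tree <- tryCatch(ape::read.tree(text = sprintf("(%s,%s);", left, right)),
                   error = function(e) NULL)
  if (is.null(tree)) return(NULL)
  dead <- grep("^X", tree$tip.label, value = TRUE)
  if (length(dead) >= length(tree$tip.label) - 1L) return(NULL)
  if (length(dead)) tree <- ape::drop.tip(tree, dead)
  tree
}

#' Simulate multispecies-coalescent gene trees within a species tree
#'
#' One allele per specimen per locus; within each species-tree branch a
#' Kingman coalescent runs with pairwise rate `2 / theta`, lineages
#' entering a branch join that branch's pool, and all survivors coalesce
#' above the root.  Specimen labels are `<species>_s<i>`.
#'
#' @param species_tree Ultrametric `phylo` whose tips are species ids.
#' @param cfg A [sim_config()] (uses `samples_per_species`, `theta`,
#'   `loci`, `seed`).
#' @return List of `phylo` gene trees (length `cfg$loci`).
#' @export
simulate_msc_gene_trees <- function(species_tree, cfg = sim_config()) {
  maybe_seed(cfg)
  ages <- node_ages(species_tree)
  ntip <- length(species_tree$tip.label)
  kids <- children_list(species_tree)
  root <- ntip + 1L
  lapply(seq_len(cfg$loci), function(l) {
    msc_one_locus_n(species_tree, ages, kids, root, ntip, cfg,
                    function(sp) cfg$samples_per_species)
  })
}

#' Simulate sequences along a tree under HKY
#'
#' The root state is drawn from the stationary frequencies and each site
#' evolves independently under HKY(`kappa`, `pi`); branch lengths are in
#' expected substitutions per site (rescale coalescent trees with
#' `cfg$rate` first).  Simulation is delegated to [phangorn::simSeq()].
#'
#' @param tree A `phylo` with branch lengths in substitutions/site.
#' @param cfg A [sim_config()] (uses `sites`, `kappa`, `pi`, `seed`).
#' @return A `seq_alignment`.
#' @export
simulate_sequences <- function(tree, cfg = sim_config()) {
  maybe_seed(cfg)
  k <- cfg$kappa
  dat <- phangorn::simSeq(tree, l = cfg$sites, Q = c(1, k, 1, 1, k, 1),
                          bf = cfg$pi, type = "DNA")
  m <- toupper(as.character(dat))
  new_alignment(apply(m, 1, paste, collapse = ""), rownames(m))
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Saitou-Nei neighbor joining on pairwise distances, negative branch
#' lengths clamped to zero, rooted at the outgroup; node supports are the
#' percentage of `cfg$bootstrap` column-resampling replicates whose NJ
#' tree contains each clade of the original rooted tree (stored as `mlb`).
#'
#' @param aln A `seq_alignment` with at least 4 taxa.
#' @param cfg A [sim_config()] (uses `bootstrap`, `seed`).
#' @param outgroup Taxon id to root at (must be in the alignment).
#' @param dist_config A [distance_config()].
#' @return Rooted `phylo` with a `support` data frame (`mlb` percentages).
#' @export
nj_with_bootstrap <- function(aln, cfg = sim_config(), outgroup,
                              dist_config = distance_config()) {
  maybe_seed(cfg)
  stopifnot(nrow(aln) >= 4L)
  if (!outgroup %in% rownames(aln)) stop("outgroup not in alignment: ", outgroup)
  taxa <- rownames(aln)
  m0 <- toupper(unclass(aln))
  X <- lapply(c("A", "C", "G", "T"), function(b) (m0 == b) * 1)
  dist_from <- function(cols) {
    Xb <- lapply(X, function(x) x[, cols, drop = FALSE])
    C <- Reduce(`+`, Xb)
    N <- tcrossprod(C)
    if (any(N[upper.tri(N)] == 0)) {
      ij <- which(N == 0 & upper.tri(N), arr.ind = TRUE)[1, ]
      stop("undefined distance: no comparable sites for pair (",
           taxa[ij[1]], ", ", taxa[ij[2]], ")")
    }
    M <- Reduce(`+`, lapply(Xb, tcrossprod))
    if (dist_config$model == "p_distance") {
      D <- 1 - M / N
    } else {
      TS <- tcrossprod(Xb[[1]], Xb[[3]]) + tcrossprod(Xb[[3]], Xb[[1]]) +
        tcrossprod(Xb[[2]], Xb[[4]]) + tcrossprod(Xb[[4]], Xb[[2]])
      w1 <- 1 - 2 * TS / N - (N - M - TS) / N
      w2 <- 1 - 2 * (N - M - TS) / N
      if (any((w1 <= 0 | w2 <= 0) & upper.tri(N))) {
        stop("K2P saturation in bootstrap distance computation")
      }
      D <- -0.5 * log(w1) - 0.25 * log(w2)
    }
    diag(D) <- 0
    dimnames(D) <- list(taxa, taxa)
    D
  }
  nj_rooted <- function(D) {
    tr <- ape::nj(D)
    tr$edge.length[tr$edge.length < 0] <- 0
    ape::root(tr, outgroup, resolve.root = TRUE)
  }
  tree <- nj_rooted(dist_from(seq_len(ncol(m0))))
  keys0 <- clade_keys(tree, taxa)
  counts <- numeric(length(keys0))
  B <- cfg$bootstrap
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(m0), ncol(m0), replace = TRUE)
    trb <- tryCatch(nj_rooted(dist_from(cols)), error = function(e) NULL)
    if (is.null(trb)) next
    counts <- counts + (keys0 %in% clade_keys(trb, taxa))
  }
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  sup <- data.frame(node = nodes, mlb = round(100 * counts / B, 1),
                    bpp = NA_real_, primary = NA_character_,
                    stringsAsFactors = FALSE)
  sup <- sup[sup$node != ntip + 1L, , drop = FALSE]   # no support on root
  tree$support <- sup
  tree
}

# Clade identity keys: each internal node's descendant tip set encoded as a
# sum of powers of two over a reference taxon ordering (exact for < 53
# taxa, plenty for desk-scale fixtures).
clade_keys <- function(tree, ref_taxa) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  w <- numeric(nn)
  w[seq_len(ntip)] <- 2^(match(tree$tip.label, ref_taxa) - 1)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    w[ord$edge[i, 1]] <- w[ord$edge[i, 1]] + w[ord$edge[i, 2]]
  }
  w[(ntip + 1L):nn]
}

#' Simulate tip ranges under DEC
#'
#' Gillespie simulation of anagenetic dispersal/extinction along each
#' branch under the [build_dec_q()] generator, with cladogenetic outcomes
#' drawn uniformly from the allowed set at each node.  A lineage hitting
#' the null range rejects the whole replicate (up to 1000 retries).
#'
#' @param chronogram Bifurcating ultrametric `phylo`.
#' @param d,e DEC rates.
#' @param cfg A [sim_config()] (uses `seed`).
#' @param areas Area codes.
#' @param max_range_size Largest allowed range.
#' @param root_range Character vector of area codes for the root; drawn
#'   uniformly from the observable states when `NULL`.
#' @return A `range_matrix` over the tips, with attribute `node_states`
#'   (true range label per node) for recovery experiments.
#' @export
simulate_dec_ranges <- function(chronogram, d, e, cfg = sim_config(),
                                areas = LETTERS[1:6],
                                max_range_size = length(areas),
                                root_range = NULL) {
  maybe_seed(cfg)
  model <- dec_model(areas, d, e, max_range_size)
  st <- model$states
  Q <- build_dec_q(model)
  outcomes <- clado_outcomes(st)
  null_id <- length(st$sets)
  ntip <- length(chronogram$tip.label)
  nn <- ntip + chronogram$Nnode
  kids <- children_list(chronogram)
  edge_of <- integer(nn)
  edge_of[chronogram$edge[, 2]] <- seq_len(nrow(chronogram$edge))
  root <- ntip + 1L
  root_id <- if (is.null(root_range)) NA_integer_ else {
    match(paste(areas[sort(match(root_range, areas))], collapse = ""), st$labels)
  }
  evolve <- function(s, t_len) {
    t <- 0
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) return(s)
      wait <- stats::rexp(1, rate)
      if (t + wait > t_len) return(s)
      t <- t + wait
      probs <- Q[s, ]; probs[s] <- 0
      s <- sample.int(length(probs), 1L, prob = probs)
      if (s == null_id) return(NA_integer_)
    }
  }
  for (try in seq_len(1000L)) {
    state <- integer(nn)
    state[root] <- if (is.na(root_id)) {
      sample.int(st$n_observable, 1L)
    } else root_id
    ok <- TRUE
    stack <- root
    while (length(stack) && ok) {
      v <- stack[1]; stack <- stack[-1]
      cs <- kids[[v]]
      if (is.null(cs)) next
      oc <- outcomes[[state[v]]]
      pick <- oc[sample.int(nrow(oc), 1L), ]
      for (k in 1:2) {
        ch <- cs[k]
        s_end <- evolve(pick[k], chronogram$edge.length[edge_of[ch]])
        if (is.na(s_end)) { ok <- FALSE; break }
        state[ch] <- s_end
        if (ch > ntip) stack <- c(stack, ch)
      }
    }
    if (!ok) next
    ranges <- lapply(seq_len(ntip), function(i) areas[st$sets[[state[i]]]])
    names(ranges) <- chronogram$tip.label
    rm <- new_range_matrix(ranges, areas)
    attr(rm, "node_states") <- stats::setNames(st$labels[state],
                                               as.character(seq_len(nn)))
    return(rm)
  }
  stop("DEC range simulation rejected 1000 replicates (null range reached)")
}

#' Build a complete benchmark fixture
#'
#' Assembles one desk-scale synthetic study: a species chronogram with an
#' outgroup grafted on the stem, the true specimen partition, per-locus
#' multispecies-coalescent gene trees turned into sequence alignments and
#' re-estimated by neighbor joining with bootstrap supports, and DEC tip
#' ranges.  When `dir` is given everything is also written in the
#' pipeline's file formats (Newick/FASTA/TSV plus a truth JSON).
#'
#' @param cfg A [sim_config()]; use [deep_preset()] / [shallow_preset()].
#' @param dir Optional output directory.
#' @param d,e DEC rates used for range simulation.
#' @return List with `species_tree` (ingroup chronogram), `partition`
#'   (truth), `gene_trees` (with `mlb` supports, rooted at the outgroup),
#'   `alignments`, `ranges`, `outgroup` (specimen id), `cfg`.
#' @export
make_benchmark_fixture <- function(cfg = deep_preset(), dir = NULL,
                                   d = 0.05, e = 0.02) {
  maybe_seed(cfg)
  inner <- cfg; inner$seed <- NULL
  # draw species trees until the internal nodes are mutually separated and
  # none sits too close to the present -- emulates a species complex whose
  # members are distinguishable lineages rather than a hard polytomy
  sp_tree <- NULL
  for (try in seq_len(500L)) {
    cand <- simulate_chronogram(inner)
    ages <- sort(node_ages(cand)[-(seq_along(cand$tip.label))])
    crown0 <- max(ages)
    if (ages[1] >= 0.1 * crown0 && min(diff(c(0, ages))) >= 0.05 * crown0) {
      sp_tree <- cand
      break
    }
  }
  if (is.null(sp_tree)) stop("no species tree met the separation condition")
  crown <- max(node_ages(sp_tree))
  if (!is.na(cfg$preset)) {
    min_split <- min(node_ages(sp_tree)[-(seq_along(sp_tree$tip.label))])
    inner$theta <- switch(cfg$preset,
                          deep = min_split / 10,
                          shallow = crown)
  }
  if (is.na(inner$theta)) stop("theta is NA and no preset is set")
  core <- sub(";$", "", write_tree(sp_tree))
  full <- ape::read.tree(text = sprintf("(%s:%.12g,OUT:%.12g);",
                                        core, 0.5 * crown, 1.5 * crown))
  full <- as_chronogram(full)
  partition <- new_partition(stats::setNames(
    rep(sp_tree$tip.label, each = cfg$samples_per_species),
    as.vector(t(outer(sp_tree$tip.label, seq_len(cfg$samples_per_species),
                      function(s, i) sprintf("%s_s%d", s, i))))))
  # gene trees: one allele per specimen for ingroup species, one for OUT
  gene_raw <- simulate_msc_gene_trees_mixed(full, inner, "OUT")
  outgroup_tip <- "OUT_s1"
  alignments <- vector("list", cfg$loci)
  gene_trees <- vector("list", cfg$loci)
  for (l in seq_len(cfg$loci)) {
    gt <- gene_raw[[l]]
    gt$edge.length <- gt$edge.length * cfg$rate
    aln <- simulate_sequences(gt, inner)
    alignments[[l]] <- aln
    gene_trees[[l]] <- nj_with_bootstrap(aln, inner, outgroup_tip)
  }
  names(gene_trees) <- names(alignments) <- sprintf("locus%03d", seq_len(cfg$loci))
  ranges <- simulate_dec_ranges(sp_tree, d, e, inner,
                                areas = LETTERS[1:4],
                                max_range_size = 2L)
  fx <- list(species_tree = sp_tree, partition = partition,
             gene_trees = gene_trees, alignments = alignments,
             ranges = ranges, outgroup = outgroup_tip, cfg = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_tree(sp_tree, file.path(dir, "species_tree.nwk"))
    write_partition(partition, file.path(dir, "partition.tsv"))
    write_ranges(ranges, file.path(dir, "ranges.tsv"))
    for (l in seq_len(cfg$loci)) {
      write_alignment(alignments[[l]], file.path(dir, sprintf("aln_%03d.fasta", l)))
      write_tree(gene_trees[[l]], file.path(dir, sprintf("genetree_%03d.nwk", l)))
    }
    jsonlite::write_json(
      list(species = sp_tree$tip.label, outgroup = outgroup_tip,
           samples_per_species = cfg$samples_per_species,
           theta = cfg$theta, crown_age = cfg$crown_age, loci = cfg$loci),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  fx
}

# MSC with one sample per species for `single` and cfg$samples_per_species
# for the rest.
simulate_msc_gene_trees_mixed <- function(species_tree, cfg, single) {
  n_of <- function(sp) if (sp %in% single) 1L else cfg$samples_per_species
  ages <- node_ages(species_tree)
  ntip <- length(species_tree$tip.label)
  kids <- children_list(species_tree)
  root <- ntip + 1L
  lapply(seq_len(cfg$loci), function(l) {
    msc_one_locus_n(species_tree, ages, kids, root, ntip, cfg, n_of)
  })
}

msc_one_locus_n <- function(tree, ages, kids, root, ntip, cfg, n_of) {
  coalesce_pool <- function(pool, t_start, t_end) {
    t <- t_start
    while (length(pool) > 1L) {
      k <- length(pool)
      wait <- stats::rexp(1, k * (k - 1) / cfg$theta)
      if (t + wait > t_end) break
      t <- t + wait
      ij <- sample.int(k, 2L)
      a <- pool[[ij[1]]]; b <- pool[[ij[2]]]
      merged <- list(nwk = sprintf("(%s:%.12g,%s:%.12g)", a$nwk, t - a$age,
                                   b$nwk, t - b$age), age = t)
      pool <- c(pool[-ij], list(merged))
    }
    pool
  }
  pool_at <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) {
    sp <- tree$tip.label[i]
    pool_at[[i]] <- lapply(seq_len(n_of(sp)), function(s) {
      list(nwk = sprintf("%s_s%d", sp, s), age = 0)
    })
  }
  ord <- ape::reorder.phylo(tree, "postorder")
  parents <- unique(ord$edge[, 1])
  for (v in parents) {
    pool <- list()
    for (ch in kids[[v]]) {
      pool <- c(pool, coalesce_pool(pool_at[[ch]], ages[ch], ages[v]))
    }
    pool_at[[v]] <- pool
  }
  pool <- coalesce_pool(pool_at[[root]], ages[root], Inf)
  ape::read.tree(text = paste0(pool[[1]]$nwk, ";"))
}
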