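#' Enumerate DEC range states
#'
#' All non-empty subsets of the areas with at most `max_range_size`
#' members, ordered by size then lexicographically, plus the null (empty)
#' range appended last as a purely computational absorbing state.
#'
#' @param areas Ordered character vector of area codes.
#' @param max_range_size Largest allowed range (default: all areas).
#' @return A `dec_states`: list with `areas`, `max_range_size`, `sets`
#'   (list of integer area-index vectors; the last is the empty null
#'   range), `labels` (e.g. `"AC"`; null is `""`), `n_observable`.
#' @export
enumerate_ranges <- function(areas, max_range_size = length(areas)) {
  A <- length(areas)
  if (A < 1L) stop("area list must be non-empty")
  stopifnot(max_range_size >= 1L, max_range_size <= A)
  sets <- list()
  for (k in seq_len(max_range_size)) {
    cmb <- utils::combn(A, k, simplify = FALSE)
    lab <- vapply(cmb, function(ix) paste(areas[ix], collapse = ""), character(1))
    sets <- c(sets, cmb[order(lab)])
  }
  n_obs <- length(sets)
  sets <- c(sets, list(integer(0)))        # null range, internal only
  labels <- vapply(sets, function(ix) paste(areas[ix], collapse = ""), character(1))
  structure(list(areas = areas, max_range_size = max_range_size,
                 sets = sets, labels = labels, n_observable = n_obs),
            class = "dec_states")
}

#' DEC model specification
#'
#' @param areas Ordered area codes.
#' @param d Dispersal (range-expansion) rate per source area per Ma.
#' @param e Extinction (range-contraction) rate per area per Ma.
#' @param max_range_size Largest allowed range.
#' @return A `dec_model` list holding the rates and the enumerated states.
#' @export
dec_model <- function(areas, d, e, max_range_size = length(areas)) {
  stopifnot(d >= 0, e >= 0)
  structure(list(areas = areas, d = d, e = e,
                 max_range_size = max_range_size,
                 states = enumerate_ranges(areas, max_range_size)),
            class = "dec_model")
}

#' Anagenetic DEC rate matrix
#'
#' Off-diagonal rates: range expansion `R -> R + {j}` at rate `d * |R|`
#' (each occupied area is a dispersal source), contraction `R -> R - {i}`
#' at rate `e` per occupied area, singletons to the null range at `e`;
#' the null range is absorbing.  Rows sum to zero.
#'
#' @param model A [dec_model()].
#' @return Square rate matrix over the states (null last), with state
#'   labels as dimnames.
#' @export
build_dec_q <- function(model) {
  st <- model$states
  S <- length(st$sets)
  sid <- function(ix) match(paste(st$areas[sort(ix)], collapse = ""), st$labels)
  Q <- matrix(0, S, S, dimnames = list(st$labels, st$labels))
  for (s in seq_len(st$n_observable)) {
    R <- st$sets[[s]]
    if (length(R) < st$max_range_size) {
      for (j in setdiff(seq_along(st$areas), R)) {
        tgt <- sid(c(R, j))
        Q[s, tgt] <- Q[s, tgt] + model$d * length(R)
      }
    }
    for (i in R) {
      tgt <- sid(setdiff(R, i))
      Q[s, tgt] <- Q[s, tgt] + model$e
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

# Ordered cladogenetic outcomes (daughter1, daughter2) for each observable
# ancestral state, all equally weighted:
#   |R| = 1: both daughters inherit R;
#   |R| >= 2: subset sympatry ({i}, R) and vicariance ({i}, R \ {i}),
#   each with both left/right assignments.
clado_outcomes <- function(states) {
  sid <- function(ix) {
    match(paste(states$areas[sort(ix)], collapse = ""), states$labels)
  }
  lapply(seq_len(states$n_observable), function(s) {
    R <- states$sets[[s]]
    if (length(R) == 1L) {
      matrix(c(s, s), ncol = 2)
    } else {
      out <- matrix(0L, nrow = 4L * length(R), ncol = 2)
      r <- 0L
      for (i in R) {
        si <- sid(i)
        rest <- sid(setdiff(R, i))
        out[r + 1L, ] <- c(si, s)       # subset sympatry, both orders
        out[r + 2L, ] <- c(s, si)
        out[r + 3L, ] <- c(si, rest)    # vicariance, both orders
        out[r + 4L, ] <- c(rest, si)
        r <- r + 4L
      }
      # for |R| = 2 the two vicariance splits coincide across i; outcomes
      # are a set, so drop duplicates
      unique(out)
    }
  })
}

# Shared machinery: postorder conditional likelihoods (pruning) with
# per-node rescaling.  Returns per-node CL vectors (pre-cladogenesis state
# at internal nodes, observed indicator at tips), per-node branch
# transition matrices, per-node "M" vectors (daughter-initial-state to
# subtree-data likelihood), and the total log-likelihood.
dec_prune <- function(tree, tips, model, Q = build_dec_q(model)) {
  st <- model$states
  S <- length(st$sets)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  areas <- attr(tips, "areas")
  if (!identical(areas, model$areas)) stop("range matrix areas do not match model")
  missing <- setdiff(tree$tip.label, rownames(tips))
  if (length(missing)) stop("tip without a coded range: ", missing[1])

  outcomes <- clado_outcomes(st)
  # transition matrix cache keyed by branch length
  el <- tree$edge.length
  uniq <- unique(el)
  Pcache <- lapply(uniq, function(t) {
    as.matrix(Matrix::expm(Q * t))
  })
  Pm <- function(t) Pcache[[match(t, uniq)]]

  CL <- matrix(0, nn, S)
  M <- matrix(0, nn, S)                  # row: node; likelihood of node's
                                         # subtree given its *initial* state
                                         # at the top of its parent branch
  logscale <- numeric(nn)
  for (i in seq_len(ntip)) {
    lab <- paste(areas[tips[tree$tip.label[i], ]], collapse = "")
    s <- match(lab, st$labels)
    if (is.na(s)) {
      stop("tip range ", lab, " of ", tree$tip.label[i],
           " not in the state space (max_range_size too small?)")
    }
    CL[i, s] <- 1
  }
  ord <- ape::reorder.phylo(tree, "postorder")
  kids <- children_list(tree)
  edge_of <- integer(nn)
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  nodes_post <- unique(ord$edge[, 1])    # parents in postorder
  for (v in nodes_post) {
    cs <- kids[[v]]
    if (length(cs) != 2L) stop("DEC requires a bifurcating tree (node ", v, ")")
    m1 <- Pm(el[edge_of[cs[1]]]) %*% CL[cs[1], ]
    m2 <- Pm(el[edge_of[cs[2]]]) %*% CL[cs[2], ]
    M[cs[1], ] <- m1
    M[cs[2], ] <- m2
    cl <- numeric(S)
    for (s in seq_len(st$n_observable)) {
      oc <- outcomes[[s]]
      cl[s] <- sum(m1[oc[, 1]] * m2[oc[, 2]]) / nrow(oc)
    }
    sc <- max(cl)
    if (sc <= 0) stop("DEC likelihood underflow at node ", v)
    CL[v, ] <- cl / sc
    logscale[v] <- log(sc) + sum(logscale[cs])
  }
  root <- ntip + 1L
  lik <- sum(CL[root, seq_len(st$n_observable)])
  list(CL = CL, M = M, logscale = logscale, Pm = Pm, outcomes = outcomes,
       logL = log(lik) + logscale[root], root = root, ntip = ntip,
       kids = kids, edge_of = edge_of, el = el, states = st)
}

#' DEC log-likelihood of tip ranges on a chronogram
#'
#' Felsenstein pruning over the DEC state space: anagenetic dispersal and
#' extinction along branches (matrix exponential of the [build_dec_q()]
#' generator), equally weighted cladogenetic outcomes at nodes, and a flat
#' root prior summing the root partial likelihoods over the observable
#' states.
#'
#' @param chronogram Ultrametric bifurcating `phylo`.
#' @param tips A `range_matrix` covering every tip.
#' @param d,e Dispersal and extinction rates (per Ma).
#' @param max_range_size Largest allowed range.
#' @return Log-likelihood (scalar).
#' @export
dec_loglik <- function(chronogram, tips, d, e,
                       max_range_size = length(attr(tips, "areas"))) {
  model <- dec_model(attr(tips, "areas"), d, e, max_range_size)
  dec_prune(chronogram, tips, model)$logL
}

#' Maximum-likelihood DEC rates
#'
#' Bounded numerical optimisation of `(d, e)` on the log scale (bounds
#' `[1e-8, 100]` each), multi-start from three initial points spread
#' around one expected event per tree depth.
#'
#' @inheritParams dec_loglik
#' @return List with `d`, `e`, `logL`, and `convergence` (0 = clean).
#' @export
fit_dec <- function(chronogram, tips,
                    max_range_size = length(attr(tips, "areas"))) {
  areas <- attr(tips, "areas")
  depth <- max(node_ages(chronogram))
  obj <- function(p) {
    -dec_loglik(chronogram, tips, exp(p[1]), exp(p[2]), max_range_size)
  }
  s <- 1 / depth
  starts <- list(log(c(0.1 * s, 0.1 * s)), log(c(s, s)), log(c(5 * s, 0.5 * s)))
  best <- NULL
  for (p0 in starts) {
    o <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B",
                   lower = log(1e-8), upper = log(100),
                   control = list(factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("DEC fit failed to converge from all starts")
  list(d = exp(best$par[1]), e = exp(best$par[2]), logL = -best$value,
       convergence = best$convergence)
}

#' Marginal ancestral range probabilities under DEC
#'
#' Standard up-down (outside-inside) passes consistent with
#' [dec_loglik()]: the marginal probability of each observable range at
#' each internal node (the lineage's range immediately before it splits),
#' normalised per node.
#'
#' @inheritParams dec_loglik
#' @param prob_min Ranges with probability below this are dropped from the
#'   formatted display strings (full distribution always returned).
#' @return An `ancestral_ranges` object: list with `prob` (internal node x
#'   observable-range probability matrix), `display` (per node,
#'   `"AC/0.48"`-style strings for ranges with probability >=
#'   `prob_min`), `d`, `e`, `logL`.
#' @export
ancestral_ranges <- function(chronogram, tips, d, e,
                             max_range_size = length(attr(tips, "areas")),
                             prob_min = 0.05) {
  model <- dec_model(attr(tips, "areas"), d, e, max_range_size)
  pr <- dec_prune(chronogram, tips, model)
  st <- pr$states
  S <- length(st$sets)
  nobs <- st$n_observable
  ntip <- pr$ntip
  nn <- ntip + chronogram$Nnode

  O <- matrix(0, nn, S)                  # outside likelihood, pre-cladogenesis
  O[pr$root, seq_len(nobs)] <- 1         # flat root prior
  # preorder: parents before children
  ord <- ape::reorder.phylo(chronogram, "postorder")
  parents_pre <- rev(unique(ord$edge[, 1]))
  for (v in parents_pre) {
    cs <- pr$kids[[v]]
    for (k in 1:2) {
      ch <- cs[k]; sib <- cs[3 - k]
      G <- numeric(S)                    # outside at child's initial state
      for (s in seq_len(nobs)) {
        if (O[v, s] == 0) next
        oc <- pr$outcomes[[s]]
        w <- O[v, s] / nrow(oc)
        # ordered outcomes: column 1 toward this child, column 2 toward sib
        for (r in seq_len(nrow(oc))) {
          G[oc[r, 1]] <- G[oc[r, 1]] + w * pr$M[sib, oc[r, 2]]
        }
      }
      O[ch, ] <- crossprod(pr$Pm(pr$el[pr$edge_of[ch]]), G)
    }
  }
  internal <- (ntip + 1L):nn
  prob <- matrix(0, length(internal), nobs,
                 dimnames = list(as.character(internal),
                                 st$labels[seq_len(nobs)]))
  for (i in seq_along(internal)) {
    v <- internal[i]
    w <- pr$CL[v, seq_len(nobs)] * O[v, seq_len(nobs)]
    tot <- sum(w)
    if (tot <= 0) stop("zero marginal mass at node ", v)
    prob[i, ] <- w / tot
  }
  display <- apply(prob, 1, function(p) {
    keep <- which(p >= prob_min)
    keep <- keep[order(p[keep], decreasing = TRUE)]
    paste(sprintf("%s/%.2f", colnames(prob)[keep], p[keep]), collapse = " ")
  })
  structure(list(prob = prob, display = display, d = d, e = e,
                 logL = pr$logL), class = "ancestral_ranges")
}

#' @export
print.ancestral_ranges <- function(x, ...) {
  cat("ancestral_ranges (DEC): d =", signif(x$d, 4), " e =", signif(x$e, 4),
      " logL =", round(x$logL, 3), "\n")
  for (nm in names(x$display)) cat("  node", nm, ":", x$display[[nm]], "\n")
  invisible(x)
}

#' Per-area binary ancestral reconstruction (BBM surrogate)
#'
#' A deterministic stand-in for Bayesian binary MCMC ancestral-area
#' estimation: each area is treated as an independent two-state
#' (absent/present) continuous-time Markov character; gain and loss rates
#' are fitted by maximum likelihood per area, and marginal presence
#' probabilities at internal nodes come from standard two-state pruning
#' with a flat root prior.  Output is labelled "BBM surrogate" — it is a
#' maximum-likelihood analogue, not the MCMC.
#'
#' @inheritParams dec_loglik
#' @return A `bbm_surrogate`: list with `prob` (internal node x area matrix
#'   of presence probabilities), `rates` (per area gain/loss), `method`.
#' @export
binary_area_reconstruction <- function(chronogram, tips) {
  areas <- attr(tips, "areas")
  ntip <- length(chronogram$tip.label)
  internal <- (ntip + 1L):(ntip + chronogram$Nnode)
  prob <- matrix(NA_real_, length(internal), length(areas),
                 dimnames = list(as.character(internal), areas))
  rates <- data.frame(area = areas, gain = NA_real_, loss = NA_real_)
  for (a in seq_along(areas)) {
    x <- as.integer(tips[chronogram$tip.label, a])   # 0 absent / 1 present
    if (all(x == x[1])) {
      warning("area ", areas[a], " constant across tips; probability fixed")
      prob[, a] <- x[1]
      next
    }
    fit <- fit_two_state(chronogram, x)
    rates$gain[a] <- fit$q01
    rates$loss[a] <- fit$q10
    prob[, a] <- fit$marginal[internal - ntip, 2]    # P(present)
  }
  structure(list(prob = prob, rates = rates, method = "BBM surrogate (ML)"),
            class = "bbm_surrogate")
}

#' @export
print.bbm_surrogate <- function(x, ...) {
  cat(x$method, "- per-node presence probabilities\n")
  print(round(x$prob, 3))
  invisible(x)
}

# Two-state CTMC: ML rates + marginal node probabilities by pruning and an
# up-down pass; flat (1/2, 1/2) root prior.
fit_two_state <- function(tree, x) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  kids <- children_list(tree)
  edge_of <- integer(nn)
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  el <- tree$edge.length
  ord <- ape::reorder.phylo(tree, "postorder")
  nodes_post <- unique(ord$edge[, 1])

  pmat <- function(q01, q10, t) {
    s <- q01 + q10
    if (s == 0) return(diag(2))
    et <- exp(-s * t)
    matrix(c(q10 + q01 * et, q10 - q10 * et,
             q01 - q01 * et, q01 + q10 * et), 2, 2) / s
  }
  prune <- function(q01, q10) {
    CL <- matrix(0, nn, 2)
    CL[cbind(seq_len(ntip), x + 1L)] <- 1
    logscale <- 0
    M <- matrix(0, nn, 2)
    for (v in nodes_post) {
      cs <- kids[[v]]
      cl <- rep(1, 2)
      for (ch in cs) {
        M[ch, ] <- pmat(q01, q10, el[edge_of[ch]]) %*% CL[ch, ]
        cl <- cl * M[ch, ]
      }
      sc <- max(cl)
      if (sc <= 0) return(list(logL = -Inf))
      CL[v, ] <- cl / sc
      logscale <- logscale + log(sc)
    }
    root <- ntip + 1L
    list(logL = log(sum(0.5 * CL[root, ])) + logscale, CL = CL, M = M)
  }
  obj <- function(p) -prune(exp(p[1]), exp(p[2]))$logL
  best <- NULL
  depth <- max(node_ages(tree))
  for (r0 in c(0.1, 1, 5)) {
    o <- tryCatch(
      stats::optim(log(c(r0 / depth, r0 / depth)), obj, method = "L-BFGS-B",
                   lower = log(1e-8), upper = log(100)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("two-state fit failed to converge")
  q01 <- exp(best$par[1]); q10 <- exp(best$par[2])
  pr <- prune(q01, q10)
  # up-down pass for marginals
  O <- matrix(0, nn, 2)
  root <- ntip + 1L
  O[root, ] <- 0.5
  parents_pre <- rev(nodes_post)
  for (v in parents_pre) {
    cs <- kids[[v]]
    for (k in seq_along(cs)) {
      ch <- cs[k]
      sibs <- cs[-k]
      g <- O[v, ]
      for (sb in sibs) g <- g * pr$M[sb, ]
      O[ch, ] <- crossprod(pmat(q01, q10, el[edge_of[ch]]), g)
    }
  }
  marg <- pr$CL * O
  marg <- marg / rowSums(marg)
  list(q01 = q01, q10 = q10, logL = pr$logL, marginal = marg)
}
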