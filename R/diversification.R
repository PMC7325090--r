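#' Branching times of an ultrametric chronogram
#'
#' Internal-node ages sorted in descending order (ages backward from the
#' present, tips at 0): `a_2 >= a_3 >= ... >= a_n`, where `a_k` is the age
#' of the event creating the k-th lineage and `a_2` the crown age.
#'
#' @param chronogram An ultrametric, fully bifurcating `phylo` (validated
#'   with [as_chronogram()] if not already flagged).
#' @return A `branching_times`: list with `ages` (length `n - 1`) and `n`
#'   (tip count).
#' @export
extract_branching_times <- function(chronogram) {
  if (!is_chronogram(chronogram)) chronogram <- as_chronogram(chronogram)
  ntip_ <- length(chronogram$tip.label)
  deg <- tabulate(chronogram$edge[, 1], nbins = ntip_ + chronogram$Nnode)
  if (any(deg[(ntip_ + 1L):(ntip_ + chronogram$Nnode)] != 2L)) {
    stop("chronogram contains polytomies; resolve before extracting ",
         "branching times")
  }
  ntip <- length(chronogram$tip.label)
  ages <- node_ages(chronogram)[(ntip + 1L):(ntip + chronogram$Nnode)]
  structure(list(ages = sort(ages, decreasing = TRUE), n = ntip),
            class = "branching_times")
}

#' Lineage-through-time step points
#'
#' @param bt A `branching_times`.
#' @return Data frame `age`, `lineages`: the step function from
#'   `(a_2, 2)`, rising by one at each subsequent branching age, ending at
#'   `(0, n)`.
#' @export
ltt_points <- function(bt) {
  data.frame(age = c(bt$ages, 0),
             lineages = c(seq.int(2L, bt$n), bt$n))
}

# Nudge exactly tied branching ages apart so every inter-event interval is
# strictly positive; perturbation scale 1e-9 x crown age.
untie_ages <- function(ages) {
  if (anyDuplicated(ages)) {
    eps <- 1e-9 * ages[1]
    dup <- duplicated(ages)
    k <- 0L
    for (i in which(dup)) {
      k <- k + 1L
      ages[i] <- ages[i] - k * eps
    }
    message("perturbed ", sum(dup), " tied branching age(s) by ~1e-9 x crown")
    ages <- sort(ages, decreasing = TRUE)
  }
  ages
}

# Total lineage-time G = sum_k k * (a_k - a_{k+1}) + n * a_n
# (equivalently 2*a_2 + sum of the remaining ages).
lineage_time <- function(ages) 2 * ages[1] + sum(ages[-1])

# Lineage-time split at a shift age t in (0, a_2): older and younger parts.
lineage_time_split <- function(ages, t) {
  n <- length(ages) + 1L
  bounds_lo <- c(ages[-1], 0)   # interval with k lineages: (a_{k+1}, a_k)
  G1 <- 0; G2 <- 0
  for (k in 2:n) {
    hi <- ages[k - 1L]
    lo <- bounds_lo[k - 1L]
    G1 <- G1 + k * max(0, hi - max(lo, t))
    G2 <- G2 + k * max(0, min(hi, t) - lo)
  }
  c(older = G1, younger = G2)
}

#' Fit one diversification model to branching times
#'
#' Maximum-likelihood fits of the reconstructed-tree likelihood,
#' conditioned on the crown age and tip count, with the constant
#' `log k` terms dropped consistently across models so AIC differences
#' are meaningful:
#'
#' * `pure_birth` — `logL = (n-2) log(lambda) - lambda * G` with `G` the
#'   total lineage-time; closed-form MLE `lambda = (n-2) / G`.
#' * `birth_death` — constant-rate birth-death likelihood over net rate
#'   `r = lambda - mu` and relative extinction `a = mu / lambda` in
#'   `[0, 1)`, maximised numerically (reduces to `pure_birth` at `a = 0`).
#' * `ddl` — logistic density dependence, `lambda(N) = lambda0 (1 - N/K)`.
#' * `ddx` — exponential density dependence, `lambda(N) = lambda0 N^-x`
#'   (equal to `pure_birth` at `x = 0`).
#' * `yule2rate` — pure birth with rates `lambda1` (older than a shift age
#'   `t_s`) and `lambda2` (younger); `t_s` is searched over the observed
#'   branching ages and their midpoints with at least one event on each
#'   side, rates profiled analytically per segment, ties resolved toward
#'   the older age.
#'
#' @param bt A `branching_times` with `n >= 3` (`n >= 4` for `yule2rate`).
#' @param model One of `"pure_birth"`, `"birth_death"`, `"ddl"`, `"ddx"`,
#'   `"yule2rate"`.
#' @return A `diversification_fit`: list with `model`, `params`, `logL`,
#'   `k`, `AIC`.
#' @export
fit_model <- function(bt, model = c("pure_birth", "birth_death", "ddl",
                                    "ddx", "yule2rate")) {
  model <- match.arg(model)
  n <- bt$n
  if (n < 3L) stop("insufficient data: need n >= 3 tips")
  if (model == "yule2rate" && n < 4L) stop("insufficient data: yule2rate needs n >= 4")
  ages <- untie_ages(bt$ages)
  fit <- switch(model,
    pure_birth = fit_pure_birth(ages, n),
    birth_death = fit_birth_death(ages, n),
    ddl = fit_ddl(ages, n),
    ddx = fit_ddx(ages, n),
    yule2rate = fit_yule2rate(ages, n))
  fit$model <- model
  fit$AIC <- 2 * fit$k - 2 * fit$logL
  structure(fit, class = "diversification_fit")
}

fit_pure_birth <- function(ages, n) {
  G <- lineage_time(ages)
  lambda <- (n - 2) / G
  list(params = list(lambda = lambda),
       logL = (n - 2) * log(lambda) - lambda * G, k = 1L)
}

# Nee et al. reconstructed-process likelihood; a = mu/lambda, r = lambda-mu.
bd_loglik <- function(ages, n, r, a) {
  if (r <= 0 || a < 0 || a >= 1) return(-Inf)
  # log(exp(r*x) - a) computed as r*x + log1p(-a*exp(-r*x)) for stability
  (n - 2) * log(r) + r * sum(ages[-1]) + n * log(1 - a) -
    2 * sum(r * ages + log1p(-a * exp(-r * ages)))
}

fit_birth_death <- function(ages, n) {
  obj <- function(p) -bd_loglik(ages, n, exp(p[1]), p[2])
  r0 <- (n - 2) / lineage_time(ages)
  best <- NULL
  for (a0 in c(1e-4, 0.5, 0.9)) {
    o <- tryCatch(
      stats::optim(c(log(r0), a0), obj, method = "L-BFGS-B",
                   lower = c(log(r0) - 12, 0), upper = c(log(r0) + 12, 1 - 1e-6)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("birth_death fit failed to converge")
  r <- exp(best$par[1]); a <- best$par[2]
  list(params = list(r = r, a = a), logL = -best$value, k = 2L)
}

# Generic density-dependent pure-birth likelihood: per-lineage rate lam[k]
# while k lineages exist (k = 2..n); events happen at the end of intervals
# 2..n-1; the final interval (n lineages) ends at the present without event.
dd_loglik <- function(ages, n, lam) {
  if (any(lam[1:(n - 2)] <= 0)) return(-Inf)    # rates at events k=2..n-1
  tau <- c(ages[-length(ages)] - ages[-1], ages[length(ages)])  # k=2..n
  k <- 2:n
  lam_n <- max(lam[n - 1], 0)
  sum(log(lam[1:(n - 2)])) -
    sum(k[-length(k)] * lam[1:(n - 2)] * tau[-length(tau)]) -
    n * lam_n * tau[length(tau)]
}

fit_ddl <- function(ages, n) {
  obj <- function(p) {
    lambda0 <- exp(p[1]); K <- (n - 1) + exp(p[2])
    -dd_loglik(ages, n, lambda0 * (1 - (2:n) / K))
  }
  r0 <- (n - 2) / lineage_time(ages)
  best <- NULL
  for (k0 in c(log(1), log(n), log(100 * n))) {
    o <- tryCatch(
      stats::optim(c(log(r0), k0), obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("ddl fit failed to converge")
  list(params = list(lambda0 = exp(best$par[1]), K = (n - 1) + exp(best$par[2])),
       logL = -best$value, k = 2L)
}

fit_ddx <- function(ages, n) {
  obj <- function(p) {
    lambda0 <- exp(p[1]); x <- p[2]
    if (x < 0 || x > 10) return(Inf)
    -dd_loglik(ages, n, lambda0 * (2:n)^(-x))
  }
  r0 <- (n - 2) / lineage_time(ages)
  best <- NULL
  for (x0 in c(0, 0.5, 2)) {
    o <- tryCatch(
      stats::optim(c(log(r0), x0), obj, method = "L-BFGS-B",
                   lower = c(log(r0) - 12, 0), upper = c(log(r0) + 12, 10)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("ddx fit failed to converge")
  list(params = list(lambda0 = exp(best$par[1]), x = best$par[2]),
       logL = -best$value, k = 2L)
}

fit_yule2rate <- function(ages, n) {
  events <- ages[-1]                      # a_3 .. a_n
  mids <- (c(ages[1], events) + c(events, 0)) / 2
  cand <- sort(unique(c(events, mids)), decreasing = TRUE)
  cand <- cand[cand > 0 & cand < ages[1]]
  best <- NULL
  for (t in cand) {
    c1 <- sum(events >= t)                # tie at t_s belongs to the older rate
    c2 <- length(events) - c1
    if (c1 < 1L || c2 < 1L) next
    G <- lineage_time_split(ages, t)
    logL <- c1 * (log(c1 / G[["older"]]) - 1) +
      c2 * (log(c2 / G[["younger"]]) - 1)
    # strict > keeps the oldest (first-seen) candidate on ties
    if (is.null(best) || logL > best$logL + 1e-12) {
      best <- list(params = list(lambda1 = c1 / G[["older"]],
                                 lambda2 = c2 / G[["younger"]], t_s = t),
                   logL = logL, k = 3L)
    }
  }
  if (is.null(best)) stop("yule2rate: no admissible shift age")
  best
}

#' Rate-constancy comparison across five diversification models
#'
#' Fits both rate-constant models (pure birth, birth-death) and all three
#' rate-variable models (ddl, ddx, yule2rate) and computes
#' `delta_AIC_RC = AIC(best rate-constant) - AIC(best rate-variable)`.
#' Negative values favour rate constancy.
#'
#' @param bt A `branching_times`.
#' @return A `rate_constancy_result`: list with `fits` (named list of
#'   [fit_model()] results), `delta_aic_rc`, `best_model`.
#' @export
rate_constancy <- function(bt) {
  models <- c("pure_birth", "birth_death", "ddl", "ddx", "yule2rate")
  fits <- lapply(models, function(m) fit_model(bt, m))
  names(fits) <- models
  aics <- vapply(fits, `[[`, numeric(1), "AIC")
  delta <- min(aics[c("pure_birth", "birth_death")]) -
    min(aics[c("ddl", "ddx", "yule2rate")])
  structure(list(fits = fits, delta_aic_rc = unname(delta),
                 best_model = names(which.min(aics))),
            class = "rate_constancy_result")
}

#' @export
print.rate_constancy_result <- function(x, ...) {
  aics <- vapply(x$fits, `[[`, numeric(1), "AIC")
  cat("rate_constancy_result: delta_AIC_RC =", signif(x$delta_aic_rc, 4),
      "| best model:", x$best_model, "\n")
  print(round(aics, 3))
  invisible(x)
}
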