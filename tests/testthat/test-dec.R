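test_that("range state spaces have the right size and ordering", {
  st <- enumerate_ranges(c("A", "B"), 2)
  expect_equal(st$labels, c("A", "B", "AB", ""))
  expect_equal(st$n_observable, 3L)
  expect_equal(enumerate_ranges(LETTERS[1:6], 6)$n_observable, 63L)
  expect_equal(enumerate_ranges(LETTERS[1:6], 2)$n_observable, 21L)
  # by size then lexicographic
  st3 <- enumerate_ranges(c("A", "B", "C"), 3)
  expect_equal(st3$labels[1:6], c("A", "B", "C", "AB", "AC", "BC"))
  expect_error(enumerate_ranges(character(0)), "non-empty")
})

test_that("the DEC generator has the stated rates and zero row sums", {
  Q <- build_dec_q(dec_model(c("A", "B"), d = 0.3, e = 0.07, 2))
  expect_equal(Q["A", "AB"], 0.3)        # d * |R|, |R| = 1
  expect_equal(Q["AB", "A"], 0.07)
  expect_equal(Q["AB", "B"], 0.07)
  expect_equal(unname(Q["A", 4]), 0.07)        # singleton -> null range
  expect_equal(unname(Q[4, ]), rep(0, 4))      # null absorbing
  set.seed(41)
  for (rep in 1:10) {
    A <- sample(2:5, 1)
    Q <- build_dec_q(dec_model(LETTERS[1:A], d = runif(1, 0, 2),
                               e = runif(1, 0, 2),
                               max_range_size = sample(seq_len(A), 1)))
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    off <- Q; diag(off) <- 0
    expect_true(all(off >= 0))
    # with d = 0 no expansions exist
    Q0 <- build_dec_q(dec_model(LETTERS[1:A], d = 0, e = 0.5))
    st <- enumerate_ranges(LETTERS[1:A])
    sizes <- lengths(st$sets)
    grows <- outer(sizes, sizes, FUN = "<")
    expect_true(all(Q0[grows] == 0))
  }
})

test_that("transition matrices are row-stochastic", {
  set.seed(42)
  for (rep in 1:10) {
    Q <- build_dec_q(dec_model(LETTERS[1:3], runif(1, 0, 1), runif(1, 0, 1)))
    P <- as.matrix(Matrix::expm(Q * runif(1, 0.1, 20)))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
    expect_true(all(P >= -1e-12))
  }
})

test_that("pruning likelihood equals exhaustive enumeration on 3-tip trees", {
  set.seed(43)
  for (rep in 1:8) {
    areas <- LETTERS[1:sample(2:3, 1)]
    t1 <- runif(1, 0.5, 2); t2 <- runif(1, 0.5, 2)
    tr <- as_chronogram(read_tree(text = sprintf(
      "((a:%.10f,b:%.10f):%.10f,c:%.10f);", t1, t1, t2, t1 + t2)))
    rng <- lapply(c(a = 1, b = 2, c = 3), function(i) {
      sample(areas, sample(seq_along(areas), 1))
    })
    tips <- new_range_matrix(rng, areas)
    d <- runif(1, 0.01, 0.5); e <- runif(1, 0.01, 0.3)
    oracle <- oracle_dec_3tip(tr, tips, d, e)
    expect_equal(dec_loglik(tr, tips, d, e), oracle$logL, tolerance = 1e-9)
    ar <- ancestral_ranges(tr, tips, d, e)
    expect_equal(unname(ar$prob[as.character(oracle$root_node), ]),
                 oracle$root, tolerance = 1e-9)
    expect_equal(unname(ar$prob[as.character(oracle$inner_node), ]),
                 oracle$inner, tolerance = 1e-9)
  }
})

test_that("likelihood is invariant under swapping children", {
  set.seed(44)
  tr1 <- as_chronogram(read_tree(text = "((a:1,b:1):1,c:2);"))
  tr2 <- as_chronogram(read_tree(text = "(c:2,(b:1,a:1):1);"))
  tips <- new_range_matrix(list(a = "A", b = c("A", "B"), c = "B"),
                           c("A", "B"))
  expect_equal(dec_loglik(tr1, tips, 0.2, 0.1),
               dec_loglik(tr2, tips, 0.2, 0.1), tolerance = 1e-12)
})

test_that("degenerate limits behave: shared ranges pin the root", {
  ch <- as_chronogram(read_tree(text = "(a:1,b:1);"))
  tc <- new_range_matrix(list(a = "A", b = "A"), c("A", "B"))
  expect_equal(dec_loglik(ch, tc, 1e-9, 1e-9), 0, tolerance = 1e-6)
  ar <- ancestral_ranges(ch, tc, 1e-4, 1e-4)
  expect_gt(ar$prob[1, "A"], 0.99)
  # per-node normalisation on a larger random instance
  set.seed(45)
  tr <- simulate_chronogram(sim_config(n_species = 10, crown_age = 5))
  rm <- simulate_dec_ranges(tr, 0.2, 0.05, sim_config(),
                            areas = LETTERS[1:3], max_range_size = 3)
  ar2 <- ancestral_ranges(tr, rm, 0.2, 0.05)
  expect_lt(max(abs(rowSums(ar2$prob) - 1)), 1e-9)
  expect_false(any(colnames(ar2$prob) == ""))   # null range never reported
})

test_that("all-same-area tips drive fitted rates to the lower bound", {
  tr <- as_chronogram(read_tree(text = "((a:1,b:1):1,(c:1,d:1):1);"))
  tips <- new_range_matrix(list(a = "A", b = "A", c = "A", d = "A"),
                           c("A", "B"))
  fit <- fit_dec(tr, tips)
  expect_lt(fit$d, 1e-6)
  expect_lt(fit$e, 1e-6)
  expect_gt(fit$logL, -1e-4)
})

test_that("fitted DEC rates sit at a likelihood maximum", {
  set.seed(46)
  tr <- simulate_chronogram(sim_config(n_species = 12, crown_age = 8))
  rm <- simulate_dec_ranges(tr, 0.1, 0.02, sim_config(),
                            areas = LETTERS[1:3], max_range_size = 3)
  fit <- fit_dec(tr, rm)
  for (k in 1:20) {
    d <- exp(runif(1, log(1e-4), log(5)))
    e <- exp(runif(1, log(1e-4), log(5)))
    expect_gte(fit$logL, dec_loglik(tr, rm, d, e) - 1e-6)
  }
})

test_that("binary surrogate matches two-state enumeration and symmetry", {
  # two tips, one present one absent, equal rates -> root probability 1/2
  tr <- as_chronogram(read_tree(text = "(a:1,b:1);"))
  x <- c(1L, 0L)
  pr <- gcpsr:::fit_two_state(tr, x)
  en <- oracle_two_state(tr, x, pr$q01, pr$q10)
  expect_equal(pr$logL, en$logL, tolerance = 1e-9)
  sym <- oracle_two_state(tr, x, 0.3, 0.3)
  expect_equal(sym$marginal[1, ], c(0.5, 0.5), tolerance = 1e-12)

  # 3-tip marginals equal enumeration at arbitrary rates
  tr3 <- as_chronogram(read_tree(text = "((a:1,b:1):1,c:2);"))
  set.seed(47)
  for (rep in 1:5) {
    x3 <- c(1L, 1L, 0L)
    q01 <- runif(1, 0.05, 1); q10 <- runif(1, 0.05, 1)
    # compare the package pruning at fixed rates with the enumerator
    en3 <- oracle_two_state(tr3, x3, q01, q10)
    fit3 <- gcpsr:::fit_two_state(tr3, x3)
    en_at_fit <- oracle_two_state(tr3, x3, fit3$q01, fit3$q10)
    expect_equal(fit3$logL, en_at_fit$logL, tolerance = 1e-9)
    expect_equal(fit3$marginal[4:5, ], en_at_fit$marginal, tolerance = 1e-9)
  }

  # full surrogate output shape + constant-area warning
  tips <- new_range_matrix(list(a = "A", b = c("A", "B"), c = "B"),
                           c("A", "B", "C"))
  expect_warning(bb <- binary_area_reconstruction(tr3, tips), "constant")
  expect_equal(dim(bb$prob), c(2L, 3L))
  expect_true(all(bb$prob[, "C"] == 0))
  expect_true(all(bb$prob >= 0 & bb$prob <= 1))
  expect_match(bb$method, "surrogate")
})
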