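test_that("support thresholds combine as any/all", {
  expect_true(clade_well_supported(list(mlb = 95)))
  expect_false(clade_well_supported(list(mlb = 50)))
  expect_true(clade_well_supported(list(bpp = 0.97)))
  expect_false(clade_well_supported(list()))
  s <- list(mlb = 65, bpp = 0.97)
  expect_true(clade_well_supported(s, concordance_config(support_combiner = "any")))
  expect_false(clade_well_supported(s, concordance_config(support_combiner = "all")))
  expect_true(clade_well_supported(list(mlb = 75, bpp = 0.99),
                                   concordance_config(support_combiner = "all")))
})

test_that("single-tree verdicts distinguish support, contradiction, noise", {
  t_sup <- read_tree(text = "((s1:1,s2:1)95:1,(x1:1,x2:1)90:1);")
  expect_equal(assess_candidate_in_tree(t_sup, c("s1", "s2"))$verdict, "supports")
  t_low <- read_tree(text = "((s1:1,s2:1)50:1,(x1:1,x2:1)90:1);")
  expect_equal(assess_candidate_in_tree(t_low, c("s1", "s2"))$verdict,
               "uninformative")
  t_con <- read_tree(text = "((s1:1,x1:1)92:1,(s2:1,x2:1)88:1);")
  expect_equal(assess_candidate_in_tree(t_con, c("s1", "s2"))$verdict,
               "contradicts")
  # unsupported conflict is only noise
  t_conlow <- read_tree(text = "((s1:1,x1:1)40:1,(s2:1,x2:1)30:1);")
  expect_equal(assess_candidate_in_tree(t_conlow, c("s1", "s2"))$verdict,
               "uninformative")
  # fewer than two members present
  expect_equal(assess_candidate_in_tree(t_sup, c("s1", "zz"))$verdict,
               "untestable")
})

test_that("verdicts match exhaustive clade enumeration on random trees", {
  set.seed(21)
  for (rep in 1:40) {
    tr <- random_supported_tree(sample(5:16, 1))
    members <- sample(tr$tip.label, sample(2:4, 1))
    expect_equal(assess_candidate_in_tree(tr, members)$verdict,
                 oracle_verdict(tr, members))
  }
})

test_that("monophyly assessment agrees with brute-force leaf-set checks", {
  set.seed(22)
  for (rep in 1:40) {
    tr <- random_supported_tree(sample(6:16, 1))
    # proper subsets only: the root clade carries no support label
    members <- sample(tr$tip.label, sample(2:4, 1))
    v <- assess_candidate_in_tree(
      tr, members, concordance_config(mlb_threshold = 0, bpp_threshold = 0))
    # with zero thresholds every clade is "supported": monophyly <=> supports
    expect_equal(v$verdict == "supports", oracle_is_monophyletic(tr, members))
  }
})

test_that("raising thresholds never upgrades a verdict to supports", {
  set.seed(23)
  for (rep in 1:20) {
    tr <- random_supported_tree(sample(6:12, 1))
    members <- sample(tr$tip.label, 3)
    v_low <- assess_candidate_in_tree(tr, members,
                                      concordance_config(mlb_threshold = 50))
    v_high <- assess_candidate_in_tree(tr, members,
                                       concordance_config(mlb_threshold = 90))
    expect_false(v_low$verdict != "supports" && v_high$verdict == "supports")
  }
})

test_that("verdict counts partition the tree set per group", {
  fx <- make_benchmark_fixture(sim_config(
    seed = 31, n_species = 5, samples_per_species = 2, loci = 6,
    sites = 300, theta = 0.05, bootstrap = 50))
  rep <- evaluate_gcpsr(fx$gene_trees, fx$partition)
  for (g in rep$report$group) {
    v <- rep$verdicts$verdict[rep$verdicts$group == g]
    expect_equal(length(v), length(fx$gene_trees))
    counts <- table(factor(v, levels = c("supports", "contradicts",
                                         "uninformative", "untestable")))
    r <- rep$report[rep$report$group == g, ]
    expect_equal(unname(counts[["supports"]]), r$n_supporting)
    expect_equal(unname(counts[["contradicts"]]), r$n_contradicting)
    expect_equal(sum(counts), length(fx$gene_trees))
    expect_lte(r$n_supporting + r$n_contradicting, r$n_testable)
  }
})

test_that("the two acceptance criteria and tiers apply as defined", {
  # construct trees giving a known verdict profile for group S = {s1,s2}
  sup <- read_tree(text = "((s1:1,s2:1)95:1,(x1:1,x2:1)90:1);")
  con <- read_tree(text = "((s1:1,x1:1)92:1,(s2:1,x2:1)88:1);")
  noise <- read_tree(text = "((s1:1,s2:1)50:1,(x1:1,x2:1)90:1);")
  part <- new_partition(c(s1 = "S", s2 = "S", x1 = "X", x2 = "X"))

  # 32 supporting of 40 testable, no contradiction -> both criteria, tier gt30
  trees <- c(rep(list(sup), 32), rep(list(noise), 8))
  r <- evaluate_gcpsr(trees, part)$report
  rS <- r[r$group == "S", ]
  expect_true(rS$criterion_a && rS$criterion_b && rS$accepted)
  expect_equal(rS$tier, "gt30")

  # 1 of 40 supporting, none contradicting -> accepted via criterion (2)
  trees <- c(list(sup), rep(list(noise), 39))
  rS <- subset(evaluate_gcpsr(trees, part)$report, group == "S")
  expect_false(rS$criterion_a)
  expect_true(rS$criterion_b && rS$accepted)
  expect_equal(rS$tier, "le10")

  # 5 supporting, 2 contradicting of 40 -> rejected on both criteria
  trees <- c(rep(list(sup), 5), rep(list(con), 2), rep(list(noise), 33))
  rS <- subset(evaluate_gcpsr(trees, part)$report, group == "S")
  expect_false(rS$criterion_a || rS$criterion_b || rS$accepted)

  # exactly 3/4 of testable passes the majority boundary (>=, not >)
  trees <- c(rep(list(sup), 3), list(con))
  rS <- subset(evaluate_gcpsr(trees, part)$report, group == "S")
  expect_true(rS$criterion_a)
  expect_false(rS$criterion_b)
})

test_that("groups never testable are tiered singleton and rejected", {
  sup <- read_tree(text = "((s1:1,s2:1)95:1,(x1:1,x2:1)90:1);")
  part <- new_partition(c(s1 = "S", s2 = "S", x1 = "X", x2 = "X", q9 = "Q"))
  r <- evaluate_gcpsr(list(sup), part)$report
  rQ <- r[r$group == "Q", ]
  expect_equal(rQ$n_testable, 0L)
  expect_false(rQ$accepted)
  expect_equal(rQ$tier, "singleton")
})

test_that("singleton rule needs both divergence and morphology", {
  dt <- new_divergence_table(
    within = data.frame(group = "big", mean = 0.001, n_pairs = 3L),
    between = data.frame(group1 = "big", group2 = "solo",
                         mean = 0.02, n_pairs = 3L),
    sizes = c(big = 3L, solo = 1L))
  expect_equal(singleton_rule("solo", dt, 0.0093, TRUE), "provisional_lineage")
  expect_equal(singleton_rule("solo", dt, 0.0093, FALSE), "undetermined")
  dt$between$mean <- 0.005
  expect_equal(singleton_rule("solo", dt, 0.0093, TRUE), "undetermined")
  expect_error(singleton_rule("big", dt, 0.0093, TRUE), "exactly one")
})
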