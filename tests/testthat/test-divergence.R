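test_that("pairwise distances match hand values and the K2P closed form", {
  expect_equal(pairwise_distance("ACGT", "ACGT"), 0)
  expect_equal(pairwise_distance("ACGT", "ACGA"), 0.25)
  # P = 0.25, Q = 0: K2P = -0.5 log(1 - 0.5) = 0.3466
  expect_equal(pairwise_distance("AAAA", "AAAG", distance_config("k2p")),
               -0.5 * log(0.5))
  # gaps/ambiguities excluded pairwise
  expect_equal(pairwise_distance("AC-T", "ACNT"), 0)
  expect_error(pairwise_distance("NNNN", "ACGT"), "no comparable")
  # saturation
  expect_error(pairwise_distance("ACACACAC", "CACACACA",
                                 distance_config("k2p")), "saturation")
})

test_that("pairwise distance is symmetric and K2P dominates p-distance", {
  set.seed(7)
  for (rep in 1:50) {
    aln <- random_alignment(2, 60, gap_frac = 0.1)
    a <- aln[1, ]; b <- aln[2, ]
    expect_identical(pairwise_distance(a, b), pairwise_distance(b, a))
    k2p <- tryCatch(pairwise_distance(a, b, distance_config("k2p")),
                    error = function(e) NULL)
    if (!is.null(k2p)) {
      expect_gte(k2p, pairwise_distance(a, b) - 1e-12)
    }
  }
})

test_that("distance_matrix equals the per-pair kernel under both policies", {
  set.seed(8)
  for (model in c("p_distance", "k2p")) {
    for (gap in c("pairwise_deletion", "complete_deletion")) {
      cfgd <- distance_config(model, gap)
      aln <- random_alignment(6, 80, gap_frac = 0.03)
      D <- tryCatch(distance_matrix(aln, cfgd), error = function(e) NULL)
      if (is.null(D)) next
      m <- unclass(aln)
      if (gap == "complete_deletion") {
        keep <- colSums(matrix(m %in% c("A", "C", "G", "T"),
                               nrow = nrow(m))) == nrow(m)
        m <- m[, keep, drop = FALSE]
      }
      for (i in 1:5) for (j in (i + 1):6) {
        expect_equal(D[i, j], oracle_pair_distance(m[i, ], m[j, ], model),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("distance_matrix agrees with ape::dist.dna", {
  set.seed(9)
  # moderately divergent sequences (iid-random pairs would saturate K2P)
  base <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  seqs <- vapply(1:8, function(i) {
    s <- base
    k <- rbinom(1, 200, 0.12)
    if (k > 0) s[sample.int(200, k)] <- sample(c("A", "C", "G", "T"), k,
                                               replace = TRUE)
    s[sample.int(200, 4)] <- "-"
    paste(s, collapse = "")
  }, character(1))
  aln <- new_alignment(seqs, sprintf("x%02d", 1:8))
  bin <- as.matrix(ape::as.DNAbin(
    strsplit(apply(unclass(aln), 1, paste, collapse = ""), "")))
  D_raw <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  D <- distance_matrix(aln)
  expect_equal(D[rownames(D_raw), colnames(D_raw)], D_raw, tolerance = 1e-12,
               ignore_attr = TRUE)
  D_k80 <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  Dk <- distance_matrix(aln, distance_config("k2p"))
  expect_equal(Dk[rownames(D_k80), colnames(D_k80)], D_k80, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("group divergence equals the brute-force double loop", {
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    aln <- random_alignment(n, sample(20:50, 1), gap_frac = 0.04)
    part <- new_partition(setNames(
      sample(sprintf("G%d", 1:3), n, replace = TRUE), rownames(aln)))
    dt <- group_divergence(aln, part)
    oracle <- oracle_group_divergence(aln, part)
    for (g in names(oracle$within)) {
      expect_equal(dt$within$mean[dt$within$group == g], oracle$within[[g]],
                   tolerance = 1e-12)
    }
    for (key in names(oracle$between)) {
      gs <- strsplit(key, "|", fixed = TRUE)[[1]]
      row <- dt$between[dt$between$group1 == gs[1] & dt$between$group2 == gs[2], ]
      expect_equal(row$mean, oracle$between[[key]], tolerance = 1e-12)
      expect_equal(row$n_pairs,
                   length(partition_groups(part)[[gs[1]]]) *
                     length(partition_groups(part)[[gs[2]]]))
    }
  }
})

test_that("identical sequences give zero within-group divergence", {
  aln <- new_alignment(c(a1 = "ACGTACGT", a2 = "ACGTACGT",
                         b1 = "ACGAACGA", b2 = "ACGAACGT"))
  part <- new_partition(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  dt <- group_divergence(aln, part)
  expect_equal(dt$within$mean[dt$within$group == "A"], 0)
  expect_error(group_divergence(
    aln, new_partition(c(a1 = "A", a2 = "A", z1 = "Z"))), "missing|absent")
})

test_that("cutoff calibration takes the maximum reference within-group mean", {
  dt <- new_divergence_table(
    within = data.frame(group = c("g1", "g2", "g3"),
                        mean = c(0.0093, 0, 0.004), n_pairs = c(3L, 1L, 3L)),
    between = data.frame(group1 = character(0), group2 = character(0),
                         mean = numeric(0), n_pairs = integer(0)),
    sizes = c(g1 = 3L, g2 = 2L, g3 = 3L))
  cr <- calibrate_cutoff(dt, c("g1", "g2", "g3"))
  expect_equal(cr$cutoff, 0.0093)
  expect_equal(cr$source_group, "g1")
  expect_equal(calibrate_cutoff(dt, "g3")$cutoff, 0.004)
  dt$sizes <- c(dt$sizes, g4 = 1L)
  expect_error(calibrate_cutoff(dt, "g4"), "2")
})

test_that("species decisions follow the accept/merge/flag/singleton rules", {
  dt <- new_divergence_table(
    within = data.frame(group = c("sp3", "sp4", "pul"),
                        mean = c(0.002, 0.001, 0.0181),
                        n_pairs = c(3L, 3L, 6L)),
    between = data.frame(
      group1 = c("pul", "pul", "pul", "sp3", "sp3", "sp4"),
      group2 = c("sp3", "sp4", "lone", "sp4", "lone", "lone"),
      mean = c(0.05, 0.06, 0.055, 0.0174, 0.004, 0.05),
      n_pairs = c(12L, 12L, 4L, 9L, 3L, 3L)),
    sizes = c(sp3 = 3L, sp4 = 3L, pul = 4L, lone = 1L))
  dec <- decide_species(dt, 0.0093)
  row <- function(g) dec[dec$group == g, ]
  # sp3 and sp4 are mutual nearest at 0.0174 > cutoff -> both accepted
  expect_equal(row("sp3")$status, "merged")     # nearest is lone at 0.004
  expect_equal(row("sp3")$nearest_group, "lone")
  expect_equal(row("sp4")$status, "accepted")
  expect_equal(row("sp4")$nearest_divergence, 0.0174)
  expect_true(row("pul")$flagged_multiple)      # delta_w = 0.0181 > cutoff
  expect_equal(row("pul")$status, "accepted")
  expect_equal(row("lone")$status, "singleton_untested")
})

test_that("two identical groups merge with each other", {
  aln <- new_alignment(c(a1 = "ACGTACGT", a2 = "ACGTACGT",
                         b1 = "ACGTACGT", b2 = "ACGTACGT"))
  part <- new_partition(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  dec <- decide_species(group_divergence(aln, part), 0.0093)
  expect_equal(dec$status, c("merged", "merged"))
  expect_equal(dec$merged_with, c("B", "A"))
})

test_that("raising the cutoff never increases the accepted count", {
  set.seed(11)
  for (rep in 1:10) {
    aln <- random_alignment(10, 60)
    part <- new_partition(setNames(
      rep(sprintf("G%d", 1:5), each = 2), rownames(aln)))
    dt <- group_divergence(aln, part)
    cuts <- sort(runif(6, 0, 0.8))
    acc <- vapply(cuts, function(cc) sum(decide_species(dt, cc)$status ==
                                           "accepted"), numeric(1))
    expect_true(all(diff(acc) <= 0))
  }
})
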