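test_that("cluster matching maximizes overlap over all permutations", {
  ref <- c(1, 1, 2, 2, 3, 3)
  expect_equal(as.integer(match_clusters(ref, ref)), 1:3)
  # a permuted copy maps back through the inverse permutation
  perm <- c(3, 1, 2)
  pred <- perm[ref]
  m <- match_clusters(pred, ref)
  expect_equal(m[perm], 1:3)

  set.seed(15)
  for (case in 1:5) {
    pred <- sample(1:3, 30, replace = TRUE)
    refr <- sample(1:3, 30, replace = TRUE)
    m <- match_clusters(pred, refr)
    overlap <- attr(m, "overlap")
    perms <- psokm:::permutations(3)
    all_overlaps <- apply(perms, 1, function(pp) sum(pp[pred] == refr))
    expect_equal(overlap, max(all_overlaps))
  }
  expect_error(match_clusters(1:3, 1:4), "equal length")
})

test_that("success rate reproduces the published cluster-size agreements", {
  # the six printed pairs that pin the 100*min/max definition down
  expect_equal(success_rate(46, 52), 88.46)
  expect_equal(success_rate(45, 52), 86.54)
  expect_equal(success_rate(239, 249), 95.98)
  expect_equal(success_rate(221, 249), 88.76)
  expect_equal(success_rate(183, 199), 91.96)
  expect_equal(success_rate(183, 218), 83.94)
  # symmetric, 100 iff equal, NA when both empty
  expect_equal(success_rate(52, 46), success_rate(46, 52))
  expect_equal(success_rate(52, 52), 100)
  expect_lt(success_rate(51, 52), 100)
  expect_true(is.na(success_rate(0, 0)))
  expect_error(success_rate(-1, 5), ">= 0")
})

test_that("type rates and general accuracy match the published arithmetic", {
  expect_equal(type_rate(49, 52), 94.23)
  expect_equal(type_rate(42, 46), 91.30)
  expect_equal(type_rate(2, 46), 4.35)
  expect_equal(type_rate(3, 52), 5.77)
  expect_equal(type_rate(1, 52), 1.92)
  expect_equal(type_rate(0, 52), 0)
  expect_true(is.na(type_rate(0, 0)))

  expect_equal(general_accuracy(94.23, 91.30), 96.89)
  expect_equal(general_accuracy(1.92, 4.35), 44.14)
  expect_equal(general_accuracy(87.55, 91.22), 95.98)
  expect_equal(general_accuracy(80.33, 77.39), 96.34)
  expect_equal(general_accuracy(55.5, 55.5), 100)
  expect_equal(general_accuracy(30, 60), general_accuracy(60, 30))
  expect_true(is.na(general_accuracy(0, 50)))
  expect_error(general_accuracy(120, 50), "percentages")
})

test_that("general accuracy works from rounded rates, as the tables were built", {
  # 1/52 vs 2/46: the unrounded ratio differs from the printed 44.14
  expect_equal(general_accuracy(type_rate(1, 52), type_rate(2, 46)), 44.14)
  unrounded <- 100 * (1 / 52) / (2 / 46)
  expect_false(isTRUE(all.equal(round(unrounded, 2), 44.14)))
})

test_that("Rand index equals brute-force pair counting", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 1 / 3)
  set.seed(16)
  for (case in 1:8) {
    n <- sample(4:12, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    expect_equal(rand_index(a, b), oracle_rand(a, b))
    # symmetry and relabeling invariance
    expect_equal(rand_index(a, b), rand_index(b, a))
    expect_equal(rand_index(a, b), rand_index(4 - a, b))
  }
  expect_equal(rand_index(c(1, 2, 2, 1), c("x", "y", "y", "x")), 1)
  expect_error(rand_index(1, 1), "at least 2")
  expect_error(rand_index(1:3, 1:4), "equal length")
})

test_that("cross-tabulation counts every subject exactly once", {
  tp <- rep("TYPE2", 5); cl <- rep("C2", 5)
  tab <- cross_tabulate(tp, cl)
  expect_equal(sum(tab), 5)
  expect_equal(unclass(tab)["TYPE2", "C2"], 5L, ignore_attr = TRUE)

  set.seed(17)
  tps <- sample(c("TYPE1", "TYPE2", "TYPE3"), 50, replace = TRUE)
  cls <- sample(c("C1", "C2", "C3"), 50, replace = TRUE)
  tab <- cross_tabulate(tps, cls)
  expect_equal(sum(tab), 50)
  for (t in rownames(tab)) {
    for (c in colnames(tab)) {
      expect_equal(unclass(tab)[t, c], sum(tps == t & cls == c),
                   ignore_attr = TRUE)
    }
  }
  expect_error(cross_tabulate(tps, cls[-1]), "equal length")
})

test_that("a partition identical to the rule labels scores perfectly", {
  coh <- simulate_cohort(cohort_config(), seed = 19)
  rep <- evaluate_partition(coh$subjects, as.integer(coh$group), "ltir")
  expect_true(all(rep$success_rates == 100))
  expect_equal(rep$rand_index, 1)
  expect_equal(rep$agreement, 1)
  ok <- stats::na.omit(c(rep$type_rates_real, rep$type_rates_algo,
                         rep$general_accuracy, rep$success_rates))
  expect_true(all(ok >= 0 & ok <= 100))
})

test_that("reports built from the published counts reproduce the printed rates", {
  cc <- rotation_reference_counts("ltir")
  hy <- report_from_counts(cc$real, cc$psokm)
  expect_equal(unname(hy$success_rates), c(88.46, 95.98, 91.96))
  km <- report_from_counts(cc$real, cc$km)
  expect_equal(unname(km$success_rates), c(86.54, 88.76, 83.94))
  expect_equal(hy$type_rates_real["TYPE2", "C1"], 94.23, ignore_attr = TRUE)
  expect_equal(hy$type_rates_algo["TYPE2", "C1"], 91.30, ignore_attr = TRUE)
  expect_equal(hy$general_accuracy["TYPE2", "C1"], 96.89, ignore_attr = TRUE)
  # the real Type 3 share in Cluster 1 is zero: printed as "-", computed as NA
  expect_true(is.na(hy$general_accuracy["TYPE3", "C1"]))
})
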