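mat_of <- function(a_clones, b_clones, K, pid = "P01") {
  m <- matrix(0L, 2, K, dimnames = list(c("A", "B"),
                                        paste0("clone", seq_len(K))))
  m["A", a_clones] <- 1L; m["B", b_clones] <- 1L
  attr(m, "patient_id") <- pid
  m
}

test_that("pair labels follow the disjoint/overlap/empty rules", {
  expect_equal(label_pair(mat_of(1, 3, 3), "A", "B")$label, "exclusive")
  expect_equal(label_pair(mat_of(c(1, 2), 2, 3), "A", "B")$label,
               "co_occurring")
  expect_equal(label_pair(mat_of(integer(0), 1, 3), "A", "B")$label,
               "not_comparable")
  # entity missing from the matrix entirely
  expect_equal(label_pair(mat_of(1, 2, 3), "A", "Z")$label,
               "not_comparable")
})

test_that("null exclusivity probability matches counting and enumeration", {
  expect_equal(pair_null_probability(3, 1, 1), 2 / 3)
  expect_equal(pair_null_probability(3, 2, 2), 0)  # pigeonhole
  expect_equal(pair_null_probability(5, 2, 2), 3 / 10)
  # exhaustive check over all placements for K <= 5
  for (K in 2:5) for (sa in 1:K) for (sb in 1:K) {
    A <- combn(K, sa, simplify = FALSE)
    B <- combn(K, sb, simplify = FALSE)
    excl <- mean(unlist(lapply(A, function(a) vapply(B, function(b)
      length(intersect(a, b)) == 0L, TRUE))))
    expect_equal(pair_null_probability(K, sa, sb), excl,
                 tolerance = 1e-12)
  }
  # symmetry in the two entities
  expect_equal(pair_null_probability(5, 2, 3),
               pair_null_probability(5, 3, 2))
})

test_that("Poisson-binomial tail is exact", {
  # closed forms
  expect_equal(poisson_binomial_tail(c(0.5, 0.5), 2), 0.25)
  expect_equal(poisson_binomial_tail(c(2 / 3, 2 / 3), 2), 4 / 9)
  expect_equal(poisson_binomial_tail(c(0.01, 0.01), 2), 1e-4)
  expect_equal(poisson_binomial_tail(c(0.3, 0.9), 0), 1)
  expect_equal(poisson_binomial_tail(c(0.3, 0.9), 3), 0)
  # equals binomial tail for equal probabilities
  expect_equal(poisson_binomial_tail(rep(0.3, 10), 4),
               pbinom(3, 10, 0.3, lower.tail = FALSE))
})

test_that("worked examples of the cohort test", {
  # two patients, K = 3, singleton sets, both exclusive -> p = (2/3)^2
  mats <- list(mat_of(1, 2, 3, "P1"), mat_of(2, 3, 3, "P2"))
  res <- exclusivity_test(mats, "A", "B")
  expect_equal(res$n_patients_both, 2L)
  expect_equal(res$n_exclusive, 2L)
  expect_equal(res$p, 4 / 9)

  # observed T = 0 -> p = 1 under the >= convention
  mats0 <- list(mat_of(1, 1, 3, "P1"), mat_of(2, 2, 3, "P2"))
  expect_equal(exclusivity_test(mats0, "A", "B")$p, 1)

  # below min_patients -> not tested
  expect_null(exclusivity_test(mats[1], "A", "B"))
  expect_error(exclusivity_test(mats, "A", "B", min_patients = 0),
               "min_patients")

  # symmetry in all scalar fields
  res_ba <- exclusivity_test(mats, "B", "A")
  expect_equal(res$p, res_ba$p)
  expect_equal(res$n_exclusive, res_ba$n_exclusive)
  expect_equal(res$per_patient$p_excl, res_ba$per_patient$p_excl)
})

test_that("exact tail agrees with brute-force enumeration on small cohorts", {
  set.seed(44)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    Ks <- sample(2:5, n, replace = TRUE)
    sa <- vapply(Ks, function(K) sample.int(K, 1), 0L)
    sb <- vapply(Ks, function(K) sample.int(K, 1), 0L)
    mats <- lapply(seq_len(n), function(j) {
      a <- sample.int(Ks[j], sa[j]); b <- sample.int(Ks[j], sb[j])
      mat_of(a, b, Ks[j], sprintf("P%d", j))
    })
    res <- exclusivity_test(mats, "A", "B", min_patients = 1)
    expect_equal(res$p,
                 oracle_exclusivity_tail(sa, sb, Ks, res$n_exclusive),
                 tolerance = 1e-12)
  }
})

test_that("planted 4-patient singleton case matches exhaustive enumeration over 4^8 placements", {
  mats <- simulate_exclusivity_cohort(4, 4, 1, 1, planted = TRUE, seed = 2)
  res <- exclusivity_test(mats, "A", "B")
  expect_equal(res$n_exclusive, 4L)
  # enumerate every joint placement of the 8 singleton clone sets
  grid <- expand.grid(rep(list(1:4), 8))
  t_all <- rowSums(sapply(1:4, function(j)
    grid[[j]] != grid[[j + 4]]))
  expect_equal(res$p, mean(t_all >= 4), tolerance = 1e-12)
  expect_equal(res$p, (3 / 4)^4)
})

test_that("the Monte-Carlo permutation mode agrees with the exact tail", {
  mats <- simulate_exclusivity_cohort(6, 4, 1, 2, planted = FALSE,
                                      seed = 3)
  res <- exclusivity_test(mats, "A", "B", n_perm = 4000, perm_seed = 9)
  se <- sqrt(res$p * (1 - res$p) / 4000)
  expect_lt(abs(res$p_perm - res$p), 4 * se + 1e-9)
})

test_that("test_all_pairs tests qualifying pairs with BH correction", {
  # genes TP53 and MUC16 altered in the same 2 patients in disjoint clones
  m1 <- matrix(c(1L, 0L, 0L, 0L, 1L, 0L), 2, 3, byrow = TRUE,
               dimnames = list(c("TP53", "MUC16"), paste0("c", 1:3)))
  attr(m1, "patient_id") <- "P05"
  m2 <- m1; attr(m2, "patient_id") <- "P81"
  out <- test_all_pairs(list(m1, m2))
  expect_equal(nrow(out), 1L)
  expect_setequal(c(out$entity_a, out$entity_b), c("TP53", "MUC16"))
  expect_equal(out$n_exclusive, 2L)
  expect_equal(out$p, 4 / 9)
  expect_equal(out$q, out$p)  # single tested pair
  r <- attr(out, "results")[[1]]
  expect_true(all(r$per_patient$label == "exclusive"))

  # a single-patient cohort yields no testable pair at min_patients = 2
  expect_equal(nrow(test_all_pairs(list(m1))), 0L)
})

test_that("null calibration: rejection rate at alpha 0.05 is near-nominal", {
  # 18 patients, K = 4, set sizes (1,2): per-patient null exclusivity
  # probability is exactly 1/2 and the discrete null has an attainable
  # level of 0.048 (see vignette); 300 cohorts here, 1000 in acceptance
  rej <- 0L
  for (r in 1:300) {
    mats <- simulate_exclusivity_cohort(18, 4, 1, 2, planted = FALSE,
                                        seed = 7000 + r)
    if (exclusivity_test(mats, "A", "B")$p <= 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 300, 0.02)
  expect_lte(rej / 300, 0.08)
})
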