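test_that("merging two biopsies applies the shared/private set algebra", {
  tu1 <- make_calls(pos = c(1L, 2L), ref = "A", alt = "C",
                    alt_count = 10L, depth = 100L, sample = "TU1")
  tu2 <- make_calls(pos = c(2L, 3L), ref = "A", alt = "C",
                    alt_count = 10L, depth = 100L, sample = "TU2")
  m <- merge_samples(tu1, tu2)
  expect_equal(nrow(m), 3L)
  expect_equal(m$status[m$pos == 1], "private_TU1")
  expect_equal(m$status[m$pos == 2], "shared")
  expect_equal(m$status[m$pos == 3], "private_TU2")
  expect_equal(m$alt_TU1[m$pos == 3], 0L)
  expect_equal(private_fraction(m), 2 / 3)

  # identical call sets -> everything shared
  m2 <- merge_samples(tu1, transform(tu1, sample_id = "TU2"))
  expect_true(all(m2$status == "shared"))
  expect_equal(private_fraction(m2), 0)

  # same gene, different loci -> two private records, not one shared
  g1 <- make_calls(pos = 10L, ref = "A", alt = "C", alt_count = 10L,
                   depth = 100L, gene = "LAMA2", sample = "TU1")
  g2 <- make_calls(pos = 20L, ref = "A", alt = "C", alt_count = 10L,
                   depth = 100L, gene = "LAMA2", sample = "TU2")
  m3 <- merge_samples(g1, g2)
  expect_setequal(m3$status, c("private_TU1", "private_TU2"))

  dup <- rbind(tu1, tu1[1, ])
  expect_error(merge_samples(dup, tu2), "duplicate variant key")
  expect_error(private_fraction(m[0, ]), "empty")
})

test_that("3 shared + 2 private gives private fraction 0.4", {
  tu1 <- make_calls(pos = 1:5, ref = "A", alt = "C", alt_count = 10L,
                    depth = 100L, sample = "TU1")
  tu2 <- make_calls(pos = 1:3, ref = "A", alt = "C", alt_count = 10L,
                    depth = 100L, sample = "TU2")
  expect_equal(private_fraction(merge_samples(tu1, tu2)), 0.4)
})

test_that("gene frequency counts each patient once per gene", {
  mk <- function(pid, genes) {
    tu1 <- make_calls(pos = seq_along(genes), ref = "A", alt = "C",
                      alt_count = 10L, depth = 100L, gene = genes,
                      patient = pid, sample = "TU1")
    merge_samples(tu1, tu1[0, ])
  }
  cohort <- list(mk("P1", c("VHL", "VHL", "VHL")),
                 mk("P2", c("VHL", "TP53")),
                 mk("P3", "TP53"), mk("P4", "SETD2"))
  gf <- gene_frequency(cohort)
  expect_equal(unname(gf["VHL"]), 0.5)   # 2 of 4 patients, multiplicity ignored
  expect_equal(unname(gf["TP53"]), 0.5)
  expect_equal(unname(gf["SETD2"]), 0.25)
  expect_error(gene_frequency(list()), "empty")
})

test_that("convergence requires distinct loci with differing biopsy patterns", {
  tu1 <- make_calls(pos = c(100L, 200L), ref = c("AG", "A"),
                    alt = c("A", "C"), alt_count = 10L, depth = 100L,
                    gene = "PBRM1",
                    effect = c("frameshift_indel", "missense"),
                    sample = "TU1")
  tu2 <- make_calls(pos = 300L, ref = "A", alt = "G", alt_count = 10L,
                    depth = 100L, gene = "PBRM1", effect = "missense",
                    sample = "TU2")
  ev <- detect_convergence(merge_samples(tu1, tu2))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gene, "PBRM1")
  expect_equal(ev$n_loci, 3L)

  # one shared mutation only -> no event
  sh <- merge_samples(tu2, transform(tu2, sample_id = "TU2"))
  expect_equal(nrow(detect_convergence(sh)), 0L)

  # two mutations both private to TU1 -> same-biopsy multiplicity, no event
  both1 <- merge_samples(tu1, tu1[0, ])
  expect_equal(nrow(detect_convergence(both1)), 0L)
})

test_that("counts conserve and swapping biopsy labels swaps private counts", {
  set.seed(23)
  for (i in 1:10) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    p1 <- sample.int(30L, n1); p2 <- sample.int(30L, n2)
    tu1 <- make_calls(pos = p1, ref = "A", alt = "C",
                      alt_count = 10L, depth = 100L, sample = "TU1")
    tu2 <- make_calls(pos = p2, ref = "A", alt = "C",
                      alt_count = 10L, depth = 100L, sample = "TU2")
    m <- merge_samples(tu1, tu2)
    expect_equal(nrow(m), length(union(p1, p2)))
    expect_equal(sum(m$status == "shared") +
                   sum(m$status != "shared"), nrow(m))
    swapped <- merge_samples(transform(tu2, sample_id = "TU1"),
                             transform(tu1, sample_id = "TU2"))
    expect_equal(sum(m$status == "shared"),
                 sum(swapped$status == "shared"))
    expect_equal(sum(m$status == "private_TU1"),
                 sum(swapped$status == "private_TU2"))
    expect_equal(private_fraction(m), private_fraction(swapped))
  }
})

test_that("noise-free classification matches simulation truth exactly", {
  cfg <- sim_config(n_patients = 4, noise = "none",
                    ffpe_artifact_count = 0, cnv_region_count = 0,
                    seed = 19)
  sim <- simulate_cohort(cfg)
  truth_frac <- c()
  obs_frac <- c()
  for (pid in names(sim$truth)) {
    tr <- sim$truth[[pid]]
    v <- sim$variants[sim$variants$patient_id == pid, ]
    m <- merge_samples(v[v$sample_id == "TU1", ], v[v$sample_id == "TU2", ])
    expect_identical(unname(tr$status[variant_key(m)]), m$status)
    truth_frac <- c(truth_frac, mean(tr$status != "shared"))
    obs_frac <- c(obs_frac, private_fraction(m))
  }
  expect_equal(obs_frac, truth_frac)
})

test_that("binomial-noise misclassification stays within the zero-read bound", {
  cfg <- sim_config(n_patients = 4, depth = 1000, ffpe_artifact_count = 0,
                    cnv_region_count = 0, seed = 20)
  sim <- simulate_cohort(cfg)
  mismatch <- 0L; total <- 0L; bound <- 0
  for (pid in names(sim$truth)) {
    tr <- sim$truth[[pid]]
    v <- sim$variants[sim$variants$patient_id == pid, ]
    m <- merge_samples(v[v$sample_id == "TU1", ], v[v$sample_id == "TU2", ])
    keys <- variant_key(m)
    mismatch <- mismatch + sum(m$status != tr$status[keys])
    total <- total + length(tr$status)
    # a status can only flip when a sample with positive expected VAF
    # draws zero alt reads
    ev <- tr$expected_vaf
    bound <- bound + sum((1 - ev[ev > 0])^cfg$depth)
  }
  # allow 3 sigma of the Poisson-ish bound, minimum a couple of events
  expect_lte(mismatch, bound + 3 * sqrt(bound) + 2)
})

test_that("cohort summary aggregates per-patient counts and events", {
  cfg <- sim_config(n_patients = 5, noise = "none",
                    ffpe_artifact_count = 0, cnv_region_count = 0,
                    seed = 21)
  sim <- simulate_cohort(cfg)
  cohort <- lapply(names(sim$truth), function(pid) {
    v <- sim$variants[sim$variants$patient_id == pid, ]
    merge_samples(v[v$sample_id == "TU1", ], v[v$sample_id == "TU2", ])
  })
  s <- cohort_summary(cohort)
  expect_equal(nrow(s$per_patient), 5L)
  expect_equal(s$per_patient$n_total,
               with(s$per_patient, n_shared + n_private_TU1 + n_private_TU2))
  expect_equal(s$mean_private_fraction,
               mean(s$per_patient$private_fraction))
  expect_true(all(s$gene_frequency <= 1 & s$gene_frequency > 0))
})
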