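small_cohort <- function(seed = 5, n = 16) {
  sim <- generate_cohort(simulation_params(n_patients = n), seed = seed)
  ann <- annotate_cohort(classify_origin(sim$records), the_map)
  list(cohort = mito_cohort(ann, sim$patients), sim = sim)
}

test_that("per-kilobase rates reproduce printed worked examples", {
  expect_equal(round(rate_per_kb(709, 16569), 2), 42.79)
  expect_equal(round(rate_per_kb(47, 956), 1), 49.2)
  expect_equal(rate_per_kb(0, 956), 0)
  expect_error(rate_per_kb(1, 0), "positive")
  # linear in count, inversely proportional to length
  expect_equal(rate_per_kb(20, 500), 2 * rate_per_kb(10, 500))
  expect_equal(rate_per_kb(10, 500), 2 * rate_per_kb(10, 1000))
})

test_that("percentages use half-up rounding to one decimal", {
  expect_equal(pct(68, 92), 73.9)
  expect_equal(pct(685, 709), 96.6)
  expect_equal(pct(1, 16), 6.3)   # 6.25 rounds half-up
})

test_that("gene rates report both position and allele tallies", {
  x <- small_cohort()
  gr <- gene_rates(x$cohort, the_map)
  expect_true(all(gr$n_alleles >= gr$n_positions))
  expect_equal(gr$rate_per_kb,
               rate_per_kb(gr$n_positions, gr$length_bp))
  # overlap positions count for both genes: totals over features can
  # exceed the number of distinct cohort positions
  keys <- unique(x$cohort$variants[, c("position", "ref", "alt")])
  expect_gte(sum(gr$n_alleles), nrow(keys))
})

test_that("class breakdown records numerators and denominators", {
  x <- small_cohort()
  bd <- class_breakdown(x$cohort)
  v <- x$cohort$variants
  som_keys <- unique(v[v$origin == "somatic", c("position", "ref", "alt")])
  eff <- bd$effect
  expect_equal(sum(eff$n), nrow(som_keys))
  expect_true(all(eff$denominator == nrow(som_keys)))
  pos_frac <- bd$positive_tumors
  expect_equal(pos_frac$n_positive,
               length(unique(v$patient_id[v$origin == "somatic"])))
  expect_equal(pos_frac$percent,
               pct(pos_frac$n_positive, nrow(x$cohort$patients)))
  # empty cohort signals an empty summary
  empty <- mito_cohort(v[0, ], x$cohort$patients)
  expect_equal(class_breakdown(empty)$positive_tumors$n_positive, 0)
})

test_that("subtype sharing partitions the somatic mutation universe", {
  x <- small_cohort(seed = 21, n = 30)
  sh <- subtype_sharing(x$cohort)
  v <- x$cohort$variants
  meta <- x$cohort$patients
  som <- v[v$origin == "somatic", ]
  som$subtype <- meta$subtype[match(som$patient_id, meta$patient_id)]
  som <- som[!is.na(som$subtype), ]
  n_universe <- nrow(unique(som[, c("position", "ref", "alt")]))
  # Venn partition cells sum to the universe
  expect_equal(sum(sh$venn$n), n_universe)
  # exclusive counts equal single-subtype Venn cells
  for (st in sh$per_subtype$subtype) {
    expect_equal(sh$per_subtype$n_exclusive[sh$per_subtype$subtype == st],
                 sum(sh$venn$n[sh$venn$combination == st]))
  }
  # per-subtype rate normalizes by the whole genome
  expect_equal(sh$per_subtype$rate_per_kb,
               sh$per_subtype$n_mutations * 1000 / 16569)
})

test_that("association test picks Fisher for sparse 2x2 and chi-square
           otherwise", {
  # perfectly independent table
  out <- association_test(matrix(10, 2, 2))
  expect_equal(out$p_value, 1)
  expect_equal(out$test_used, "chi_square")
  # sparse diagonal table: Fisher's exact two-sided p = 2/choose(10,5)
  out2 <- association_test(matrix(c(5, 0, 0, 5), 2))
  expect_equal(out2$test_used, "fisher")
  expect_equal(out2$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  # sparse larger-than-2x2 falls back to chi-square with a warning
  expect_warning(out3 <- association_test(matrix(c(3, 1, 2, 4, 1, 3), 2)),
                 "chi-square")
  expect_equal(out3$test_used, "chi_square")
  expect_error(association_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
  # planted independence: p-values roughly uniform across simulated tables
  set.seed(31)
  ps <- replicate(200, {
    a <- sample(c("x", "y"), 60, replace = TRUE)
    b <- sample(c("u", "v"), 60, replace = TRUE)
    association_test(table(a, b))$p_value
  })
  # tied p-values are expected for discrete tables; the KS check is coarse
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("mutation-profile clustering is deterministic and recovers
           planted structure", {
  # two identical profiles merge at distance 0; disjoint profiles at 1
  v <- data.frame(
    patient_id = c("P1", "P2", "P3", "P1", "P2"),
    position = c(100L, 100L, 200L, 300L, 300L),
    ref = "A", alt = "G",
    blood_maf = 0, tumor_maf = 0.5,
    origin = factor("somatic", levels = c("germline", "somatic",
                                          "probable_mutation", "absent")),
    stringsAsFactors = FALSE)
  meta <- data.frame(patient_id = c("P1", "P2", "P3"))
  cl <- cluster_profiles(mito_cohort(v, meta))
  d <- as.matrix(stats::cophenetic(cl$hclust))
  expect_equal(d["P1", "P2"], 0)
  expect_equal(d["P1", "P3"], 1)

  # planted two-group structure: top-level split recovers the groups
  groups <- rep(c("A", "B"), each = 4)
  ids <- sprintf("P%d", 1:8)
  muts <- lapply(seq_along(ids), function(i) {
    core <- if (groups[i] == "A") 1:6 else 11:16
    data.frame(patient_id = ids[i], position = as.integer(core * 10),
               ref = "A", alt = "G", blood_maf = 0, tumor_maf = 0.4,
               origin = factor("somatic",
                               levels = levels(v$origin)),
               stringsAsFactors = FALSE)
  })
  co <- mito_cohort(do.call(rbind, muts), data.frame(patient_id = ids))
  cl2 <- cluster_profiles(co)
  top <- stats::cutree(cl2$hclust, k = 2)
  expect_equal(length(unique(top[ids[groups == "A"]])), 1)
  expect_equal(length(unique(top[ids[groups == "B"]])), 1)
  expect_true(top[ids[1]] != top[ids[8]])

  # fewer than two eligible patients is an error signal
  expect_error(cluster_profiles(mito_cohort(v[v$patient_id == "P1", ],
                                            meta)), ">= 2")
})
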