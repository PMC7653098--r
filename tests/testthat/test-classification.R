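mk_rec <- function(blood_maf, tumor_maf, patient = "P1", position = 1000L,
                   ref = "A", alt = "G") {
  data.frame(patient_id = patient, position = position, ref = ref, alt = alt,
             blood_maf = blood_maf, tumor_maf = tumor_maf,
             stringsAsFactors = FALSE)
}

test_that("origin classification applies the MAF threshold rules", {
  cls <- function(b, t) as.character(classify_origin(mk_rec(b, t))$origin)
  expect_equal(cls(0.0005, 0.30), "somatic")
  expect_equal(cls(0.005, 0.99), "probable_mutation")
  expect_equal(cls(0.50, 0.0), "germline")   # regardless of tumor MAF
  expect_equal(cls(0.0, 0.0), "absent")
  # boundary: blood MAF exactly at the somatic cutoff is probable (strict <)
  expect_equal(cls(0.001, 0.30), "probable_mutation")
  # blood exactly at the germline cutoff is not germline (strict >)
  expect_equal(cls(0.01, 0.30), "probable_mutation")
  expect_error(classify_origin(mk_rec(1.2, 0)), "\\[0, 1\\]")
})

test_that("germline evidence propagates across the cohort", {
  rec <- rbind(mk_rec(0.40, 0.50, "P1"),   # germline-evidenced carrier
               mk_rec(0.0,  0.30, "P2"),   # would be somatic in isolation
               mk_rec(0.0,  0.30, "P3", position = 2000L))
  out <- classify_origin(rec)
  expect_equal(as.character(out$origin),
               c("germline", "germline", "somatic"))
})

test_that("origin classes partition detected records and respond
           monotonically to the somatic threshold", {
  set.seed(11)
  n <- 400
  rec <- mk_rec(blood_maf = round(runif(n, 0, 0.05), 4),
                tumor_maf = round(runif(n), 4),
                patient = sprintf("P%03d", seq_len(n)),
                position = sample(16569, n))
  out <- classify_origin(rec)
  detected <- out$tumor_maf > 0.01 | out$blood_maf > 0.01
  # exactly one class per record; every tumor-detected record gets a
  # non-absent class
  expect_false(any(is.na(out$origin)))
  expect_true(all(out$origin[out$tumor_maf > 0.01] != "absent"))
  expect_true(all(out$origin[!detected] %in% c("absent", "germline")))

  # raising somatic_normal_max can only move probable -> somatic
  relaxed <- classify_origin(rec, classification_config(
    somatic_normal_max = 0.005))
  moved <- as.character(out$origin) != as.character(relaxed$origin)
  expect_true(all(out$origin[moved] == "probable_mutation"))
  expect_true(all(relaxed$origin[moved] == "somatic"))
  expect_false(any(out$origin == "somatic" & relaxed$origin != "somatic"))
})

test_that("ploidy is a step function with documented boundaries", {
  cfg <- classification_config()
  expect_equal(as.character(classify_ploidy(c(0.5, 0.96, 0.005), cfg)),
               c("heteroplasmic", "homoplasmic", "undetected"))
  # documented boundary decisions: exactly 0.95 is homoplasmic,
  # exactly 0.01 is heteroplasmic
  expect_equal(as.character(classify_ploidy(0.95, cfg)), "homoplasmic")
  expect_equal(as.character(classify_ploidy(0.01, cfg)), "heteroplasmic")
  expect_error(classify_ploidy(-0.1, cfg), "\\[0, 1\\]")
})

test_that("shift analysis matches the brute-force rank-sum oracle", {
  # uniform upward shift: all deltas +0.8, no heteroplasmy->homoplasmy flips
  rec <- mk_rec(rep(0.10, 5), rep(0.90, 5), sprintf("P%d", 1:5))
  out <- shift_analysis(classify_origin(rec))
  expect_equal(out$n_pairs, 5)
  expect_equal(unlist(out$delta), rep(0.8, 5))
  expect_equal(out$n_shift_to_homoplasmy, 0)

  # tumor reaching homoplasmy from heteroplasmic blood is counted
  rec2 <- mk_rec(c(0.2, 0.3), c(0.97, 0.5), c("P1", "P2"))
  out2 <- shift_analysis(classify_origin(rec2))
  expect_equal(out2$n_shift_to_homoplasmy, 1)

  # identical distributions: deltas 0, p ~ 1
  rec3 <- mk_rec(rep(0.3, 6), rep(0.3, 6), sprintf("P%d", 1:6))
  out3 <- shift_analysis(classify_origin(rec3))
  expect_equal(unlist(out3$delta), rep(0, 6))
  expect_gt(out3$p_value, 0.9)

  # U statistic equals brute-force enumeration over all pairs, across
  # random carrier sets (both small/exact and larger/approximate n)
  set.seed(42)
  for (n in c(4, 7, 12, 30)) {
    blood <- round(rbeta(n, 2, 8), 3)
    tumor <- round(rbeta(n, 8, 2), 3)
    rec <- mk_rec(pmax(blood, 0.011), tumor, sprintf("P%d", seq_len(n)))
    out <- shift_analysis(classify_origin(rec))
    expect_equal(out$statistic, brute_u(tumor, pmax(blood, 0.011)))
  }

  # no germline carriers -> empty result
  expect_equal(nrow(shift_analysis(classify_origin(mk_rec(0, 0.5)))), 0)
})

test_that("recurrence counts carriers, singletons and cohort frequency", {
  rec <- rbind(mk_rec(0.5, 0.5, "P1"), mk_rec(0.5, 0.5, "P2"),
               mk_rec(0.0005, 0.3, "P3", position = 2000L))
  out <- recurrence(classify_origin(rec), n_patients = 92)
  shared <- out[out$position == 1000, ]
  expect_equal(shared$carriers, 2)
  expect_false(shared$singleton)
  expect_equal(round(100 * shared$frequency, 1), 2.2)
  single <- out[out$position == 2000, ]
  expect_true(single$singleton)
  expect_equal(round(100 * single$frequency, 1), 1.1)
  expect_equal(nrow(recurrence(classify_origin(mk_rec(0, 0)))), 0)
})
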