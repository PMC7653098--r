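test_that("variant typing and substitution classes partition correctly", {
  expect_equal(variant_type("A", "G"), "SNV")
  expect_equal(variant_type("C", "CC"), "insertion")
  expect_equal(variant_type("AT", "A"), "deletion")

  expect_equal(substitution_class("A", "G"), "transition")
  expect_equal(substitution_class("G", "T"), "transversion")
  expect_equal(substitution_class("AT", "A"), "not_applicable")

  # enumeration over the 12 ordered base pairs: 4 transitions,
  # 8 transversions, and every SNV falls in exactly one class
  pairs <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- substitution_class(pairs$ref, pairs$alt)
  expect_equal(sum(cls == "transition"), 4)
  expect_equal(sum(cls == "transversion"), 8)
  expect_true(all(cls %in% c("transition", "transversion")))
})

test_that("protein annotation handles strands, indels and mismatches", {
  # L-strand gene: allele complementation (planted synonymous context)
  a <- annotate_variant(14470, "T", "C", the_map)
  expect_equal(a$region, "ND6")
  expect_equal(a$effect, "synonymous")

  # frameshift vs in-frame indel by length difference mod 3
  fs <- annotate_variant(13340, ref_base(the_map, 13340),
                         paste0(ref_base(the_map, 13340), "A"), the_map)
  expect_equal(fs$effect, "frameshift")
  inframe_alt <- paste0(ref_base(the_map, 13340), "AAA")
  inf <- annotate_variant(13340, ref_base(the_map, 13340), inframe_alt, the_map)
  expect_equal(inf$effect, "inframe_indel")

  # ATP8/ATP6 overlap yields one consequence per gene
  ov <- annotate_variant(8550, ref_base(the_map, 8550),
                         setdiff(c("A", "C", "G", "T"),
                                 ref_base(the_map, 8550))[1], the_map)
  expect_setequal(ov$region, c("ATP8", "ATP6"))
  expect_equal(nrow(ov), 2)

  # trailing bases of a polyadenylation-completed stop codon
  sr <- annotate_variant(4262, ref_base(the_map, 4262),
                         setdiff(c("A", "C", "G", "T"),
                                 ref_base(the_map, 4262))[1], the_map)
  expect_true("stop_region" %in% sr$effect)

  # reference mismatch is a data error naming the position
  wrong <- setdiff(c("A", "C", "G", "T"), ref_base(the_map, 13333))[1]
  expect_error(annotate_variant(13333, wrong, "A", the_map), "13333")
})

test_that("non-protein features annotate at category level", {
  a <- annotate_variant(10463, "T", "C", the_map)
  expect_true(any(a$region == "TRNR" & a$effect == "tRNA"))
  r <- annotate_variant(3219, "G", "T", the_map)
  expect_true("rRNA" %in% r$effect)
  d <- annotate_variant(16200, ref_base(the_map, 16200), "A", the_map)
  expect_true("dloop_noncoding" %in% d$effect)
  i <- annotate_variant(5581, "A", "G", the_map)
  expect_true("intergenic" %in% i$effect)
  # position inside both a tRNA and the L-strand replication origin gets
  # both annotations
  dual <- annotate_variant(5777, "G", "A", the_map)
  expect_setequal(dual$effect, c("tRNA", "regulatory"))
})

test_that("fast-path annotation agrees with whole-gene retranslation on a
           sampled codon set from an H- and an L-strand gene", {
  set.seed(7)
  for (gene in c("ND2", "ND6")) {
    oracle <- oracle_gene_snvs(gene, the_map)
    pick <- oracle[sample(nrow(oracle), 150), ]
    for (k in seq_len(nrow(pick))) {
      a <- annotate_variant(pick$position[k], pick$ref[k], pick$alt[k],
                            the_map)
      a <- a[a$region == gene, ]
      expect_equal(a$effect, pick$effect[k],
                   label = paste(gene, pick$position[k], pick$alt[k]))
      expect_equal(a$aa_change, pick$aa_change[k])
    }
  }
})

test_that("cohort annotation counts planted effects exactly", {
  sim <- generate_cohort(simulation_params(n_patients = 12), seed = 99)
  ann <- annotate_cohort(classify_origin(sim$records), the_map)
  m <- merge(ann, sim$truth,
             by = c("patient_id", "position", "ref", "alt"), sort = FALSE)
  expect_equal(nrow(m), nrow(ann))
  expect_true(all(m$effect.x == m$effect.y))
  # every SNV is either transition or transversion
  snv <- ann[ann$variant_type == "SNV", ]
  expect_true(all(snv$substitution_class %in% c("transition", "transversion")))
})
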