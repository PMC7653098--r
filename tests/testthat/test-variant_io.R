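write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("TSV reader computes MAFs and applies depth filters", {
  df <- data.frame(patient_id = "P01", position = 663, ref = "A", alt = "G",
                   blood_alt = 10, blood_depth = 1000,
                   tumor_alt = 900, tumor_depth = 1000)
  out <- read_paired_tsv(write_tsv_fixture(df))
  expect_equal(out$blood_maf, 0.01)
  expect_equal(out$tumor_maf, 0.9)

  # zero-depth row excluded with a warning
  df2 <- rbind(df, data.frame(patient_id = "P01", position = 100, ref = "A",
                              alt = "T", blood_alt = 0, blood_depth = 1000,
                              tumor_alt = 0, tumor_depth = 0))
  expect_warning(out2 <- read_paired_tsv(write_tsv_fixture(df2)), "zero depth")
  expect_equal(nrow(out2), 1)

  # sub-300x row excluded with a warning
  df3 <- rbind(df, data.frame(patient_id = "P01", position = 100, ref = "A",
                              alt = "T", blood_alt = 5, blood_depth = 250,
                              tumor_alt = 5, tumor_depth = 500))
  expect_warning(out3 <- read_paired_tsv(write_tsv_fixture(df3)), "below 300")
  expect_equal(nrow(out3), 1)

  # alt reads beyond depth is a validation error naming the row
  df4 <- df; df4$blood_alt <- 2000
  expect_error(read_paired_tsv(write_tsv_fixture(df4)), "exceed depth")

  # header-only file gives an empty table
  empty <- read_paired_tsv(write_tsv_fixture(df[0, ]))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("blood_maf", "tumor_maf") %in% names(empty)))
})

test_that("indel alleles normalize to left-aligned parsimonious form", {
  df <- data.frame(patient_id = "P01",
                   position = c(99, 13885), ref = c("CAT", "CA"),
                   alt = c("CT", "CCA"),
                   blood_alt = 0, blood_depth = 1000,
                   tumor_alt = 500, tumor_depth = 1000)
  out <- read_paired_tsv(write_tsv_fixture(df))
  # CAT>CT at 99: shared suffix T stripped -> CA>C (anchor kept)
  expect_equal(out$ref[1], "CA"); expect_equal(out$alt[1], "C")
  expect_equal(out$position[1], 99)
  # CA>CCA at 13885: shared suffix A stripped -> C>CC insertion
  expect_equal(out$ref[2], "C"); expect_equal(out$alt[2], "CC")
  expect_equal(variant_type(out$ref[2], out$alt[2]), "insertion")
})

vcf_fixture <- function(body, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrM,length=16569>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           "BLOOD\tTUMOR"))
  writeLines(c(header, body), path)
  path
}

test_that("two-sample VCF reading decomposes multiallelic sites", {
  body <- c(
    "chrM\t663\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/0:500,0\t0/1:350,150",
    "chrM\t750\t.\tA\tG,T\t.\tPASS\t.\tGT:AD\t0/1:600,300,100\t0/1:500,400,100")
  out <- read_paired_vcf(vcf_fixture(body), "BLOOD", "TUMOR",
                         patient_id = "P01")
  # one record per (site, alt) pair
  expect_equal(nrow(out), 3)
  snv <- out[out$position == 663, ]
  expect_equal(snv$blood_maf, 0)
  expect_equal(snv$tumor_maf, 0.3)
  tri <- out[out$position == 750, ]
  expect_equal(nrow(tri), 2)
  expect_setequal(tri$alt, c("G", "T"))
  expect_equal(sort(tri$blood_maf), c(0.1, 0.3))

  # a VCF without AD is a format error
  body2 <- "chrM\t663\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1"
  expect_error(read_paired_vcf(vcf_fixture(body2), "BLOOD", "TUMOR"),
               "AD")
  # unknown sample name is an error
  expect_error(read_paired_vcf(vcf_fixture(body), "BLOOD", "NOPE"),
               "sample")
})

test_that("classified table round-trips through write/read", {
  cls <- annotate_cohort(tiny_classified(), the_map)
  path <- tempfile(fileext = ".tsv")
  write_classified(path, cls)
  back <- read_classified(path)
  expect_equal(nrow(back), nrow(cls))
  key <- function(d) paste(d$patient_id, d$position, d$ref, d$alt)
  back <- back[match(key(cls), key(back)), ]
  expect_equal(back$origin, as.character(cls$origin))
  expect_equal(back$effect, cls$effect)
  expect_equal(back$aa_change, cls$aa_change)
  expect_equal(back$blood_maf, cls$blood_maf, tolerance = 1e-12)
  expect_equal(back$tumor_alt, cls$tumor_alt)
  # header row only for an empty input
  write_classified(path, cls[0, ])
  expect_equal(nrow(read_classified(path)), 0)
})
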