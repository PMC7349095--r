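test_that("variant TSV reading handles well-formed, empty and invalid input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("chrom", "pos", "ref", "alt", "tumor_ref_count",
                 "tumor_alt_count", "normal_ref_count", "normal_alt_count",
                 "gene", "effect", "coding_flag", "pop_af",
                 "prediction_class"), collapse = "\t")
  writeLines(c(hdr,
               "chr19\t100\tA\tT\t10\t10\t30\t0\tSMARCA4\tmissense\tTRUE\t0.001\tprobably_damaging",
               "19\t200\tC\tG\t20\t2\t25\t1\tPLK5\tsynonymous\tTRUE\tNA\tunknown",
               "19\t300\tG\tA\t15\t5\t12\t6\tunknown\tother\tFALSE\t0.2\tbenign"),
             path)
  v <- read_variant_table(path)
  expect_equal(nrow(v), 3)
  expect_equal(v$chrom, rep("19", 3))  # chr prefix stripped
  expect_equal(v$tumor_alt, c(10L, 2L, 5L))
  expect_true(is.na(v$pop_af[2]))

  # header only -> empty
  writeLines(hdr, path)
  expect_equal(nrow(read_variant_table(path)), 0)

  # negative count -> validation error citing the row
  writeLines(c(hdr, "19\t100\tA\tT\t10\t-1\t30\t0\tG\tmissense\tTRUE\tNA\tunknown"),
             path)
  expect_error(read_variant_table(path), "row 1")

  # missing required column -> format error naming it
  writeLines("chrom\tpos\tref\talt", path)
  expect_error(read_variant_table(path), "tumor_ref_count")
})

test_that("variant table with missing optional columns gets unknown markers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\ttumor_ref_count\ttumor_alt_count\tnormal_ref_count\tnormal_alt_count",
               "19\t100\tA\tT\t10\t10\t30\t0"), path)
  v <- read_variant_table(path)
  expect_equal(v$gene, "unknown")
  expect_equal(v$effect, "other")
  expect_equal(v$prediction, "unknown")
  expect_true(is.na(v$pop_af))
  expect_true(is.na(v$coding))
})

test_that("VCF dialect extracts tumor/normal AD counts", {
  skip_if_not_installed("vcfR")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL",
    "chr19\t373916\t.\tA\tT\t.\tPASS\t.\tGT:AD\t0/1:12,28\t0/0:30,1",
    "chr19\t500000\t.\tC\tG\t.\tPASS\t.\tGT:AD\t0/1:20,20\t0/1:15,15"),
    path)
  v <- read_variant_table(path, dialect = "vcf", tumor_sample = "TUMOR",
                          normal_sample = "NORMAL")
  expect_equal(v$chrom, c("19", "19"))
  expect_equal(v$tumor_alt, c(28L, 20L))
  expect_equal(v$normal_ref, c(30L, 15L))
})

test_that("SEG writing round-trips and rejects overlapping segments", {
  path <- withr::local_tempfile(fileext = ".seg")
  seg <- data.frame(sample = "S1", chrom = "19", start = 373916,
                    end = 11465316, n_probes = 500L, mean_log2 = 0.01,
                    stringsAsFactors = FALSE)
  write_seg(seg, path)
  expect_equal(length(readLines(path)), 2)  # header + one data line
  back <- read_seg(path)
  expect_equal(back$mean_log2, 0.01, tolerance = 1e-6)
  expect_equal(back$start, 373916)

  write_seg(seg[0, ], path)
  expect_equal(length(readLines(path)), 1)  # header only

  overlap <- rbind(seg, transform(seg, start = 1e6, end = 2e6))
  expect_error(write_seg(overlap, path), "overlapping")
})

test_that("GMT parsing collapses duplicates and reports malformed lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET1\tdesc\tA\tB\tA", "SET2\tdesc\tX\tY"), path)
  sets <- read_gene_sets(path)
  expect_equal(length(sets), 2)
  expect_equal(sets$SET1, c("A", "B"))

  writeLines(c("SET1\tdesc\tA", "SET1\tdesc\tB"), path)
  expect_error(read_gene_sets(path), "duplicate")

  writeLines("SETX\tonly_two_fields", path)
  expect_error(read_gene_sets(path), "line 1")
})

test_that("BED conversion is the single 0-based/1-based boundary, both ways", {
  path <- withr::local_tempfile(fileext = ".bed")
  iv <- data.frame(chrom = "19", start = 373916, end = 11465316,
                   gene = "REGION", stringsAsFactors = FALSE)
  write_bed(iv, path)
  raw <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(as.numeric(raw[2]), 373915)   # BED start is 0-based
  expect_equal(as.numeric(raw[3]), 11465316) # BED end exclusive
  back <- read_bed(path, col_names = "gene")
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
  expect_equal(back$gene, "REGION")
})

test_that("writer/reader pairs round-trip random records losslessly", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(1:8, 1)
    v <- make_variants(n, seed = rep)
    v$pop_af <- ifelse(runif(n) < 0.5, round(runif(n), 4), NA_real_)
    v$coding <- runif(n) < 0.5
    path <- tempfile(fileext = ".tsv")
    write_variant_table(v, path)
    back <- read_variant_table(path)
    expect_equal(back, v, ignore_attr = TRUE)
    unlink(path)
  }
  # SEG round trip on random non-overlapping segments
  set.seed(100)
  for (rep in 1:20) {
    k <- sample(1:6, 1)
    bounds <- sort(sample.int(1e7, 2 * k))
    seg <- data.frame(
      sample = "S1", chrom = "7",
      start = bounds[seq(1, 2 * k, 2)], end = bounds[seq(2, 2 * k, 2)],
      n_probes = sample(3:500, k, replace = TRUE),
      mean_log2 = round(rnorm(k), 6), stringsAsFactors = FALSE)
    path <- tempfile(fileext = ".seg")
    write_seg(seg, path)
    expect_equal(read_seg(seg_path <- path), seg, ignore_attr = TRUE)
    unlink(path)
  }
})

test_that("region strings parse and format with 1-based inclusive coordinates", {
  r <- parse_region("Chr19:373.916-11.465.316")
  expect_equal(r$chrom, "19")
  expect_equal(r$start, 373916)
  expect_equal(r$end, 11465316)
  expect_equal(format_region(r), "chr19:373916-11465316")
  expect_equal(interval_width(r), 11465316 - 373916 + 1)
  expect_error(parse_region("chr19-badformat"), "cannot parse")
  expect_error(genomic_interval("19", 10, 5), "coordinates")
  expect_error(genomic_interval("19", 0, 5), "coordinates")
})

test_that("manifest round-trips, validates uniqueness and flags missing files", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "s1.tsv"); writeLines("x", f1)
  m <- list(samples = data.frame(
    sample_id = c("S1", "S2"), variants = c(f1, "."),
    coverage = c(".", "."), probes = c(".", "."),
    group = c("a", "b"), stringsAsFactors = FALSE),
    expression = NA_character_, expr_groups = NA_character_,
    gene_sets = NA_character_, genes = NA_character_)
  path <- file.path(dir, "manifest.tsv")
  write_manifest(m, path)
  back <- read_manifest(path)
  expect_equal(back$samples$sample_id, c("S1", "S2"))
  expect_true(is.na(back$expression))
  expect_silent(validate_manifest(back))

  m$samples$sample_id <- c("S1", "S1")
  expect_error(validate_manifest(m), "duplicate")
  m$samples$sample_id <- c("S1", "S2")
  m$samples$variants[2] <- file.path(dir, "absent.tsv")
  expect_error(validate_manifest(m), "missing file")
})
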