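# VCF reading, depth filtering, counts and ts/tv.

write_fixture_vcf <- function(rows, sample_col = TRUE, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=t1,length=500>",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (sample_col) c("FORMAT", "lib1")), collapse = "\t")
  )
  writeLines(c(header, rows), path)
  path
}

test_that("read_snvs keeps single-base alleles and drops other variant types", {
  rows <- c(
    "t1\t10\t.\tC\tT\t.\tPASS\tDP=20\tDP\t20",   # SNV
    "t1\t20\t.\tA\tG\t.\tPASS\tDP=21\tDP\t21",   # SNV
    "t1\t30\t.\tAC\tA\t.\tPASS\tDP=22\tDP\t22",  # deletion
    "t1\t40\t.\tG\tGTT\t.\tPASS\tDP=23\tDP\t23", # insertion
    "t1\t50\t.\tT\tA\t.\tPASS\tDP=24\tDP\t24"    # SNV
  )
  lib <- read_snvs(write_fixture_vcf(rows))
  expect_equal(count_snvs(lib), 3)
  expect_equal(lib$records$pos, c(10L, 20L, 50L))
  expect_equal(lib$records$depth, c(20L, 21L, 24L))
})

test_that("multi-allelic rows decompose into one record per single-base alt", {
  rows <- c(
    "t1\t10\t.\tC\tT,G\t.\tPASS\tDP=30\tDP\t30",
    "t1\t20\t.\tA\tG,ATT\t.\tPASS\tDP=31\tDP\t31",  # one SNV allele + one indel
    "t1\t30\t.\tG\t*\t.\tPASS\tDP=32\tDP\t32"       # spanning deletion dropped
  )
  lib <- read_snvs(write_fixture_vcf(rows))
  expect_equal(count_snvs(lib), 3)
  expect_equal(lib$records$alt[lib$records$pos == 10], c("T", "G"))
  expect_equal(lib$records$alt[lib$records$pos == 20], "G")
})

test_that("depth prefers FORMAT DP, falls back to INFO, else 0", {
  rows <- c("t1\t10\t.\tC\tT\t.\tPASS\tDP=99\tDP\t15")
  expect_equal(read_snvs(write_fixture_vcf(rows))$records$depth, 15L)

  rows_info <- c("t1\t10\t.\tC\tT\t.\tPASS\tDP=99")
  expect_equal(read_snvs(write_fixture_vcf(rows_info, sample_col = FALSE))$records$depth, 99L)

  rows_none <- c("t1\t10\t.\tC\tT\t.\tPASS\t.")
  expect_equal(read_snvs(write_fixture_vcf(rows_none, sample_col = FALSE))$records$depth, 0L)
})

test_that("empty and malformed VCFs follow the contracts", {
  empty <- write_fixture_vcf(character(0))
  lib <- read_snvs(empty)
  expect_equal(count_snvs(lib), 0)
  expect_identical(titv_ratio(lib), NA_real_)

  bad <- write_fixture_vcf(c("t1\t10\t.\tC\tT\t.\tPASS\tDP=1\tDP\t1",
                             "t1\tnotanumber\t.\tC\tT"))
  expect_error(read_snvs(bad), "line 7", class = "castevar_data_error")
  expect_error(read_snvs(tempfile()), "not found")

  # library id defaults to the file name
  expect_equal(read_snvs(empty)$library_id,
               sub("\\.vcf$", "", basename(empty)))
})

test_that("depth filter retains strictly greater depths and is idempotent", {
  rec <- data.frame(transcript_id = "t1", pos = 1:4,
                    ref = "C", alt = "T", depth = c(5L, 10L, 11L, 200L))
  lib <- library_variants("x", rec)
  kept <- filter_by_depth(lib, 10)
  expect_equal(kept$records$depth, c(11L, 200L))
  expect_equal(filter_by_depth(kept, 10)$records, kept$records)
  # min_depth = 0 drops only depth-0 records under the strict rule
  rec0 <- data.frame(transcript_id = "t1", pos = 1:2,
                     ref = "C", alt = "T", depth = c(0L, 1L))
  expect_equal(filter_by_depth(library_variants("y", rec0), 0)$records$depth, 1L)
  # non-strict mode keeps the boundary
  expect_equal(filter_by_depth(lib, 10, strict = FALSE)$records$depth,
               c(10L, 11L, 200L))
  expect_error(filter_by_depth(lib, -1), "non-negative",
               class = "castevar_config_error")
})

test_that("filtering commutes with partitioning by transcript", {
  st <- small_study()
  lib <- read_snvs(st$manifest$vcf[[1]])
  whole <- filter_by_depth(lib, 10)
  by_tx <- split(lib$records, lib$records$transcript_id)
  split_counts <- vapply(by_tx, function(r) {
    count_snvs(filter_by_depth(library_variants("part", r), 10))
  }, integer(1))
  expect_equal(sum(split_counts), count_snvs(whole))
})

test_that("ts/tv ratio matches its definition and strand complementation", {
  rec <- function(ref, alt) data.frame(transcript_id = "t", pos = seq_along(ref),
                                       ref = ref, alt = alt, depth = 50L)
  expect_equal(titv_ratio(library_variants("a", rec(c("C", "G", "A"),
                                                    c("T", "A", "C")))), 2)
  expect_equal(titv_ratio(library_variants("b", rec(c("A", "A"),
                                                    c("C", "T")))), 0)
  # no transversions -> undefined marker
  expect_identical(titv_ratio(library_variants("c", rec("A", "G"))), NA_real_)
  # complementing every record leaves the ratio unchanged
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(3)
  refs <- sample(names(comp), 30, replace = TRUE)
  alts <- vapply(refs, function(r) sample(setdiff(names(comp), r), 1), "")
  expect_equal(titv_ratio(library_variants("d", rec(refs, alts))),
               titv_ratio(library_variants("e", rec(unname(comp[refs]),
                                                    unname(comp[alts])))))
})

test_that("duplicate records resolve last-read-wins with a warning", {
  rec <- data.frame(transcript_id = "t1", pos = c(5L, 5L),
                    ref = "C", alt = "T", depth = c(10L, 30L))
  expect_warning(lib <- library_variants("x", rec), "duplicate")
  expect_equal(count_snvs(lib), 1)
  expect_equal(lib$records$depth, 30L)
})

test_that("read counts reconcile with the generator's ground truth", {
  st <- small_study()
  truth <- st$truth
  for (id in names(st$manifest$vcf)) {
    lib <- read_snvs(st$manifest$vcf[[id]], id)
    expect_equal(count_snvs(lib), sum(truth$library_id == id))
    expect_equal(count_snvs(lib), st$cfg$variants_per_library)
    # depth filter agrees with a brute-force recount on the parsed records
    expect_equal(count_snvs(filter_by_depth(lib, 10)),
                 sum(lib$records$depth > 10))
  }
})
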