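# The synthetic-study generator: construction guarantees, determinism,
# planted mutation spectrum and ground-truth conservation.

test_that("config validation rejects impossible compositions", {
  expect_error(simulation_config(gc_content = 0), "gc_content",
               class = "castevar_config_error")
  expect_error(simulation_config(gc_content = 1), "gc_content",
               class = "castevar_config_error")
  expect_error(simulation_config(orf_codons_range = c(5L, 2L)), "range",
               class = "castevar_config_error")
  expect_error(simulation_config(subset_fraction = 1.2), "subset_fraction",
               class = "castevar_config_error")
  expect_error(simulation_config(soldier_nonsyn_enrichment = 0.5),
               "enrichment", class = "castevar_config_error")
})

test_that("minimal transcript is exactly ATG + codon + stop", {
  cfg <- simulation_config(n_transcripts = 1L, orf_codons_range = c(1L, 1L),
                           utr_len_range = c(0L, 0L), subset_fraction = 0,
                           variants_per_library = 0L, seed = 3L)
  ref <- generate_reference(cfg)
  s <- unname(ref$sequences[1])
  expect_equal(nchar(s), 9L)
  expect_equal(substr(s, 1, 3), "ATG")
  expect_true(substr(s, 7, 9) %in% c("TAA", "TAG", "TGA"))
  expect_equal(ref$orfs$start, 1L)
  expect_equal(ref$orfs$end, 9L)
})

test_that("the planted ORF is the longest ORF of every transcript", {
  ref <- generate_reference(small_config())
  for (i in seq_along(ref$sequences)) {
    found <- find_longest_orf(ref$sequences[[i]])
    expect_equal(found$start, ref$orfs$start[i])
    expect_equal(found$end, ref$orfs$end[i])
  }
})

test_that("design has one library per caste x population cell and subset size", {
  cfg <- simulation_config(n_transcripts = 100L, subset_fraction = 0.1,
                           orf_codons_range = c(10L, 20L),
                           utr_len_range = c(0L, 10L), seed = 5L)
  ref <- generate_reference(cfg)
  libs <- ref$design$libraries
  expect_equal(nrow(libs), 9L)
  expect_equal(sort(unique(libs$caste)), c("nymph", "soldier", "worker"))
  expect_equal(sort(unique(libs$population)), c("Boston", "Raleigh", "Toronto"))
  expect_false(anyDuplicated(paste(libs$caste, libs$population)) > 0)
  expect_length(ref$design$subset_ids, 10L)
  expect_true(all(ref$design$subset_ids %in% names(ref$sequences)))
})

test_that("identical config and seed reproduce byte-identical studies", {
  cfg <- simulation_config(n_transcripts = 10L, orf_codons_range = c(5L, 15L),
                           utr_len_range = c(0L, 10L),
                           variants_per_library = 50L, seed = 9L)
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  m1 <- generate_study(cfg, d1)
  m2 <- generate_study(cfg, d2)
  for (f in c("reference", "metadata", "subset", "ground_truth")) {
    expect_identical(readLines(m1[[f]]), readLines(m2[[f]]))
  }
  for (id in names(m1$vcf)) {
    expect_identical(readLines(m1$vcf[[id]]), readLines(m2$vcf[[id]]))
  }
  # a different seed changes at least one VCF
  cfg3 <- cfg; cfg3$seed <- cfg$seed + 1L
  m3 <- generate_study(cfg3, d3)
  differs <- any(vapply(names(m1$vcf), function(id) {
    !identical(readLines(m1$vcf[[id]]), readLines(m3$vcf[[id]]))
  }, logical(1)))
  expect_true(differs)
})

test_that("planted variants respect the placement contracts", {
  st <- small_study()
  ref <- st$ref
  lv <- plant_variants(ref, ref$design, st$cfg, "worker_Boston")
  rec <- lv$records
  expect_equal(nrow(rec), st$cfg$variants_per_library)
  expect_false(anyDuplicated(paste(rec$transcript_id, rec$pos)) > 0)
  expect_true(all(rec$ref != rec$alt))
  # ref column matches the reference base at every planted site
  expect_true(all(substr(ref$sequences[rec$transcript_id], rec$pos, rec$pos)
                  == rec$ref))
  # ground-truth labels partition into the four classes
  expect_true(all(rec$class %in% c("synonymous", "nonsynonymous",
                                   "stopgain", "noncoding")))
  expect_true(all(rec$titv %in% c("transition", "transversion")))
  expect_error(plant_variants(ref, ref$design, st$cfg, "no_such_library"),
               "unknown library", class = "castevar_config_error")
})

test_that("zero variants produce a valid empty VCF; too many error out", {
  cfg <- simulation_config(n_transcripts = 5L, orf_codons_range = c(5L, 10L),
                           utr_len_range = c(0L, 5L),
                           variants_per_library = 0L, seed = 21L)
  d <- tempfile()
  man <- generate_study(cfg, d)
  expect_length(man$vcf, 9L)
  lib <- read_snvs(man$vcf[[1]])
  expect_equal(count_snvs(lib), 0)

  cfg_big <- cfg
  cfg_big$variants_per_library <- 10000L
  ref <- generate_reference(cfg)
  expect_error(plant_variants(ref, ref$design, cfg_big, "nymph_Raleigh"),
               "exceeds available sites", class = "castevar_config_error")
})

test_that("planted labels agree with the package classifier on every variant", {
  st <- small_study()
  truth <- st$truth
  orfs <- st$ref$orfs
  cls <- castevar:::classify_changes(truth$transcript, truth$pos, truth$ref,
                                     truth$alt, st$ref$sequences, orfs)
  expect_equal(cls, truth$class)
})

test_that("null enrichment leaves subset and background mixes exchangeable", {
  # with enrichment 1 the syn/nonsyn mix of coding variants must be
  # independent of subset membership: chi-square p > 0.01 in >= 19/20 seeds
  failures <- 0L
  for (seed in 1:20) {
    cfg <- simulation_config(n_transcripts = 30L,
                             orf_codons_range = c(15L, 30L),
                             utr_len_range = c(5L, 15L),
                             variants_per_library = 600L,
                             subset_fraction = 0.3,
                             library_effect_sd = 0,
                             seed = seed)
    ref <- generate_reference(cfg)
    lv <- plant_variants(ref, ref$design, cfg, "soldier_Toronto")
    rec <- lv$records[lv$records$class %in% c("synonymous", "nonsynonymous"), ]
    in_subset <- rec$transcript_id %in% ref$design$subset_ids
    p <- suppressWarnings(
      stats::chisq.test(table(in_subset, rec$class))$p.value)
    if (p <= 0.01) failures <- failures + 1L
  }
  expect_lte(failures, 1L)
})

test_that("population count multipliers scale per-library variant numbers", {
  cfg <- simulation_config(
    n_transcripts = 20L, orf_codons_range = c(10L, 20L),
    utr_len_range = c(0L, 10L), variants_per_library = 200L,
    population_count_multiplier = c(Raleigh = 1, Boston = 0.5, Toronto = 2),
    seed = 13L
  )
  ref <- generate_reference(cfg)
  n_of <- function(id) nrow(plant_variants(ref, ref$design, cfg, id)$records)
  expect_equal(n_of("nymph_Raleigh"), 200L)
  expect_equal(n_of("nymph_Boston"), 100L)
  expect_equal(n_of("nymph_Toronto"), 400L)
})
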