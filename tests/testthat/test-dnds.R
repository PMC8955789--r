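test_that("Jukes-Cantor correction matches its closed form and contracts", {
  expect_identical(jc_distance(0), 0)
  expect_equal(jc_distance(0.1), 0.10733, tolerance = 1e-5 / 0.10733)
  expect_equal(jc_distance(0.5), 0.82396, tolerance = 1e-5 / 0.82396)
  expect_error(jc_distance(0.75), "saturates")
  expect_error(jc_distance(-0.01), "non-negative")
  # d >= p, strictly increasing, d -> p as p -> 0
  p <- seq(0, 0.74, by = 0.01)
  d <- jc_distance(p)
  expect_true(all(d >= p))
  expect_true(all(diff(d) > 0))
  expect_lt(abs(jc_distance(1e-4) / 1e-4 - 1), 1e-3)
})

test_that("NG86 site counts match hand-enumerated codons", {
  tt <- ng86_site_counts("TTT")
  expect_equal(tt$syn_sites, 1 / 3)
  expect_equal(tt$nonsyn_sites, 8 / 3)
  gg <- ng86_site_counts("GGG")
  expect_equal(gg$syn_sites, 1)
  expect_equal(gg$nonsyn_sites, 2)
  # TGT -> TGA is a stop-gain and counts toward neither class
  tg <- ng86_site_counts("TGT")
  expect_equal(tg$syn_sites, 1 / 3)
  expect_equal(tg$nonsyn_sites, 7 / 3)
})

test_that("NG86 site counts are additive and exclude the terminal stop", {
  a <- ng86_site_counts("TTTGGG")
  expect_equal(a$syn_sites, 1 / 3 + 1)
  expect_equal(a$nonsyn_sites, 8 / 3 + 2)
  with_stop <- ng86_site_counts("TTTGGGTAA")
  expect_equal(with_stop, a)
  expect_error(ng86_site_counts("TTTT"), "divisible by 3")
  expect_error(ng86_site_counts("TTTTAAGGG"), "internal stop")
})

test_that("per-codon site mass partitions into syn + nonsyn + stop-adjacent", {
  # every sense codon carries 3 sites split among the three classes
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  for (cd in sense) {
    sc <- ng86_site_counts(cd)
    stop_mass <- 0
    for (p in 1:3) {
      for (b in c("A", "C", "G", "T")) {
        if (b == substr(cd, p, p)) next
        mut <- cd
        substr(mut, p, p) <- b
        if (code[mut] == "*") stop_mass <- stop_mass + 1 / 3
      }
    }
    expect_equal(sc$syn_sites + sc$nonsyn_sites + stop_mass, 3, info = cd)
  }
})

test_that("SNV classification against the ORF matches codon translation", {
  ref <- c(tx = "ATGAAATAA")
  orf <- find_longest_orf(ref[["tx"]])
  snv <- function(pos, refb, alt) list(transcript_id = "tx", pos = pos,
                                       ref = refb, alt = alt)
  expect_equal(classify_snv(orf, snv(6, "A", "G"), ref), "synonymous")    # AAA->AAG
  expect_equal(classify_snv(orf, snv(4, "A", "C"), ref), "nonsynonymous") # AAA->CAA
  expect_equal(classify_snv(orf, snv(4, "A", "T"), ref), "stopgain")      # AAA->TAA
  expect_equal(classify_snv(orf, snv(8, "A", "G"), ref), "noncoding")     # terminal stop
  expect_equal(classify_snv(NULL, snv(2, "T", "C"), ref), "noncoding")    # no ORF
  expect_error(classify_snv(orf, snv(6, "C", "G"), ref), "disagrees")
})

test_that("classification agrees with a translation oracle on random cases", {
  set.seed(7)
  ref <- generate_reference(small_config())
  ids <- sample(names(ref$sequences), 5)
  for (id in ids) {
    seq <- ref$sequences[[id]]
    orf <- list(start = ref$orfs$start[ref$orfs$transcript_id == id],
                end = ref$orfs$end[ref$orfs$transcript_id == id])
    pos <- sample(nchar(seq), 40, replace = FALSE)
    for (p in pos) {
      refb <- substr(seq, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
      got <- classify_snv(orf, list(transcript_id = id, pos = p,
                                    ref = refb, alt = alt),
                          ref$sequences[id])
      expect_equal(got, oracle_classify(seq, orf, p, alt),
                   info = paste(id, p, refb, alt))
    }
  }
})

test_that("pooled dN/dS follows the hand computation on a crafted library", {
  # ORF ATG AAA GGG GGG TAA:
  # sites syn = 0 + 1/3 + 1 + 1, nonsyn = 3 + 7/3 + 2 + 2
  ref <- c(tx = "ATGAAAGGGGGGTAA")
  rec <- data.frame(
    transcript_id = "tx",
    pos = c(9L, 4L, 5L, 15L),
    ref = c("G", "A", "A", "A"),
    alt = c("A", "G", "T", "G"),
    depth = 50L
  )
  # pos 9 GGG->GGA syn; pos 4 AAA->GAA nonsyn; pos 5 AAA->ATA nonsyn;
  # pos 15 inside terminal stop -> noncoding
  lib <- library_variants("crafted", rec)
  est <- estimate_dnds(lib, ref)
  syn_sites <- 7 / 3
  nonsyn_sites <- 28 / 3
  expect_equal(est$p_s, 1 / syn_sites)
  expect_equal(est$p_n, 2 / nonsyn_sites)
  expect_equal(est$d_s, -0.75 * log(1 - 4 * est$p_s / 3))
  expect_equal(est$ratio, est$d_n / est$d_s)
  expect_equal(unname(est$counts[c("syn", "nonsyn", "noncoding")]),
               c(1, 2, 1))
})

test_that("equal substitution proportions give a ratio of exactly 1", {
  # ORF ATG GGG GGG GGG TAA: syn sites 3, nonsyn sites 3 + 3*2 = 9;
  # 1 synonymous and 3 nonsynonymous hits make p_s = p_n = 1/3
  ref <- c(tx = "ATGGGGGGGGGGTAA")
  rec <- data.frame(
    transcript_id = "tx",
    pos = c(6L, 4L, 7L, 11L),
    ref = "G",
    alt = c("A", "A", "C", "T"),
    depth = 30L
  )
  est <- estimate_dnds(library_variants("balanced", rec), ref)
  expect_equal(est$p_s, est$p_n)
  expect_equal(est$ratio, 1)
})

test_that("estimate_dnds handles subsets, ORF-less transcripts and degenerates", {
  ref <- c(a = "ATGAAAGGGTAA", b = "CCCCCCCCC", s = "ATGTTTGGGGGGTGA")
  rec <- data.frame(
    transcript_id = c("a", "b", "s"),
    pos = c(4L, 2L, 6L),
    ref = c("A", "C", "T"),
    alt = c("G", "T", "C"),
    depth = 20L
  )
  lib <- library_variants("mix", rec)
  whole <- estimate_dnds(lib, ref)
  # the variant on ORF-less transcript b is noncoding
  expect_equal(unname(whole$counts[["noncoding"]]), 1)
  sub <- estimate_dnds(lib, ref, subset = "s")
  expect_equal(unname(sub$counts[["syn"]]), 1)  # TTT->TTC
  expect_equal(unname(sub$counts[["nonsyn"]]), 0)
  expect_error(estimate_dnds(lib, ref, subset = "zzz"), "absent")
  expect_error(estimate_dnds(lib, ref["b"]), "degenerate|no synonymous",
               class = "castevar_data_error")
})

test_that("per-transcript mode reconciles with the pooled tallies", {
  st <- small_study()
  lib <- read_snvs(st$manifest$vcf[["nymph_Boston"]], "nymph_Boston")
  pooled <- estimate_dnds(lib, st$ref$sequences, orfs = st$ref$orfs)
  per_tx <- estimate_dnds(lib, st$ref$sequences, mode = "per-transcript",
                          orfs = st$ref$orfs)
  expect_equal(sum(per_tx$syn_subs), unname(pooled$counts[["syn"]]))
  expect_equal(sum(per_tx$nonsyn_subs), unname(pooled$counts[["nonsyn"]]))
  expect_equal(sum(per_tx$syn_sites), unname(pooled$sites[["syn"]]))
  expect_equal(sum(per_tx$nonsyn_sites), unname(pooled$sites[["nonsyn"]]))
})
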