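# Shared fixtures: configs scaled for test runtime, a cached small on-disk
# study, and independent brute-force oracles.

small_config <- function(...) {
  simulation_config(
    n_transcripts = 40L, orf_codons_range = c(20L, 40L),
    utr_len_range = c(5L, 20L), variants_per_library = 800L,
    subset_fraction = 0.1, seed = 42L, ...
  )
}

# medium reference for the 30K-variant recovery checks
medium_config <- function(...) {
  simulation_config(
    n_transcripts = 250L, orf_codons_range = c(80L, 160L),
    utr_len_range = c(20L, 60L), variants_per_library = 30000L,
    subset_fraction = 0.04, seed = 11L, ...
  )
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, make(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_study <- function() {
  cached("small_study", function() {
    cfg <- small_config()
    dir <- tempfile("study_small_")
    manifest <- generate_study(cfg, dir)
    list(cfg = cfg, dir = dir, manifest = manifest,
         ref = generate_reference(cfg),
         truth = read.delim(manifest$ground_truth, stringsAsFactors = FALSE))
  })
}

medium_reference <- function() {
  cached("medium_reference", function() generate_reference(medium_config()))
}

# Brute-force ORF oracle: walk codons from every ATG in every frame.
oracle_longest_orf <- function(seq) {
  n <- nchar(seq)
  best <- NULL
  for (s in seq_len(max(0, n - 2))) {
    if (substr(seq, s, s + 2) != "ATG") next
    p <- s
    while (p + 2 <= n) {
      codon <- substr(seq, p, p + 2)
      if (codon %in% c("TAA", "TAG", "TGA")) {
        len <- p + 2 - s + 1
        if (is.null(best) || len > best$length) best <- list(start = s, end = p + 2, length = len)
        break
      }
      p <- p + 3
    }
  }
  best
}

# Brute-force NG86 oracle: enumerate all 9 single-base changes of each codon
# and classify them with Biostrings translation.
oracle_ng86 <- function(codon) {
  aa <- function(cd) as.character(Biostrings::translate(
    Biostrings::DNAString(cd), no.init.codon = TRUE))
  ref_aa <- aa(codon)
  syn <- 0; nonsyn <- 0
  for (p in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, p, p)) next
      mut <- codon
      substr(mut, p, p) <- b
      mut_aa <- aa(mut)
      if (mut_aa == "*") next  # stop-gains count toward neither class
      if (mut_aa == ref_aa) syn <- syn + 1 / 3 else nonsyn <- nonsyn + 1 / 3
    }
  }
  c(syn = syn, nonsyn = nonsyn)
}

# classify one substitution by translating whole codons with Biostrings
oracle_classify <- function(seq, orf, pos, alt) {
  if (is.null(orf) || pos < orf$start || pos > orf$end - 3) return("noncoding")
  cpos <- ((pos - orf$start) %% 3) + 1
  cstart <- pos - cpos + 1
  codon <- substr(seq, cstart, cstart + 2)
  mut <- codon
  substr(mut, cpos, cpos) <- alt
  aa <- function(cd) as.character(Biostrings::translate(
    Biostrings::DNAString(cd), no.init.codon = TRUE))
  if (aa(mut) == "*") return("stopgain")
  if (aa(mut) == aa(codon)) "synonymous" else "nonsynonymous"
}

pipeline_fixture <- function() {
  cached("pipeline_run", function() {
    out <- tempfile("pipeline_")
    cfg <- pipeline_config(mode = "simulate", sim = small_config(),
                           out_dir = out)
    list(study = run_study(cfg), out = out, cfg = cfg)
  })
}

random_groups <- function(k = 3, n = 5) {
  g <- lapply(seq_len(k), function(i) rnorm(n, mean = i))
  names(g) <- letters[seq_len(k)]
  g
}

# one-way ANOVA F from explicit sums of squares (regression-on-indicators)
oracle_anova_f <- function(g) {
  values <- unlist(g)
  grand <- mean(values)
  means <- vapply(g, mean, numeric(1))
  ssb <- sum(lengths(g) * (means - grand)^2)
  ssw <- sum(unlist(lapply(g, function(v) (v - mean(v))^2)))
  df1 <- length(g) - 1
  df2 <- length(values) - length(g)
  (ssb / df1) / (ssw / df2)
}
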