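# Synthetic study generator: a seeded 3-caste x 3-population design with a
# known reference transcriptome, planted SNVs and ground-truth labels.

CASTES <- c("nymph", "soldier", "worker")
POPULATIONS <- c("Raleigh", "Boston", "Toronto")

#' Configuration of a synthetic variant study
#'
#' Defines the study conditions the generator emulates: a consensus
#' reference of ORF-bearing transcripts, nine libraries in a 3-caste x
#' 3-population design, planted SNVs with a controllable
#' transition/transversion ratio and negative-binomial read depths, and a
#' designated caste-associated transcript subset in which soldier libraries
#' carry elevated nonsynonymous substitution odds.
#'
#' @param n_transcripts Number of transcripts in the reference.
#' @param orf_codons_range `(min, max)` inner (non-stop) codons per planted ORF.
#' @param utr_len_range `(min, max)` nucleotides per UTR flank.
#' @param gc_content GC fraction of UTR sequence, strictly in (0, 1).
#' @param variants_per_library Planted SNVs per library.
#' @param titv_target Expected transitions/transversions of planted SNVs; a
#'   planted variant is a transition with probability
#'   `titv_target / (1 + titv_target)`, otherwise one of the two
#'   transversions uniformly.
#' @param depth_mean,depth_dispersion Mean and dispersion (size) of the
#'   negative-binomial per-variant read-depth model.
#' @param subset_fraction Fraction of transcripts designated caste-associated;
#'   `ceiling(subset_fraction * n_transcripts)` transcripts are sampled.
#' @param nonsyn_weight Odds multiplier applied to every nonsynonymous
#'   candidate change in every library (1 = neutral placement).  Calibrate
#'   with [calibrate_study()] to plant a target background dN/dS.
#' @param soldier_nonsyn_enrichment Additional odds multiplier (>= 1) applied
#'   to nonsynonymous changes in subset transcripts of soldier libraries.
#' @param library_effect_sd Standard deviation (log scale) of a per-library
#'   lognormal multiplier on the nonsynonymous odds, emulating biological
#'   between-library variability of dN/dS; 0 disables it.
#' @param population_count_multiplier Optional named multiplier of
#'   `variants_per_library` per population (emulates population-level SNV
#'   count differences); default all 1.
#' @param seed Master seed; per-library RNG substreams are derived from it by
#'   stable hashing of the library ID.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_transcripts = 400L,
                              orf_codons_range = c(90L, 210L),
                              utr_len_range = c(30L, 120L),
                              gc_content = 0.45,
                              variants_per_library = 20000L,
                              titv_target = 1.7,
                              depth_mean = 40,
                              depth_dispersion = 5,
                              subset_fraction = 0.04,
                              nonsyn_weight = 1,
                              soldier_nonsyn_enrichment = 1,
                              library_effect_sd = 0.08,
                              population_count_multiplier = NULL,
                              seed = 1L) {
  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    orf_codons_range = as.integer(orf_codons_range),
    utr_len_range = as.integer(utr_len_range),
    gc_content = gc_content,
    variants_per_library = as.integer(variants_per_library),
    titv_target = titv_target,
    depth_mean = depth_mean,
    depth_dispersion = depth_dispersion,
    subset_fraction = subset_fraction,
    nonsyn_weight = nonsyn_weight,
    soldier_nonsyn_enrichment = soldier_nonsyn_enrichment,
    library_effect_sd = library_effect_sd,
    population_count_multiplier = population_count_multiplier,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop_config("invalid simulation config: ", msg)
  chk(length(cfg$n_transcripts) == 1 && !is.na(cfg$n_transcripts) &&
        cfg$n_transcripts >= 1, "n_transcripts must be a positive integer")
  chk(length(cfg$orf_codons_range) == 2 && !anyNA(cfg$orf_codons_range) &&
        cfg$orf_codons_range[1] >= 1 &&
        cfg$orf_codons_range[1] <= cfg$orf_codons_range[2],
      "orf_codons_range must be a nonempty positive range")
  chk(length(cfg$utr_len_range) == 2 && !anyNA(cfg$utr_len_range) &&
        cfg$utr_len_range[1] >= 0 &&
        cfg$utr_len_range[1] <= cfg$utr_len_range[2],
      "utr_len_range must be a nonempty non-negative range")
  chk(is.numeric(cfg$gc_content) && cfg$gc_content > 0 && cfg$gc_content < 1,
      "gc_content must lie strictly in (0, 1)")
  chk(cfg$variants_per_library >= 0, "variants_per_library must be non-negative")
  chk(is.numeric(cfg$titv_target) && cfg$titv_target > 0,
      "titv_target must be positive")
  chk(cfg$depth_mean > 0 && cfg$depth_dispersion > 0,
      "depth model parameters must be positive")
  chk(cfg$subset_fraction >= 0 && cfg$subset_fraction <= 1,
      "subset_fraction must lie in [0, 1]")
  chk(cfg$nonsyn_weight > 0, "nonsyn_weight must be positive")
  chk(cfg$soldier_nonsyn_enrichment >= 1,
      "soldier_nonsyn_enrichment must be >= 1")
  chk(cfg$library_effect_sd >= 0, "library_effect_sd must be non-negative")
  if (!is.null(cfg$population_count_multiplier)) {
    chk(all(POPULATIONS %in% names(cfg$population_count_multiplier)) &&
          all(cfg$population_count_multiplier > 0),
        "population_count_multiplier must be a positive vector named by population")
  }
  chk(length(cfg$seed) == 1 && !is.na(cfg$seed), "seed must be an integer")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  %d transcripts (ORF %d-%d codons, UTR %d-%d nt, GC %.2f)\n",
              x$n_transcripts, x$orf_codons_range[1], x$orf_codons_range[2],
              x$utr_len_range[1], x$utr_len_range[2], x$gc_content))
  cat(sprintf("  %d variants/library, ts/tv %.2f, depth NB(mu=%g, size=%g)\n",
              x$variants_per_library, x$titv_target, x$depth_mean,
              x$depth_dispersion))
  cat(sprintf("  subset fraction %.3f, nonsyn weight %.3f, soldier enrichment %.3f\n",
              x$subset_fraction, x$nonsyn_weight, x$soldier_nonsyn_enrichment))
  cat(sprintf("  library effect sd %.3f, seed %d\n", x$library_effect_sd, x$seed))
  invisible(x)
}

#' The 3-caste x 3-population study design
#'
#' One library per caste x population cell (9 libraries), plus the designated
#' caste-associated transcript subset.
#'
#' @param subset_ids Character vector of subset transcript IDs.
#' @param libraries Optional data frame (`library_id`, `caste`, `population`)
#'   overriding the default full-factorial grid.
#' @return An object of class `study_design`.
#' @export
study_design <- function(subset_ids = character(0), libraries = NULL) {
  if (is.null(libraries)) {
    grid <- expand.grid(caste = CASTES, population = POPULATIONS,
                        stringsAsFactors = FALSE)
    libraries <- data.frame(
      library_id = paste(grid$caste, grid$population, sep = "_"),
      caste = grid$caste, population = grid$population,
      stringsAsFactors = FALSE
    )
  }
  cells <- paste(libraries$caste, libraries$population)
  if (anyDuplicated(cells)) stop_config("duplicate caste x population cells")
  structure(list(libraries = libraries, subset_ids = subset_ids),
            class = "study_design")
}

#' Generate a synthetic reference transcriptome and study design
#'
#' Each transcript is assembled as 5'UTR + `ATG` + k inner sense codons +
#' stop codon + 3'UTR, with k drawn from `orf_codons_range`, UTR lengths from
#' `utr_len_range` and UTR bases i.i.d. with the configured GC content (stop
#' triplets are allowed in UTRs, exercising the ORF finder).  Every transcript
#' is re-scanned with [find_longest_orf()] and resampled until the planted
#' ORF is the longest one, so planted coordinates are exact ground truth.
#'
#' @param config A [simulation_config()].
#' @return A list with `sequences` (named character vector), `orfs`
#'   (data frame `transcript_id`, `start`, `end` of the planted = longest
#'   ORFs) and `design` (a [study_design()] whose `subset_ids` are the
#'   caste-associated transcripts).
#' @export
generate_reference <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  n <- config$n_transcripts
  ids <- sprintf("TR%05d", seq_len(n))
  utr_probs <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
                 G = config$gc_content / 2, T = (1 - config$gc_content) / 2)

  seqs <- character(n)
  start <- integer(n)
  end <- integer(n)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      k <- sample(config$orf_codons_range[1]:config$orf_codons_range[2], 1L)
      l5 <- sample(config$utr_len_range[1]:config$utr_len_range[2], 1L)
      l3 <- sample(config$utr_len_range[1]:config$utr_len_range[2], 1L)
      utr5 <- paste(sample(BASES, l5, replace = TRUE, prob = utr_probs),
                    collapse = "")
      utr3 <- paste(sample(BASES, l3, replace = TRUE, prob = utr_probs),
                    collapse = "")
      body <- paste(sample(SENSE_CODONS, k, replace = TRUE), collapse = "")
      s <- paste0(utr5, "ATG", body, sample(STOP_CODONS, 1L), utr3)
      planted <- c(l5 + 1L, l5 + 3L + 3L * k + 3L)
      found <- find_longest_orf(s)
      if (!is.null(found) && found$start == planted[1] && found$end == planted[2]) {
        seqs[i] <- s
        start[i] <- planted[1]
        end[i] <- planted[2]
        break
      }
      if (try == 200) stop_config("could not embed a dominant ORF in transcript ", ids[i])
    }
  }
  names(seqs) <- ids
  n_subset <- ceiling(config$subset_fraction * n)
  subset_ids <- sort(sample(ids, n_subset))
  list(
    sequences = seqs,
    orfs = data.frame(transcript_id = ids, start = start, end = end,
                      stringsAsFactors = FALSE),
    design = study_design(subset_ids = subset_ids)
  )
}

# Enumerate every candidate single-base change of the reference: one row per
# (transcript, position, alt) with its ground-truth class and mutation type.
# This table drives variant planting, calibration and ground-truth labelling.
site_change_table <- function(sequences, orfs) {
  lens <- nchar(sequences)
  tx <- rep(names(sequences), lens)
  pos <- sequence(lens)
  refbase <- unlist(strsplit(sequences, ""), use.names = FALSE)

  tx3 <- rep(tx, each = 3L)
  pos3 <- rep(pos, each = 3L)
  ref3 <- rep(refbase, each = 3L)
  alt3 <- unlist(ALT_BASES[refbase], use.names = FALSE)

  seqs_rep <- sequences[tx3]
  m <- match(tx3, orfs$transcript_id)
  ostart <- orfs$start[m]
  oend <- orfs$end[m]
  cls <- rep("noncoding", length(tx3))
  coding <- !is.na(ostart) & pos3 >= ostart & pos3 <= (oend - 3L)
  if (any(coding)) {
    cpos <- ((pos3[coding] - ostart[coding]) %% 3L) + 1L
    cstart <- pos3[coding] - cpos + 1L
    codon <- substr(seqs_rep[coding], cstart, cstart + 2L)
    cls[coding] <- CHANGE_CLASS[cbind(match(codon, CODONS), cpos,
                                      match(alt3[coding], BASES))]
  }
  data.frame(
    site = rep(seq_along(tx), each = 3L),
    transcript_id = tx3, pos = pos3, ref = ref3, alt = alt3,
    class = cls,
    transition = is_transition(ref3, alt3),
    stringsAsFactors = FALSE
  )
}

# Per-change placement weights for one library.  Base weight encodes the
# ts/tv model (transition: t, each transversion: (1-t)/2, with
# t = titv/(1+titv)); nonsynonymous changes get the global odds multiplier
# (times the per-library effect), and those in subset transcripts of soldier
# libraries the additional enrichment.
change_weights <- function(changes, config, is_soldier, subset_ids,
                           library_effect = 1) {
  t_prob <- config$titv_target / (1 + config$titv_target)
  w <- ifelse(changes$transition, t_prob, (1 - t_prob) / 2)
  nonsyn <- changes$class == "nonsynonymous"
  w[nonsyn] <- w[nonsyn] * config$nonsyn_weight * library_effect
  if (is_soldier && config$soldier_nonsyn_enrichment != 1 &&
      length(subset_ids)) {
    boost <- nonsyn & changes$transcript_id %in% subset_ids
    w[boost] <- w[boost] * config$soldier_nonsyn_enrichment
  }
  w
}

#' Plant one library's SNVs
#'
#' Places `variants_per_library` SNVs on the reference (at most one per
#' transcript position) with odds proportional to the per-change weights of
#' the configured mutation model: transitions with probability
#' `titv_target/(1+titv_target)` versus each transversion, nonsynonymous
#' changes scaled by `nonsyn_weight` (and, in subset transcripts of soldier
#' libraries, by `soldier_nonsyn_enrichment`).  Depths are drawn from the
#' negative-binomial model.  Each library runs in its own seed substream
#' derived from the master seed and the library ID.
#'
#' @param reference The list returned by [generate_reference()] (or a list
#'   with `sequences` and `orfs`).
#' @param design A [study_design()].
#' @param config The [simulation_config()].
#' @param library_id One of the design's library IDs.
#' @param changes Optional precomputed [site_change_table] (internal reuse).
#' @return A [library_variants()] object whose records carry the planted
#'   ground-truth columns `class` (synonymous / nonsynonymous / stopgain /
#'   noncoding) and `titv` (transition / transversion).
#' @export
plant_variants <- function(reference, design, config, library_id,
                           changes = NULL) {
  validate_simulation_config(config)
  libs <- design$libraries
  row <- match(library_id, libs$library_id)
  if (is.na(row)) stop_config("unknown library: ", library_id)
  if (is.null(changes)) changes <- site_change_table(reference$sequences,
                                                     reference$orfs)

  n_var <- config$variants_per_library
  if (!is.null(config$population_count_multiplier)) {
    n_var <- as.integer(round(
      n_var * config$population_count_multiplier[[libs$population[row]]]))
  }
  n_sites <- max(changes$site)
  if (n_var > n_sites) {
    stop_config("variants_per_library (", n_var,
                ") exceeds available sites (", n_sites, ")")
  }

  set.seed(substream_seed(config$seed, library_id))
  caste <- libs$caste[row]
  library_effect <- if (config$library_effect_sd > 0) {
    exp(rnorm(1, mean = -config$library_effect_sd^2 / 2,
              sd = config$library_effect_sd))
  } else 1

  w <- change_weights(changes, config, is_soldier = caste == "soldier",
                      subset_ids = design$subset_ids,
                      library_effect = library_effect)

  if (n_var == 0) {
    rec <- empty_records()
    rec$class <- character(0)
    rec$titv <- character(0)
    return(library_variants(library_id, rec, caste, libs$population[row]))
  }

  # weighted sampling of positions without replacement (exponential-key trick)
  site_w <- rowsum(w, changes$site)[, 1]
  keys <- rexp(n_sites) / site_w
  picked <- sort(order(keys)[seq_len(n_var)])

  # choose the alt at each picked position proportionally to change weights
  wm <- matrix(w, nrow = 3L)[, picked, drop = FALSE]
  cum <- apply(wm, 2, cumsum)
  u <- runif(n_var) * cum[3L, ]
  alt_idx <- 1L + (u > cum[1L, ]) + (u > cum[2L, ])
  change_row <- (picked - 1L) * 3L + alt_idx

  rec <- data.frame(
    transcript_id = changes$transcript_id[change_row],
    pos = changes$pos[change_row],
    ref = changes$ref[change_row],
    alt = changes$alt[change_row],
    depth = rnbinom(n_var, size = config$depth_dispersion,
                    mu = config$depth_mean),
    class = changes$class[change_row],
    titv = ifelse(changes$transition[change_row], "transition", "transversion"),
    stringsAsFactors = FALSE
  )
  ord <- order(rec$transcript_id, rec$pos)
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  library_variants(library_id, rec, caste, libs$population[row])
}

write_vcf <- function(records, sequences, library_id, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=castevar synthetic study generator",
    sprintf("##contig=<ID=%s,length=%d>", names(sequences), nchar(sequences)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", library_id, sep = "\t")
  )
  rows <- if (nrow(records)) {
    paste(records$transcript_id, records$pos, ".", records$ref, records$alt,
          ".", "PASS", paste0("DP=", records$depth), "DP", records$depth,
          sep = "\t")
  } else character(0)
  writeLines(c(header, rows), path)
}

#' Generate a complete synthetic study on disk
#'
#' Writes the reference FASTA, one VCF per library (9), the library metadata
#' TSV, the caste-associated subset ID list, and a ground-truth TSV of
#' planted per-variant labels, then returns (and writes) a manifest of all
#' paths.  Identical config and seed produce byte-identical outputs.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of paths: `reference`, `vcf` (named by
#'   library), `metadata`, `subset`, `ground_truth`, `manifest`.
#' @export
generate_study <- function(config, out_dir) {
  validate_simulation_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_config("cannot create output directory ", out_dir)

  ref <- generate_reference(config)
  changes <- site_change_table(ref$sequences, ref$orfs)

  fasta_path <- file.path(out_dir, "reference.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$sequences),
                              fasta_path)

  libs <- ref$design$libraries
  vcf_paths <- setNames(file.path(out_dir, paste0(libs$library_id, ".vcf")),
                        libs$library_id)
  truth <- vector("list", nrow(libs))
  for (i in seq_len(nrow(libs))) {
    lv <- plant_variants(ref, ref$design, config, libs$library_id[i],
                         changes = changes)
    write_vcf(lv$records, ref$sequences, libs$library_id[i], vcf_paths[i])
    if (nrow(lv$records)) {
      truth[[i]] <- data.frame(library_id = libs$library_id[i],
                               lv$records[c("transcript_id", "pos", "ref",
                                            "alt", "class", "titv")],
                               stringsAsFactors = FALSE)
      names(truth[[i]])[2] <- "transcript"
    }
  }

  meta_path <- file.path(out_dir, "metadata.tsv")
  write.table(libs, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)

  subset_path <- file.path(out_dir, "subset_ids.txt")
  writeLines(ref$design$subset_ids, subset_path)

  truth_path <- file.path(out_dir, "ground_truth.tsv")
  truth_df <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  if (is.null(truth_df)) {
    truth_df <- data.frame(library_id = character(0), transcript = character(0),
                           pos = integer(0), ref = character(0),
                           alt = character(0), class = character(0),
                           titv = character(0))
  }
  write.table(truth_df, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    reference = fasta_path,
    vcf = as.list(vcf_paths),
    metadata = meta_path,
    subset = subset_path,
    ground_truth = truth_path
  )
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  manifest$manifest <- manifest_path
  invisible(manifest)
}
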