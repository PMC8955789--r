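# End-to-end orchestration: simulate or ingest, filter, catalogue, estimate,
# test, and write the study-shaped reports.

#' Configuration of a full pipeline run
#'
#' In `simulate` mode the pipeline writes a synthetic study with
#' [generate_study()] and then ingests its own outputs, so a later `ingest`
#' run pointed at the same directory reproduces every downstream number
#' bit-identically.  In `ingest` mode all input paths are required.
#'
#' @param mode `"simulate"` or `"ingest"`.
#' @param sim A [simulation_config()] (simulate mode).
#' @param reference Path to the reference FASTA (ingest mode).
#' @param vcf_dir Directory containing one `.vcf` per library (ingest mode);
#'   alternatively give `vcf_paths` explicitly.
#' @param vcf_paths Optional character vector of VCF paths.
#' @param metadata Path to the library metadata TSV with header
#'   `library_id  caste  population` (ingest mode).
#' @param subset Optional path to a transcript-ID list (one per line) of
#'   caste-associated genes.
#' @param min_depth,strict Read-depth filter settings, see [filter_by_depth()].
#' @param dnds_mode `"pooled"` or `"per-transcript"`, see [estimate_dnds()].
#' @param adjustment Dunn post-hoc adjustment method, see [dunn_posthoc()].
#' @param out_dir Optional directory for report TSVs and the run manifest.
#' @param seed Overrides `sim$seed` in simulate mode.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"), sim = NULL,
                            reference = NULL, vcf_dir = NULL, vcf_paths = NULL,
                            metadata = NULL, subset = NULL,
                            min_depth = 10L, strict = TRUE,
                            dnds_mode = c("pooled", "per-transcript"),
                            adjustment = c("BH", "bonferroni", "holm", "none"),
                            out_dir = NULL, seed = NULL) {
  mode <- match.arg(mode)
  dnds_mode <- match.arg(dnds_mode)
  adjustment <- match.arg(adjustment)
  if (mode == "simulate") {
    if (is.null(sim)) sim <- simulation_config()
    if (!inherits(sim, "simulation_config")) {
      stop_config("simulate mode requires a simulation_config")
    }
    if (!is.null(seed)) sim$seed <- as.integer(seed)
  } else {
    missing <- c(
      if (is.null(reference)) "reference",
      if (is.null(vcf_dir) && is.null(vcf_paths)) "vcf_dir/vcf_paths",
      if (is.null(metadata)) "metadata"
    )
    if (length(missing)) {
      stop_config("ingest mode requires input paths: ",
                  paste(missing, collapse = ", "))
    }
  }
  structure(
    list(mode = mode, sim = sim, reference = reference, vcf_dir = vcf_dir,
         vcf_paths = vcf_paths, metadata = metadata, subset = subset,
         min_depth = min_depth, strict = strict, dnds_mode = dnds_mode,
         adjustment = adjustment, out_dir = out_dir,
         seed = if (!is.null(sim)) sim$seed else seed),
    class = "pipeline_config"
  )
}

#' Run the full variant-analysis study
#'
#' Produces, per library: filtered SNV count, transition/transversion ratio,
#' SBS-6 and SBS-96 catalogues, and whole-transcriptome plus gene-subset
#' dN/dS estimates; then caste- and population-grouped tests — Kruskal--Wallis
#' with Dunn post-hoc on SNV counts, one-way ANOVA with Tukey post-hoc on
#' ts/tv and on dN/dS (whole and subset).  With an output directory set, the
#' reports and a run manifest (versions, seed, thresholds) are written as
#' plain TSV/YAML.
#'
#' @param cfg A [pipeline_config()].
#' @return An object of class `snv_study` with elements `libraries` (per-
#'   library summary), `table1` (grouped mean +/- SD of SNV counts), `sbs6`
#'   and `sbs96` (class-by-library matrices), `dnds` (per library and scope),
#'   `stats` (tidy omnibus + post-hoc rows), `tests` (the `group_test`
#'   objects) and `files` (paths written, if any).
#' @export
run_study <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) {
    stop_config("cfg must be a pipeline_config")
  }
  files <- list()
  if (cfg$mode == "simulate") {
    sim_dir <- if (!is.null(cfg$out_dir)) {
      file.path(cfg$out_dir, "study")
    } else {
      tempfile("castevar_study_")
    }
    manifest <- generate_study(cfg$sim, sim_dir)
    cfg$reference <- manifest$reference
    cfg$vcf_paths <- unlist(manifest$vcf)
    cfg$metadata <- manifest$metadata
    cfg$subset <- manifest$subset
    files$study <- manifest
  }

  seqs <- as_reference(cfg$reference)
  meta <- read.delim(cfg$metadata, stringsAsFactors = FALSE)
  needed <- c("library_id", "caste", "population")
  if (!all(needed %in% names(meta))) {
    stop_config("metadata must have columns ", paste(needed, collapse = ", "))
  }

  vcf_paths <- cfg$vcf_paths
  if (is.null(vcf_paths)) {
    vcf_paths <- list.files(cfg$vcf_dir, pattern = "\\.vcf$", full.names = TRUE)
  }
  if (length(vcf_paths) == 0) stop_config("no VCF files found")
  lib_ids <- sub("\\.vcf$", "", basename(vcf_paths))
  orphan <- setdiff(lib_ids, meta$library_id)
  if (length(orphan)) {
    stop_config("VCF libraries missing from metadata: ",
                paste(orphan, collapse = ", "))
  }

  subset_ids <- NULL
  if (!is.null(cfg$subset)) {
    subset_ids <- readLines(cfg$subset, warn = FALSE)
    subset_ids <- subset_ids[nzchar(subset_ids)]
  }

  orfs <- orf_table(seqs)
  m <- match(lib_ids, meta$library_id)
  libs <- vector("list", length(vcf_paths))
  for (i in seq_along(vcf_paths)) {
    lv <- read_snvs(vcf_paths[i], library_id = lib_ids[i],
                    caste = meta$caste[m[i]], population = meta$population[m[i]])
    libs[[i]] <- filter_by_depth(lv, cfg$min_depth, cfg$strict)
  }
  names(libs) <- lib_ids

  sbs6 <- lapply(libs, build_sbs6)
  sbs96 <- lapply(libs, build_sbs96, reference = seqs)
  dnds_whole <- lapply(libs, estimate_dnds, reference = seqs, orfs = orfs)
  dnds_subset <- if (!is.null(subset_ids) && length(subset_ids)) {
    lapply(libs, estimate_dnds, reference = seqs, subset = subset_ids,
           orfs = orfs)
  } else NULL

  libsum <- data.frame(
    library_id = lib_ids,
    caste = meta$caste[m],
    population = meta$population[m],
    n_snv = vapply(libs, count_snvs, integer(1)),
    titv = vapply(libs, titv_ratio, numeric(1)),
    dnds_whole = vapply(dnds_whole, `[[`, numeric(1), "ratio"),
    dnds_subset = if (is.null(dnds_subset)) NA_real_ else
      vapply(dnds_subset, `[[`, numeric(1), "ratio"),
    row.names = NULL, stringsAsFactors = FALSE
  )

  dnds_df <- do.call(rbind, lapply(c(dnds_whole, dnds_subset), function(e) {
    data.frame(
      library_id = e$library_id, scope = e$scope,
      p_s = e$p_s, p_n = e$p_n, d_s = e$d_s, d_n = e$d_n, dnds = e$ratio,
      n_syn = e$counts[["syn"]], n_nonsyn = e$counts[["nonsyn"]],
      n_stopgain = e$counts[["stopgain"]], n_noncoding = e$counts[["noncoding"]],
      stringsAsFactors = FALSE
    )
  }))
  rownames(dnds_df) <- NULL

  # grouped tests: counts get the rank tests, ratios the ANOVA family
  measures <- list(
    counts = list(values = libsum$n_snv, omnibus = "kruskal"),
    titv = list(values = libsum$titv, omnibus = "anova"),
    dnds_whole = list(values = libsum$dnds_whole, omnibus = "anova")
  )
  if (!is.null(dnds_subset)) {
    measures$dnds_subset <- list(values = libsum$dnds_subset, omnibus = "anova")
  }
  tests <- list()
  stat_rows <- list()
  for (meas in names(measures)) {
    if (anyNA(measures[[meas]]$values)) {
      warning("measure '", meas, "' is undefined for some libraries; ",
              "its group tests are skipped", call. = FALSE)
      next
    }
    for (grouping in c("caste", "population")) {
      gl <- split(measures[[meas]]$values, libsum[[grouping]])
      if (measures[[meas]]$omnibus == "kruskal") {
        omni <- kruskal_wallis(gl)
        post <- dunn_posthoc(gl, adjustment = cfg$adjustment)
      } else {
        omni <- anova_oneway(gl)
        post <- tukey_hsd(gl)
      }
      key <- paste(meas, grouping, sep = ".")
      tests[[key]] <- list(omnibus = omni, posthoc = post)
      stat_rows[[key]] <- rbind(
        data.frame(measure = meas, grouping = grouping, test = omni$method,
                   statistic = omni$statistic,
                   df = paste(omni$df, collapse = ","), p = omni$p_value,
                   pair = NA_character_, estimate = NA_real_, p_adj = NA_real_,
                   stringsAsFactors = FALSE),
        data.frame(measure = meas, grouping = grouping, test = post$method,
                   statistic = NA_real_, df = NA_character_, p = NA_real_,
                   pair = paste(post$pairwise$group1, post$pairwise$group2,
                                sep = "-"),
                   estimate = post$pairwise$estimate,
                   p_adj = post$pairwise$p_adj, stringsAsFactors = FALSE)
      )
    }
  }
  stats_df <- do.call(rbind, stat_rows)
  rownames(stats_df) <- NULL

  study <- structure(
    list(
      config = cfg,
      libraries = libsum,
      table1 = summarize_table1(libsum),
      sbs6 = sbs_matrix(sbs6),
      sbs96 = sbs_matrix(sbs96),
      sbs96_exclusions = t(vapply(sbs96, `[[`, numeric(2), "excluded")),
      dnds = dnds_df,
      stats = stats_df,
      tests = tests,
      files = files
    ),
    class = "snv_study"
  )

  if (!is.null(cfg$out_dir)) {
    study$files <- c(study$files, write_reports(study, cfg))
  }
  study
}

write_reports <- function(study, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    library_summary = file.path(cfg$out_dir, "library_summary.tsv"),
    table1 = file.path(cfg$out_dir, "table1.tsv"),
    sbs6 = file.path(cfg$out_dir, "sbs6_matrix.tsv"),
    sbs96 = file.path(cfg$out_dir, "sbs96_matrix.tsv"),
    dnds = file.path(cfg$out_dir, "dnds.tsv"),
    stats = file.path(cfg$out_dir, "stats.tsv"),
    run_manifest = file.path(cfg$out_dir, "run_manifest.yaml")
  )
  wt <- function(x, path, rn = FALSE) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = rn,
                col.names = if (rn) NA else TRUE)
  }
  wt(study$libraries, paths$library_summary)
  wt(study$table1, paths$table1)
  wt(study$sbs6, paths$sbs6, rn = TRUE)
  wt(study$sbs96, paths$sbs96, rn = TRUE)
  wt(study$dnds, paths$dnds)
  wt(study$stats, paths$stats)
  yaml::write_yaml(list(
    package = as.character(packageVersion("castevar")),
    r_version = as.character(getRversion()),
    mode = cfg$mode,
    seed = cfg$seed,
    min_depth = cfg$min_depth,
    strict_depth_filter = cfg$strict,
    dnds_mode = cfg$dnds_mode,
    dunn_adjustment = cfg$adjustment,
    sd_convention = "sample (n-1)",
    inputs = list(reference = cfg$reference, metadata = cfg$metadata,
                  subset = cfg$subset,
                  vcf = as.list(unname(cfg$vcf_paths))),
    reports = lapply(paths, identity)
  ), paths$run_manifest)
  paths
}

#' Grouped mean +/- SD summary of SNV counts
#'
#' Summarises per-library SNV counts by caste and by population (six rows for
#' the full design), using the sample standard deviation (n - 1 denominator).
#'
#' @param libsum Per-library summary data frame with columns `library_id`,
#'   `caste`, `population`, `n_snv` (as produced by [run_study()]).
#' @return Data frame with columns `grouping`, `group`, `n`, `mean_snv`,
#'   `sd_snv`.
#' @export
summarize_table1 <- function(libsum) {
  needed <- c("caste", "population", "n_snv")
  if (!all(needed %in% names(libsum))) {
    stop_config("libsum must have columns ", paste(needed, collapse = ", "))
  }
  one <- function(grouping) {
    gl <- split(libsum$n_snv, libsum[[grouping]])
    data.frame(
      grouping = grouping, group = names(gl), n = lengths(gl),
      mean_snv = vapply(gl, mean, numeric(1)),
      sd_snv = vapply(gl, function(v) if (length(v) > 1) sd(v) else NA_real_,
                      numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  rbind(one("caste"), one("population"))
}

#' @export
print.snv_study <- function(x, ...) {
  cat(sprintf("<snv_study> %d libraries (%s mode), min_depth %s (%s)\n",
              nrow(x$libraries), x$config$mode, x$config$min_depth,
              if (x$config$strict) "depth > threshold" else "depth >= threshold"))
  print(x$libraries, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.snv_study <- function(object, ...) {
  cat("SNV counts by group (mean +/- sample SD):\n")
  print(object$table1, row.names = FALSE, digits = 6)
  cat("\nGroup tests (omnibus rows):\n")
  omni <- object$stats[is.na(object$stats$pair), c("measure", "grouping",
                                                   "test", "statistic", "df", "p")]
  print(omni, row.names = FALSE, digits = 4)
  invisible(object)
}
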