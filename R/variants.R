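#' Construct a per-library set of SNV records
#'
#' The unit of analysis throughout the package: one sequencing library's
#' biallelic single-nucleotide variants against the reference transcriptome,
#' labelled with its caste and population.  Duplicate
#' `(transcript_id, pos, alt)` triples are resolved last-read-wins with a
#' warning.
#'
#' @param library_id Library identifier (string).
#' @param records Data frame with columns `transcript_id`, `pos`, `ref`,
#'   `alt`, `depth` (extra columns are preserved).
#' @param caste,population Optional group labels.
#' @return An object of class `library_variants`.
#' @export
library_variants <- function(library_id, records,
                             caste = NA_character_, population = NA_character_) {
  needed <- c("transcript_id", "pos", "ref", "alt", "depth")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    stop_data("records must be a data frame with columns ",
              paste(needed, collapse = ", "))
  }
  records$pos <- as.integer(records$pos)
  records$depth <- as.integer(records$depth)
  if (nrow(records)) {
    if (any(!records$ref %in% BASES) || any(!records$alt %in% BASES)) {
      stop_data("ref and alt must be single bases in {A,C,G,T}")
    }
    if (any(records$ref == records$alt)) stop_data("alt must differ from ref")
    if (any(records$pos < 1L)) stop_data("pos must be >= 1")
    if (any(records$depth < 0L)) stop_data("depth must be non-negative")
    key <- paste(records$transcript_id, records$pos, records$alt)
    if (anyDuplicated(key)) {
      warning("duplicate (transcript, pos, alt) records: keeping last occurrence",
              call. = FALSE)
      records <- records[!duplicated(key, fromLast = TRUE), , drop = FALSE]
      rownames(records) <- NULL
    }
  }
  structure(
    list(library_id = library_id, caste = caste, population = population,
         records = records),
    class = "library_variants"
  )
}

#' @export
print.library_variants <- function(x, ...) {
  cat(sprintf("<library_variants> %s (caste=%s, population=%s): %d SNVs\n",
              x$library_id, x$caste, x$population, nrow(x$records)))
  invisible(x)
}

empty_records <- function() {
  data.frame(transcript_id = character(0), pos = integer(0),
             ref = character(0), alt = character(0), depth = integer(0),
             stringsAsFactors = FALSE)
}

#' Read the biallelic SNVs of one library from a VCF
#'
#' Parses a VCF v4.2 file and keeps exactly the rows that describe single
#' nucleotide variants: REF and ALT both single bases in `{A,C,G,T}`.
#' Indels, MNVs, symbolic alleles (`<...>`) and spanning deletions (`*`) are
#' dropped.  Multi-allelic rows are decomposed, each single-base ALT becoming
#' its own record at the same position.  Read depth is taken from the first
#' sample's FORMAT `DP` field when present, falling back to INFO `DP`, else 0.
#'
#' @param vcf_path Path to a VCF file.
#' @param library_id Library identifier; defaults to the file name without
#'   its `.vcf` extension.
#' @param caste,population Optional group labels attached to the result.
#' @return A [library_variants()] object.
#' @export
read_snvs <- function(vcf_path, library_id = NULL,
                      caste = NA_character_, population = NA_character_) {
  if (!is.character(vcf_path) || length(vcf_path) != 1 || !file.exists(vcf_path)) {
    stop_data("VCF file not found: ", vcf_path)
  }
  if (is.null(library_id)) {
    library_id <- sub("\\.vcf(\\.gz)?$", "", basename(vcf_path))
  }

  lines <- readLines(vcf_path, warn = FALSE)
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8 || is.na(suppressWarnings(as.integer(f[2])))) {
      stop_data("malformed VCF row at line ", i, " of ", basename(vcf_path))
    }
  }
  if (length(body) == 0) {
    return(library_variants(library_id, empty_records(), caste, population))
  }

  vcf <- suppressWarnings(vcfR::read.vcfR(vcf_path, verbose = FALSE))
  fix <- vcf@fix

  dp <- rep(NA_integer_, nrow(fix))
  if (ncol(vcf@gt) >= 2) {
    fmt_dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    if (!is.null(fmt_dp)) dp <- as.integer(fmt_dp[, 1])
  }
  info_dp <- suppressWarnings(as.integer(vcfR::extract.info(vcf, element = "DP")))
  dp[is.na(dp)] <- info_dp[is.na(dp)]
  dp[is.na(dp)] <- 0L

  alts <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  row_idx <- rep(seq_len(nrow(fix)), n_alt)
  rec <- data.frame(
    transcript_id = fix[row_idx, "CHROM"],
    pos = as.integer(fix[row_idx, "POS"]),
    ref = toupper(fix[row_idx, "REF"]),
    alt = toupper(unlist(alts, use.names = FALSE)),
    depth = dp[row_idx],
    stringsAsFactors = FALSE
  )
  keep <- rec$ref %in% BASES & rec$alt %in% BASES & rec$ref != rec$alt
  rec <- rec[keep, , drop = FALSE]
  rownames(rec) <- NULL
  library_variants(library_id, rec, caste, population)
}

#' Filter a library's SNVs by read depth
#'
#' Retains records whose depth exceeds the threshold — strictly greater by
#' default, matching the high-quality "depth > 10" convention.  Set
#' `strict = FALSE` to retain `depth >= min_depth` instead.  Record order is
#' preserved and the operation is idempotent.
#'
#' @param lib A [library_variants()] object.
#' @param min_depth Non-negative integer threshold (default 10).
#' @param strict Logical; retain `depth > min_depth` (default) or
#'   `depth >= min_depth`.
#' @return A filtered [library_variants()] object.
#' @export
filter_by_depth <- function(lib, min_depth = 10L, strict = TRUE) {
  stopifnot(inherits(lib, "library_variants"))
  if (!is.numeric(min_depth) || length(min_depth) != 1 || min_depth < 0) {
    stop_config("min_depth must be a non-negative number")
  }
  keep <- if (strict) lib$records$depth > min_depth else lib$records$depth >= min_depth
  lib$records <- lib$records[keep, , drop = FALSE]
  rownames(lib$records) <- NULL
  lib
}

#' Count a library's SNVs
#'
#' @param lib A [library_variants()] object.
#' @return The number of SNV records.
#' @export
count_snvs <- function(lib) {
  stopifnot(inherits(lib, "library_variants"))
  nrow(lib$records)
}

#' Transition/transversion ratio of a library
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine changes
#' (`A<->G`, `C<->T`); every other ref->alt pair is a transversion.  Returns
#' `NA` (the explicit undefined marker) when there are no transversions.
#'
#' @param lib A [library_variants()] object, or a records data frame with
#'   `ref` and `alt` columns.
#' @return `transitions / transversions`, or `NA_real_` when undefined.
#' @export
titv_ratio <- function(lib) {
  rec <- if (inherits(lib, "library_variants")) lib$records else lib
  if (nrow(rec) == 0) return(NA_real_)
  ts <- sum(is_transition(rec$ref, rec$alt))
  tv <- nrow(rec) - ts
  if (tv == 0) return(NA_real_)
  ts / tv
}
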