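# Nei-Gojobori (NG86) dN/dS with Jukes-Cantor correction.

#' Jukes--Cantor correction of a substitution proportion
#'
#' Converts an observed proportion of substituted sites into an estimated
#' number of substitutions per site under the one-parameter substitution
#' model: `d = -(3/4) * log(1 - 4p/3)`.  The correction is strictly
#' increasing, satisfies `d >= p`, and saturates at `p = 3/4` where it is
#' undefined.
#'
#' @param p Proportion(s) in `[0, 3/4)`.
#' @return Corrected distance(s), non-negative.
#' @examples
#' jc_distance(0)     # 0
#' jc_distance(0.1)   # 0.10733
#' @export
jc_distance <- function(p) {
  if (!is.numeric(p)) stop_data("p must be numeric")
  if (any(is.na(p))) stop_data("p must not contain NA")
  if (any(p < 0)) stop_data("p must be non-negative")
  if (any(p >= 0.75)) {
    stop_data("Jukes-Cantor correction saturates at p >= 3/4 (got ",
              format(max(p)), ")")
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei--Gojobori synonymous and nonsynonymous site counts of an ORF
#'
#' For every codon of the coding sequence (a terminal stop codon, if present,
#' is excluded) and every codon position, each of the three possible
#' single-base changes is classified against the standard genetic code.  A
#' position contributes `#synonymous/3` synonymous and `#nonsynonymous/3`
#' nonsynonymous sites; changes that create a stop codon contribute to
#' neither class, so a codon's sites may sum to less than 3.
#'
#' @param orf_sequence Coding sequence (character scalar, length divisible by
#'   3, no internal stop codons; `U` normalised to `T`).
#' @return A list with numeric elements `syn_sites` and `nonsyn_sites`.
#' @examples
#' ng86_site_counts("TTT")  # syn 1/3, nonsyn 8/3
#' @export
ng86_site_counts <- function(orf_sequence) {
  if (!is.character(orf_sequence) || length(orf_sequence) != 1) {
    stop_data("orf_sequence must be a single character string")
  }
  seq <- toupper(chartr("Uu", "Tt", orf_sequence))
  if (grepl("[^ACGT]", seq)) stop_data("orf_sequence contains non-ACGTU characters")
  n <- nchar(seq)
  if (n %% 3 != 0) stop_data("orf_sequence length must be divisible by 3")
  if (n == 0) return(list(syn_sites = 0, nonsyn_sites = 0))
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  if (codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  if (any(codons %in% STOP_CODONS)) stop_data("internal stop codon in orf_sequence")
  if (length(codons) == 0) return(list(syn_sites = 0, nonsyn_sites = 0))
  sites <- NG86_CODON_SITES[codons, , drop = FALSE]
  list(syn_sites = sum(sites[, "syn"]), nonsyn_sites = sum(sites[, "nonsyn"]))
}

# Vectorised classification of substitutions against the longest ORF.
# tx/pos/ref/alt are parallel vectors; seqs a named reference; orfs the
# orf_table() of the same reference.  Returns a character vector in
# {synonymous, nonsynonymous, stopgain, noncoding} or "mismatch" where the
# stated ref disagrees with the reference base.
classify_changes <- function(tx, pos, ref, alt, seqs, orfs) {
  m <- match(tx, orfs$transcript_id)
  if (anyNA(m) || any(!(tx %in% names(seqs)))) {
    stop_data("records reference transcripts absent from the reference")
  }
  tx_seq <- seqs[tx]
  if (any(pos < 1L | pos > nchar(tx_seq))) {
    stop_data("record position outside transcript bounds")
  }
  out <- rep("noncoding", length(tx))
  true_ref <- substr(tx_seq, pos, pos)
  out[true_ref != ref] <- "mismatch"

  start <- orfs$start[m]
  end <- orfs$end[m]
  # coding = inside the ORF but not in the terminal stop codon
  coding <- out == "noncoding" & !is.na(start) & pos >= start & pos <= (end - 3L)
  if (any(coding)) {
    cpos <- ((pos[coding] - start[coding]) %% 3L) + 1L
    cstart <- pos[coding] - cpos + 1L
    codon <- substr(tx_seq[coding], cstart, cstart + 2L)
    out[coding] <- CHANGE_CLASS[cbind(match(codon, CODONS), cpos,
                                      match(alt[coding], BASES))]
  }
  out
}

#' Classify one SNV against a transcript's longest ORF
#'
#' A variant is `noncoding` when it falls outside the ORF (or inside the
#' terminal stop codon, which is excluded from site counting), `stopgain`
#' when the mutated codon is a stop, and otherwise `synonymous` or
#' `nonsynonymous` by comparing the translations of the reference and mutant
#' codons.
#'
#' @param orf An ORF as returned by [find_longest_orf()] (list with `start`,
#'   `end`), or `NULL` for a transcript without one.
#' @param snv A single SNV: list or one-row data frame with `transcript_id`,
#'   `pos`, `ref`, `alt`.
#' @param reference Named character vector, `DNAStringSet`, or FASTA path.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"stopgain"`,
#'   `"noncoding"`.
#' @export
classify_snv <- function(orf, snv, reference) {
  seqs <- as_reference(reference)
  orfs <- data.frame(
    transcript_id = snv$transcript_id,
    start = if (is.null(orf)) NA_integer_ else orf$start,
    end = if (is.null(orf)) NA_integer_ else orf$end,
    stringsAsFactors = FALSE
  )
  cls <- classify_changes(snv$transcript_id, as.integer(snv$pos),
                          snv$ref, snv$alt, seqs, orfs)
  if (cls == "mismatch") {
    stop_data("SNV ref base disagrees with the reference sequence at ",
              snv$transcript_id, ":", snv$pos)
  }
  cls
}

#' Estimate dN/dS for a library by the Nei--Gojobori method
#'
#' Each transcript's coding template is its longest ORF.  In the default
#' pooled mode, synonymous/nonsynonymous substitution counts and NG86 site
#' counts are summed over all in-scope transcripts that have an ORF;
#' `p_s = syn_subs / syn_sites` and `p_n = nonsyn_subs / nonsyn_sites` are
#' Jukes--Cantor corrected to `d_s`, `d_n`, and the ratio is `d_n / d_s`
#' (`NA`, the undefined marker, when `d_s = 0`).  Stop-gain variants,
#' noncoding variants, variants on ORF-less transcripts and reference
#' mismatches are excluded from the proportions and reported in the `counts`
#' tally.  Per-transcript mode returns one estimate per transcript instead.
#'
#' @param lib A [library_variants()] object.
#' @param reference Named character vector, `DNAStringSet`, or FASTA path.
#' @param subset Optional character vector of transcript IDs restricting the
#'   analysis (e.g. a caste-associated gene list).
#' @param mode `"pooled"` (one estimate, default) or `"per-transcript"`.
#' @param orfs Optional precomputed [orf_table()] for the same reference.
#' @return In pooled mode an object of class `dnds_estimate` with fields
#'   `p_s`, `p_n`, `d_s`, `d_n`, `ratio`, `sites`, `counts`; in
#'   per-transcript mode a data frame with one row per in-scope transcript.
#' @export
estimate_dnds <- function(lib, reference, subset = NULL,
                          mode = c("pooled", "per-transcript"), orfs = NULL) {
  stopifnot(inherits(lib, "library_variants"))
  mode <- match.arg(mode)
  seqs <- as_reference(reference)
  if (is.null(orfs)) orfs <- orf_table(seqs)

  scope_ids <- names(seqs)
  if (!is.null(subset)) {
    missing <- setdiff(subset, names(seqs))
    if (length(missing)) {
      stop_data("subset transcripts absent from the reference: ",
                paste(utils::head(missing, 3), collapse = ", "))
    }
    scope_ids <- intersect(names(seqs), subset)
  }

  orfs_scope <- orfs[orfs$transcript_id %in% scope_ids, , drop = FALSE]
  has_orf <- !is.na(orfs_scope$start)

  # NG86 site totals over all in-scope transcripts that have an ORF
  site_tot <- c(syn = 0, nonsyn = 0)
  per_tx_sites <- NULL
  if (any(has_orf)) {
    per_tx_sites <- t(mapply(function(id, s, e) {
      sc <- ng86_site_counts(substr(seqs[[id]], s, e))
      c(sc$syn_sites, sc$nonsyn_sites)
    }, orfs_scope$transcript_id[has_orf], orfs_scope$start[has_orf],
      orfs_scope$end[has_orf]))
    colnames(per_tx_sites) <- c("syn", "nonsyn")
    site_tot <- c(syn = sum(per_tx_sites[, "syn"]),
                  nonsyn = sum(per_tx_sites[, "nonsyn"]))
  }

  rec <- lib$records[lib$records$transcript_id %in% scope_ids, , drop = FALSE]
  cls <- if (nrow(rec)) {
    classify_changes(rec$transcript_id, rec$pos, rec$ref, rec$alt, seqs, orfs)
  } else character(0)
  n_mismatch <- sum(cls == "mismatch")
  if (n_mismatch) {
    warning(n_mismatch, " record(s) disagree with the reference base; excluded",
            call. = FALSE)
  }

  if (mode == "per-transcript") {
    ids <- orfs_scope$transcript_id[has_orf]
    out <- data.frame(
      transcript_id = ids,
      syn_sites = per_tx_sites[, "syn"], nonsyn_sites = per_tx_sites[, "nonsyn"],
      syn_subs = 0L, nonsyn_subs = 0L, stopgain_subs = 0L, noncoding_subs = 0L,
      row.names = NULL, stringsAsFactors = FALSE
    )
    if (nrow(rec)) {
      tally <- table(factor(rec$transcript_id, levels = ids),
                     factor(cls, levels = c("synonymous", "nonsynonymous",
                                            "stopgain", "noncoding")))
      out$syn_subs <- as.integer(tally[, "synonymous"])
      out$nonsyn_subs <- as.integer(tally[, "nonsynonymous"])
      out$stopgain_subs <- as.integer(tally[, "stopgain"])
      out$noncoding_subs <- as.integer(tally[, "noncoding"])
    }
    out$p_s <- ifelse(out$syn_sites > 0, out$syn_subs / out$syn_sites, NA_real_)
    out$p_n <- ifelse(out$nonsyn_sites > 0, out$nonsyn_subs / out$nonsyn_sites, NA_real_)
    ok_s <- !is.na(out$p_s) & out$p_s < 0.75
    ok_n <- !is.na(out$p_n) & out$p_n < 0.75
    out$d_s <- ifelse(ok_s, -0.75 * log(1 - 4 * out$p_s / 3), NA_real_)
    out$d_n <- ifelse(ok_n, -0.75 * log(1 - 4 * out$p_n / 3), NA_real_)
    out$dnds <- ifelse(!is.na(out$d_s) & out$d_s > 0 & !is.na(out$d_n),
                       out$d_n / out$d_s, NA_real_)
    return(out)
  }

  if (site_tot[["syn"]] == 0) {
    stop_data("degenerate input: no synonymous sites in scope (",
              sum(has_orf), " transcripts with an ORF)")
  }
  counts <- c(
    syn = sum(cls == "synonymous"),
    nonsyn = sum(cls == "nonsynonymous"),
    stopgain = sum(cls == "stopgain"),
    noncoding = sum(cls == "noncoding"),
    mismatch = n_mismatch
  )
  p_s <- counts[["syn"]] / site_tot[["syn"]]
  p_n <- counts[["nonsyn"]] / site_tot[["nonsyn"]]
  d_s <- jc_distance(p_s)
  d_n <- jc_distance(p_n)
  structure(
    list(
      library_id = lib$library_id,
      scope = if (is.null(subset)) "whole" else "subset",
      n_transcripts = length(scope_ids),
      n_orf_transcripts = sum(has_orf),
      p_s = p_s, p_n = p_n, d_s = d_s, d_n = d_n,
      ratio = if (d_s > 0) d_n / d_s else NA_real_,
      sites = site_tot, counts = counts
    ),
    class = "dnds_estimate"
  )
}

#' @export
print.dnds_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("<dnds_estimate> %s (%s scope, %d/%d transcripts with ORF)\n",
              x$library_id, x$scope, x$n_orf_transcripts, x$n_transcripts))
  cat(sprintf("  p_S = %.*g  p_N = %.*g  d_S = %.*g  d_N = %.*g\n",
              digits, x$p_s, digits, x$p_n, digits, x$d_s, digits, x$d_n))
  cat(sprintf("  dN/dS = %s\n",
              if (is.na(x$ratio)) "undefined (d_S = 0)"
              else formatC(x$ratio, digits = digits, format = "g")))
  cat(sprintf("  substitutions: %d syn, %d nonsyn (+%d stop-gain, %d noncoding excluded)\n",
              x$counts[["syn"]], x$counts[["nonsyn"]],
              x$counts[["stopgain"]], x$counts[["noncoding"]]))
  invisible(x)
}

#' Pool dN/dS counts across several libraries
#'
#' Sums substitution counts over libraries while counting each library's
#' NG86 site totals once per library (so the proportion is the
#' variant-weighted mean of per-library proportions and sites are not
#' double-counted across libraries sharing a reference).
#'
#' @param libs List of [library_variants()] objects.
#' @inheritParams estimate_dnds
#' @return A `dnds_estimate` object; `library_id` concatenates the inputs.
#' @export
pooled_dnds <- function(libs, reference, subset = NULL, orfs = NULL) {
  stopifnot(length(libs) > 0,
            all(vapply(libs, inherits, logical(1), "library_variants")))
  seqs <- as_reference(reference)
  if (is.null(orfs)) orfs <- orf_table(seqs)
  ests <- lapply(libs, estimate_dnds, reference = seqs, subset = subset,
                 orfs = orfs)
  counts <- Reduce(`+`, lapply(ests, `[[`, "counts"))
  sites <- Reduce(`+`, lapply(ests, `[[`, "sites"))
  p_s <- counts[["syn"]] / sites[["syn"]]
  p_n <- counts[["nonsyn"]] / sites[["nonsyn"]]
  d_s <- jc_distance(p_s)
  d_n <- jc_distance(p_n)
  structure(
    list(
      library_id = paste(vapply(libs, `[[`, character(1), "library_id"),
                         collapse = "+"),
      scope = ests[[1]]$scope,
      n_transcripts = ests[[1]]$n_transcripts,
      n_orf_transcripts = ests[[1]]$n_orf_transcripts,
      p_s = p_s, p_n = p_n, d_s = d_s, d_n = d_n,
      ratio = if (d_s > 0) d_n / d_s else NA_real_,
      sites = sites, counts = counts
    ),
    class = "dnds_estimate"
  )
}
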