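# SBS-6 and SBS-96 pyrimidine-referenced mutational catalogues.

#' Class alphabets for SBS catalogues
#'
#' `sbs6_classes()` returns the six pyrimidine-referenced substitution types;
#' `sbs96_classes()` returns the 96 trinucleotide classes in the conventional
#' order: types ordered `C>A, C>G, C>T, T>A, T>C, T>G`, contexts ordered
#' lexicographically (5' base, then 3' base) within each type.
#'
#' @return Character vector of class labels.
#' @export
sbs6_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' @rdname sbs6_classes
#' @export
sbs96_classes <- function() {
  unlist(lapply(sbs6_classes(), function(type) {
    as.vector(t(outer(BASES, BASES, function(f, t3)
      paste0(f, "[", type, "]", t3))))
  }), use.names = FALSE)
}

#' Canonical SBS-96 class of a single-base substitution
#'
#' Expresses a substitution and its immediate 5'/3' context in the
#' pyrimidine-referenced convention: when the reference base is a purine the
#' whole trinucleotide is reverse-complemented (bases complemented, flanks
#' swapped) so the reported reference base is always `C` or `T`.  With
#' `lead = "purine"` the complementary convention is used instead.
#'
#' @param ref,alt Reference and alternate base (vectors over `A,C,G,T`,
#'   `ref != alt`).
#' @param five_prime,three_prime Flanking bases on the transcript strand.
#' @param lead Which base family the reported reference is normalised to.
#' @return Character vector of class strings such as `"A[C>T]G"`.
#' @examples
#' canonical_sbs_class("C", "T", "A", "A")  # "A[C>T]A"
#' canonical_sbs_class("G", "A", "T", "C")  # "G[C>T]A"
#' @export
canonical_sbs_class <- function(ref, alt, five_prime, three_prime,
                                lead = c("pyrimidine", "purine")) {
  lead <- match.arg(lead)
  bad <- !(ref %in% BASES) | !(alt %in% BASES) |
    !(five_prime %in% BASES) | !(three_prime %in% BASES)
  if (any(bad)) stop_data("all bases must be one of A, C, G, T")
  if (any(ref == alt)) stop_data("alt must differ from ref")
  n <- max(length(ref), length(alt), length(five_prime), length(three_prime))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  five_prime <- rep_len(five_prime, n); three_prime <- rep_len(three_prime, n)

  flip <- if (lead == "pyrimidine") ref %in% c("A", "G") else ref %in% c("C", "T")
  r <- ifelse(flip, COMPLEMENT[ref], ref)
  a <- ifelse(flip, COMPLEMENT[alt], alt)
  f5 <- ifelse(flip, COMPLEMENT[three_prime], five_prime)
  f3 <- ifelse(flip, COMPLEMENT[five_prime], three_prime)
  paste0(f5, "[", r, ">", a, "]", f3)
}

# pyrimidine-referenced substitution type from the base pair alone
sbs6_type <- function(ref, alt) {
  flip <- ref %in% c("A", "G")
  paste0(ifelse(flip, COMPLEMENT[ref], ref), ">",
         ifelse(flip, COMPLEMENT[alt], alt))
}

new_sbs_catalogue <- function(counts, scheme, library_id, excluded) {
  structure(
    list(library_id = library_id, scheme = scheme, counts = counts,
         excluded = excluded),
    class = "sbs_catalogue"
  )
}

#' @export
print.sbs_catalogue <- function(x, ...) {
  cat(sprintf("<sbs_catalogue> %s, %s: %d classified SNVs", x$scheme,
              if (is.null(x$library_id) || is.na(x$library_id)) "?" else x$library_id,
              sum(x$counts)))
  if (sum(x$excluded) > 0) {
    cat(sprintf(" (%d edge-excluded, %d ref-mismatch)",
                x$excluded[["edge"]], x$excluded[["mismatch"]]))
  }
  cat("\n")
  invisible(x)
}

#' Build the SBS-6 catalogue of a library
#'
#' Tallies every SNV into one of the six pyrimidine-referenced substitution
#' types; purine-reference records are complemented.  All six classes are
#' always present (zero-filled) and the counts sum to the number of records.
#'
#' @param lib A [library_variants()] object.
#' @return An `sbs_catalogue` object with a 6-element `counts` vector.
#' @export
build_sbs6 <- function(lib) {
  stopifnot(inherits(lib, "library_variants"))
  counts <- setNames(integer(6), sbs6_classes())
  rec <- lib$records
  if (nrow(rec)) {
    tab <- table(factor(sbs6_type(rec$ref, rec$alt), levels = sbs6_classes()))
    counts[] <- as.integer(tab)
  }
  new_sbs_catalogue(counts, "SBS6", lib$library_id,
                    c(edge = 0L, mismatch = 0L))
}

#' Build the SBS-96 trinucleotide catalogue of a library
#'
#' Reads the 5' and 3' flanking bases from the reference transcript (sense
#' strand) at `pos - 1` and `pos + 1` and classifies each SNV with
#' [canonical_sbs_class()].  Records at position 1 or at the transcript end
#' lack a flank and are excluded from the catalogue; records whose VCF
#' reference base disagrees with the FASTA are excluded and flagged, never
#' silently recoded.  Both exclusion tallies are reported so that
#' `sum(counts) + edge + mismatch` equals the record count.
#'
#' @param lib A [library_variants()] object.
#' @param reference Named character vector, `DNAStringSet`, or FASTA path.
#' @param lead Reported reference-base family, see [canonical_sbs_class()].
#' @return An `sbs_catalogue` object with a 96-element `counts` vector and
#'   an `excluded` tally (`edge`, `mismatch`).
#' @export
build_sbs96 <- function(lib, reference, lead = c("pyrimidine", "purine")) {
  stopifnot(inherits(lib, "library_variants"))
  lead <- match.arg(lead)
  seqs <- as_reference(reference)
  classes <- sbs96_classes()
  if (lead == "purine") {
    classes <- canonical_sbs_class(
      substr(classes, 3, 3), substr(classes, 5, 5),
      substr(classes, 1, 1), substr(classes, 7, 7), lead = "purine")
  }
  counts <- setNames(integer(96), classes)
  rec <- lib$records
  excluded <- c(edge = 0L, mismatch = 0L)
  if (nrow(rec)) {
    unknown <- !(rec$transcript_id %in% names(seqs))
    if (any(unknown)) {
      stop_data("records reference unknown transcripts: ",
                paste(unique(rec$transcript_id[unknown])[1:min(3, sum(unknown))],
                      collapse = ", "))
    }
    tx_seq <- seqs[rec$transcript_id]
    tx_len <- nchar(tx_seq)
    if (any(rec$pos > tx_len)) stop_data("record position beyond transcript end")
    fasta_ref <- substr(tx_seq, rec$pos, rec$pos)
    mismatch <- fasta_ref != rec$ref
    edge <- !mismatch & (rec$pos == 1L | rec$pos == tx_len)
    excluded <- c(edge = sum(edge), mismatch = sum(mismatch))
    if (any(mismatch)) {
      warning(sum(mismatch), " record(s) disagree with the reference base; excluded",
              call. = FALSE)
    }
    ok <- !mismatch & !edge
    if (any(ok)) {
      cls <- canonical_sbs_class(
        rec$ref[ok], rec$alt[ok],
        substr(tx_seq[ok], rec$pos[ok] - 1L, rec$pos[ok] - 1L),
        substr(tx_seq[ok], rec$pos[ok] + 1L, rec$pos[ok] + 1L),
        lead = lead
      )
      tab <- table(factor(cls, levels = classes))
      counts[] <- as.integer(tab)
    }
  }
  new_sbs_catalogue(counts, "SBS96", lib$library_id, excluded)
}

#' Combine per-library SBS-96 catalogues into a class-by-library matrix
#'
#' @param catalogues List of `sbs_catalogue` objects of the same scheme.
#' @return An integer matrix, one row per class (conventional order), one
#'   column per library.
#' @export
sbs_matrix <- function(catalogues) {
  stopifnot(length(catalogues) > 0,
            all(vapply(catalogues, inherits, logical(1), "sbs_catalogue")))
  schemes <- unique(vapply(catalogues, `[[`, character(1), "scheme"))
  if (length(schemes) != 1) stop_data("catalogues mix SBS schemes")
  m <- vapply(catalogues, `[[`, numeric(length(catalogues[[1]]$counts)), "counts")
  colnames(m) <- unname(vapply(catalogues, `[[`, character(1), "library_id"))
  m
}
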