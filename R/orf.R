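#' Find the longest open reading frame of a transcript
#'
#' Scans the forward strand in all three frames for spans running from an
#' `ATG` to the first in-frame stop codon (`TAA`, `TAG`, `TGA`), and returns
#' the longest such span, measured from the A of the start codon through the
#' last base of the stop codon.  Ties are broken in favour of the smallest
#' start position.  Input `U` is normalised to `T`.
#'
#' @param sequence A single transcript sequence (character scalar over
#'   `A,C,G,T,U`, case-insensitive).
#' @return A list with elements `start`, `end` (1-based inclusive transcript
#'   coordinates) and `length`, or `NULL` when the transcript contains no
#'   start/stop-bounded frame.
#' @examples
#' find_longest_orf("ATGAAATAA")
#' find_longest_orf("AAACCCGGG")  # NULL: no ATG
#' @export
find_longest_orf <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence)) {
    stop_data("sequence must be a single character string")
  }
  seq <- chartr("Uu", "Tt", sequence)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop_data("sequence contains non-ACGTU characters")

  starts <- match_all(seq, "ATG")
  if (length(starts) == 0) return(NULL)
  stops <- sort(unlist(lapply(STOP_CODONS, match_all, x = seq), use.names = FALSE))

  best <- NULL
  for (f in 0:2) {
    s_f <- starts[(starts - 1L) %% 3L == f]
    t_f <- stops[(stops - 1L) %% 3L == f]
    if (length(s_f) == 0 || length(t_f) == 0) next
    # first in-frame stop strictly downstream of each start
    idx <- findInterval(s_f, t_f) + 1L
    ok <- idx <= length(t_f)
    if (!any(ok)) next
    s_ok <- s_f[ok]
    ends <- t_f[idx[ok]] + 2L
    lens <- ends - s_ok + 1L
    j <- which(lens == max(lens))
    j <- j[which.min(s_ok[j])]
    cand <- list(start = s_ok[j], end = ends[j], length = lens[j])
    if (is.null(best) || cand$length > best$length ||
        (cand$length == best$length && cand$start < best$start)) {
      best <- cand
    }
  }
  best
}

# all match positions of a fixed pattern (patterns used here cannot
# self-overlap, so gregexpr is sufficient)
match_all <- function(x, pattern) {
  m <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Longest-ORF table for a reference transcriptome
#'
#' Applies [find_longest_orf()] to every transcript of a reference and
#' returns one row per transcript; transcripts without an ORF get `NA`
#' coordinates.
#'
#' @param reference Named character vector of transcript sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @return A data frame with columns `transcript_id`, `start`, `end`.
#' @export
orf_table <- function(reference) {
  seqs <- as_reference(reference)
  orfs <- lapply(seqs, find_longest_orf)
  data.frame(
    transcript_id = names(seqs),
    start = vapply(orfs, function(o) if (is.null(o)) NA_integer_ else o$start, integer(1)),
    end = vapply(orfs, function(o) if (is.null(o)) NA_integer_ else o$end, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
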