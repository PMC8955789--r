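# Internal helpers: classed error conditions, seeding, sequence coercion.

stop_config <- function(...) {
  stop(structure(
    class = c("castevar_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_data <- function(...) {
  stop(structure(
    class = c("castevar_data_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Stable 31-bit string hash (independent of R internals) so each library gets
# its own reproducible RNG substream; adding a library never perturbs others.
hash_string <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

substream_seed <- function(master_seed, id) {
  as.integer((as.numeric(master_seed) + hash_string(id)) %% 2147483647)
}

# Coerce a reference transcriptome to a named uppercase character vector
# (U normalised to T).  Accepts a named character vector, a DNAStringSet,
# or a path to a FASTA file.  FASTA IDs are trimmed at the first whitespace.
as_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    seqs <- as.character(reference)
  } else if (is.character(reference) && length(reference) == 1 &&
             is.null(names(reference)) && file.exists(reference)) {
    seqs <- as.character(Biostrings::readDNAStringSet(reference))
  } else if (is.character(reference)) {
    seqs <- reference
  } else {
    stop_data("reference must be a named character vector, DNAStringSet or FASTA path")
  }
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop_data("reference transcripts must be named")
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- chartr("u", "t", seqs)
  seqs <- chartr("U", "T", toupper(seqs))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop_data("reference contains non-ACGTU characters in: ",
              paste(utils::head(names(seqs)[bad], 3), collapse = ", "))
  }
  seqs
}

#' @importFrom methods is
NULL
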