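#' Assembly contiguity statistics (span, N50, L50)
#'
#' N50 is the length of the sequence at which the cumulative sum of lengths,
#' taken in descending order, first reaches at least half the assembly span;
#' L50 is the number of sequences needed to reach it. The `>= span/2`
#' convention is used at the threshold.
#'
#' @param lengths Positive integer vector of sequence lengths (from a FASTA
#'   via [fasta_lengths()] or from [simulate_contigs()]).
#' @return One-row tibble: `span`, `n50`, `l50`, `n_sequences`.
#' @export
#' @examples
#' contiguity_stats(c(10, 5, 3, 2))   # N50 10, L50 1
#' contiguity_stats(c(5, 4, 3, 2, 1)) # N50 4, L50 2
contiguity_stats <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list", call. = FALSE)
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("sequence lengths must be positive", call. = FALSE)
  }
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  span <- sum(s)
  l50 <- which(cumsum(s) >= span / 2)[1]
  tibble(span = span, n50 = s[l50], l50 = l50, n_sequences = length(s))
}

#' Sequence lengths of a FASTA file
#'
#' Lengths exclude line breaks; lowercase and N bases are counted.
#'
#' @param path Path to a FASTA file.
#' @return Named integer vector of sequence lengths.
#' @export
fasta_lengths <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(Biostrings::width(seqs), names(seqs))
}

#' Base-matched downsampling fraction between two data sets
#'
#' When comparing assemblies from two sequencing runs of unequal yield, the
#' larger set is downsampled so both use the same number of bases. The
#' fraction to keep is `100 * min / max`, rounded to one decimal.
#'
#' @param bases_a,bases_b Total bases in each set (both positive).
#' @return List with `keep_percent` and `downsample` (`"a"` or `"b"`, the
#'   larger set).
#' @export
#' @examples
#' keep_fraction(878, 1000)  # keep 87.8% of set b
keep_fraction <- function(bases_a, bases_b) {
  stopifnot(length(bases_a) == 1L, length(bases_b) == 1L)
  if (is.na(bases_a) || is.na(bases_b) || bases_a <= 0 || bases_b <= 0) {
    stop("base counts must be positive", call. = FALSE)
  }
  list(keep_percent = round(100 * min(bases_a, bases_b) / max(bases_a, bases_b), 1),
       downsample = if (bases_a >= bases_b) "a" else "b")
}
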