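#' Split a sequence into maximal homopolymer runs
#'
#' A homopolymer run is a maximal stretch of identical consecutive
#' nucleotides; e.g. `ATTTAACC` splits into `A`, `TTT`, `AA`, `CC`. The
#' returned runs are sorted, non-overlapping, and tile the sequence exactly
#' (their lengths sum to the sequence length), so joining them reproduces
#' the input.
#'
#' @param seq Character scalar nucleotide sequence (validated with
#'   [validate_sequence()]).
#' @param id Identifier used in error messages.
#' @return A data frame with one row per run and columns `base`, `start`,
#'   `end` (1-based, inclusive) and `length`.
#' @examples
#' split_runs("ATTTAACC")
#' @export
split_runs <- function(seq, id = "sequence") {
  chars <- validate_sequence(seq, id = id)
  r <- rle(chars)
  len <- r$lengths
  end <- cumsum(len)
  data.frame(base = r$values,
             start = end - len + 1L,
             end = end,
             length = len,
             stringsAsFactors = FALSE)
}

#' Build a run-length spectrum
#'
#' Counts maximal homopolymer runs by length, independently of nucleotide
#' content. Lengths are top-coded: every run of length `>= lmax` is counted
#' in the `lmax` bin. Raw (un-top-coded) lengths are retained so that mass
#' conservation (sum of length x count = total sequence length) can be
#' checked.
#'
#' @param runs A run data frame from [split_runs()] (possibly row-bound
#'   across sequences), or an integer vector of run lengths.
#' @param lmax Top-code bin; runs of this length or longer are pooled
#'   (default 10).
#' @return An object of class `run_spectrum`: a list with `counts` (named by
#'   bin `1..lmax`), `proportions`, `total_runs`, `lmax`, `raw_lengths`
#'   (table of un-top-coded lengths) and `total_bases`. An empty run list
#'   yields `total_runs = 0` with `NA` proportions and `empty = TRUE`, not
#'   an error.
#' @export
run_spectrum <- function(runs, lmax = 10L) {
  lmax <- as.integer(lmax)
  stopifnot(lmax >= 1L)
  lens <- if (is.data.frame(runs)) as.integer(runs$length) else as.integer(runs)
  stopifnot(!anyNA(lens), all(lens >= 1L) || length(lens) == 0L)
  counts <- tabulate(pmin(lens, lmax), nbins = lmax)
  names(counts) <- as.character(seq_len(lmax))
  total <- length(lens)
  props <- if (total > 0L) counts / total else rep(NA_real_, lmax)
  names(props) <- names(counts)
  structure(list(counts = counts,
                 proportions = props,
                 total_runs = total,
                 lmax = lmax,
                 raw_lengths = table(lens),
                 total_bases = sum(lens),
                 empty = total == 0L),
            class = "run_spectrum")
}

#' @export
print.run_spectrum <- function(x, ...) {
  cat(sprintf("Run-length spectrum: %d runs over %d bases (lmax = %d%s)\n",
              x$total_runs, x$total_bases, x$lmax,
              if (isTRUE(x$empty)) ", EMPTY" else ""))
  print(data.frame(length_bin = names(x$counts),
                   count = as.integer(x$counts),
                   proportion = round(unname(x$proportions), 5)),
        row.names = FALSE)
  invisible(x)
}

#' Pooled run-length spectrum of a sequence panel
#'
#' Equivalent to concatenating the run lists of all sequences and calling
#' [run_spectrum()]; runs never span a sequence boundary.
#'
#' @param seqs Character vector of sequences, or a panel data frame with a
#'   `seq` column.
#' @param lmax Top-code bin passed to [run_spectrum()].
#' @return A `run_spectrum` object.
#' @export
pooled_spectrum <- function(seqs, lmax = 10L) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  stopifnot(length(seqs) >= 1L)
  lens <- unlist(lapply(seq_along(seqs), function(i) {
    split_runs(seqs[[i]], id = paste0("seq", i))$length
  }), use.names = FALSE)
  run_spectrum(lens, lmax = lmax)
}

#' Per-position homopolymer barcode track
#'
#' For every position of a gene, the length of the maximal run covering it,
#' or 0 when that run is shorter than `min_len`. This is the track behind a
#' white-to-black "barcode" rendering of homopolymer positions along a gene,
#' where only runs of `min_len` (default 3) or more repeats are shown and
#' display shading saturates at `max_len` (default 8).
#'
#' @param seq Nucleotide sequence.
#' @param min_len Minimum run length to report (shorter runs map to 0).
#' @param max_len Display saturation, stored as an attribute; values are not
#'   truncated.
#' @param gene_id Identifier stored as an attribute.
#' @return Integer vector, one value per position, with attributes
#'   `gene_id`, `min_len`, `max_len`.
#' @export
barcode_track <- function(seq, min_len = 3L, max_len = 8L, gene_id = "gene") {
  runs <- split_runs(seq, id = gene_id)
  vals <- ifelse(runs$length >= min_len, runs$length, 0L)
  track <- rep(as.integer(vals), runs$length)
  structure(track, gene_id = gene_id, min_len = as.integer(min_len),
            max_len = as.integer(max_len))
}

#' Export a spectrum as a tidy data frame
#'
#' @param spec A `run_spectrum`.
#' @param group Optional group label column.
#' @return Data frame with columns `group`, `length_bin`, `count`,
#'   `proportion`.
#' @export
spectrum_table <- function(spec, group = NA_character_) {
  stopifnot(inherits(spec, "run_spectrum"))
  data.frame(group = group,
             length_bin = seq_len(spec$lmax),
             count = as.integer(spec$counts),
             proportion = unname(spec$proportions),
             stringsAsFactors = FALSE)
}
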