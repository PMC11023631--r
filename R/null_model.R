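#' Shuffle the nucleotides of a sequence
#'
#' Draws a uniformly random permutation of the residues (Fisher-Yates via
#' [sample()]), preserving the base composition exactly. The caller controls
#' reproducibility through R's RNG state (`set.seed()`); higher-level
#' functions derive one deterministic stream per sequence with
#' [seed_for_sequence()].
#'
#' @param seq Nucleotide sequence.
#' @return The shuffled sequence as a character scalar.
#' @export
shuffle_sequence <- function(seq) {
  chars <- validate_sequence(seq)
  paste(chars[sample.int(length(chars))], collapse = "")
}

#' Derive a per-sequence RNG seed from a root seed and a sequence id
#'
#' Deterministic 31-bit stream derivation so that per-sequence null spectra
#' do not depend on the order in which a panel is processed.
#'
#' @param seed Integer root seed.
#' @param id Sequence identifier.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
seed_for_sequence <- function(seed, id) {
  h <- 0
  for (k in utf8ToInt(as.character(id))) h <- (h * 31 + k) %% 2147483647
  as.integer(((seed %% 2147483647) * 48271 + h) %% 2147483647)
}

#' Monte-Carlo null spectrum of a sequence
#'
#' Expected ("theoretical") run-length spectrum under the
#' composition-preserving null: the sequence is shuffled `n_reps` times and
#' the run-length spectrum of each shuffle is computed with the same
#' split/enumerate operations as the observed spectrum; per-bin means and
#' standard deviations over replicates are returned. The default of 10,000
#' replicates matches the standard protocol for this analysis.
#'
#' @param seq Nucleotide sequence.
#' @param n_reps Number of shuffle replicates (>= 1).
#' @param lmax Top-code bin (see [run_spectrum()]).
#' @param seed Integer seed; results are bit-reproducible for a fixed
#'   (`seed`, `n_reps`, input).
#' @return An object of class `null_spectrum`: list with `mean_counts`,
#'   `mc_sd` (per-bin SD over replicates), `n_reps`, `seed`, `proportions`
#'   (mean counts normalized by the mean total run count),
#'   `mean_total_runs`, `lmax`, `n_bases`, `exact = FALSE`.
#' @export
null_spectrum <- function(seq, n_reps = 10000L, lmax = 10L, seed = 1L) {
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("n_reps must be a positive integer")
  lmax <- as.integer(lmax)
  chars <- validate_sequence(seq)
  codes <- match(chars, DNA_BASES)
  n <- length(codes)
  set.seed(seed)
  acc <- numeric(lmax)
  acc2 <- numeric(lmax)
  for (i in seq_len(n_reps)) {
    lens <- rle(codes[sample.int(n)])$lengths
    ct <- tabulate(pmin(lens, lmax), nbins = lmax)
    acc <- acc + ct
    acc2 <- acc2 + ct * ct
  }
  mean_counts <- acc / n_reps
  mc_sd <- if (n_reps > 1L) {
    sqrt(pmax(0, (acc2 - n_reps * mean_counts^2) / (n_reps - 1L)))
  } else rep(NA_real_, lmax)
  names(mean_counts) <- names(mc_sd) <- as.character(seq_len(lmax))
  total <- sum(mean_counts)
  structure(list(mean_counts = mean_counts,
                 mc_sd = mc_sd,
                 n_reps = n_reps,
                 seed = as.integer(seed),
                 proportions = mean_counts / total,
                 mean_total_runs = total,
                 lmax = lmax,
                 n_bases = n,
                 exact = FALSE),
            class = "null_spectrum")
}

#' @export
print.null_spectrum <- function(x, ...) {
  cat(sprintf("%s null spectrum: %d bases, %s replicates (lmax = %d)\n",
              if (isTRUE(x$exact)) "Exact permutation" else "Monte-Carlo",
              x$n_bases, format(x$n_reps, big.mark = ","), x$lmax))
  print(data.frame(length_bin = names(x$mean_counts),
                   mean_count = round(unname(x$mean_counts), 5),
                   sd = round(unname(x$mc_sd), 5)),
        row.names = FALSE)
  invisible(x)
}

#' Exact null spectrum by permutation enumeration
#'
#' Enumerates every distinct arrangement of the sequence's base multiset
#' (each arrangement is equiprobable under a uniform permutation) and
#' averages their run-length spectra. Intended as an exact oracle for small
#' sequences; refuses when the number of distinct arrangements exceeds
#' `max_perms`.
#'
#' @param seq Nucleotide sequence.
#' @param lmax Top-code bin.
#' @param max_perms Cap on the number of distinct arrangements (default 1e5).
#' @return A `null_spectrum` object with `exact = TRUE`, `n_reps` equal to
#'   the number of distinct arrangements, and `mc_sd` the population SD of
#'   per-arrangement counts.
#' @export
exact_null_enumeration <- function(seq, lmax = 10L, max_perms = 1e5) {
  lmax <- as.integer(lmax)
  chars <- validate_sequence(seq)
  n <- length(chars)
  tab <- table(chars)
  n_perm <- round(exp(lfactorial(n) - sum(lfactorial(as.integer(tab)))))
  if (n_perm > max_perms) {
    stop(sprintf(paste0("sequence has %s distinct permutations (cap %s); ",
                        "use the Monte-Carlo null_spectrum() instead"),
                 format(n_perm, big.mark = ","),
                 format(max_perms, big.mark = ",")))
  }
  bases <- names(tab)
  counts0 <- as.integer(tab)
  acc <- numeric(lmax)
  acc2 <- numeric(lmax)
  n_leaf <- 0L
  buf <- character(n)
  rec <- function(depth, counts) {
    if (depth > n) {
      lens <- rle(buf)$lengths
      ct <- tabulate(pmin(lens, lmax), nbins = lmax)
      acc <<- acc + ct
      acc2 <<- acc2 + ct * ct
      n_leaf <<- n_leaf + 1L
      return(invisible(NULL))
    }
    for (j in seq_along(bases)) {
      if (counts[j] > 0L) {
        buf[depth] <<- bases[j]
        counts[j] <- counts[j] - 1L
        rec(depth + 1L, counts)
        counts[j] <- counts[j] + 1L
      }
    }
  }
  rec(1L, counts0)
  stopifnot(n_leaf == n_perm)
  mean_counts <- acc / n_leaf
  mc_sd <- sqrt(pmax(0, acc2 / n_leaf - mean_counts^2))
  names(mean_counts) <- names(mc_sd) <- as.character(seq_len(lmax))
  total <- sum(mean_counts)
  structure(list(mean_counts = mean_counts,
                 mc_sd = mc_sd,
                 n_reps = n_leaf,
                 seed = NA_integer_,
                 proportions = mean_counts / total,
                 mean_total_runs = total,
                 lmax = lmax,
                 n_bases = n,
                 exact = TRUE),
            class = "null_spectrum")
}

#' Expected number of maximal runs of a given length in an i.i.d. sequence
#'
#' Closed-form expectation for a sequence of `n` bases drawn i.i.d. from a
#' composition vector `p`: a maximal run of length exactly `L` starting in
#' the interior requires a mismatching base on both sides, and a run
#' touching either end requires one mismatch, giving (for `L < n`)
#' \deqn{\sum_b (n - L - 1)\, p_b^L (1-p_b)^2 + 2\, p_b^L (1-p_b)}
#' with the interior term dropped when `n - L - 1 < 0`, and
#' \eqn{\sum_b p_b^n} for `L = n`. This is the asymptotic oracle for the
#' shuffle null at large `n` (where shuffling a typical i.i.d. draw is
#' close to i.i.d. resampling); it is validated against exhaustive
#' enumeration of all sequences for small `n` in the test suite.
#'
#' @param p Base-probability vector (sums to 1; any length >= 1).
#' @param n Sequence length.
#' @param L Run length, `1 <= L <= n`.
#' @return Expected count of maximal runs of length exactly `L`.
#' @export
iid_expected_runs <- function(p, n, L) {
  if (!is.numeric(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("p must be a probability vector summing to 1")
  }
  n <- as.integer(n)
  L <- as.integer(L)
  if (is.na(L) || L < 1L || L > n) stop("L must satisfy 1 <= L <= n")
  if (L == n) return(sum(p^n))
  interior <- max(n - L - 1L, 0L)
  sum(interior * p^L * (1 - p)^2 + 2 * p^L * (1 - p))
}

#' Expected i.i.d. spectrum over all bins
#'
#' Convenience wrapper around [iid_expected_runs()] returning expected
#' counts for bins `1..lmax`, with the top bin collecting all `L >= lmax`.
#'
#' @inheritParams iid_expected_runs
#' @param lmax Top-code bin.
#' @return Named numeric vector of expected counts per bin.
#' @export
iid_expected_spectrum <- function(p, n, lmax = 10L) {
  lmax <- as.integer(lmax)
  ex <- vapply(seq_len(min(lmax - 1L, n)), function(L) iid_expected_runs(p, n, L),
               numeric(1))
  if (lmax <= n) {
    top <- sum(vapply(lmax:n, function(L) iid_expected_runs(p, n, L), numeric(1)))
    ex <- c(ex, top)
  }
  ex <- c(ex, rep(0, lmax - length(ex)))
  names(ex) <- as.character(seq_len(lmax))
  ex
}
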