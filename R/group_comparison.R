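#' Observed and theoretical run-length frequencies per sequence group
#'
#' For each group in a labeled sequence panel: the observed frequencies are
#' the pooled run-length spectrum of the group's sequences; the theoretical
#' frequencies are the pooled per-sequence Monte-Carlo null means (each
#' sequence shuffled independently, preserving its own composition),
#' normalized to proportions. Per-sequence RNG streams are derived from
#' (`seed`, sequence id) with [seed_for_sequence()], so results do not
#' depend on processing order.
#'
#' @param panel Data frame with columns `id`, `seq`, `group` (every
#'   sequence must carry a non-empty group label).
#' @param n_reps Shuffle replicates per sequence (default 10,000).
#' @param lmax Top-code bin.
#' @param seed Root seed.
#' @return A data frame of class `group_frequencies` with columns `group`,
#'   `length_bin`, `obs_count`, `obs_freq`, `theo_count`, `theo_freq`,
#'   `theo_sd` (Monte-Carlo SE of `theo_count`), and attributes `n_reps`,
#'   `seed`, `lmax`.
#' @export
group_frequencies <- function(panel, n_reps = 10000L, lmax = 10L, seed = 1L) {
  check_panel(panel, need_group = TRUE)
  lmax <- as.integer(lmax)
  groups <- unique(panel$group)
  out <- lapply(groups, function(g) {
    sub <- panel[panel$group == g, , drop = FALSE]
    obs <- pooled_spectrum(sub$seq, lmax = lmax)
    theo <- numeric(lmax)
    theo_var <- numeric(lmax)
    for (i in seq_len(nrow(sub))) {
      ns <- null_spectrum(sub$seq[[i]], n_reps = n_reps, lmax = lmax,
                          seed = seed_for_sequence(seed, sub$id[[i]]))
      theo <- theo + ns$mean_counts
      theo_var <- theo_var + ns$mc_sd^2 / ns$n_reps
    }
    data.frame(group = g,
               length_bin = seq_len(lmax),
               obs_count = as.integer(obs$counts),
               obs_freq = unname(obs$proportions),
               theo_count = unname(theo),
               theo_freq = unname(theo / sum(theo)),
               theo_sd = sqrt(unname(theo_var)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "n_reps") <- as.integer(n_reps)
  attr(res, "seed") <- as.integer(seed)
  attr(res, "lmax") <- lmax
  class(res) <- c("group_frequencies", "data.frame")
  res
}

# Internal: a ratio with an explicit status flag; no silent dropping.
ratio_with_status <- function(num, den) {
  status <- ifelse(den > 0,
                   ifelse(num > 0, "finite", "zero_numerator"),
                   "undefined_zero_denominator")
  list(ratio = num / den, status = status)
}

#' Per-length enrichment ratio between two groups
#'
#' Observed and theoretical frequency ratios `group_a / group_b` per length
#' bin (e.g. sedentary chromosomal integron integrases over mobile integron
#' integrases). Bins with a zero denominator are flagged
#' `undefined_zero_denominator` (the ratio value is then `Inf` or `NaN`);
#' zero numerators over positive denominators are flagged `zero_numerator`.
#' No pseudo-counts are added by default; `pseudocount` exists for
#' exploratory use only and is non-canonical.
#'
#' @param freqs A `group_frequencies` data frame, or any data frame with the
#'   same columns restricted to the two groups of interest.
#' @param group_a,group_b Group labels; the ratio is a over b.
#' @param pseudocount Added to all counts before frequencies are recomputed
#'   (default 0; non-canonical).
#' @return A data frame of class `group_comparison` with columns
#'   `length_bin`, `obs_freq_a`, `obs_freq_b`, `theo_freq_a`, `theo_freq_b`,
#'   `obs_ratio`, `theo_ratio`, `obs_status`, `theo_status`.
#' @export
enrichment_ratio <- function(freqs, group_a, group_b, pseudocount = 0) {
  stopifnot(is.data.frame(freqs))
  fa <- freqs[freqs$group == group_a, , drop = FALSE]
  fb <- freqs[freqs$group == group_b, , drop = FALSE]
  if (nrow(fa) == 0L || nrow(fb) == 0L) {
    stop("groups not found in frequency table: ",
         paste(setdiff(c(group_a, group_b), freqs$group), collapse = ", "))
  }
  fa <- fa[order(fa$length_bin), ]
  fb <- fb[order(fb$length_bin), ]
  if (!identical(fa$length_bin, fb$length_bin)) {
    stop("mismatched length-bin sets between groups")
  }
  if (pseudocount > 0) {
    fa$obs_freq <- (fa$obs_count + pseudocount) / sum(fa$obs_count + pseudocount)
    fb$obs_freq <- (fb$obs_count + pseudocount) / sum(fb$obs_count + pseudocount)
    fa$theo_freq <- (fa$theo_count + pseudocount) / sum(fa$theo_count + pseudocount)
    fb$theo_freq <- (fb$theo_count + pseudocount) / sum(fb$theo_count + pseudocount)
  }
  obs <- ratio_with_status(fa$obs_freq, fb$obs_freq)
  theo <- ratio_with_status(fa$theo_freq, fb$theo_freq)
  res <- data.frame(length_bin = fa$length_bin,
                    obs_freq_a = fa$obs_freq,
                    obs_freq_b = fb$obs_freq,
                    theo_freq_a = fa$theo_freq,
                    theo_freq_b = fb$theo_freq,
                    obs_ratio = obs$ratio,
                    theo_ratio = theo$ratio,
                    obs_status = obs$status,
                    theo_status = theo$status,
                    stringsAsFactors = FALSE)
  attr(res, "group_a") <- group_a
  attr(res, "group_b") <- group_b
  attr(res, "pseudocount") <- pseudocount
  class(res) <- c("group_comparison", "data.frame")
  res
}
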