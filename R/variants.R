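#' Variant filter configuration
#'
#' Defaults follow the standard deep-sequencing post-calling protocol for
#' this analysis: a 0.1% allele-frequency threshold (appropriate for a
#' median coverage around 10,000x) and a two-sided Fisher strand-balance
#' test at alpha = 0.05 with no multiple-testing correction.
#'
#' @param min_freq Minimum allele frequency; records with `freq >= min_freq`
#'   are kept (default 0.001).
#' @param strand_alpha Significance level of the strand-balance test;
#'   records with `p < strand_alpha` are removed (default 0.05).
#' @param min_depth Minimum depth (default 0, i.e. no depth filter).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_freq = 0.001, strand_alpha = 0.05, min_depth = 0L) {
  stopifnot(min_freq >= 0, min_freq <= 1, strand_alpha > 0, strand_alpha < 1,
            min_depth >= 0)
  structure(list(min_freq = min_freq, strand_alpha = strand_alpha,
                 min_depth = as.integer(min_depth)),
            class = "filter_config")
}

#' Classify a variant by its REF/ALT alleles
#'
#' Length-preserving single-base changes are SNVs, length-preserving
#' multi-base changes are MNVs, and any length-changing allele pair is an
#' indel.
#'
#' @param ref,alt Allele strings (vectorized).
#' @return Character vector over `"SNV"`, `"MNV"`, `"indel"`.
#' @export
classify_variant <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt)) || anyNA(ref) || anyNA(alt)) {
    stop("empty allele string")
  }
  nr <- nchar(ref)
  na <- nchar(alt)
  ifelse(nr != na, "indel", ifelse(nr == 1L, "SNV", "MNV"))
}

#' Parse a Freebayes-style VCF into per-allele variant records
#'
#' Reads a VCF v4.2 file with [vcfR::read.vcfR()] and decomposes each site
#' into one record per ALT allele, extracting the Freebayes observation
#' counts: `AO`/`SAF`/`SAR` are per-allele (`Number=A`), `RO`/`SRF`/`SRR`/
#' `DP` are per-site. The allele frequency is `AO / (AO + RO)` by default
#' (robust to DP inflation at overlapping alleles), or `AO / DP`.
#'
#' Records lacking the per-strand keys are kept (and still eligible for the
#' frequency filter) but marked `has_strand = FALSE` and excluded from
#' strand-balance testing, with a warning giving the count.
#'
#' @param vcf Path to a VCF file.
#' @param freq_mode `"count_ratio"` for `AO/(AO+RO)` (default) or `"depth"`
#'   for `AO/DP`.
#' @return Data frame with one row per ALT allele: `contig`, `pos`, `ref`,
#'   `alt`, `vtype`, `ao`, `ro`, `alt_fwd`, `alt_rev`, `ref_fwd`,
#'   `ref_rev`, `dp`, `freq`, `has_strand`.
#' @export
parse_variants <- function(vcf, freq_mode = c("count_ratio", "depth")) {
  freq_mode <- match.arg(freq_mode)
  v <- suppressWarnings(vcfR::read.vcfR(vcf, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  empty <- data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), vtype = character(), ao = integer(),
                      ro = integer(), alt_fwd = integer(), alt_rev = integer(),
                      ref_fwd = integer(), ref_rev = integer(), dp = integer(),
                      freq = numeric(), has_strand = logical(),
                      stringsAsFactors = FALSE)
  if (is.null(fix) || nrow(v@fix) == 0L) return(empty)
  fix <- v@fix
  info_num <- function(key) suppressWarnings(vcfR::extract.info(v, element = key))
  ao <- info_num("AO")
  ro <- info_num("RO")
  saf <- info_num("SAF")
  sar <- info_num("SAR")
  srf <- info_num("SRF")
  srr <- info_num("SRR")
  dp <- info_num("DP")
  split_int <- function(x) {
    if (is.null(x) || is.na(x)) return(NA_integer_)
    as.integer(strsplit(x, ",", fixed = TRUE)[[1L]])
  }
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    n_alt <- length(alts)
    rec_ao <- split_int(ao[i])
    rec_saf <- split_int(saf[i])
    rec_sar <- split_int(sar[i])
    if (length(rec_ao) == 1L && n_alt > 1L) rec_ao <- rep(rec_ao, n_alt)
    rows[[i]] <- data.frame(
      contig = fix[i, "CHROM"],
      pos = as.integer(fix[i, "POS"]),
      ref = fix[i, "REF"],
      alt = alts,
      vtype = classify_variant(rep(fix[i, "REF"], n_alt), alts),
      ao = rec_ao,
      ro = rep(split_int(ro[i])[1L], n_alt),
      alt_fwd = if (length(rec_saf) == n_alt) rec_saf else rep(NA_integer_, n_alt),
      alt_rev = if (length(rec_sar) == n_alt) rec_sar else rep(NA_integer_, n_alt),
      ref_fwd = rep(split_int(srf[i])[1L], n_alt),
      ref_rev = rep(split_int(srr[i])[1L], n_alt),
      dp = rep(split_int(dp[i])[1L], n_alt),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)
  rec$freq <- if (freq_mode == "count_ratio") {
    rec$ao / (rec$ao + rec$ro)
  } else {
    rec$ao / rec$dp
  }
  rec$has_strand <- !(is.na(rec$alt_fwd) | is.na(rec$alt_rev) |
                        is.na(rec$ref_fwd) | is.na(rec$ref_rev))
  if (any(!rec$has_strand)) {
    warning(sprintf("%d record(s) lack per-strand counts; excluded from strand filtering",
                    sum(!rec$has_strand)))
  }
  rec
}

# Internal: append removal log rows to a record set's "removed" attribute,
# harmonizing columns (filters may add columns such as strand_p).
log_removed <- function(records, removed, reason) {
  prev <- attr(records, "removed")
  if (nrow(removed) > 0L) {
    removed$reason <- reason
    if (!is.null(prev)) {
      for (nm in setdiff(names(removed), names(prev))) prev[[nm]] <- NA
      for (nm in setdiff(names(prev), names(removed))) removed[[nm]] <- NA
      removed <- removed[, names(prev), drop = FALSE]
    }
    attr(records, "removed") <- rbind(prev, removed)
  } else {
    attr(records, "removed") <- prev
  }
  records
}

#' Removal log of a filtered record set
#'
#' Every input record is accounted for across filtering: it either survives
#' or appears here with exactly one reason.
#'
#' @param records A record data frame returned by a filter.
#' @return Data frame of removed records with a `reason` column.
#' @export
removed_variants <- function(records) {
  rem <- attr(records, "removed")
  if (is.null(rem)) {
    rem <- cbind(records[0, , drop = FALSE],
                 data.frame(reason = character(), stringsAsFactors = FALSE))
  }
  rem
}

#' Allele-frequency filter
#'
#' Keeps records with `freq >= min_freq` (boundary kept) and
#' `dp >= min_depth`; ordering is preserved and removals are logged on the
#' `"removed"` attribute (see [removed_variants()]).
#'
#' @param records Variant records from [parse_variants()].
#' @param config A [filter_config()].
#' @return Surviving records.
#' @export
frequency_filter <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"), "freq" %in% names(records))
  keep <- records$freq >= config$min_freq & records$dp >= config$min_depth
  out <- records[keep, , drop = FALSE]
  attr(out, "removed") <- attr(records, "removed")
  log_removed(out, records[!keep, , drop = FALSE], "low_freq")
}

#' Two-sided Fisher exact p-value for strand balance
#'
#' Exact hypergeometric summation on the 2x2 table
#' `[[alt_fwd, alt_rev], [ref_fwd, ref_rev]]`: the two-sided p-value sums
#' all tables with the observed margins whose probability does not exceed
#' the observed table's (up to the same 1e-7 relative tolerance that
#' [stats::fisher.test()] uses, with which this agrees). Vectorized over
#' records. An all-zero table yields `NA`.
#'
#' @param alt_fwd,alt_rev,ref_fwd,ref_rev Non-negative read counts.
#' @return Numeric vector of p-values.
#' @export
strand_fisher_p <- function(alt_fwd, alt_rev, ref_fwd, ref_rev) {
  mapply(function(a, b, c, d) {
    if (anyNA(c(a, b, c, d))) return(NA_real_)
    m1 <- a + b
    m2 <- c + d
    k <- a + c
    if (m1 + m2 == 0) return(NA_real_)
    lo <- max(0, k - m2)
    hi <- min(k, m1)
    x <- lo:hi
    logp <- stats::dhyper(x, m1, m2, k, log = TRUE)
    sum(exp(logp[logp <= stats::dhyper(a, m1, m2, k, log = TRUE) + log1p(1e-7)]))
  }, alt_fwd, alt_rev, ref_fwd, ref_rev)
}

#' Strand-balance filter
#'
#' Removes records whose alt/ref read counts are significantly imbalanced
#' between sequencing strands (`p < strand_alpha`, two-sided Fisher exact
#' test on allele x strand) -- the classic signature of a sequencing
#' artifact rather than a real low-frequency variant. Records without
#' strand counts are kept with a warning; all-zero tables are excluded with
#' a warning.
#'
#' @inheritParams frequency_filter
#' @return Surviving records, with a `strand_p` column added; removals are
#'   logged on the `"removed"` attribute.
#' @export
strand_balance_filter <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (nrow(records) == 0L) {
    records$strand_p <- numeric(0)
    return(records)
  }
  p <- rep(NA_real_, nrow(records))
  testable <- records$has_strand
  p[testable] <- strand_fisher_p(records$alt_fwd[testable],
                                 records$alt_rev[testable],
                                 records$ref_fwd[testable],
                                 records$ref_rev[testable])
  zero_table <- testable & is.na(p)
  if (any(zero_table)) {
    warning(sprintf("%d record(s) with all-zero strand tables excluded", sum(zero_table)))
  }
  if (any(!testable)) {
    warning(sprintf("%d record(s) without strand counts kept untested", sum(!testable)))
  }
  records$strand_p <- p
  biased <- testable & !is.na(p) & p < config$strand_alpha
  keep <- !biased & !zero_table
  out <- records[keep, , drop = FALSE]
  attr(out, "removed") <- attr(records, "removed")
  out <- log_removed(out, records[biased, , drop = FALSE], "strand_bias")
  log_removed(out, records[zero_table, , drop = FALSE], "zero_strand_table")
}

#' Apply frequency then strand-balance filters
#'
#' The two filters are order-commutative (each tests a record property
#' independent of the other records); this helper applies both and keeps
#' the combined removal log.
#'
#' @inheritParams frequency_filter
#' @return Surviving records with the combined `"removed"` attribute.
#' @export
filter_variants <- function(records, config = filter_config()) {
  strand_balance_filter(frequency_filter(records, config), config)
}
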