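#' Normalize an indel to parsimonious, left-aligned VCF form
#'
#' VCF encodes homopolymer indels ambiguously: the same physical event can
#' be written at any position within the run and padded with shared bases.
#' This normalizer (i) trims shared suffix then prefix bases down to the
#' minimal representation, and (ii) left-aligns the event against the
#' reference, producing the canonical anchor-base form (`REF = anchor +
#' deleted bases` / `ALT = anchor`, or the insertion mirror image). SNV/MNV
#' records are returned unchanged apart from trimming.
#'
#' @param pos 1-based position of the first REF base.
#' @param ref,alt Allele strings.
#' @param refseq Reference sequence of the gene/contig the coordinates
#'   refer to.
#' @return List with `pos`, `ref`, `alt`.
#' @export
normalize_indel <- function(pos, ref, alt, refseq) {
  stopifnot(nzchar(ref), nzchar(alt))
  n <- nchar(refseq)
  if (pos < 1L || pos + nchar(ref) - 1L > n) {
    stop(sprintf("variant at position %d with REF '%s' lies outside the reference (length %d)",
                 pos, ref, n))
  }
  if (substr(refseq, pos, pos + nchar(ref) - 1L) != toupper(ref)) {
    stop(sprintf("REF allele '%s' does not match reference at position %d", ref, pos))
  }
  r <- strsplit(toupper(ref), "", fixed = TRUE)[[1L]]
  a <- strsplit(toupper(alt), "", fixed = TRUE)[[1L]]
  # parsimony: trim shared suffix, then shared prefix (advancing pos)
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    pos <- pos + 1L
  }
  if (length(r) == length(a)) {
    return(list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = "")))
  }
  ref_chars <- strsplit(toupper(refseq), "", fixed = TRUE)[[1L]]
  if (length(r) > 1L && length(a) == 1L && r[1L] == a[1L]) {
    # deletion of seg = r[-1], occupying positions (pos+1)..(pos+len)
    i <- pos + 1L
    j <- pos + length(r) - 1L
    while (i > 2L && ref_chars[i - 1L] == ref_chars[j]) {
      i <- i - 1L
      j <- j - 1L
    }
    anchor <- i - 1L
    return(list(pos = anchor,
                ref = paste(ref_chars[anchor:j], collapse = ""),
                alt = ref_chars[anchor]))
  }
  if (length(a) > 1L && length(r) == 1L && r[1L] == a[1L]) {
    # insertion of seg = a[-1] after position pos
    seg <- a[-1L]
    while (pos > 1L && ref_chars[pos] == seg[length(seg)]) {
      seg <- c(ref_chars[pos], seg[-length(seg)])
      pos <- pos - 1L
    }
    return(list(pos = pos,
                ref = ref_chars[pos],
                alt = paste(c(ref_chars[pos], seg), collapse = "")))
  }
  # complex substitution (e.g. length-changing without shared anchor)
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Attribute indel variants to homopolymer runs
#'
#' Maps each surviving indel onto the homopolymer run that generated it
#' under a slipped-strand mispairing model: after normalization
#' ([normalize_indel()]), an indel is attributed to run R iff (a) all of
#' its net inserted/deleted bases equal R's base, and (b) its normalized
#' anchor position lies within R or at the position immediately 5' of R
#' (the VCF anchor-base convention). Runs shorter than `min_len` are not
#' attribution targets; SNV/MNV records are never attributed.
#'
#' @param records Variant records (typically after [filter_variants()])
#'   with coordinates on `refseq`.
#' @param runs Run table from [split_runs()] on the same reference gene.
#' @param refseq The reference gene sequence (same coordinate system as
#'   `records`).
#' @param min_len Minimum run length to be an attribution target
#'   (default 3).
#' @return An object of class `hotspot_attribution`: list with `variants`
#'   (records plus `norm_pos`, `norm_ref`, `norm_alt`, `run_index`),
#'   `runs`, `min_len`, `refseq`.
#' @export
attribute_indels_to_runs <- function(records, runs, refseq, min_len = 3L) {
  stopifnot(is.data.frame(runs), all(c("base", "start", "end", "length") %in% names(runs)))
  n <- nchar(refseq)
  records$norm_pos <- records$pos
  records$norm_ref <- records$ref
  records$norm_alt <- records$alt
  records$run_index <- rep(NA_integer_, nrow(records))
  eligible <- which(runs$length >= min_len)
  for (i in seq_len(nrow(records))) {
    if (records$pos[i] + nchar(records$ref[i]) - 1L > n) {
      stop(sprintf("variant at position %d extends beyond the gene end (%d)",
                   records$pos[i], n))
    }
    if (records$vtype[i] != "indel") next
    nz <- normalize_indel(records$pos[i], records$ref[i], records$alt[i], refseq)
    records$norm_pos[i] <- nz$pos
    records$norm_ref[i] <- nz$ref
    records$norm_alt[i] <- nz$alt
    if (nchar(nz$ref) == nchar(nz$alt)) next  # degenerate, not a pure indel
    longer <- if (nchar(nz$ref) > nchar(nz$alt)) nz$ref else nz$alt
    seg <- substring(longer, 2L)
    seg_bases <- unique(strsplit(seg, "", fixed = TRUE)[[1L]])
    if (length(seg_bases) != 1L) next  # multi-base event: not a homopolymer slip
    anchor <- nz$pos
    for (j in eligible) {
      if (runs$base[j] == seg_bases &&
          anchor >= runs$start[j] - 1L && anchor <= runs$end[j]) {
        records$run_index[i] <- j
        break
      }
    }
  }
  structure(list(variants = records, runs = runs, min_len = as.integer(min_len),
                 refseq = refseq),
            class = "hotspot_attribution")
}

#' Hotspot tables: per-run and per-position mutation frequencies
#'
#' Summarizes a [attribute_indels_to_runs()] result into (i) a per-run
#' table of summed indel frequencies over all attribution-eligible runs
#' (the slippage-hotspot ranking), and (ii) a per-position table of variant
#' frequencies by type. Positions are reported 1-based relative to the A of
#' the ATG start codon (`A of ATG = position 1`); `atg_pos` gives the
#' position of that A in the reference coordinate system.
#'
#' @param attribution A `hotspot_attribution`.
#' @param atg_pos Reference position of the A of the start codon
#'   (default 1).
#' @return List of class `hotspot_tables` with `per_run` (columns
#'   `run_start`, `run_start_atg`, `base`, `length`, `summed_indel_freq`,
#'   `n_variants`) sorted by decreasing summed frequency, and
#'   `per_position` (columns `position_atg`, `vtype`, `freq`). Empty input
#'   yields empty tables with headers.
#' @export
hotspot_table <- function(attribution, atg_pos = 1L) {
  stopifnot(inherits(attribution, "hotspot_attribution"))
  v <- attribution$variants
  runs <- attribution$runs
  eligible <- which(runs$length >= attribution$min_len)
  per_run <- data.frame(run_index = eligible,
                        run_start = runs$start[eligible],
                        run_start_atg = runs$start[eligible] - atg_pos + 1L,
                        base = runs$base[eligible],
                        length = runs$length[eligible],
                        summed_indel_freq = 0,
                        n_variants = 0L,
                        stringsAsFactors = FALSE)
  if (nrow(v) > 0L) {
    hit <- v[!is.na(v$run_index), , drop = FALSE]
    if (nrow(hit) > 0L) {
      agg_f <- tapply(hit$freq, hit$run_index, sum)
      agg_n <- tapply(hit$freq, hit$run_index, length)
      idx <- match(as.integer(names(agg_f)), per_run$run_index)
      per_run$summed_indel_freq[idx] <- as.numeric(agg_f)
      per_run$n_variants[idx] <- as.integer(agg_n)
    }
  }
  per_run <- per_run[order(-per_run$summed_indel_freq, per_run$run_start), ,
                     drop = FALSE]
  rownames(per_run) <- NULL
  per_position <- data.frame(position_atg = integer(), vtype = character(),
                             freq = numeric(), stringsAsFactors = FALSE)
  if (nrow(v) > 0L) {
    per_position <- data.frame(position_atg = v$norm_pos - atg_pos + 1L,
                               vtype = v$vtype,
                               freq = v$freq,
                               stringsAsFactors = FALSE)
    per_position <- per_position[order(per_position$position_atg), , drop = FALSE]
    rownames(per_position) <- NULL
  }
  structure(list(per_run = per_run, per_position = per_position,
                 atg_pos = as.integer(atg_pos)),
            class = "hotspot_tables")
}

#' @export
print.hotspot_tables <- function(x, ...) {
  cat("Hotspot attribution (positions relative to A of ATG = 1)\n")
  cat("Top runs by summed indel frequency:\n")
  print(utils::head(x$per_run, 5), row.names = FALSE)
  cat(sprintf("%d variant position(s) in the per-position table\n",
              nrow(x$per_position)))
  invisible(x)
}
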