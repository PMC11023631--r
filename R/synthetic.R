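#' Generate a synthetic coding sequence with planted homopolymer runs
#'
#' Draws a sequence i.i.d. from a base composition, then overwrites the
#' planted runs. Planted runs are flank-guarded: the bases immediately 5'
#' and 3' of a planted run are forced to differ from the run base, so the
#' planted length is exact. In `orf_mode` the sequence starts with `ATG`,
#' ends with a stop codon, and contains no internal stop codons (violating
#' codons are resampled; positions inside planted runs are exempt and an
#' error is raised if a planted run forces a stop). With
#' `max_background_run` set, the i.i.d. background is rejection-sampled
#' until no non-planted run exceeds it, so the planted runs are the only
#' long runs.
#'
#' @param length Sequence length in bp (divisible by 3 in `orf_mode`).
#' @param composition Base-probability vector in `A,C,G,T` order (default
#'   uniform).
#' @param planted_runs `NULL` or a data frame with columns `base`,
#'   `length`, `start` (1-based start offset).
#' @param orf_mode Enforce ATG start, terminal stop, no internal stops.
#' @param seed Integer seed; output is seed-deterministic.
#' @param max_background_run Maximum allowed length of non-planted runs
#'   (default `Inf`, no constraint).
#' @param max_iter Rejection-sampling cap (default 1000).
#' @return The sequence as a character scalar.
#' @export
generate_cds <- function(length, composition = rep(0.25, 4), planted_runs = NULL,
                         orf_mode = FALSE, seed = 1L,
                         max_background_run = Inf, max_iter = 1000L) {
  n <- as.integer(length)
  stopifnot(n >= 1L, is.numeric(composition), length(composition) == 4L,
            all(composition >= 0), abs(sum(composition) - 1) < 1e-8)
  comp <- unname(composition)
  if (orf_mode && (n %% 3L != 0L || n < 9L)) {
    stop("orf_mode requires length divisible by 3 and >= 9")
  }
  pr <- planted_runs
  if (!is.null(pr)) {
    stopifnot(is.data.frame(pr), all(c("base", "length", "start") %in% names(pr)))
    pr$base <- toupper(pr$base)
    pr$end <- pr$start + pr$length - 1L
    stopifnot(all(pr$base %in% DNA_BASES), all(pr$length >= 1L),
              all(pr$start >= 1L), all(pr$end <= n))
    if (nrow(pr) > 1L) {
      o <- order(pr$start)
      # guarded intervals [start-1, end+1] must not overlap
      if (any(pr$start[o][-1L] - 1L <= pr$end[o][-nrow(pr)] + 1L)) {
        stop("planted runs (including flank guards) overlap")
      }
    }
    if (orf_mode && any(pr$start <= 3L | pr$end >= n - 2L)) {
      stop("planted runs may not overlap the start or stop codon")
    }
  }
  fixed <- integer(0)       # positions whose value is imposed
  fixed_val <- character(0)
  guard_pos <- integer(0)   # positions forbidden to carry guard_ban
  guard_ban <- character(0)
  if (!is.null(pr)) {
    for (i in seq_len(nrow(pr))) {
      idx <- pr$start[i]:pr$end[i]
      fixed <- c(fixed, idx)
      fixed_val <- c(fixed_val, rep(pr$base[i], length(idx)))
      for (g in c(pr$start[i] - 1L, pr$end[i] + 1L)) {
        if (g >= 1L && g <= n) {
          guard_pos <- c(guard_pos, g)
          guard_ban <- c(guard_ban, pr$base[i])
        }
      }
    }
  }
  sample_base <- function(k, ban = NULL) {
    allowed <- if (is.null(ban)) DNA_BASES else setdiff(DNA_BASES, ban)
    w <- comp[match(allowed, DNA_BASES)]
    if (sum(w) <= 0) w <- rep(1, length(allowed))
    sample(allowed, k, replace = TRUE, prob = w)
  }
  set.seed(seed)
  for (iter in seq_len(max_iter)) {
    s <- sample(DNA_BASES, n, replace = TRUE, prob = comp)
    if (orf_mode) {
      s[1:3] <- c("A", "T", "G")
      s[(n - 2L):n] <- strsplit(sample(c("TAA", "TAG", "TGA"), 1L), "")[[1L]]
    }
    if (length(fixed)) s[fixed] <- fixed_val
    orf_fixed <- if (orf_mode) c(1:3, (n - 2L):n) else integer(0)
    hard <- c(fixed, orf_fixed)
    for (j in seq_along(guard_pos)) {
      g <- guard_pos[j]
      if (g %in% hard) {
        if (s[g] == guard_ban[j]) {
          stop(sprintf("flank guard at position %d conflicts with a fixed base", g))
        }
      } else if (s[g] == guard_ban[j]) {
        s[g] <- sample_base(1L, ban = guard_ban[j])
      }
    }
    if (orf_mode) {
      s <- fix_internal_stops(s, hard_positions = hard,
                              guard_pos = guard_pos, guard_ban = guard_ban,
                              sample_base = sample_base)
    }
    if (is.finite(max_background_run)) {
      r <- rle(s)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      bg <- rep(TRUE, length(ends))
      if (!is.null(pr)) {
        for (i in seq_len(nrow(pr))) {
          bg[starts <= pr$end[i] & ends >= pr$start[i]] <- FALSE
        }
      }
      if (any(r$lengths[bg] > max_background_run)) next
    }
    if (!is.null(pr)) {
      # planted runs must be exactly their stated length
      r <- rle(s)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (i in seq_len(nrow(pr))) {
        k <- which(starts == pr$start[i] & ends == pr$end[i] &
                     r$values == pr$base[i])
        if (length(k) != 1L) stop("internal error: planted run not exact")
      }
    }
    return(paste(s, collapse = ""))
  }
  stop(sprintf(paste0("rejection sampling exceeded %d iterations; relax ",
                      "max_background_run or change the composition"), max_iter))
}

# Internal: resample free positions of internal stop codons until none remain.
fix_internal_stops <- function(s, hard_positions, guard_pos, guard_ban,
                               sample_base, max_rounds = 200L) {
  n <- length(s)
  stops <- c("TAA", "TAG", "TGA")
  ban_at <- function(pos) {
    j <- which(guard_pos == pos)
    if (length(j)) guard_ban[j[1L]] else NULL
  }
  for (round in seq_len(max_rounds)) {
    codon_starts <- seq(4L, n - 5L, by = 3L)  # internal codons only
    cods <- vapply(codon_starts, function(cs) paste(s[cs:(cs + 2L)], collapse = ""),
                   character(1))
    bad <- codon_starts[cods %in% stops]
    if (length(bad) == 0L) return(s)
    for (cs in bad) {
      free <- setdiff(cs:(cs + 2L), hard_positions)
      if (length(free) == 0L) {
        stop("planted runs force an internal stop codon; adjust the gene spec")
      }
      for (p in free) s[p] <- sample_base(1L, ban = ban_at(p))
    }
  }
  stop("could not eliminate internal stop codons (constraint conflict)")
}

#' Generate a labeled two-group sequence panel
#'
#' Emulates the contrast between sedentary chromosomal integron (SCI)
#' integrases, whose spectra carry long homopolymers, and mobile integron
#' (MI) integrases, whose homopolymers are much shorter:
#' * `"SCI-like"`: each sequence carries one planted flank-guarded run of
#'   length 7-9 (uniformly chosen) at a random interior position;
#' * `"MI-like"`: sequences are rejection-sampled until they contain no
#'   run of 6 or more;
#' * `"iid"`: plain i.i.d. sequences with no constraint (null panels for
#'   calibration).
#'
#' @param n_seqs Number of sequences (>= 1).
#' @param length Sequence length in bp (default 1000).
#' @param composition Base-probability vector (default uniform).
#' @param policy `"SCI-like"`, `"MI-like"` or `"iid"`.
#' @param seed Root seed; per-sequence seeds are derived from it and the
#'   sequence id.
#' @param group Group label; defaults to the policy name.
#' @param plant_lengths Candidate planted-run lengths for `"SCI-like"`
#'   (default `7:9`).
#' @param mi_max_run Maximum run length tolerated by `"MI-like"`
#'   (default 5).
#' @param id_prefix Prefix of the sequence ids (default: the group label),
#'   so two panels destined for one comparison get distinct ids.
#' @return A panel data frame with columns `id`, `seq`, `group`.
#' @export
generate_group_panel <- function(n_seqs, length = 1000L,
                                 composition = rep(0.25, 4),
                                 policy = c("SCI-like", "MI-like", "iid"),
                                 seed = 1L, group = NULL,
                                 plant_lengths = 7:9, mi_max_run = 5L,
                                 id_prefix = NULL) {
  policy <- match.arg(policy)
  stopifnot(n_seqs >= 1L)
  if (is.null(group)) group <- policy
  prefix <- if (is.null(id_prefix)) sub("-like$", "", group) else id_prefix
  ids <- sprintf("%s_%03d", prefix, seq_len(n_seqs))
  seqs <- character(n_seqs)
  for (i in seq_len(n_seqs)) {
    s_i <- seed_for_sequence(seed, ids[i])
    if (policy == "SCI-like") {
      set.seed(s_i)
      run_len <- if (length(plant_lengths) == 1L) plant_lengths else sample(plant_lengths, 1L)
      start <- sample(seq(2L, length - run_len), 1L)
      base <- sample(DNA_BASES, 1L, prob = composition)
      seqs[i] <- generate_cds(length, composition,
                              planted_runs = data.frame(base = base,
                                                        length = run_len,
                                                        start = start),
                              seed = seed_for_sequence(s_i, "cds"))
    } else if (policy == "MI-like") {
      seqs[i] <- generate_cds(length, composition, seed = s_i,
                              max_background_run = mi_max_run)
    } else {
      seqs[i] <- generate_cds(length, composition, seed = s_i)
    }
  }
  data.frame(id = ids, seq = seqs, group = group, stringsAsFactors = FALSE)
}

#' Synthetic integrase-like gene with the canonical hotspot layout
#'
#' A 960 bp ORF-mode gene emulating the homopolymer layout of the *intIA*
#' integrase of *Vibrio cholerae*: an 8xA run starting 57 bp after the A of
#' the ATG (i.e. at position 58), plus one 7-mer and one 6-mer further
#' along the gene, with the i.i.d. background capped at runs of 5 so that
#' those three planted runs are the gene's largest homopolymers.
#'
#' @param seed Integer seed.
#' @param length Gene length (default 960; divisible by 3).
#' @param composition Background base composition (default uniform).
#' @return The gene as a character scalar.
#' @export
simulate_integrase_gene <- function(seed = 1L, length = 960L,
                                    composition = rep(0.25, 4)) {
  generate_cds(length, composition,
               planted_runs = data.frame(base = c("A", "T", "A"),
                                         length = c(8L, 7L, 6L),
                                         start = c(58L, 401L, 700L)),
               orf_mode = TRUE, seed = seed, max_background_run = 5L)
}

#' Slippage model for synthetic variant simulation
#'
#' A minimal, clearly non-canonical quantitative stand-in for slipped-strand
#' mispairing (SSM): the indel rate of a run of length `L` is
#' `min(r1 * g^(L-1), rate_max)` -- geometric growth with run length -- on
#' top of a flat background SNV noise rate. It exists so hotspot recovery
#' can be tested against a known ground truth; it is not an empirical
#' mutation model.
#'
#' @param r1 Indel rate of a length-1 run (default 1e-5).
#' @param g Growth factor per additional repeat unit (default 4).
#' @param rate_max Cap on the per-run indel rate (default 0.5).
#' @param snv_rate Per-site background SNV allele frequency (default 1e-5).
#' @param coverage Reads per site (default 10000).
#' @param strand_bias_fraction Fraction of emitted variants planted as
#'   strand-biased artifacts (all alt reads on one strand; default 0).
#' @return A list of class `slippage_model`.
#' @export
slippage_model <- function(r1 = 1e-5, g = 4, rate_max = 0.5, snv_rate = 1e-5,
                           coverage = 10000L, strand_bias_fraction = 0) {
  stopifnot(r1 >= 0, r1 <= 1, g > 0, rate_max >= 0, rate_max <= 1,
            snv_rate >= 0, snv_rate <= 1, coverage >= 1,
            strand_bias_fraction >= 0, strand_bias_fraction <= 1)
  structure(list(r1 = r1, g = g, rate_max = rate_max, snv_rate = snv_rate,
                 coverage = as.integer(coverage),
                 strand_bias_fraction = strand_bias_fraction),
            class = "slippage_model")
}

#' Per-run slippage rate under a model
#'
#' @param model A [slippage_model()].
#' @param L Run length(s).
#' @return Numeric vector of capped rates `min(r1 * g^(L-1), rate_max)`.
#' @export
slippage_rate <- function(model, L) {
  stopifnot(inherits(model, "slippage_model"))
  pmin(model$r1 * model$g^(L - 1), model$rate_max)
}

#' Simulate a variant table from a gene under a slippage model
#'
#' For every homopolymer run of length `>= min_run` (default 3), emits a
#' single +/-1 bp indel of the run's base with allele frequency given by
#' [slippage_rate()], anchored in left-aligned parsimonious VCF form at the
#' base immediately 5' of the run. Background SNVs are emitted per site at
#' the model's noise rate. Alt read counts are binomial at the model's
#' coverage; reads split between strands binomially at 0.5, except planted
#' strand-biased artifacts which place all alt reads on one strand.
#' Variants whose binomial draw yields zero alt reads are not called
#' (a called variant has at least one supporting read). Runs starting at
#' reference position 1 have no 5' anchor base and are skipped.
#'
#' @param gene Reference gene sequence.
#' @param model A [slippage_model()].
#' @param seed Integer seed.
#' @param min_run Minimum run length that can slip (default 3).
#' @param contig Contig name used in the records (default
#'   `"synthetic_gene"`).
#' @return List with `variants` (data frame in the [parse_variants()]
#'   schema) and `truth` (one row per emitted variant: `pos`, `ref`,
#'   `alt`, `mechanism` = `"slippage"` or `"background_snv"`, `run_start`,
#'   `run_length`, `true_rate`, `strand_biased`).
#' @export
simulate_variants <- function(gene, model, seed = 1L, min_run = 3L,
                              contig = "synthetic_gene") {
  stopifnot(inherits(model, "slippage_model"))
  chars <- validate_sequence(gene)
  n <- length(chars)
  runs <- split_runs(gene)
  set.seed(seed)
  cov <- model$coverage
  var_rows <- list()
  truth_rows <- list()
  add <- function(pos, ref, alt, ao, biased, mechanism, run_start, run_length,
                  true_rate) {
    if (biased) {
      side <- sample(c("fwd", "rev"), 1L)
      saf <- if (side == "fwd") ao else 0L
    } else {
      saf <- stats::rbinom(1L, ao, 0.5)
    }
    ro <- cov - ao
    srf <- stats::rbinom(1L, ro, 0.5)
    k <- length(var_rows) + 1L
    var_rows[[k]] <<- data.frame(
      contig = contig, pos = pos, ref = ref, alt = alt,
      vtype = classify_variant(ref, alt),
      ao = ao, ro = ro, alt_fwd = saf, alt_rev = ao - saf,
      ref_fwd = srf, ref_rev = ro - srf, dp = cov,
      freq = ao / (ao + ro), has_strand = TRUE,
      stringsAsFactors = FALSE)
    truth_rows[[k]] <<- data.frame(
      pos = pos, ref = ref, alt = alt, mechanism = mechanism,
      run_start = run_start, run_length = run_length,
      true_rate = true_rate, strand_biased = biased,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(runs))) {
    if (runs$length[i] < min_run) next
    if (runs$start[i] == 1L) next  # no 5' anchor for a left-aligned record
    rate <- slippage_rate(model, runs$length[i])
    ao <- stats::rbinom(1L, cov, rate)
    if (ao < 1L) next
    anchor <- runs$start[i] - 1L
    anchor_base <- chars[anchor]
    if (sample(c(TRUE, FALSE), 1L)) {
      ref <- paste0(anchor_base, runs$base[i])  # deletion of one repeat unit
      alt <- anchor_base
    } else {
      ref <- anchor_base                        # insertion of one repeat unit
      alt <- paste0(anchor_base, runs$base[i])
    }
    biased <- stats::runif(1L) < model$strand_bias_fraction
    add(anchor, ref, alt, ao, biased, "slippage",
        runs$start[i], runs$length[i], rate)
  }
  if (model$snv_rate > 0) {
    ao_bg <- stats::rbinom(n, cov, model$snv_rate)
    for (p in which(ao_bg >= 1L)) {
      alt <- sample(setdiff(DNA_BASES, chars[p]), 1L)
      biased <- stats::runif(1L) < model$strand_bias_fraction
      add(p, chars[p], alt, ao_bg[p], biased, "background_snv",
          NA_integer_, NA_integer_, model$snv_rate)
    }
  }
  if (length(var_rows) == 0L) {
    variants <- parse_variants_empty()
    truth <- data.frame(pos = integer(), ref = character(), alt = character(),
                        mechanism = character(), run_start = integer(),
                        run_length = integer(), true_rate = numeric(),
                        strand_biased = logical(), stringsAsFactors = FALSE)
    return(list(variants = variants, truth = truth))
  }
  variants <- do.call(rbind, var_rows)
  truth <- do.call(rbind, truth_rows)
  o <- order(variants$pos)
  list(variants = variants[o, , drop = FALSE],
       truth = truth[o, , drop = FALSE])
}

# Internal: empty record frame in the parse_variants() schema.
parse_variants_empty <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), vtype = character(), ao = integer(),
             ro = integer(), alt_fwd = integer(), alt_rev = integer(),
             ref_fwd = integer(), ref_rev = integer(), dp = integer(),
             freq = numeric(), has_strand = logical(), stringsAsFactors = FALSE)
}

#' Write simulated variant records as a Freebayes-dialect VCF
#'
#' Emits a VCF v4.2 file with per-allele observation counts in the INFO
#' column (`AO`, `SAF`, `SAR` with `Number=A`; `RO`, `SRF`, `SRR`, `DP`
#' per site), the dialect consumed by [parse_variants()].
#'
#' @param variants Record data frame from [simulate_variants()].
#' @param file Output path.
#' @param contig_len Contig length for the header (default: max position
#'   plus 1).
#' @return `file`, invisibly.
#' @export
write_variants_vcf <- function(variants, file, contig_len = NULL) {
  contig <- if (nrow(variants)) variants$contig[1] else "synthetic_gene"
  if (is.null(contig_len)) {
    contig_len <- if (nrow(variants)) max(variants$pos + nchar(variants$ref)) else 1L
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=homorun simulate_variants (synthetic data)",
    sprintf("##contig=<ID=%s,length=%d>", contig, as.integer(contig_len)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"Alternate allele observation count\">",
    "##INFO=<ID=RO,Number=1,Type=Integer,Description=\"Reference allele observation count\">",
    "##INFO=<ID=SAF,Number=A,Type=Integer,Description=\"Alternate allele observations on the forward strand\">",
    "##INFO=<ID=SAR,Number=A,Type=Integer,Description=\"Alternate allele observations on the reverse strand\">",
    "##INFO=<ID=SRF,Number=1,Type=Integer,Description=\"Reference allele observations on the forward strand\">",
    "##INFO=<ID=SRR,Number=1,Type=Integer,Description=\"Reference allele observations on the reverse strand\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  body <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    info <- sprintf("DP=%d;AO=%d;RO=%d;SAF=%d;SAR=%d;SRF=%d;SRR=%d",
                    variants$dp[i], variants$ao[i], variants$ro[i],
                    variants$alt_fwd[i], variants$alt_rev[i],
                    variants$ref_fwd[i], variants$ref_rev[i])
    body[i] <- paste(variants$contig[i], variants$pos[i], ".", variants$ref[i],
                     variants$alt[i], ".", ".", info, sep = "\t")
  }
  writeLines(c(hdr, body), file)
  invisible(file)
}
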