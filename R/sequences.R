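#' @keywords internal
DNA_BASES <- c("A", "C", "G", "T")

#' Validate a nucleotide sequence
#'
#' Uppercases the input, maps `U` to `T` (RNA input is tolerated with a
#' warning) and checks that every residue is one of `A`, `C`, `G`, `T`.
#' Ambiguity codes (`N` and other IUPAC symbols) are rejected by default:
#' silently breaking runs at ambiguous residues would bias run-length
#' spectra, so the caller must decide what to do with such sequences.
#'
#' @param seq Character scalar, the nucleotide sequence.
#' @param id Identifier used in error messages.
#' @param on_invalid `"error"` (default) stops with a message naming the
#'   first offending position; `"drop"` returns `NULL` with a warning so a
#'   batch loader can skip the sequence.
#' @return A character vector of single residues, or `NULL` when an invalid
#'   sequence is dropped.
#' @export
validate_sequence <- function(seq, id = "sequence", on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) {
    if (on_invalid == "drop") {
      warning(sprintf("dropping '%s': empty sequence", id))
      return(NULL)
    }
    stop(sprintf("'%s': sequence is empty", id))
  }
  if (any(chars == "U")) {
    warning(sprintf("'%s': RNA input, mapping U to T", id))
    chars[chars == "U"] <- "T"
  }
  bad <- which(!(chars %in% DNA_BASES))
  if (length(bad) > 0L) {
    if (on_invalid == "drop") {
      warning(sprintf("dropping '%s': non-ACGT residue '%s' at position %d",
                      id, chars[bad[1L]], bad[1L]))
      return(NULL)
    }
    stop(sprintf("'%s': non-ACGT residue '%s' at position %d (and %d more)",
                 id, chars[bad[1L]], bad[1L], length(bad) - 1L))
  }
  chars
}

#' Load a FASTA file into a sequence panel
#'
#' Reads a (multi-)FASTA file with [Biostrings::readDNAStringSet()] and
#' returns a sequence panel: a data frame with columns `id`, `seq` and
#' `group`. Group labels may come from a two-column TSV (`id`, `group`),
#' from a single label applied to the whole file, or be left `NA`.
#'
#' @param fasta Path to a FASTA file.
#' @param groups Either `NULL`, a single group label for all records, or the
#'   path to a headerless two-column TSV mapping sequence ids to labels.
#' @param on_invalid Passed to [validate_sequence()]; `"drop"` skips
#'   sequences containing ambiguity codes with a warning.
#' @return A data frame with columns `id`, `seq`, `group`, `source`.
#' @export
read_fasta_panel <- function(fasta, groups = NULL, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  ss <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", fasta, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- as.character(ss)
  keep <- logical(length(ids))
  for (i in seq_along(ids)) {
    chars <- validate_sequence(seqs[[i]], id = ids[[i]], on_invalid = on_invalid)
    if (!is.null(chars)) {
      seqs[[i]] <- paste(chars, collapse = "")
      keep[[i]] <- TRUE
    }
  }
  panel <- data.frame(id = ids[keep], seq = unname(seqs[keep]),
                      group = NA_character_, source = fasta,
                      stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    if (length(groups) == 1L && file.exists(groups)) {
      map <- utils::read.table(groups, sep = "\t", header = FALSE,
                               col.names = c("id", "group"),
                               stringsAsFactors = FALSE)
      panel$group <- map$group[match(panel$id, map$id)]
    } else {
      panel$group <- as.character(groups)
    }
  }
  panel
}

#' Write a sequence panel to FASTA
#'
#' @param panel Data frame with columns `id` and `seq`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fasta_panel <- function(panel, file) {
  ss <- Biostrings::DNAStringSet(panel$seq)
  names(ss) <- panel$id
  Biostrings::writeXStringSet(ss, file)
  invisible(file)
}

# Internal: check a panel data.frame has what downstream operations need.
check_panel <- function(panel, need_group = FALSE) {
  stopifnot(is.data.frame(panel), all(c("id", "seq") %in% names(panel)),
            nrow(panel) >= 1L)
  if (anyDuplicated(panel$id)) stop("sequence ids must be unique within a panel")
  if (need_group) {
    if (!("group" %in% names(panel)) || anyNA(panel$group) || any(panel$group == "")) {
      bad <- if ("group" %in% names(panel)) {
        panel$id[is.na(panel$group) | panel$group == ""]
      } else panel$id
      stop("unlabeled sequences: ", paste(bad, collapse = ", "))
    }
  }
  invisible(panel)
}
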