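#' Construct a cassette-array annotation
#'
#' Holds the spans needed to draw an integron cassette array map for one
#' strain: the SCI parts (possibly split across an interspace), the IS
#' elements inside the array, and which side the integrase sits on.
#' Coordinates are 1-based inclusive (GFF convention). IS elements must
#' fall within the array envelope (first part start to last part end).
#'
#' @param strain Strain identifier.
#' @param parts Data frame with columns `start`, `end` (one row per SCI
#'   part).
#' @param is_elements Data frame with columns `start`, `end`,
#'   `orientation` (`"+"`, `"-"` or `"unknown"`) and optionally `family`.
#' @param integrase_side `"left"` or `"right"`; alternatively supply
#'   `integrase` coordinates and the side is derived from the integrase
#'   midpoint relative to the envelope midpoint.
#' @param integrase Optional numeric `c(start, end)` of the integrase gene.
#' @return An object of class `array_annotation`.
#' @export
array_annotation <- function(strain, parts, is_elements = NULL,
                             integrase_side = NULL, integrase = NULL) {
  stopifnot(is.data.frame(parts), all(c("start", "end") %in% names(parts)),
            nrow(parts) >= 1L, all(parts$start <= parts$end))
  env <- c(min(parts$start), max(parts$end))
  if (is.null(is_elements)) {
    is_elements <- data.frame(start = numeric(), end = numeric(),
                              orientation = character(), family = character(),
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(c("start", "end", "orientation") %in% names(is_elements)))
  if (!("family" %in% names(is_elements))) is_elements$family <- NA_character_
  stopifnot(all(is_elements$orientation %in% c("+", "-", "unknown")))
  outside <- is_elements$start < env[1] | is_elements$end > env[2]
  if (any(outside)) {
    stop("IS element(s) outside the array envelope [", env[1], ", ", env[2], "]: ",
         paste(sprintf("[%s,%s]", is_elements$start[outside],
                       is_elements$end[outside]), collapse = " "))
  }
  if (is.null(integrase_side)) {
    if (is.null(integrase)) stop("supply integrase_side or integrase coordinates")
    mid <- mean(integrase)
    integrase_side <- if (mid <= mean(env)) "left" else "right"
  }
  integrase_side <- match.arg(integrase_side, c("left", "right"))
  structure(list(strain = strain, parts = parts, is_elements = is_elements,
                 integrase_side = integrase_side, envelope = env),
            class = "array_annotation")
}

#' Normalize an array map to [0, 1] and orient the integrase left
#'
#' Linearly maps the array envelope onto `[0, 1]` and, when the integrase
#' sits on the right-hand side, reflects the map (`x -> 1 - x`) and flips
#' IS orientations so that every strain is drawn with its integrase on the
#' left. Gaps between SCI parts (the interspace) are flagged as open
#' intervals.
#'
#' @param annotation An [array_annotation()].
#' @return Object of class `normalized_map`: list with `strain`, `parts`,
#'   `is_elements` (normalized coordinates), `gaps`, `reflected`.
#' @export
normalize_map <- function(annotation) {
  stopifnot(inherits(annotation, "array_annotation"))
  env <- annotation$envelope
  span <- env[2] - env[1]
  if (span <= 0) stop("degenerate envelope: start == end")
  f <- function(x) (x - env[1]) / span
  parts <- data.frame(start = f(annotation$parts$start),
                      end = f(annotation$parts$end))
  ise <- annotation$is_elements
  ise_n <- data.frame(start = f(ise$start), end = f(ise$end),
                      orientation = ise$orientation, family = ise$family,
                      stringsAsFactors = FALSE)
  m <- structure(list(strain = annotation$strain,
                      parts = parts[order(parts$start), , drop = FALSE],
                      is_elements = ise_n,
                      gaps = NULL,
                      reflected = FALSE),
                 class = "normalized_map")
  if (annotation$integrase_side == "right") m <- reflect_map(m)
  m$gaps <- map_gaps(m$parts)
  m
}

# Internal: open intervals of [0,1] not covered by any part.
map_gaps <- function(parts) {
  p <- parts[order(parts$start), , drop = FALSE]
  gaps <- data.frame(start = numeric(), end = numeric())
  cur <- p$end[1]
  for (i in seq_len(nrow(p))[-1]) {
    if (p$start[i] > cur) {
      gaps <- rbind(gaps, data.frame(start = cur, end = p$start[i]))
    }
    cur <- max(cur, p$end[i])
  }
  gaps
}

#' Reflect a normalized map
#'
#' Applies `x -> 1 - x` to every interval and flips `+`/`-` orientations
#' (`unknown` is preserved). Applying the reflection twice is the identity
#' up to floating-point tolerance.
#'
#' @param map A `normalized_map`.
#' @return The reflected `normalized_map`.
#' @export
reflect_map <- function(map) {
  stopifnot(inherits(map, "normalized_map"))
  rf <- function(d) {
    new <- data.frame(start = 1 - d$end, end = 1 - d$start)
    extra <- setdiff(names(d), c("start", "end"))
    for (nm in extra) new[[nm]] <- d[[nm]]
    new  # row identity preserved; consumers sort when they need to
  }
  map$parts <- rf(map$parts)
  ise <- rf(map$is_elements)
  ise$orientation <- ifelse(ise$orientation == "+", "-",
                            ifelse(ise$orientation == "-", "+", "unknown"))
  map$is_elements <- ise
  map$gaps <- map_gaps(map$parts)
  map$reflected <- !map$reflected
  map
}

#' Segment invertible by recombination between two IS copies
#'
#' Two copies of an IS in inverted (opposite) orientation on one replicon
#' form a substrate for homologous recombination that inverts the segment
#' between them. This reports whether the pair is an inverted repeat and,
#' if so, the inter-IS segment under the convention that the segment spans
#' from the end of the upstream IS to the start of the downstream IS,
#' exclusive of the ISs themselves (1-based inclusive coordinates). No
#' sequence-level recombination is modeled.
#'
#' @param is_a,is_b Lists with `start`, `end`, `orientation`.
#' @return List with `status` (`"inverted_repeat"`, `"direct_repeat"` or
#'   `"indeterminate"`), and for inverted pairs `segment_start`,
#'   `segment_end`, `segment_length`.
#' @export
inversion_segment <- function(is_a, is_b) {
  for (x in list(is_a, is_b)) {
    stopifnot(all(c("start", "end", "orientation") %in% names(x)),
              x$start <= x$end,
              x$orientation %in% c("+", "-", "unknown"))
  }
  if (is_a$start <= is_b$end && is_b$start <= is_a$end) {
    stop("IS elements overlap; no defined inter-IS segment")
  }
  if (is_a$orientation == "unknown" || is_b$orientation == "unknown") {
    return(list(status = "indeterminate"))
  }
  if (is_a$orientation == is_b$orientation) {
    return(list(status = "direct_repeat"))
  }
  up <- if (is_a$start < is_b$start) is_a else is_b
  down <- if (is_a$start < is_b$start) is_b else is_a
  list(status = "inverted_repeat",
       segment_start = up$end + 1,
       segment_end = down$start - 1,
       segment_length = down$start - up$end - 1)
}

#' Read array annotations from a long-format TSV
#'
#' Expects columns `strain`, `feature_type` (`SCI_part`, `IS`,
#' `integrase`), `start`, `end`, `strand`, and builds one
#' [array_annotation()] per strain.
#'
#' @param file Path to the TSV.
#' @return Named list of `array_annotation` objects.
#' @export
read_array_table <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("strain", "feature_type", "start", "end", "strand") %in% names(tab)))
  out <- lapply(split(tab, tab$strain), function(d) {
    parts <- d[d$feature_type == "SCI_part", c("start", "end")]
    ise <- d[d$feature_type == "IS", , drop = FALSE]
    ise <- data.frame(start = ise$start, end = ise$end,
                      orientation = ifelse(ise$strand %in% c("+", "-"),
                                           ise$strand, "unknown"),
                      stringsAsFactors = FALSE)
    intg <- d[d$feature_type == "integrase", , drop = FALSE]
    array_annotation(strain = d$strain[1], parts = parts, is_elements = ise,
                     integrase = if (nrow(intg)) c(intg$start[1], intg$end[1]) else NULL,
                     integrase_side = if (nrow(intg)) NULL else "left")
  })
  out
}
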