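#' Heptapeptide variant sets
#'
#' The canonical WRKY heptapeptide is WRKYGQK; WRKYGKK is the common variant
#' of subgroup IIc (the only variant observed in gymnosperms such as Taxus
#' and Picea). The extended set adds variants reported from angiosperms
#' (e.g. soybean): WRKYGEK, WRKYGKR, WRKYEDK, WKKYGQK, WHQYGLK.
#'
#' @param set `"canonical"` (default) or `"extended"`.
#' @return Character vector of 7-letter patterns.
#' @export
wrky_variants <- function(set = c("canonical", "extended")) {
  set <- match.arg(set)
  canon <- c("WRKYGQK", "WRKYGKK")
  if (set == "canonical") return(canon)
  c(canon, "WRKYGEK", "WRKYGKR", "WRKYEDK", "WKKYGQK", "WHQYGLK")
}

#' Zinc-finger grammars
#'
#' The two metal-coordinating arrangements that type WRKY domains:
#' C2H2 = C-X(4-5)-C-X(22-23)-H-X(1)-H (Groups I and II) and
#' C2HC = C-X(7)-C-X(23)-H-X(1)-C (Group III). Spacer ranges are inclusive
#' residue counts between consecutive anchor residues.
#'
#' @param name `"C2H2"` or `"C2HC"`.
#' @return A list of class `zf_grammar` with fields `name`, `anchors`,
#'   `spacer_min`, `spacer_max`.
#' @export
zf_grammar <- function(name = c("C2H2", "C2HC")) {
  name <- match.arg(name)
  g <- switch(name,
    C2H2 = list(name = "C2H2", anchors = c("C", "C", "H", "H"),
                spacer_min = c(4L, 22L, 1L), spacer_max = c(5L, 23L, 1L)),
    C2HC = list(name = "C2HC", anchors = c("C", "C", "H", "C"),
                spacer_min = c(7L, 23L, 1L), spacer_max = c(7L, 23L, 1L)))
  validate_zf_grammar(g)
}

validate_zf_grammar <- function(g) {
  stopifnot(is.list(g), all(c("name", "anchors", "spacer_min", "spacer_max")
                            %in% names(g)))
  if (length(g$spacer_min) != length(g$anchors) - 1L ||
      length(g$spacer_max) != length(g$anchors) - 1L)
    stop("number of spacer ranges must equal number of anchors - 1")
  if (any(g$spacer_min < 0L) || any(g$spacer_min > g$spacer_max))
    stop("spacer ranges must satisfy 0 <= min <= max")
  class(g) <- "zf_grammar"
  g
}

#' Locate heptapeptide anchors in a protein
#'
#' Exact-string matching of the listed heptapeptide patterns; all distinct
#' start positions are reported left to right, each tagged with the variant
#' that matched. Coordinates are 0-based, half-open.
#'
#' @param record A single-row `protein_records` entry, or a plain sequence
#'   string.
#' @param variants Non-empty character vector of 7-letter patterns.
#' @return Data frame with columns `start`, `end`, `heptapeptide`, `variant`.
#' @export
find_heptapeptides <- function(record, variants = wrky_variants()) {
  seqstr <- if (is.character(record)) record[[1L]] else record$sequence[[1L]]
  if (!length(variants)) stop("variant list must be non-empty")
  if (any(nchar(variants) != 7L)) stop("all heptapeptide patterns must have 7 letters")
  hits <- lapply(variants, function(v) {
    m <- gregexpr(v, seqstr, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    data.frame(start = as.integer(m) - 1L, variant = v,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    return(data.frame(start = integer(), end = integer(),
                      heptapeptide = character(), variant = character(),
                      stringsAsFactors = FALSE))
  hits <- hits[!duplicated(hits$start), , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  data.frame(start = hits$start, end = hits$start + 7L,
             heptapeptide = substring(seqstr, hits$start + 1L, hits$start + 7L),
             variant = ifelse(hits$variant == "WRKYGQK", "canonical", hits$variant),
             stringsAsFactors = FALSE)
}

#' Match a zinc-finger grammar downstream of a heptapeptide
#'
#' Searches at most `window` residues downstream of the heptapeptide end for
#' an arrangement of the grammar's anchor residues whose spacings satisfy all
#' ranges. The earliest arrangement wins: lowest first-C position, and among
#' arrangements sharing the first C, the lexicographically smallest position
#' vector.
#'
#' @param record Protein record or sequence string.
#' @param anchor_end 0-based position one past the heptapeptide (its `end`).
#' @param grammar A `zf_grammar`.
#' @param window Maximum residues scanned downstream of the heptapeptide end.
#' @return Integer vector of 0-based anchor positions, or `NULL` if no valid
#'   arrangement exists.
#' @export
match_zinc_finger <- function(record, anchor_end, grammar, window = 80L) {
  seqstr <- if (is.character(record)) record[[1L]] else record$sequence[[1L]]
  stopifnot(inherits(grammar, "zf_grammar"))
  chars <- strsplit(seqstr, "")[[1L]]
  lo <- anchor_end + 1L                      # 1-based index of first scanned residue
  hi <- min(length(chars), anchor_end + window)
  if (lo > hi) return(NULL)
  first_sites <- which(chars[lo:hi] == grammar$anchors[1L]) + lo - 1L
  n_anchor <- length(grammar$anchors)
  # depth-first search over spacer choices in increasing order; the first
  # complete assignment is the earliest/lexicographically smallest one
  extend <- function(pos) {
    k <- length(pos)
    if (k == n_anchor) return(pos)
    for (gap in grammar$spacer_min[k]:grammar$spacer_max[k]) {
      nxt <- pos[k] + gap + 1L
      if (nxt > hi) next
      if (chars[nxt] == grammar$anchors[k + 1L]) {
        res <- extend(c(pos, nxt))
        if (!is.null(res)) return(res)
      }
    }
    NULL
  }
  for (p1 in first_sites) {
    res <- extend(p1)
    if (!is.null(res)) return(as.integer(res - 1L))  # back to 0-based
  }
  NULL
}

#' Scan one protein for WRKY domains
#'
#' One domain is emitted per heptapeptide anchor. Zinc-finger typing tries
#' C2H2 first, then C2HC; an anchor matching both grammars is flagged
#' ambiguous and typed C2H2 (the majority class), leaving the final call to
#' phylogenetic placement. Anchors whose domain would overlap an earlier
#' domain's residues are dropped (leftmost anchor wins). When two or more
#' domains survive on one protein the first is tagged `N` and the last `C`
#' (`M` for any in between); a lone domain is tagged `single`.
#'
#' @param record A single-row `protein_records` entry.
#' @param variants Heptapeptide patterns to anchor on.
#' @param window Zinc-finger search window (residues downstream of the
#'   heptapeptide end).
#' @param grammars List of the two grammars (order = tie-break preference).
#' @return Data frame of class `wrky_domains`, one row per domain, with
#'   0-based half-open coordinates: `protein_id`, `domain_index`, `start`,
#'   `end`, `hepta_start`, `hepta_end`, `heptapeptide`, `variant`, `zf_type`,
#'   `zf_positions` (comma-joined 0-based), `ambiguous`, `terminal`.
#' @export
scan_protein <- function(record, variants = wrky_variants(), window = 80L,
                         grammars = list(zf_grammar("C2H2"), zf_grammar("C2HC"))) {
  if (is.character(record)) record <- protein_records("query", record)
  stopifnot(nrow(record) == 1L, length(grammars) >= 1L)
  anchors <- find_heptapeptides(record, variants)
  rows <- list()
  last_end <- -1L
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    if (a$start < last_end) next                 # overlap: keep earlier anchor
    matches <- lapply(grammars, function(g)
      match_zinc_finger(record, a$end, g, window))
    hit <- which(!vapply(matches, is.null, logical(1L)))
    if (length(hit)) {
      use <- hit[1L]
      zf <- matches[[use]]
      row <- data.frame(
        protein_id = record$id, start = a$start, end = zf[length(zf)] + 1L,
        hepta_start = a$start, hepta_end = a$end,
        heptapeptide = a$heptapeptide, variant = a$variant,
        zf_type = grammars[[use]]$name,
        zf_positions = paste(zf, collapse = ","),
        ambiguous = length(hit) > 1L, stringsAsFactors = FALSE)
    } else {
      row <- data.frame(
        protein_id = record$id, start = a$start, end = a$end,
        hepta_start = a$start, hepta_end = a$end,
        heptapeptide = a$heptapeptide, variant = a$variant,
        zf_type = "incomplete", zf_positions = "",
        ambiguous = FALSE, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- row
    last_end <- row$end
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), start = integer(), end = integer(),
               hepta_start = integer(), hepta_end = integer(),
               heptapeptide = character(), variant = character(),
               zf_type = character(), zf_positions = character(),
               ambiguous = logical(), stringsAsFactors = FALSE)
  n <- nrow(out)
  out$domain_index <- seq_len(n)
  out$terminal <- if (n >= 2L)
    c("N", rep("M", n - 2L), "C") else rep("single", n)
  class(out) <- c("wrky_domains", "data.frame")
  out
}

#' Scan a collection of proteins for WRKY domains
#'
#' @inheritParams scan_protein
#' @param records A `protein_records` collection.
#' @return A `wrky_domains` data frame over all proteins.
#' @export
scan_proteins <- function(records, variants = wrky_variants(), window = 80L,
                          grammars = list(zf_grammar("C2H2"), zf_grammar("C2HC"))) {
  stopifnot(inherits(records, "protein_records"))
  parts <- lapply(seq_len(nrow(records)), function(i)
    scan_protein(records[i, , drop = FALSE], variants, window, grammars))
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(out)) out <- scan_protein(protein_records("x", "A"), variants,
                                        window, grammars)[0, ]
  class(out) <- c("wrky_domains", "data.frame")
  out
}

#' Extract domain subsequences as protein records
#'
#' Cuts each scanned domain out of its source protein, optionally with
#' flanking residues (clipped at the sequence bounds). For proteins carrying
#' an N- and C-terminal domain the extracted records are suffixed `-N` / `-C`
#' (`-M` for middle domains); single domains keep the protein id.
#'
#' @param records The `protein_records` the domains were scanned from.
#' @param domains A `wrky_domains` data frame.
#' @param flank Residues added on each side (>= 0).
#' @return A `protein_records` collection of domain subsequences.
#' @export
extract_domain_sequences <- function(records, domains, flank = 0L) {
  stopifnot(inherits(records, "protein_records"), flank >= 0L)
  if (nrow(domains) == 0L)
    return(protein_records(character(), character()))
  seqs <- stats::setNames(records$sequence, records$id)
  ids <- character(nrow(domains))
  subseq <- character(nrow(domains))
  for (i in seq_len(nrow(domains))) {
    d <- domains[i, ]
    s <- seqs[[d$protein_id]]
    from <- max(0L, d$start - flank)
    to <- min(nchar(s), d$end + flank)
    subseq[i] <- substring(s, from + 1L, to)
    ids[i] <- if (d$terminal == "single") d$protein_id else
      paste0(d$protein_id, "-", d$terminal)
  }
  protein_records(ids, subseq)
}

#' Re-validate a scanned zinc finger against its grammar
#'
#' Checks that the reported anchor positions are strictly increasing, carry
#' the grammar's residues in the source sequence, and that consecutive
#' spacings fall inside the grammar's ranges.
#'
#' @param sequence Source protein sequence.
#' @param zf_positions Integer vector of 0-based anchor positions.
#' @param grammar A `zf_grammar`.
#' @return `TRUE` if the arrangement satisfies the grammar.
#' @export
validate_zinc_finger <- function(sequence, zf_positions, grammar) {
  stopifnot(inherits(grammar, "zf_grammar"))
  p <- as.integer(zf_positions)
  if (length(p) != length(grammar$anchors)) return(FALSE)
  if (any(diff(p) <= 0L)) return(FALSE)
  res <- substring(sequence, p + 1L, p + 1L)
  if (!all(res == grammar$anchors)) return(FALSE)
  gaps <- diff(p) - 1L
  all(gaps >= grammar$spacer_min & gaps <= grammar$spacer_max)
}
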