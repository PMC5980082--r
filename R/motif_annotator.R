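MOTIF_CLASSES <- c("EAR_LxLxL", "EAR_DLNxxP", "LxxLL", "HARF", "LeucineZipper")

motif_hit_frame <- function(protein_id = character(), class = character(),
                            subtype = character(), match = character(),
                            start = integer(), end = integer()) {
  data.frame(protein_id = protein_id, class = class, subtype = subtype,
             match = match, start = start, end = end,
             stringsAsFactors = FALSE)
}

# all (overlapping) matches of a regex; returns 0-based half-open intervals
regex_hits <- function(seqstr, pattern, len) {
  starts <- integer(0)
  from <- 1L
  repeat {
    m <- regexpr(pattern, substring(seqstr, from), perl = TRUE)
    if (m == -1L) break
    starts <- c(starts, from + m - 1L)
    from <- from + m       # step one past the last start: overlaps allowed
  }
  data.frame(start = starts - 1L, end = starts - 1L + len)
}

seq_of <- function(record) {
  if (is.character(record)) record[[1L]] else record$sequence[[1L]]
}

id_of <- function(record) {
  if (is.character(record)) "query" else record$id[[1L]]
}

#' Find LxxLL coactivator-interaction motifs
#'
#' All (possibly overlapping) occurrences of the 5-mer L-x-x-L-L; the
#' subtype is the literal matched 5-mer (e.g. LSQLL).
#'
#' @param record A single-row `protein_records` entry or sequence string.
#' @return A motif-hit data frame (`protein_id`, `class`, `subtype`,
#'   `match`, `start`, `end`; 0-based half-open).
#' @export
find_lxxll <- function(record) {
  s <- seq_of(record)
  h <- regex_hits(s, "L..LL", 5L)
  if (!nrow(h)) return(motif_hit_frame())
  lit <- substring(s, h$start + 1L, h$end)
  motif_hit_frame(rep(id_of(record), nrow(h)), "LxxLL", lit, lit,
                  h$start, h$end)
}

#' Find the HARF motif of Group IId WRKYs
#'
#' Occurrences of the 11-mer RTGHARFRR(A/G)P, a peptide of unknown function
#' inside the calmodulin-binding region of some Group IId members.
#'
#' @inheritParams find_lxxll
#' @return A motif-hit data frame.
#' @export
find_harf <- function(record) {
  s <- seq_of(record)
  h <- regex_hits(s, "RTGHARFRR[AG]P", 11L)
  if (!nrow(h)) return(motif_hit_frame())
  lit <- substring(s, h$start + 1L, h$end)
  motif_hit_frame(rep(id_of(record), nrow(h)), "HARF", lit, lit,
                  h$start, h$end)
}

#' Find EAR transcriptional-repression motifs
#'
#' Two structural classes are matched: `EAR_LxLxL` (core L-x-L-x-L; the
#' reported subtype carries one residue of trailing context when available,
#' reproducing conventional 6-letter subtype names such as LKLDLY or
#' LKLALS) and `EAR_DLNxxP` (D-L-N-x-x-P, e.g. DLNHNP). All overlapping
#' occurrences are reported.
#'
#' @inheritParams find_lxxll
#' @return A motif-hit data frame.
#' @export
find_ear <- function(record) {
  s <- seq_of(record)
  id <- id_of(record)
  out <- list()
  h <- regex_hits(s, "L.L.L", 5L)
  if (nrow(h)) {
    # one trailing residue of context when available (6-mer subtype names)
    ctx_end <- pmin(h$end + 1L, nchar(s))
    lit <- substring(s, h$start + 1L, h$end)
    sub <- substring(s, h$start + 1L, ctx_end)
    out[[1L]] <- motif_hit_frame(rep(id, nrow(h)), "EAR_LxLxL", sub, lit,
                                 h$start, h$end)
  }
  h <- regex_hits(s, "DLN..P", 6L)
  if (nrow(h)) {
    lit <- substring(s, h$start + 1L, h$end)
    out[[2L]] <- motif_hit_frame(rep(id, nrow(h)), "EAR_DLNxxP", lit, lit,
                                 h$start, h$end)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) motif_hit_frame() else res[order(res$start), , drop = FALSE]
}

#' Heuristic leucine-zipper detector
#'
#' Reports maximal stretches in which at least `min_repeats` leucines occur
#' at an exact `period`-residue spacing (the heptad repeat). With
#' `allow_iv = TRUE`, isoleucine or valine may substitute at internal
#' repeat positions, but the first and last position must be leucine. This
#' is a heuristic construction, not a profile match against any domain
#' database.
#'
#' @inheritParams find_lxxll
#' @param period Repeat spacing in residues (default 7).
#' @param min_repeats Minimum number of repeat positions (default 4).
#' @param allow_iv Permit I/V at internal repeat positions.
#' @return A motif-hit data frame; the subtype records the repeat count,
#'   e.g. `"L7x4"`.
#' @export
find_leucine_zipper <- function(record, period = 7L, min_repeats = 4L,
                                allow_iv = FALSE) {
  if (period < 1L || min_repeats < 1L) stop("period and min_repeats must be positive")
  s <- seq_of(record)
  chars <- strsplit(s, "")[[1L]]
  internal_ok <- if (allow_iv) c("L", "I", "V") else "L"
  hits <- motif_hit_frame()
  n <- length(chars)
  claimed <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (chars[i] != "L" || claimed[i]) next
    run <- i
    k <- i + period
    while (k <= n && chars[k] %in% internal_ok) {
      run <- c(run, k)
      k <- k + period
    }
    while (length(run) && chars[run[length(run)]] != "L")
      run <- run[-length(run)]           # last position must be leucine
    if (length(run) >= min_repeats) {
      claimed[run] <- TRUE
      st <- run[1L] - 1L
      en <- run[length(run)]
      hits <- rbind(hits, motif_hit_frame(
        id_of(record), "LeucineZipper",
        sprintf("L%dx%d", period, length(run)),
        substring(s, st + 1L, en), st, en))
    }
  }
  hits
}

#' Annotate accessory motifs across a protein collection
#'
#' Runs the requested motif classes over every record and returns the
#' concatenated, coordinate-sorted hits. Records never interact: the result
#' on a collection equals the union of per-record results.
#'
#' @param records A `protein_records` collection.
#' @param classes Subset of
#'   `c("EAR_LxLxL", "EAR_DLNxxP", "LxxLL", "HARF", "LeucineZipper")`.
#' @param ... Extra arguments passed to [find_leucine_zipper()].
#' @return A motif-hit data frame sorted by protein id and start; per-class
#'   counts in `attr(, "class_counts")`.
#' @export
annotate_motifs <- function(records, classes = MOTIF_CLASSES, ...) {
  stopifnot(inherits(records, "protein_records"))
  bad <- setdiff(classes, MOTIF_CLASSES)
  if (length(bad)) stop("unknown motif class(es): ", paste(bad, collapse = ", "))
  parts <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    if (any(c("EAR_LxLxL", "EAR_DLNxxP") %in% classes)) {
      e <- find_ear(rec)
      parts[[length(parts) + 1L]] <- e[e$class %in% classes, , drop = FALSE]
    }
    if ("LxxLL" %in% classes) parts[[length(parts) + 1L]] <- find_lxxll(rec)
    if ("HARF" %in% classes) parts[[length(parts) + 1L]] <- find_harf(rec)
    if ("LeucineZipper" %in% classes)
      parts[[length(parts) + 1L]] <- find_leucine_zipper(rec, ...)
  }
  out <- do.call(rbind, c(list(motif_hit_frame()), parts))
  out <- out[order(match(out$protein_id, records$id), out$start,
                   match(out$class, MOTIF_CLASSES)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "class_counts") <- table(factor(out$class, levels = MOTIF_CLASSES))
  out
}

#' Merge externally computed domain annotations
#'
#' Profile-based domains (e.g. Pfam Plant_zf_clust, CaMBD, HSF) are not
#' computed by this package; they can be imported from a TSV
#' (`protein_id`, `domain_name`, `start`, `end`, `source`) and merged with
#' motif hits into one report.
#'
#' @param hits A motif-hit data frame.
#' @param path TSV of external annotations.
#' @return Combined data frame with a `source` column (`"wrkyscan"` for
#'   in-package hits).
#' @export
merge_external_annotations <- function(hits, path) {
  ext <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("protein_id", "domain_name", "start", "end", "source")
  miss <- setdiff(need, names(ext))
  if (length(miss)) stop("annotation TSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  own <- data.frame(protein_id = hits$protein_id, domain_name = hits$class,
                    start = hits$start, end = hits$end, source = "wrkyscan",
                    stringsAsFactors = FALSE)
  out <- rbind(own, ext[, need])
  out[order(out$protein_id, out$start), , drop = FALSE]
}
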