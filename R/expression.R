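#' Relative expression by the 2^-ddCt method
#'
#' Classic qPCR quantification: replicate Ct values are averaged per
#' (sample, gene) well group, dCt = mean Ct(target) - mean Ct(reference) is
#' formed per sample, ddCt = dCt(sample) - dCt(calibrator), and relative
#' expression is 2^-ddCt (the calibrator maps to 1 exactly). No
#' amplification-efficiency correction is applied.
#'
#' @param ct A `ct_table` (long format; one row per replicate well).
#' @param target Target gene id.
#' @param reference Reference (housekeeping) gene id, e.g. actin.
#' @param calibrator Sample label used as the calibrator (relative
#'   expression 1).
#' @return Data frame with one row per sample: `sample`, `gene`,
#'   `treatment`/`timepoint` when present, `dct`, `ddct`, `rel_expr`
#'   (= 2^-ddCt) and `dispersion` (sd of the target replicate Ct values).
#' @export
ddct <- function(ct, target, reference, calibrator) {
  ct <- ct_table(as.data.frame(ct))
  samples <- unique(ct$sample)
  if (!calibrator %in% samples) stop("calibrator sample '", calibrator,
                                     "' not present in Ct table")
  rows <- lapply(samples, function(s) {
    tgt <- ct$ct[ct$sample == s & ct$gene == target]
    ref <- ct$ct[ct$sample == s & ct$gene == reference]
    if (!length(ref))
      stop("normalization error: no reference-gene ('", reference,
           "') wells for sample '", s, "'")
    if (!length(tgt))
      stop("no target-gene ('", target, "') wells for sample '", s, "'")
    extra <- ct[ct$sample == s, intersect(c("treatment", "timepoint"),
                                          names(ct)), drop = FALSE]
    data.frame(sample = s, gene = target,
               extra[1L, , drop = FALSE],
               dct = mean(tgt) - mean(ref),
               dispersion = if (length(tgt) > 1L) stats::sd(tgt) else 0,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  cal_dct <- out$dct[out$sample == calibrator]
  out$ddct <- out$dct - cal_dct
  out$rel_expr <- 2^(-out$ddct)
  out
}

#' Log2 fold-change contrasts over an expression matrix
#'
#' For each named contrast (numerator column, denominator column) the log2
#' fold change of every gene is the difference of the two log2-scale
#' columns. Direction is called from the sign once |log2FC| reaches the
#' threshold; genes masked in either column propagate as missing.
#'
#' @param expr An `expression_matrix` (values on log2 scale).
#' @param contrasts Named list; each element `c(numerator, denominator)`
#'   column labels.
#' @param lfc_threshold Minimum |log2FC| to call a direction (default 1).
#' @return Data frame with `gene`, `contrast`, `log2fc`, `direction`
#'   (`up`/`down`/`unchanged`/`missing`), `missing`.
#' @export
contrast_matrix <- function(expr, contrasts, lfc_threshold = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  vals <- expr$values
  unknown <- setdiff(unlist(contrasts), colnames(vals))
  if (length(unknown))
    stop("contrast refers to unknown column(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(names(contrasts)) || any(!nzchar(names(contrasts))))
    stop("contrasts must be named")
  out <- lapply(names(contrasts), function(nm) {
    cc <- contrasts[[nm]]
    lfc <- vals[, cc[1L]] - vals[, cc[2L]]
    miss <- expr$mask[, cc[1L]] | expr$mask[, cc[2L]]
    dir <- ifelse(miss, "missing",
                  ifelse(abs(lfc) >= lfc_threshold,
                         ifelse(lfc > 0, "up", "down"), "unchanged"))
    data.frame(gene = rownames(vals), contrast = nm,
               log2fc = ifelse(miss, NA_real_, lfc), direction = dir,
               missing = miss, stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Tally contrast directions
#'
#' @param results Output of [contrast_matrix()].
#' @return Data frame with one row per contrast and columns `up`, `down`,
#'   `unchanged`, `missing`, `n` (the row tallies always sum to `n`).
#' @export
direction_counts <- function(results) {
  lv <- c("up", "down", "unchanged", "missing")
  out <- lapply(unique(results$contrast), function(nm) {
    d <- results$direction[results$contrast == nm]
    tt <- table(factor(d, levels = lv))
    data.frame(contrast = nm, up = tt[["up"]], down = tt[["down"]],
               unchanged = tt[["unchanged"]], missing = tt[["missing"]],
               n = length(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Hierarchical clustering of genes for heatmap rendering
#'
#' Agglomerative clustering (default: average linkage on Euclidean
#' distances) of the gene rows of an expression matrix. Rows containing
#' masked cells are dropped by default, or zero-imputed behind an explicit
#' flag. Equal-distance merge ties are resolved by `stats::hclust`'s
#' deterministic lowest-index rule, so the output is reproducible for a
#' fixed row order.
#'
#' @param expr An `expression_matrix`.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param metric Distance metric for [stats::dist()].
#' @param impute_zero If `TRUE`, masked cells are set to 0 instead of
#'   dropping their rows.
#' @return List with `order` (leaf gene ids, left to right), `hclust` (the
#'   merge tree) and `dropped` (gene ids excluded for missingness).
#' @export
cluster_genes <- function(expr, linkage = "average", metric = "euclidean",
                          impute_zero = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"))
  vals <- expr$values
  if (impute_zero) {
    vals[expr$mask] <- 0
    dropped <- character(0)
  } else {
    keep <- rowSums(expr$mask) == 0L
    dropped <- rownames(vals)[!keep]
    vals <- vals[keep, , drop = FALSE]
  }
  if (nrow(vals) < 2L)
    stop("clustering needs >= 2 usable gene rows (have ", nrow(vals), ")")
  hc <- stats::hclust(stats::dist(vals, method = metric), method = linkage)
  list(order = rownames(vals)[hc$order], hclust = hc, dropped = dropped)
}
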