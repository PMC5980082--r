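# Residue pools. Domain templates avoid C and H outside the zinc-finger
# anchors (so anchor arrangements are unambiguous), W outside the
# heptapeptide (so no accidental anchors) and L everywhere (so accessory
# motif patterns cannot arise inside domains). Background avoids C for the
# same anchor-uniqueness reason; other residues are rejection-checked.
TEMPLATE_AA <- c("A", "D", "E", "F", "G", "I", "K", "M", "N", "P", "Q",
                 "R", "S", "T", "V", "Y")
BACKGROUND_AA <- setdiff(AA_ALPHABET, c("C", "X"))

# Minimal-standard linear congruential generator: templates are a pure
# function of hard-coded seeds, independent of R's RNG stream, so the
# generator and the scanner share no code path and template bytes never
# depend on session state.
lcg_new <- function(seed) {
  state <- as.double(seed %% 2147483647L)
  if (state == 0) state <- 42
  list(next_unif = function() {
    state <<- (16807 * state) %% 2147483647
    state / 2147483647
  })
}

lcg_chars <- function(rng, n, pool = TEMPLATE_AA) {
  vapply(seq_len(n), function(i) pool[floor(rng$next_unif() * length(pool)) + 1L],
         character(1L))
}

lcg_mutate <- function(chars, frac, rng, pool = TEMPLATE_AA) {
  for (i in seq_along(chars)) {
    if (rng$next_unif() < frac) {
      repl <- pool[floor(rng$next_unif() * length(pool)) + 1L]
      if (repl == chars[i])
        repl <- pool[(match(repl, pool) %% length(pool)) + 1L]
      chars[i] <- repl
    }
  }
  chars
}

# Fixed per-label zinc-finger spacer lengths (within the grammar ranges).
# Each subgroup template carries one characteristic spacing so that
# same-label domains stay column-homologous under the internal-gap-free
# anchored alignment.
TEMPLATE_SPACERS <- list(
  "I-N" = c(4L, 23L), "I-C" = c(4L, 23L),
  "IIa" = c(5L, 23L), "IIb" = c(5L, 23L), "IIc" = c(4L, 22L),
  "IId" = c(5L, 22L), "IIe" = c(5L, 22L), "III" = c(7L, 23L))

#' Consensus WRKY domain templates per subgroup
#'
#' Hand-built fixture domains conforming to each subgroup's grammar (not
#' copied from any database). All templates descend from one ancestral
#' segment set; subgroup templates are derived through controlled mutation
#' fractions that mirror the superclade structure of the family (I-N/I-C
#' from one parent, IIa/IIb from another, IId/IIe from a third, IIc and III
#' on their own branches), so reference panels built from them reproduce
#' the expected tree shape.
#'
#' @return Named list (labels I-N, I-C, IIa-IIe, III); each element has
#'   `segments` (pre, linker, sp1, sp2, sp3, post character vectors),
#'   `spacers` (the fixed s1/s2 lengths) and `grammar` (`"C2H2"` or
#'   `"C2HC"`).
#' @export
wrky_domain_templates <- function() {
  base_rng <- lcg_new(20180326L)
  seg_len <- c(pre = 10L, linker = 12L, sp1 = 7L, sp2 = 23L, sp3 = 1L,
               post = 6L)
  base <- lapply(seg_len, function(n) lcg_chars(base_rng, n))
  derive <- function(parent, frac, seed) {
    rng <- lcg_new(seed)
    lapply(parent, lcg_mutate, frac = frac, rng = rng)
  }
  p_I  <- derive(base, 0.25, 101L)
  p_ab <- derive(base, 0.25, 202L)
  p_c  <- derive(base, 0.25, 303L)
  p_de <- derive(base, 0.25, 404L)
  p_3  <- derive(base, 0.30, 505L)
  segs <- list(
    "I-N" = derive(p_I, 0.10, 111L), "I-C" = derive(p_I, 0.10, 112L),
    "IIa" = derive(p_ab, 0.08, 221L), "IIb" = derive(p_ab, 0.08, 222L),
    "IIc" = p_c,
    "IId" = derive(p_de, 0.08, 441L), "IIe" = derive(p_de, 0.08, 442L),
    "III" = p_3)
  lapply(stats::setNames(names(segs), names(segs)), function(lab) {
    list(segments = segs[[lab]], spacers = TEMPLATE_SPACERS[[lab]],
         grammar = if (lab == "III") "C2HC" else "C2H2")
  })
}

#' Generate one ground-truth WRKY domain sequence
#'
#' Starts from the subgroup's consensus template, assembles
#' pre + heptapeptide + linker + zinc finger with the template's spacer
#' lengths, and applies substitutions at the given per-site rate, never
#' touching the heptapeptide or the zinc-finger anchor residues.
#' Substitution letters are drawn from a pool excluding C, H, W and L so
#' that the planted anchor arrangement (and motif truth) stays unique at
#' any rate. Uses R's RNG stream; seed with [set.seed()] upstream.
#'
#' @param label One of I-N, I-C, IIa-IIe, III (bare `"I"` is an alias for
#'   `"I-N"`).
#' @param rate Per-site substitution probability in \[0, 1).
#' @param heptapeptide The planted heptapeptide (default canonical).
#' @param spacer_jitter If `TRUE`, spacer lengths are drawn uniformly from
#'   the grammar ranges instead of the template's fixed values (breaks
#'   column homology between same-label domains; see the methods vignette).
#' @return List with `sequence` and `truth` (a one-row data frame:
#'   `label`, `heptapeptide`, `hepta_start`, `zf_type`, `zf_positions`).
#' @export
make_domain <- function(label, rate = 0, heptapeptide = "WRKYGQK",
                        spacer_jitter = FALSE) {
  if (label == "I") label <- "I-N"
  tpl <- wrky_domain_templates()[[label]]
  if (is.null(tpl)) stop("unknown subgroup label: ", label)
  stopifnot(rate >= 0, rate < 1)
  g <- zf_grammar(tpl$grammar)
  sp <- if (spacer_jitter) {
    c(sample(g$spacer_min[1L]:g$spacer_max[1L], 1L),
      sample(g$spacer_min[2L]:g$spacer_max[2L], 1L))
  } else tpl$spacers
  s <- tpl$segments
  chars <- c(s$pre, strsplit(heptapeptide, "")[[1L]], s$linker,
             "C", s$sp1[seq_len(sp[1L])], "C", s$sp2[seq_len(sp[2L])],
             "H", s$sp3, g$anchors[4L], s$post)
  hepta_start <- length(s$pre)                       # 0-based
  p1 <- hepta_start + 7L + length(s$linker)
  zf <- c(p1, p1 + sp[1L] + 1L)
  zf <- c(zf, zf[2L] + sp[2L] + 1L)
  zf <- c(zf, zf[3L] + 2L)
  protected <- c(hepta_start:(hepta_start + 6L), zf) + 1L  # 1-based
  if (rate > 0) {
    pool <- setdiff(TEMPLATE_AA, "L")   # template pool already excludes L
    for (i in setdiff(seq_along(chars), protected)) {
      if (stats::runif(1L) < rate) {
        repl <- sample(pool, 1L)
        if (repl == chars[i]) repl <- sample(setdiff(pool, repl), 1L)
        chars[i] <- repl
      }
    }
  }
  list(sequence = paste(chars, collapse = ""),
       truth = data.frame(label = label, heptapeptide = heptapeptide,
                          hepta_start = hepta_start, zf_type = g$name,
                          zf_positions = paste(zf, collapse = ","),
                          stringsAsFactors = FALSE))
}

# Planted motif literals per class (and label-specific LxxLL flavours).
MOTIF_LITERALS <- list(
  LxxLL = c("I" = "LSQLL", "IId" = "LIRLL", "III" = "LYQLL",
            default = "LSQLL"),
  EAR_LxLxL = "LKLDLY",
  EAR_DLNxxP = "DLNHNP",
  HARF = "RTGHARFRRAP",
  LeucineZipper = "LADEKAGLQRSTVGLEAGKDAL")

# Default motif-planting plan, mirroring where the motif classes are
# observed in conifer/Arabidopsis WRKYs: LxxLL in Groups I, IId and III;
# EAR and a leucine zipper in IIb; HARF in IId.
default_motif_plan <- function() {
  list("I" = "LxxLL",
       "IIb" = c("EAR_LxLxL", "LeucineZipper"),
       "IId" = c("HARF", "LxxLL"),
       "III" = "LxxLL")
}

motif_literal <- function(class, label) {
  lits <- MOTIF_LITERALS[[class]]
  if (length(lits) == 1L) return(unname(lits))
  grp <- if (label %in% names(lits)) label else "default"
  unname(lits[[grp]])
}

# Patterns that must never arise by accident in background sequence.
forbidden_patterns <- function() {
  c(wrky_variants("extended"), "L..LL", "L.L.L", "DLN..P", "RTGHARFRR[AG]P")
}

# leucine runs on an exact 7-periodic raster with >= min_repeats members;
# returns a list of 1-based position vectors (maximal runs only)
zipper_runs <- function(chars, period = 7L, min_repeats = 4L) {
  is_l <- chars == "L"
  runs <- list()
  seen <- rep(FALSE, length(chars))
  for (i in which(is_l)) {
    if (seen[i]) next
    run <- i
    k <- i + period
    while (k <= length(chars) && is_l[k]) { run <- c(run, k); k <- k + period }
    seen[run] <- TRUE
    if (length(run) >= min_repeats) runs[[length(runs) + 1L]] <- run
  }
  runs
}

# Replace residues inside `mutable` until no forbidden pattern with a
# mutable position remains (planted features are protected and skipped).
scrub_sequence <- function(seqstr, mutable) {
  pats <- forbidden_patterns()
  for (iter in 1:1000) {
    chars <- strsplit(seqstr, "")[[1L]]
    hit <- 0L
    for (p in pats) {
      m <- gregexpr(p, seqstr, perl = TRUE)[[1L]]
      if (m[1L] == -1L) next
      lens <- attr(m, "match.length")
      for (k in seq_along(m)) {
        cand <- intersect(m[k]:(m[k] + lens[k] - 1L), mutable)
        if (length(cand)) { hit <- cand[1L]; break }
      }
      if (hit) break
    }
    if (hit == 0L) {
      for (run in zipper_runs(chars)) {
        cand <- intersect(run, mutable)
        if (length(cand)) { hit <- cand[1L]; break }
      }
    }
    if (hit == 0L) return(seqstr)
    chars[hit] <- "A"
    seqstr <- paste(chars, collapse = "")
  }
  warning("background scrub did not converge")
  seqstr
}

#' Generate one ground-truth WRKY protein
#'
#' Embeds one WRKY domain (two for Group I: an N- then a C-terminal domain
#' separated by at least 20 background residues) in random background
#' sequence, and plants accessory motifs in the C-terminal background
#' according to the plan. Background composition is uniform over the
#' standard residues excluding cysteine, with rejection-scrubbing of any
#' accidental heptapeptide or motif pattern, so the planted truth is the
#' unique parse of the sequence.
#'
#' @param id Protein identifier.
#' @param label Group label: I, IIa-IIe or III.
#' @param rate Domain substitution rate (background is always random).
#' @param motif_plan Named list mapping group labels to motif classes to
#'   plant (default [default_motif_plan()]); use `list()` for none.
#' @param heptapeptide Planted heptapeptide.
#' @return List with `id`, `sequence`, `label`, `domains` (truth rows with
#'   absolute 0-based coordinates) and `motifs` (truth rows: class,
#'   subtype, start, end).
#' @export
make_protein <- function(id, label, rate = 0, motif_plan = default_motif_plan(),
                         heptapeptide = "WRKYGQK") {
  stopifnot(label %in% c("I", GROUP_LABELS))
  bg <- function(n) paste(sample(BACKGROUND_AA, n, replace = TRUE),
                          collapse = "")
  dom_labels <- if (label == "I") c("I-N", "I-C") else label
  doms <- lapply(dom_labels, make_domain, rate = rate,
                 heptapeptide = heptapeptide)
  nterm <- bg(sample(20:50, 1L))
  mid <- if (label == "I") bg(sample(25:60, 1L)) else NULL
  # C-terminal background with planted motifs, each padded by 4 inert
  # glycines on both sides
  classes <- motif_plan[[label]]
  cterm_parts <- bg(sample(15:30, 1L))
  motif_truth <- list()
  for (cl in classes) {
    lit <- motif_literal(cl, label)
    cterm_parts <- c(cterm_parts, "GGGG", lit, "GGGG", bg(sample(10:25, 1L)))
  }
  pieces <- c(nterm, doms[[1L]]$sequence,
              if (!is.null(mid)) c(mid, doms[[2L]]$sequence),
              cterm_parts)
  seqstr <- paste(pieces, collapse = "")
  # absolute coordinates of planted features
  lens <- nchar(pieces)
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  dom_piece <- if (label == "I") c(2L, 4L) else 2L
  dom_rows <- lapply(seq_along(dom_labels), function(k) {
    tr <- doms[[k]]$truth
    off <- offsets[dom_piece[k]]
    zf <- as.integer(strsplit(tr$zf_positions, ",")[[1L]]) + off
    data.frame(protein_id = id, label = tr$label,
               heptapeptide = tr$heptapeptide,
               hepta_start = tr$hepta_start + off,
               start = tr$hepta_start + off, end = zf[length(zf)] + 1L,
               zf_type = tr$zf_type,
               zf_positions = paste(zf, collapse = ","),
               piece_start = off,
               piece_end = off + nchar(doms[[k]]$sequence),
               stringsAsFactors = FALSE)
  })
  dom_rows <- do.call(rbind, dom_rows)
  # motif coordinates: pieces after the last domain
  base_piece <- length(pieces) - length(cterm_parts)
  moff <- offsets[base_piece + 1L]
  cursor <- moff + nchar(cterm_parts[1L])
  k <- 2L
  for (cl in classes) {
    cursor <- cursor + 4L                       # GGGG pad
    lit <- motif_literal(cl, label)
    core_len <- if (cl == "EAR_LxLxL") 5L else nchar(lit)
    motif_truth[[length(motif_truth) + 1L]] <- data.frame(
      protein_id = id, class = cl, subtype = lit,
      start = cursor, end = cursor + core_len, stringsAsFactors = FALSE)
    cursor <- cursor + nchar(lit) + 4L
    cursor <- cursor + nchar(cterm_parts[k + 3L])
    k <- k + 4L
  }
  motif_truth <- if (length(motif_truth)) do.call(rbind, motif_truth) else
    data.frame(protein_id = character(), class = character(),
               subtype = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  # scrub accidental patterns outside planted features
  keep <- rep(FALSE, nchar(seqstr))
  for (r in seq_len(nrow(dom_rows)))
    keep[(dom_rows$piece_start[r] + 1L):dom_rows$piece_end[r]] <- TRUE
  for (r in seq_len(nrow(motif_truth))) {
    lit <- motif_literal(motif_truth$class[r], label)
    keep[(motif_truth$start[r] + 1L):(motif_truth$start[r] + nchar(lit))] <- TRUE
  }
  seqstr <- scrub_sequence(seqstr, which(!keep))
  list(id = id, sequence = seqstr, label = label, domains = dom_rows,
       motifs = motif_truth)
}

#' Generate a labelled set of WRKY proteins
#'
#' @param counts Named integer vector of proteins per group label; the
#'   default mirrors the group sizes reported for the Taxus chinensis
#'   transcriptome (16 I, 8 IIa, 10 IIb, 14 IIc, 5 IId, 7 IIe, 1 III).
#' @param rate Domain substitution rate.
#' @param motif_plan Motif-planting plan (see [make_protein()]).
#' @param seed Optional seed applied with [set.seed()].
#' @param prefix Identifier prefix.
#' @return List with `records` (a `protein_records`), `truth` (per-protein
#'   labels), `domains` and `motifs` (planted feature coordinates).
#' @export
make_wrky_set <- function(counts = c(I = 16L, IIa = 8L, IIb = 10L, IIc = 14L,
                                     IId = 5L, IIe = 7L, III = 1L),
                          rate = 0, motif_plan = default_motif_plan(),
                          seed = NULL, prefix = "SYNW") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(counts >= 0L), all(names(counts) %in% c("I", GROUP_LABELS)))
  labels <- rep(names(counts), counts)
  n <- length(labels)
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  prots <- lapply(seq_len(n), function(i)
    make_protein(ids[i], labels[i], rate = rate, motif_plan = motif_plan))
  records <- protein_records(ids, vapply(prots, `[[`, character(1L), "sequence"))
  truth <- data.frame(protein_id = ids, label = labels,
                      n_domains = ifelse(labels == "I", 2L, 1L),
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth,
       domains = do.call(rbind, lapply(prots, `[[`, "domains")),
       motifs = do.call(rbind, lapply(prots, `[[`, "motifs")))
}

#' Generate a synthetic labelled reference panel
#'
#' Domain records per subgroup template, with low within-label divergence
#' (the `rate` substitutions) and high between-label divergence (from the
#' template derivation). A synthetic stand-in for a curated reference panel
#' such as the Arabidopsis AtWRKY domain set.
#'
#' @param n_per_label References per label (>= 2).
#' @param rate Within-label substitution rate.
#' @param seed Optional seed.
#' @return A `reference_panel` data frame (`id`, `label`, `sequence`).
#' @export
make_reference_panel <- function(n_per_label = 3L, rate = 0.03, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_per_label < 2L) stop("at least 2 references per subgroup are required")
  rows <- list()
  for (lab in PANEL_LABELS) {
    for (k in seq_len(n_per_label)) {
      d <- make_domain(lab, rate = rate)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("REF_%s_%d", lab, k), label = lab,
        sequence = d$sequence, stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, rows)
  attr(panel, "provenance") <- "synthetic panel generated from in-package templates"
  class(panel) <- c("reference_panel", "data.frame")
  panel
}

#' Generate an expression matrix with planted regulation
#'
#' Emulates three treatment-contrast transcriptome datasets: for each
#' contrast a planted number of genes goes up or down (log2 effect sizes
#' drawn from `effect_range`), the rest stay unchanged, Gaussian noise is
#' added on the log2 scale, and a fraction of gene/dataset cells is masked
#' as missing. Defaults mirror the differential tallies of the Taxus study
#' (MeJA: 7 up / 43 down of 61; GA: 10 up / 45 down; fresh vs long-term
#' subcultured cells: 15 up / 42 down).
#'
#' @param n_genes Number of genes.
#' @param plan Data frame with columns `contrast`, `numerator`,
#'   `denominator`, `n_up`, `n_down`.
#' @param effect_range Range of planted |log2FC| for regulated genes.
#' @param noise_sd Gaussian noise sd per cell (log2 scale).
#' @param missing_frac Fraction of genes masked per contrast.
#' @param seed Optional seed.
#' @return List with `expr` (an `expression_matrix`), `contrasts` (named
#'   list usable by [contrast_matrix()]) and `truth` (gene, contrast,
#'   planted log2fc, direction).
#' @export
make_expression <- function(n_genes = 61L,
                            plan = data.frame(
                              contrast = c("MeJA_vs_control", "GA_vs_control",
                                           "NA_vs_CA"),
                              numerator = c("MeJA", "GA", "NA_cells"),
                              denominator = c("control_MeJA", "control_GA",
                                              "CA_cells"),
                              n_up = c(7L, 10L, 15L),
                              n_down = c(43L, 45L, 42L),
                              stringsAsFactors = FALSE),
                            effect_range = c(1.5, 4.1), noise_sd = 0.1,
                            missing_frac = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(plan$n_up + plan$n_down <= n_genes))
  genes <- sprintf("G%03d", seq_len(n_genes))
  cols <- unique(c(rbind(plan$numerator, plan$denominator)))
  vals <- matrix(NA_real_, n_genes, length(cols),
                 dimnames = list(genes, cols))
  mask <- matrix(FALSE, n_genes, length(cols), dimnames = dimnames(vals))
  base <- stats::runif(n_genes, 3, 10)
  truth <- list()
  for (r in seq_len(nrow(plan))) {
    num <- plan$numerator[r]; den <- plan$denominator[r]
    reg <- sample(genes, plan$n_up[r] + plan$n_down[r])
    lfc <- stats::setNames(rep(0, n_genes), genes)
    lfc[reg[seq_len(plan$n_up[r])]] <-
      stats::runif(plan$n_up[r], effect_range[1L], effect_range[2L])
    lfc[reg[plan$n_up[r] + seq_len(plan$n_down[r])]] <-
      -stats::runif(plan$n_down[r], effect_range[1L], effect_range[2L])
    vals[, den] <- base + stats::rnorm(n_genes, 0, noise_sd)
    vals[, num] <- base + lfc + stats::rnorm(n_genes, 0, noise_sd)
    n_miss <- floor(missing_frac * n_genes)
    missing <- if (n_miss > 0L) sample(genes, n_miss) else character(0)
    mask[missing, c(num, den)] <- TRUE
    truth[[r]] <- data.frame(
      gene = genes, contrast = plan$contrast[r], log2fc = unname(lfc),
      direction = ifelse(genes %in% missing, "missing",
                         ifelse(lfc > 0, "up",
                                ifelse(lfc < 0, "down", "unchanged"))),
      stringsAsFactors = FALSE)
  }
  vals[mask] <- NA_real_
  contrasts <- stats::setNames(
    lapply(seq_len(nrow(plan)), function(r)
      c(plan$numerator[r], plan$denominator[r])), plan$contrast)
  list(expr = expression_matrix(vals, mask), contrasts = contrasts,
       truth = do.call(rbind, truth))
}

#' Default qPCR fold-change plan
#'
#' One representative gene per subgroup under methyl jasmonate elicitation
#' over a 0/1/3/6 h time course; the 3 h fold changes mirror the strong
#' induction reported for Taxus cell cultures (up to 16.5-fold), with a
#' partial return towards baseline at 6 h and one insensitive gene.
#'
#' @return Data frame with columns `gene`, `treatment`, `timepoint`, `fold`.
#' @export
default_ct_plan <- function() {
  genes <- c("WRKY_IIc", "WRKY_III", "WRKY_I", "WRKY_IIe", "WRKY_IId",
             "WRKY_IIa", "WRKY_IIb")
  f1 <- c(3.0, 3.0, 1.5, 3.0, 4.0, 3.0, 1.0)
  f3 <- c(12.1, 11.0, 2.6, 11.2, 16.5, 10.1, 1.1)
  f6 <- c(1.8, 2.5, 1.2, 1.6, 1.9, 2.3, 0.9)
  data.frame(gene = rep(genes, times = 4L),
             treatment = "MeJA",
             timepoint = rep(c(0, 1, 3, 6), each = length(genes)),
             fold = c(rep(1, length(genes)), f1, f3, f6),
             stringsAsFactors = FALSE)
}

#' Generate a replicate qPCR Ct table with known fold changes
#'
#' Builds triplicate Ct values per (sample, gene) well group: the reference
#' gene sits at a constant cycle number, targets at
#' `ref_ct + base_dct - log2(fold)`, each well perturbed by Gaussian noise.
#' At `noise_sd = 0` the 2^-ddCt calculator recovers the planted fold
#' changes exactly.
#'
#' @param plan Data frame `gene`, `treatment`, `timepoint`, `fold` (fold 1
#'   at the calibrator timepoint 0).
#' @param noise_sd Per-well Ct noise sd (cycles).
#' @param n_reps Replicate wells per group (default 3).
#' @param reference Reference gene id.
#' @param ref_ct,base_dct Baseline cycle numbers.
#' @param seed Optional seed.
#' @return List with `ct` (a `ct_table`), `truth` (= `plan` plus `sample`),
#'   `reference` and `calibrator` (sample label of timepoint 0, per
#'   treatment).
#' @export
make_ct <- function(plan = default_ct_plan(), noise_sd = 0.05, n_reps = 3L,
                    reference = "Actin", ref_ct = 20, base_dct = 4,
                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(plan$fold > 0), noise_sd >= 0, n_reps >= 1L)
  plan$sample <- sprintf("%s_%gh", plan$treatment, plan$timepoint)
  rows <- list()
  for (s in unique(plan$sample)) {
    sub <- plan[plan$sample == s, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      sample = s, gene = reference,
      ct = ref_ct + stats::rnorm(n_reps, 0, noise_sd),
      treatment = sub$treatment[1L], timepoint = sub$timepoint[1L],
      stringsAsFactors = FALSE)
    for (r in seq_len(nrow(sub))) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, gene = sub$gene[r],
        ct = ref_ct + base_dct - log2(sub$fold[r]) +
          stats::rnorm(n_reps, 0, noise_sd),
        treatment = sub$treatment[r], timepoint = sub$timepoint[r],
        stringsAsFactors = FALSE)
    }
  }
  ct <- ct_table(do.call(rbind, rows))
  calibrators <- stats::setNames(
    sprintf("%s_0h", unique(plan$treatment)), unique(plan$treatment))
  list(ct = ct, truth = plan, reference = reference,
       calibrator = calibrators)
}

#' Write a full synthetic study bundle to disk
#'
#' Deterministic given the seed: proteins + truth, reference panel,
#' expression matrix and Ct table, all as plain text (FASTA/TSV).
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed governing every random draw.
#' @param counts,rate Passed to [make_wrky_set()].
#' @param n_per_label Panel size per label.
#' @return Invisibly, a list of the written paths and the truth objects.
#' @export
simulate_wrky_study <- function(out_dir, seed,
                                counts = c(I = 16L, IIa = 8L, IIb = 10L,
                                           IIc = 14L, IId = 5L, IIe = 7L,
                                           III = 1L),
                                rate = 0, n_per_label = 3L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  prot <- make_wrky_set(counts = counts, rate = rate)
  panel <- make_reference_panel(n_per_label = n_per_label)
  expr <- make_expression()
  ct <- make_ct()
  paths <- list(
    proteins = file.path(out_dir, "proteins.fasta"),
    truth = file.path(out_dir, "truth.tsv"),
    panel = file.path(out_dir, "panel.fasta"),
    panel_labels = file.path(out_dir, "panel_labels.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    ct = file.path(out_dir, "ct.tsv"))
  write_fasta(prot$records, paths$proteins)
  write_tsv(prot$truth, paths$truth)
  write_fasta(protein_records(panel$id, panel$sequence), paths$panel)
  write_tsv(panel[, c("id", "label")], paths$panel_labels)
  write_expression_table(expr$expr, paths$expression)
  write_tsv(as.data.frame(ct$ct), paths$ct)
  invisible(list(paths = paths, proteins = prot, panel = panel,
                 expression = expr, ct = ct, seed = as.integer(seed)))
}
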