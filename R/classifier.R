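PANEL_LABELS <- c("I-N", "I-C", "IIa", "IIb", "IIc", "IId", "IIe", "III")
GROUP_LABELS <- c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III")

#' Load a labelled reference panel of WRKY domains
#'
#' A panel is a set of reference WRKY domain sequences (e.g. Arabidopsis
#' AtWRKY domains) with subgroup labels, used for phylogenetic placement of
#' query domains. Labels are restricted to I-N, I-C, IIa-IIe and III; panels
#' carrying other labels (e.g. IIf/IIg) are rejected at load time.
#'
#' @param fasta Path to the panel FASTA, or a `protein_records` collection.
#' @param labels Path to a two-column TSV (id, label) with header, or a
#'   data frame with columns `id` and `label`.
#' @param provenance Free-text note on where the panel came from.
#' @return A data frame of class `reference_panel` with columns `id`,
#'   `label`, `sequence`.
#' @export
read_reference_panel <- function(fasta, labels, provenance = "") {
  recs <- if (inherits(fasta, "protein_records")) fasta else read_fasta(fasta)
  lab <- if (is.data.frame(labels)) labels else
    utils::read.table(labels, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(lab)))
    stop("panel label table needs columns 'id' and 'label'")
  bad <- setdiff(unique(lab$label), PANEL_LABELS)
  if (length(bad))
    stop("unsupported panel label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(PANEL_LABELS, collapse = ", "), ")")
  miss <- setdiff(recs$id, lab$id)
  if (length(miss))
    stop("panel sequence(s) without a label: ", paste(miss, collapse = ", "))
  panel <- merge(recs[, c("id", "sequence")], lab[, c("id", "label")],
                 by = "id", sort = TRUE)
  if (!all(table(panel$label) >= 1L)) stop("empty panel")
  attr(panel, "provenance") <- provenance
  class(panel) <- c("reference_panel", "data.frame")
  panel
}

#' Structural (rule-tier) group assignment from scanned domains
#'
#' Applies the classical domain-count / zinc-finger rules: two or more
#' complete C2H2 domains define Group I; a single complete C2HC domain
#' defines Group III; a single complete C2H2 domain defines Group II (the
#' subgroup is resolved later by phylogenetic placement); no complete domain
#' leaves the protein unclassified.
#'
#' @param domains `wrky_domains` rows of one protein (order-irrelevant).
#' @return List with `label` (`"I"`, `"II"`, `"III"` or `"unclassified"`)
#'   and `reason` (human-readable evidence string).
#' @export
rule_classify <- function(domains) {
  complete <- domains[domains$zf_type != "incomplete", , drop = FALSE]
  n <- nrow(complete)
  summary <- sprintf("%d domain(s), %d complete (%s)", nrow(domains), n,
                     if (n) paste(sort(complete$zf_type), collapse = "+") else "-")
  if (n >= 2L && all(complete$zf_type == "C2H2"))
    return(list(label = "I", reason = paste0("two C2H2 domains; ", summary)))
  if (n == 1L && complete$zf_type == "C2HC")
    return(list(label = "III", reason = paste0("single C2HC domain; ", summary)))
  if (n == 1L && complete$zf_type == "C2H2")
    return(list(label = "II", reason = paste0("single C2H2 domain; ", summary)))
  list(label = "unclassified",
       reason = paste0("no complete WRKY domain or unusual combination; ", summary))
}

# tip sets for every internal node, as a logical matrix nodes x tips
node_tip_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  M <- matrix(FALSE, length(nodes), ntip,
              dimnames = list(as.character(nodes), tree$tip.label))
  for (k in seq_along(nodes))
    M[k, descendant_tips(tree, nodes[k])] <- TRUE
  M
}

#' Place query WRKY domains on a reference panel by neighbor joining
#'
#' Builds one joint NJ tree of all query domains plus the panel (anchored
#' alignment, Poisson-corrected distances) and labels each query with the
#' single subgroup label of the smallest clade containing it whose reference
#' leaves are uniformly labelled (other query leaves are ignored). If no
#' such clade exists below the root, the nearest reference by corrected
#' distance decides. Clades labelled I-N or I-C yield Group I (the truncated
#' Group I rescue).
#'
#' @param queries `protein_records` of query domain sequences (one
#'   heptapeptide anchor each).
#' @param panel A `reference_panel`.
#' @param variants Heptapeptide patterns for the anchored alignment.
#' @param n_boot Bootstrap replicates for clade support (0 = no bootstrap;
#'   supports reported as `NA`).
#' @param seed Seed for the bootstrap resampler.
#' @return Data frame with `protein_id`, `label`, `tier`, `evidence`,
#'   `nearest_refs`, `support`; the joint tree is attached as attribute
#'   `tree`.
#' @export
placement_classify <- function(queries, panel, variants = wrky_variants("extended"),
                               n_boot = 0L, seed = 1L) {
  stopifnot(inherits(panel, "reference_panel"))
  if (nrow(queries) == 0L) stop("no query domains to place")
  clash <- intersect(queries$id, panel$id)
  if (length(clash))
    stop("query ids clash with panel ids: ", paste(clash, collapse = ", "))
  combined <- protein_records(c(queries$id, panel$id),
                              c(queries$sequence, panel$sequence))
  aln <- tryCatch(align_domains(combined, variants = variants),
                  error = function(e)
                    stop("unclassifiable query: ", conditionMessage(e),
                         call. = FALSE))
  D <- domain_distances(aln)
  support_map <- NULL
  if (n_boot > 0L) {
    tree <- bootstrap_support(aln, n_reps = n_boot, seed = seed)
    splits <- tree_bipartitions(tree)
    ntip <- length(tree$tip.label)
    support_map <- stats::setNames(
      tree$node.label[as.integer(names(splits)) - ntip], unname(splits))
  } else {
    tree <- neighbor_joining(D)
  }
  is_ref <- tree$tip.label %in% panel$id
  ref_label <- stats::setNames(panel$label, panel$id)
  tipmat <- node_tip_matrix(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  # candidate clades: each internal edge contributes its descendant side and
  # the complementary side
  sides <- list()
  for (k in seq_len(nrow(tipmat))) {
    node <- rownames(tipmat)[k]
    if (as.integer(node) == root) next
    sides[[length(sides) + 1L]] <- tipmat[k, ]
    sides[[length(sides) + 1L]] <- !tipmat[k, ]
  }
  side_info <- lapply(sides, function(s) {
    refs <- tree$tip.label[s & is_ref]
    labs <- unique(ref_label[refs])
    list(size = sum(s), uniform = if (length(labs) == 1L) labs else NA_character_)
  })
  anchor <- sort(tree$tip.label, method = "radix")[1L]
  out <- vector("list", nrow(queries))
  for (q in seq_len(nrow(queries))) {
    qid <- queries$id[q]
    qcol <- match(qid, tree$tip.label)
    best <- NULL
    for (k in seq_along(sides)) {
      info <- side_info[[k]]
      if (is.na(info$uniform) || !sides[[k]][qcol]) next
      if (is.null(best) || info$size < best$size)
        best <- list(size = info$size, label = info$uniform, idx = k)
    }
    dq <- D[qid, panel$id]
    nearest <- panel$id[order(dq, method = "radix")][1:min(3L, nrow(panel))]
    if (!is.null(best)) {
      lab <- best$label
      supp <- NA_real_
      if (!is.null(support_map)) {
        side_tips <- tree$tip.label[sides[[best$idx]]]
        key_side <- if (anchor %in% side_tips)
          setdiff(tree$tip.label, side_tips) else side_tips
        key <- paste(sort(key_side, method = "radix"), collapse = "|")
        if (key %in% names(support_map))
          supp <- suppressWarnings(as.numeric(support_map[[key]]))
      }
      evidence <- sprintf("smallest uniform clade (%d leaves, refs labelled %s)",
                          best$size, lab)
    } else {
      lab <- unname(ref_label[nearest[1L]])
      supp <- NA_real_
      evidence <- sprintf("nearest-reference fallback (%s, d = %.4f)",
                          nearest[1L], dq[nearest[1L]])
    }
    final <- if (lab %in% c("I-N", "I-C")) "I" else lab
    out[[q]] <- data.frame(protein_id = qid, label = final,
                           tier = "placement", evidence = evidence,
                           nearest_refs = paste(nearest, collapse = ","),
                           support = supp, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "tree") <- tree
  res
}

#' Classify a protein collection into WRKY groups
#'
#' Two-tier classification: structural rules assign Group I, bare Group II
#' and Group III; every Group-II-pending protein (single complete C2H2
#' domain, including zinc fingers flagged ambiguous) is then placed on the
#' reference panel tree to resolve the subgroup (IIa-IIe) or rescue a
#' truncated Group I member. Without a panel, Group II members keep the bare
#' `II` label.
#'
#' @param records A `protein_records` collection.
#' @param panel Optional `reference_panel`.
#' @param variants,window Scanner settings.
#' @param n_boot,seed Bootstrap settings for placement support.
#' @return Data frame of class `group_assignments` with one row per input
#'   protein (`protein_id`, `label`, `tier`, `evidence`, `nearest_refs`,
#'   `support`); per-label counts in `attr(, "counts")`, the scan table in
#'   `attr(, "domains")`, and the placement tree (if any) in
#'   `attr(, "tree")`.
#' @export
classify_all <- function(records, panel = NULL, variants = wrky_variants(),
                         window = 80L, n_boot = 0L, seed = 1L) {
  stopifnot(inherits(records, "protein_records"))
  domains <- scan_proteins(records, variants = variants, window = window)
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    dom_i <- domains[domains$protein_id == records$id[i], , drop = FALSE]
    rc <- rule_classify(dom_i)
    rows[[i]] <- data.frame(protein_id = records$id[i], label = rc$label,
                            tier = "rule", evidence = rc$reason,
                            nearest_refs = "", support = NA_real_,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(protein_id = character(), label = character(),
                      tier = character(), evidence = character(),
                      nearest_refs = character(), support = numeric(),
                      stringsAsFactors = FALSE)
  tree <- NULL
  pending <- res$protein_id[res$label == "II"]
  if (length(pending) && !is.null(panel)) {
    pend_dom <- domains[domains$protein_id %in% pending &
                          domains$zf_type != "incomplete", , drop = FALSE]
    seqs <- stats::setNames(records$sequence, records$id)
    qrecs <- protein_records(
      pend_dom$protein_id,
      substring(seqs[pend_dom$protein_id], pend_dom$start + 1L, pend_dom$end))
    placed <- placement_classify(qrecs, panel, variants = wrky_variants("extended"),
                                 n_boot = n_boot, seed = seed)
    tree <- attr(placed, "tree")
    idx <- match(placed$protein_id, res$protein_id)
    res[idx, c("label", "tier", "evidence", "nearest_refs", "support")] <-
      placed[, c("label", "tier", "evidence", "nearest_refs", "support")]
  } else if (length(pending)) {
    res$evidence[res$label == "II"] <-
      paste0(res$evidence[res$label == "II"], "; subgroup pending (no reference panel)")
  }
  counts <- table(factor(res$label, levels = c(GROUP_LABELS, "II", "unclassified")))
  stopifnot(sum(counts) == nrow(records))
  attr(res, "counts") <- counts
  attr(res, "domains") <- domains
  attr(res, "tree") <- tree
  class(res) <- c("group_assignments", "data.frame")
  res
}

#' Per-label count summary of assignments
#'
#' @param assignments A `group_assignments` data frame.
#' @return Named integer vector over all group labels.
#' @export
group_counts <- function(assignments) {
  cts <- attr(assignments, "counts")
  if (is.null(cts))
    cts <- table(factor(assignments$label,
                        levels = c(GROUP_LABELS, "II", "unclassified")))
  stats::setNames(as.integer(cts), names(cts))
}

#' Check superclade monophyly on a labelled tree
#'
#' The five Group II subgroups collapse into three superclades on WRKY
#' trees: IIa+IIb, IIc, and IId+IIe. For each superclade this reports
#' whether the leaves carrying its labels form a connected subtree
#' (monophyly on the unrooted tree). Sets with fewer than two members, or
#' covering all but at most one leaf, are vacuously monophyletic.
#'
#' @param tree A `phylo` object.
#' @param labels Named character vector: tip label -> subgroup label.
#' @param superclades Named list of label sets to test.
#' @return Data frame with columns `superclade`, `n_leaves`, `monophyletic`.
#' @export
superclade_check <- function(tree, labels,
                             superclades = list("IIa+b" = c("IIa", "IIb"),
                                                "IIc" = "IIc",
                                                "IId+e" = c("IId", "IIe"))) {
  tips <- if (inherits(tree, "phylo")) tree$tip.label else character(0)
  n <- length(tips)
  keys <- if (n >= 4L) unname(tree_bipartitions(tree)) else character(0)
  anchor <- if (n) sort(tips, method = "radix")[1L] else ""
  out <- lapply(names(superclades), function(nm) {
    members <- tips[!is.na(labels[tips]) & labels[tips] %in% superclades[[nm]]]
    mono <- if (length(members) <= 1L || length(members) >= n - 1L) TRUE else {
      side <- if (anchor %in% members) setdiff(tips, members) else members
      paste(sort(side, method = "radix"), collapse = "|") %in% keys
    }
    data.frame(superclade = nm, n_leaves = length(members),
               monophyletic = mono, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
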