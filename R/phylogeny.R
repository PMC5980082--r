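#' Anchor-based alignment of WRKY domain sequences
#'
#' WRKY domains are short (~60 aa) and share an invariant heptapeptide, so a
#' gap-free anchored alignment approximates a progressive alignment: every
#' row is shifted so the heptapeptide starts in the same column, and flanks
#' are padded with terminal gaps (`-`). Each record must contain exactly one
#' heptapeptide anchor.
#'
#' @param records A `protein_records` collection of domain sequences.
#' @param variants Heptapeptide patterns used as the anchor.
#' @param trim If `TRUE`, columns outside the shortest common (all-row
#'   non-gap) span are removed.
#' @return An object of class `domain_alignment`: list with `seqs` (named
#'   equal-length gapped strings) and `anchor_col` (1-based column of the
#'   anchor W).
#' @export
align_domains <- function(records, variants = wrky_variants("extended"),
                          trim = FALSE) {
  stopifnot(inherits(records, "protein_records"))
  if (nrow(records) == 0L) stop("no records to align")
  offs <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    a <- find_heptapeptides(records[i, , drop = FALSE], variants)
    if (nrow(a) != 1L)
      stop("record '", records$id[i], "' has ", nrow(a),
           " heptapeptide anchors (exactly 1 required for anchored alignment)")
    offs[i] <- a$start
  }
  left <- max(offs)
  padded <- vapply(seq_len(nrow(records)), function(i) {
    paste0(strrep("-", left - offs[i]), records$sequence[i])
  }, character(1L))
  width <- max(nchar(padded))
  padded <- vapply(padded, function(s)
    paste0(s, strrep("-", width - nchar(s))), character(1L), USE.NAMES = FALSE)
  aln <- structure(list(seqs = stats::setNames(padded, records$id),
                        anchor_col = left + 1L),
                   class = "domain_alignment")
  if (trim) {
    m <- alignment_matrix(aln)
    keep <- colSums(m == "-") == 0L
    if (!any(keep)) stop("no common span: trimming would remove all columns")
    idx <- which(keep)
    m <- m[, idx, drop = FALSE]
    aln$seqs <- stats::setNames(apply(m, 1L, paste, collapse = ""),
                                names(aln$seqs))
    aln$anchor_col <- match(left + 1L, idx)
  }
  aln
}

#' Alignment as a character matrix
#'
#' @param alignment A `domain_alignment`.
#' @return Character matrix, rows = sequences, columns = alignment columns.
#' @export
alignment_matrix <- function(alignment) {
  stopifnot(inherits(alignment, "domain_alignment"))
  m <- do.call(rbind, strsplit(alignment$seqs, ""))
  rownames(m) <- names(alignment$seqs)
  m
}

#' Proportion of differing sites between two aligned rows
#'
#' Pairwise deletion: only columns where both rows are non-gap are counted.
#'
#' @param alignment A `domain_alignment` (or character matrix).
#' @param i,j Row labels or indices.
#' @return Proportion in \[0, 1\].
#' @export
p_distance <- function(alignment, i, j) {
  m <- if (is.matrix(alignment)) alignment else alignment_matrix(alignment)
  a <- m[i, ]; b <- m[j, ]
  use <- a != "-" & b != "-"
  n <- sum(use)
  if (n == 0L)
    stop("undefined distance: rows '", i, "' and '", j,
         "' share no overlapping (non-gap) columns")
  sum(a[use] != b[use]) / n
}

#' Poisson correction of an observed proportion of differing sites
#'
#' Converts the observed proportion `p` of differing amino-acid sites into an
#' estimate of substitutions per site under a Poisson model of equal-rate
#' substitution: `d = -ln(1 - p)`.
#'
#' @param p Numeric vector, each value in \[0, 1).
#' @return Corrected distance(s), `d >= p`.
#' @export
poisson_correct <- function(p) {
  if (any(p < 0)) stop("p must be >= 0")
  if (any(p >= 1)) stop("Poisson correction saturates at p = 1 (got p >= 1)")
  -log(1 - p)
}

#' Pairwise distance matrix of an alignment
#'
#' Computes p-distances under pairwise deletion for every pair, optionally
#' Poisson-corrected. Saturated pairs (p = 1, possible on very short
#' overlaps) are capped just below 1 before correction, with a warning.
#'
#' @param alignment A `domain_alignment`.
#' @param correction `"poisson"` (default) or `"p"` for uncorrected.
#' @return Symmetric numeric matrix with zero diagonal and sequence labels
#'   as dimnames.
#' @export
domain_distances <- function(alignment, correction = c("poisson", "p")) {
  correction <- match.arg(correction)
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  labs <- rownames(m)
  gap <- m == "-"
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  capped <- FALSE
  for (i in seq_len(n - 1L)) {
    ai <- m[i, ]; gi <- gap[i, ]
    for (j in (i + 1L):n) {
      use <- !gi & !gap[j, ]
      nn <- sum(use)
      if (nn == 0L)
        stop("undefined distance: rows '", labs[i], "' and '", labs[j],
             "' share no overlapping columns")
      p <- sum(ai[use] != m[j, use]) / nn
      if (correction == "poisson") {
        if (p >= 1) { p <- 1 - 0.5 / nn; capped <- TRUE }
        p <- -log(1 - p)
      }
      D[i, j] <- D[j, i] <- p
    }
  }
  if (capped)
    warning("saturated p-distance(s) capped below 1 before Poisson correction")
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining: at each step the pair minimising the Q
#' criterion `Q(i,j) = (n-2) d(i,j) - r(i) - r(j)` is joined, with branch
#' lengths from the Saitou-Nei formulas. Ties in Q are broken
#' deterministically by the lexicographically lowest label pair (each
#' internal node inherits the smallest leaf label in its subtree). Negative
#' branch lengths are clamped to zero and the total clamped magnitude is
#' recorded in the `clamped_deficit` attribute. The result is an unrooted
#' tree (trifurcation at the root node).
#'
#' @param D Symmetric numeric matrix with unique dimnames, n >= 3.
#' @return An [ape::read.tree] `phylo` object with attribute
#'   `clamped_deficit`.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D)) D <- as.matrix(D)
  labs <- rownames(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(labs) || anyDuplicated(labs)) stop("distance matrix needs unique labels")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  fmt <- function(x) sprintf("%.10g", x)
  nwk <- labs            # current newick fragment per active node
  key <- labs            # tie-break key: smallest leaf label in subtree
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit - x; 0 } else x
  }
  while (nrow(D) > 3L) {
    nn <- nrow(D)
    r <- rowSums(D)
    Q <- (nn - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    if (nrow(cand) > 1L) {
      pk <- apply(cand, 1L, function(ij) {
        kk <- sort(c(key[ij[1L]], key[ij[2L]]), method = "radix")
        paste(kk, collapse = "\r")
      })
      cand <- cand[order(pk, method = "radix")[1L], , drop = FALSE]
    }
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    vi <- clamp(0.5 * D[i, j] + (r[i] - r[j]) / (2 * (nn - 2)))
    vj <- clamp(D[i, j] - (0.5 * D[i, j] + (r[i] - r[j]) / (2 * (nn - 2))))
    newfrag <- paste0("(", nwk[i], ":", fmt(vi), ",", nwk[j], ":", fmt(vj), ")")
    newkey <- sort(c(key[i], key[j]), method = "radix")[1L]
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(nn), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nwk <- c(nwk[keep], newfrag)
    key <- c(key[keep], newkey)
    rn <- c(rownames(D)[keep], paste0("&", newkey))
    dimnames(D2) <- list(rn, rn)
    D <- D2
  }
  # final three nodes join at an unresolved root
  v1 <- clamp(0.5 * (D[1, 2] + D[1, 3] - D[2, 3]))
  v2 <- clamp(0.5 * (D[1, 2] + D[2, 3] - D[1, 3]))
  v3 <- clamp(0.5 * (D[1, 3] + D[2, 3] - D[1, 2]))
  text <- paste0("(", nwk[1L], ":", fmt(v1), ",", nwk[2L], ":", fmt(v2),
                 ",", nwk[3L], ":", fmt(v3), ");")
  tree <- ape::read.tree(text = text)
  attr(tree, "clamped_deficit") <- deficit
  tree
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves into two sets; the split is
#' canonicalised as the sorted side not containing the lexicographically
#' smallest tip, joined by `|`. Trivial splits (single tip) are excluded.
#'
#' @param tree A `phylo` object.
#' @return Character vector of canonical split keys (possibly empty), named
#'   by the child node number of the defining edge.
#' @export
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  ntip <- length(tips)
  anchor <- sort(tips, method = "radix")[1L]
  internal <- tree$edge[tree$edge[, 2L] > ntip, 2L]
  out <- character(0)
  for (node in internal) {
    below <- tips[descendant_tips(tree, node)]
    side <- if (anchor %in% below) setdiff(tips, below) else below
    if (length(side) < 2L || length(side) > ntip - 2L) next
    out[as.character(node)] <- paste(sort(side, method = "radix"),
                                     collapse = "|")
  }
  out
}

# tip indices below an internal node (iterative post-order accumulation)
descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  stack <- node
  tips <- integer(0)
  while (length(stack)) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == cur, 2L]
    tips <- c(tips, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  tips
}

#' Do two trees share the same unrooted topology?
#'
#' @param t1,t2 `phylo` objects over the same tip set.
#' @return `TRUE` when tip sets and non-trivial bipartitions coincide.
#' @export
same_topology <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) return(FALSE)
  setequal(unname(tree_bipartitions(t1)), unname(tree_bipartitions(t2)))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and reports for every internal edge of the point-estimate
#' tree the percentage of replicates containing the same bipartition.
#' Supports are stored as node labels of the returned tree.
#'
#' @param alignment A `domain_alignment`.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Mandatory integer seed for reproducibility.
#' @param correction Distance correction passed to [domain_distances()].
#' @return The point-estimate `phylo` tree with `node.label` carrying
#'   supports (percent, empty for the root and trivial nodes) and attribute
#'   `seed`.
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed,
                              correction = "poisson") {
  if (missing(seed)) stop("a seed is required for bootstrap reproducibility")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  point <- neighbor_joining(domain_distances(alignment, correction))
  splits <- tree_bipartitions(point)
  counts <- stats::setNames(numeric(length(splits)), unname(splits))
  m <- alignment_matrix(alignment)
  L <- ncol(m)
  set.seed(as.integer(seed))
  for (b in seq_len(n_reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    rep_aln <- structure(list(
      seqs = stats::setNames(apply(m[, idx, drop = FALSE], 1L, paste,
                                   collapse = ""), rownames(m)),
      anchor_col = NA_integer_), class = "domain_alignment")
    rep_tree <- tryCatch(
      neighbor_joining(suppressWarnings(domain_distances(rep_aln, correction))),
      error = function(e) NULL)
    if (is.null(rep_tree)) next
    found <- unname(tree_bipartitions(rep_tree))
    hit <- names(counts) %in% found
    counts[hit] <- counts[hit] + 1
  }
  support <- round(100 * counts / n_reps, 1)
  ntip <- length(point$tip.label)
  node_lab <- rep("", point$Nnode)
  for (k in seq_along(splits)) {
    node <- as.integer(names(splits)[k])
    node_lab[node - ntip] <- format(support[[unname(splits[k])]])
  }
  point$node.label <- node_lab
  attr(point, "seed") <- as.integer(seed)
  attr(point, "n_reps") <- as.integer(n_reps)
  point
}

#' Read / write trees in newick format
#'
#' Thin wrappers with explicit error reporting; bootstrap supports ride
#' along as internal node labels.
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @param text Optional newick string (used instead of `path`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  src <- if (is.null(text)) NULL else text
  tree <- tryCatch(
    if (is.null(text)) ape::read.tree(file = path) else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree))
    stop("malformed newick in ", if (is.null(text)) path else "text input")
  tree
}
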