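# Independent oracles used to freeze expected values. These deliberately
# share no code with the implementation they check.

# Brute-force zinc-finger search: enumerate every position quadruple inside
# the window and keep those satisfying anchor letters and spacer ranges;
# order candidates by their full position vector so the "earliest wins"
# rule is explicit.
enumerate_zinc_fingers <- function(seqstr, anchor_end, anchors,
                                   spacer_min, spacer_max, window = 80L) {
  chars <- strsplit(seqstr, "")[[1L]]
  lo <- anchor_end + 1L
  hi <- min(length(chars), anchor_end + window)
  if (lo > hi) return(list())
  idx <- lo:hi
  cand <- list()
  p1s <- idx[chars[idx] == anchors[1L]]
  for (p1 in p1s) for (p2 in idx[idx > p1 & chars[idx] == anchors[2L]])
    for (p3 in idx[idx > p2 & chars[idx] == anchors[3L]])
      for (p4 in idx[idx > p3 & chars[idx] == anchors[4L]]) {
        gaps <- c(p2 - p1, p3 - p2, p4 - p3) - 1L
        if (all(gaps >= spacer_min & gaps <= spacer_max))
          cand[[length(cand) + 1L]] <- c(p1, p2, p3, p4) - 1L
      }
  if (!length(cand)) return(list())
  ord <- order(vapply(cand, function(p) sprintf("%06d%06d%06d%06d", p[1L],
                                                p[2L], p[3L], p[4L]),
                      character(1L)))
  cand[ord]
}

# Random unrooted binary tree with positive branch lengths; its cophenetic
# matrix is exactly additive.
random_additive_tree <- function(n, min_bl = 0.1, max_bl = 2) {
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) stats::runif(k, min_bl, max_bl))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# Least-squares branch-length fit of a fixed topology to a distance matrix;
# returns the residual sum of squares. Used to verify by exhaustive
# enumeration that the generating topology is the best-fitting one.
ls_fit_rss <- function(topology, D) {
  tips <- topology$tip.label
  n <- length(tips)
  pairs <- t(utils::combn(n, 2L))
  # edge incidence matrix: which edges lie on the path between each tip pair
  A <- matrix(0, nrow(pairs), nrow(topology$edge))
  for (r in seq_len(nrow(pairs))) {
    p <- ape::nodepath(topology, pairs[r, 1L], pairs[r, 2L])
    for (k in seq_len(length(p) - 1L)) {
      e <- which((topology$edge[, 1L] == p[k] & topology$edge[, 2L] == p[k + 1L]) |
                 (topology$edge[, 1L] == p[k + 1L] & topology$edge[, 2L] == p[k]))
      A[r, e] <- 1
    }
  }
  d <- D[cbind(tips[pairs[, 1L]], tips[pairs[, 2L]])]
  fit <- stats::lm.fit(A, d)
  sum(fit$residuals^2)
}

# Deterministic scan for all LxxLL windows by explicit enumeration.
enumerate_lxxll <- function(seqstr) {
  chars <- strsplit(seqstr, "")[[1L]]
  starts <- integer(0)
  for (i in seq_len(max(0L, length(chars) - 4L))) {
    w <- chars[i:(i + 4L)]
    if (w[1L] == "L" && w[4L] == "L" && w[5L] == "L")
      starts <- c(starts, i - 1L)
  }
  starts
}

bundled_panel <- function() {
  read_reference_panel(
    system.file("extdata", "synthetic_panel.fasta", package = "wrkyscan"),
    system.file("extdata", "synthetic_panel_labels.tsv", package = "wrkyscan"))
}
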