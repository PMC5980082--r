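test_that("anchored alignment pins the heptapeptide column and pads flanks", {
  d <- make_domain("IIa")$sequence
  aln <- align_domains(protein_records(c("x", "y"), c(d, d)))
  expect_equal(p_distance(aln, "x", "y"), 0)
  expect_equal(nchar(aln$seqs[["x"]]), nchar(aln$seqs[["y"]]))

  a <- paste0(strrep("G", 3), "WRKYGQK", strrep("A", 10))
  b <- paste0(strrep("G", 10), "WRKYGQK", strrep("A", 10))
  aln2 <- align_domains(protein_records(c("a", "b"), c(a, b)))
  expect_equal(substr(aln2$seqs[["a"]], 1, 7), strrep("-", 7))
  expect_equal(aln2$anchor_col, 11L)

  expect_error(align_domains(protein_records("z", "AAAA")), "'z'")
})

test_that("p-distance counts differing sites under pairwise deletion", {
  base <- strrep("A", 60)
  mut <- base
  substr(mut, 10, 10) <- "V"; substr(mut, 20, 20) <- "V"; substr(mut, 30, 30) <- "V"
  m <- rbind(x = strsplit(base, "")[[1]], y = strsplit(mut, "")[[1]])
  expect_equal(p_distance(m, "x", "y"), 3 / 60)
  expect_equal(p_distance(m, "x", "y"), p_distance(m, "y", "x"))
  # disjoint gap patterns have no overlapping columns
  g <- rbind(x = c("A", "A", "-", "-"), y = c("-", "-", "A", "A"))
  expect_error(p_distance(g, "x", "y"), "no overlapping")
})

test_that("Poisson correction has the closed form and is monotone", {
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.5), log(2), tolerance = 1e-14)
  expect_error(poisson_correct(1), "saturat")
  p <- seq(0, 0.99, by = 1e-3)
  d <- poisson_correct(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("neighbor joining reproduces a known additive 4-taxon tree exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) gives these path distances
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(D)
  truth <- read_newick(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_true(same_topology(tr, truth))
  # branch lengths: path distances on the reconstructed tree equal D
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
  expect_equal(attr(tr, "clamped_deficit"), 0)
})

test_that("neighbor joining handles degenerate and small inputs", {
  D3 <- matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- neighbor_joining(D3)
  expect_equal(sort(tr3$tip.label), c("a", "b", "c"))
  expect_equal(tr3$Nnode, 1L)
  expect_error(neighbor_joining(D3[1:2, 1:2]), "at least 3")
  # two identical rows produce a zero-length cherry
  D <- matrix(c(0, 0, 4, 4,
                0, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4,
              dimnames = list(c("p", "q", "r", "s"), c("p", "q", "r", "s")))
  tr <- neighbor_joining(D)
  cd <- ape::cophenetic.phylo(tr)
  expect_equal(cd["p", "q"], 0)
  expect_true(same_topology(tr, read_newick(text = "((p:0,q:0):2,(r:1,s:1):1);")))
})

test_that("NJ recovers random additive topologies and matches an independent NJ", {
  skip_if_not_installed("phangorn")
  set.seed(2024)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    tr <- random_additive_tree(n)
    D <- ape::cophenetic.phylo(tr)
    mine <- neighbor_joining(D)
    expect_true(same_topology(mine, tr))
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(tr)), 0)
    expect_true(same_topology(mine, ape::nj(D)))
  }
})

test_that("NJ tie-breaking is deterministic under equal Q values", {
  # fully symmetric matrix: many equal-Q pairs
  D <- matrix(2, 5, 5); diag(D) <- 0
  dimnames(D) <- list(letters[1:5], letters[1:5])
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("bootstrap supports are reproducible, bounded and sensitive to structure", {
  # two well-separated 3-leaf clusters: central edge support 100
  set.seed(6)
  a <- make_domain("IIa", rate = 0.01)$sequence
  b <- make_domain("III", rate = 0.01)$sequence
  recs <- protein_records(c("a1", "a2", "a3", "b1", "b2", "b3"),
                          c(a, make_domain("IIa", rate = 0.01)$sequence,
                            make_domain("IIa", rate = 0.01)$sequence,
                            b, make_domain("III", rate = 0.01)$sequence,
                            make_domain("III", rate = 0.01)$sequence))
  aln <- align_domains(recs)
  tr <- bootstrap_support(aln, n_reps = 100L, seed = 42L)
  supports <- suppressWarnings(as.numeric(tr$node.label))
  supports <- supports[!is.na(supports)]
  expect_true(all(supports >= 0 & supports <= 100))
  splits <- tree_bipartitions(tr)
  central <- splits[splits %in% c("a1|a2|a3", "b1|b2|b3")]
  stopifnot(length(central) >= 1)
  ntip <- length(tr$tip.label)
  expect_equal(as.numeric(tr$node.label[as.integer(names(central)) - ntip]),
               rep(100, length(central)))
  # determinism
  tr2 <- bootstrap_support(aln, n_reps = 100L, seed = 42L)
  expect_identical(tr$node.label, tr2$node.label)
  expect_error(bootstrap_support(aln, n_reps = 0L, seed = 1L), "n_reps")
  expect_error(bootstrap_support(aln, n_reps = 10L), "seed")
  # degenerate alignment of identical sequences does not crash
  same <- protein_records(c("s1", "s2", "s3", "s4"), rep(a, 4))
  tr3 <- bootstrap_support(align_domains(same), n_reps = 10L, seed = 1L)
  expect_s3_class(tr3, "phylo")
})

test_that("newick round-trips preserve topology, lengths and supports", {
  txt <- "((A:1,B:2)95:1,C:3);"
  tr <- read_newick(text = txt)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_true(same_topology(tr, back))
  expect_equal(tr$edge.length, back$edge.length, tolerance = 1e-9)
  expect_equal(tr$node.label, back$node.label)
  expect_error(read_newick(text = "((A:1,B:2"), "malformed")
})
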