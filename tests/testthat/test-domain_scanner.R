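test_that("heptapeptide anchors are located with variant tags", {
  hits <- find_heptapeptides("AAWRKYGQKAA")
  expect_equal(hits$start, 2L)
  expect_equal(hits$variant, "canonical")

  hits <- find_heptapeptides("WRKYGKKAAAA")
  expect_equal(hits$variant, "WRKYGKK")

  expect_equal(nrow(find_heptapeptides("AAWRKYGAKAA")), 0L)
  # angiosperm variants only behind the extended set
  expect_equal(nrow(find_heptapeptides("AAWRKYGEKAA")), 0L)
  expect_equal(nrow(find_heptapeptides("AAWRKYGEKAA", wrky_variants("extended"))), 1L)
  expect_error(find_heptapeptides("AA", character(0)), "non-empty")
})

test_that("zinc-finger matching agrees with exhaustive enumeration", {
  mk <- function(...) paste0(...)
  fill <- function(n) strrep("A", n)
  # C2H2 with spacings (4, 22, 1)
  s1 <- mk("WRKYGQK", fill(10), "C", fill(4), "C", fill(22), "H", "A", "H")
  # C2HC with spacings (7, 23, 1)
  s2 <- mk("WRKYGQK", fill(10), "C", fill(7), "C", fill(23), "H", "A", "C")
  for (case in list(list(s1, "C2H2"), list(s2, "C2HC"))) {
    g <- zf_grammar(case[[2]])
    got <- match_zinc_finger(case[[1]], 7L, g)
    oracle <- enumerate_zinc_fingers(case[[1]], 7L, g$anchors,
                                     g$spacer_min, g$spacer_max)
    expect_equal(got, oracle[[1]])
    expect_true(validate_zinc_finger(case[[1]], got, g))
  }
  # earliest-arrangement rule on a sequence with several valid candidates
  set.seed(9)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "H", "G"), 90, replace = TRUE,
                      prob = c(0.4, 0.2, 0.2, 0.2)), collapse = "")
    seqstr <- paste0("WRKYGQK", s)
    for (gname in c("C2H2", "C2HC")) {
      g <- zf_grammar(gname)
      got <- match_zinc_finger(seqstr, 7L, g)
      oracle <- enumerate_zinc_fingers(seqstr, 7L, g$anchors,
                                       g$spacer_min, g$spacer_max)
      if (length(oracle)) expect_equal(got, oracle[[1]]) else expect_null(got)
    }
  }
})

test_that("absent zinc fingers yield incomplete domains", {
  seqstr <- paste0("AA", "WRKYGQK", strrep("A", 90))
  expect_null(match_zinc_finger(seqstr, 9L, zf_grammar("C2H2")))
  d <- scan_protein(seqstr)
  expect_equal(d$zf_type, "incomplete")
  expect_equal(d$end, d$hepta_end)
})

test_that("a domain matching both grammars is flagged ambiguous and typed C2H2", {
  zf <- strrep("A", 41)
  substr(zf, 1, 1) <- "C"; substr(zf, 7, 7) <- "C"; substr(zf, 9, 9) <- "C"
  substr(zf, 31, 31) <- "H"; substr(zf, 33, 33) <- "H"; substr(zf, 35, 35) <- "C"
  seqstr <- paste0("WRKYGQK", strrep("A", 5), zf)
  expect_false(is.null(match_zinc_finger(seqstr, 7L, zf_grammar("C2H2"))))
  expect_false(is.null(match_zinc_finger(seqstr, 7L, zf_grammar("C2HC"))))
  d <- scan_protein(seqstr)
  expect_true(d$ambiguous)
  expect_equal(d$zf_type, "C2H2")
})

test_that("multi-domain proteins get N/C terminal tags and overlaps keep the left anchor", {
  set.seed(21)
  p <- make_protein("two", "I")
  d <- scan_protein(protein_records(p$id, p$sequence))
  expect_equal(nrow(d), 2L)
  expect_equal(d$terminal, c("N", "C"))
  expect_equal(d$zf_type, c("C2H2", "C2H2"))

  one <- make_protein("one", "III")
  d1 <- scan_protein(protein_records(one$id, one$sequence))
  expect_equal(d1$terminal, "single")
  expect_equal(d1$zf_type, "C2HC")

  expect_equal(nrow(scan_protein("AAAAGGGG")), 0L)

  # an anchor inside an accepted domain is dropped (leftmost wins): plant a
  # WRKYGKK inside the second zinc spacer without disturbing the anchors
  dom <- make_domain("IIc")$sequence
  zf <- as.integer(strsplit(make_domain("IIc")$truth$zf_positions, ",")[[1]])
  inner <- dom
  substr(inner, zf[2] + 3L, zf[2] + 9L) <- "WRKYGKK"
  di <- scan_protein(inner)
  expect_equal(nrow(di), 1L)
  expect_equal(di$heptapeptide, "WRKYGQK")
  expect_true(validate_zinc_finger(inner,
    as.integer(strsplit(di$zf_positions, ",")[[1]]), zf_grammar("C2H2")))
})

test_that("scanner output is invariant to anchor-free flanks", {
  set.seed(3)
  p <- make_protein("inv", "IIe")
  base <- scan_protein(protein_records("inv", p$sequence))
  flank <- strrep("GQSTV", 20)
  shifted <- scan_protein(protein_records("inv", paste0(flank, p$sequence, flank)))
  off <- nchar(flank)
  expect_equal(shifted$start, base$start + off)
  expect_equal(shifted$zf_type, base$zf_type)
  expect_equal(shifted$heptapeptide, base$heptapeptide)
})

test_that("scanner recovers planted truth exactly on zero-noise synthetic proteins", {
  set.seed(5)
  sim <- make_wrky_set(counts = c(I = 3L, IIa = 2L, IIb = 2L, IIc = 2L,
                                  IId = 2L, IIe = 2L, III = 2L), rate = 0)
  d <- scan_proteins(sim$records)
  expect_equal(nrow(d), nrow(sim$domains))
  m <- merge(d, sim$domains, by = c("protein_id", "hepta_start"))
  expect_equal(nrow(m), nrow(d))
  expect_equal(m$zf_type.x, m$zf_type.y)
  expect_equal(m$zf_positions.x, m$zf_positions.y)
  expect_equal(m$heptapeptide.x, m$heptapeptide.y)
  # every reported spacing re-validates against its grammar
  for (r in seq_len(nrow(d))) {
    if (d$zf_type[r] == "incomplete") next
    g <- zf_grammar(d$zf_type[r])
    seqstr <- sim$records$sequence[sim$records$id == d$protein_id[r]]
    expect_true(validate_zinc_finger(
      seqstr, as.integer(strsplit(d$zf_positions[r], ",")[[1]]), g))
  }
})

test_that("domain extraction applies flanks, clipping and -N/-C naming", {
  set.seed(8)
  p <- make_protein("gi", "I")
  recs <- protein_records(p$id, p$sequence)
  d <- scan_protein(recs)
  ex0 <- extract_domain_sequences(recs, d, flank = 0L)
  expect_equal(ex0$id, c("gi-N", "gi-C"))
  expect_equal(nchar(ex0$sequence[1]), d$end[1] - d$start[1])
  # large flank clips at the sequence bounds
  exbig <- extract_domain_sequences(recs, d, flank = 10000L)
  expect_equal(nchar(exbig$sequence[1]), nchar(p$sequence))

  one <- make_protein("solo", "IIa")
  r1 <- protein_records(one$id, one$sequence)
  ex1 <- extract_domain_sequences(r1, scan_protein(r1))
  expect_equal(ex1$id, "solo")
})
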