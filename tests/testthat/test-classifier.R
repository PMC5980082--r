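domrow <- function(zf_type, ambiguous = FALSE) {
  data.frame(protein_id = "p", zf_type = zf_type, ambiguous = ambiguous,
             stringsAsFactors = FALSE)
}

test_that("structural rules assign I / II / III / unclassified", {
  expect_equal(rule_classify(rbind(domrow("C2H2"), domrow("C2H2")))$label, "I")
  expect_equal(rule_classify(domrow("C2HC"))$label, "III")
  expect_equal(rule_classify(domrow("C2H2"))$label, "II")
  expect_equal(rule_classify(domrow("incomplete"))$label, "unclassified")
  expect_equal(rule_classify(domrow("C2H2")[0, ])$label, "unclassified")
  # one complete + one incomplete domain still reads as Group II material
  expect_equal(rule_classify(rbind(domrow("C2H2"), domrow("incomplete")))$label, "II")
  # pure function of the set: order of domains is irrelevant
  two <- rbind(domrow("C2H2"), domrow("incomplete"), domrow("C2H2"))
  expect_equal(rule_classify(two)$label, rule_classify(two[c(3, 1, 2), ])$label)
})

test_that("reference panels reject unsupported labels and unlabeled sequences", {
  panel <- bundled_panel()
  expect_s3_class(panel, "reference_panel")
  expect_setequal(unique(panel$label),
                  c("I-N", "I-C", "IIa", "IIb", "IIc", "IId", "IIe", "III"))
  recs <- protein_records(c("x1", "x2"), c("WRKYGQKAAA", "WRKYGQKCCC"))
  expect_error(read_reference_panel(
    recs, data.frame(id = c("x1", "x2"), label = c("IIa", "IIg"))),
    "IIg")
  expect_error(read_reference_panel(
    recs, data.frame(id = "x1", label = "IIa")), "without a label")
})

test_that("self-placement returns the reference's own label with full support", {
  panel <- bundled_panel()
  ref <- panel[panel$label == "IIa", ][1, ]
  q <- protein_records("query1", ref$sequence)
  res <- placement_classify(q, panel, n_boot = 50L, seed = 7L)
  expect_equal(res$label, "IIa")
  expect_equal(res$tier, "placement")
  expect_false(is.na(res$support) && !grepl("nearest", res$evidence))
})

test_that("placement recovers the label after seeded substitutions outside anchors", {
  panel <- bundled_panel()
  set.seed(123)
  d <- make_domain("IIc", rate = 0)
  chars <- strsplit(d$sequence, "")[[1]]
  protected <- c(d$truth$hepta_start + 0:6,
                 as.integer(strsplit(d$truth$zf_positions, ",")[[1]])) + 1L
  idx <- sample(setdiff(seq_along(chars), protected), 5L)
  chars[idx] <- vapply(chars[idx], function(ch)
    sample(setdiff(c("A", "G", "S", "T", "V"), ch), 1L), character(1))
  res <- placement_classify(
    protein_records("mut", paste(chars, collapse = "")), panel)
  expect_equal(res$label, "IIc")
})

test_that("a lone C-terminal Group I domain is rescued into Group I by placement", {
  panel <- bundled_panel()
  set.seed(77)
  d <- make_domain("I-C", rate = 0.02)
  res <- placement_classify(protein_records("trunc", d$sequence), panel)
  expect_equal(res$label, "I")
})

test_that("classify_all recovers synthetic labels exactly and counts conserve n", {
  set.seed(31)
  sim <- make_wrky_set(counts = c(I = 10L, IIa = 10L, IIb = 10L, IIc = 10L,
                                  IId = 10L, IIe = 10L, III = 10L), rate = 0)
  a <- classify_all(sim$records, panel = bundled_panel())
  expect_equal(a$label, sim$truth$label)
  expect_equal(sum(group_counts(a)), nrow(sim$records))
  expect_true(all(a$tier[a$label %in% c("IIa", "IIb", "IIc", "IId", "IIe")]
                  == "placement"))
  expect_true(all(nzchar(a$evidence)))
})

test_that("classify_all on empty input returns empty output with zero counts", {
  empty <- protein_records(character(), character())
  a <- classify_all(empty, panel = bundled_panel())
  expect_equal(nrow(a), 0L)
  expect_equal(sum(group_counts(a)), 0L)
})

test_that("without a panel Group II members stay bare II with a pending note", {
  set.seed(12)
  sim <- make_wrky_set(counts = c(IIb = 2L, III = 1L), rate = 0)
  a <- classify_all(sim$records)
  expect_equal(sort(unname(group_counts(a)[c("II", "III")])), c(1L, 2L))
  expect_match(a$evidence[a$label == "II"][1], "pending")
})

test_that("label recovery degrades monotonically (non-strictly) with substitution rate", {
  panel <- bundled_panel()
  rates <- c(0, 0.05, 0.1, 0.2)
  hits <- totals <- numeric(length(rates))
  for (s in 1:3) {
    for (k in seq_along(rates)) {
      set.seed(1000 + 17 * s)
      sim <- make_wrky_set(counts = c(I = 2L, IIa = 2L, IIb = 2L, IIc = 2L,
                                      IId = 2L, IIe = 2L, III = 2L),
                           rate = rates[k])
      a <- classify_all(sim$records, panel = panel)
      hits[k] <- hits[k] + sum(a$label == sim$truth$label)
      totals[k] <- totals[k] + nrow(sim$records)
    }
  }
  rec <- hits / totals
  expect_equal(rec[1], 1)
  expect_true(all(diff(rec) <= 1e-12))
})

test_that("superclades are monophyletic on the panel tree and break when grafted", {
  panel <- bundled_panel()
  aln <- align_domains(protein_records(panel$id, panel$sequence))
  tree <- neighbor_joining(domain_distances(aln))
  sc <- superclade_check(tree, stats::setNames(panel$label, panel$id))
  expect_equal(sc$monophyletic, c(TRUE, TRUE, TRUE))

  # constructed counterexample: an IIa leaf grafted inside the IIc clade
  bad <- read_newick(text = paste0(
    "((a1:1,a2:1):1,((c1:1,(a3:1,c2:1):1):1,c3:1):1,(d1:1,d2:1):1);"))
  labs <- c(a1 = "IIa", a2 = "IIa", a3 = "IIa", c1 = "IIc", c2 = "IIc",
            c3 = "IIc", d1 = "IId", d2 = "IId")
  sc2 <- superclade_check(bad, labs)
  expect_false(sc2$monophyletic[sc2$superclade == "IIa+b"])
  expect_false(sc2$monophyletic[sc2$superclade == "IIc"])
  expect_true(sc2$monophyletic[sc2$superclade == "IId+e"])

  # degenerate tiny trees are vacuously monophyletic
  tiny <- read_newick(text = "(x:1,y:1,z:1);")
  sc3 <- superclade_check(tiny, c(x = "IIa", y = "IIc", z = "IId"))
  expect_true(all(sc3$monophyletic))
})
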