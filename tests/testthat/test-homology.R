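test_that("Smith-Waterman reproduces hand-derived and oracle scores", {
  # identical 7-mers align along the BLOSUM62 diagonal: 4+9+6+5+6+6+8
  h <- smith_waterman("ACDEFGH", "ACDEFGH")
  expect_equal(h$raw_score, 44)
  expect_equal(h$query_span, c(1L, 7L))
  expect_equal(h$aligned_query, "ACDEFGH")

  # no positively scoring residue pair: floor at zero, empty spans
  h0 <- smith_waterman("GGGG", "PPPP")
  expect_equal(h0$raw_score, 0)
  expect_length(h0$query_span, 0)

  # symmetry of the optimal score under a symmetric matrix
  set.seed(11)
  for (k in 1:5) {
    a <- random_aa(12); b <- random_aa(12)
    expect_equal(smith_waterman(a, b)$raw_score,
                 smith_waterman(b, a)$raw_score)
  }

  # against the explicit gap-length-enumeration oracle and Biostrings
  set.seed(21)
  for (k in 1:15) {
    a <- random_aa(8); b <- random_aa(8)
    s <- smith_waterman(a, b)$raw_score
    expect_equal(s, oracle_sw_score(a, b))
    expect_equal(s, biostrings_sw_score(a, b))
  }

  expect_error(smith_waterman("", "ACD"), "non-empty")
  expect_error(smith_waterman("ACD", "ACD", gap_open = 0), "positive")
})

test_that("aligned strings ungap to the spanned subsequences", {
  set.seed(31)
  for (k in 1:10) {
    a <- random_aa(40); b <- random_aa(40)
    h <- smith_waterman(a, b)
    if (h$raw_score == 0) next
    expect_equal(gsub("-", "", h$aligned_query),
                 substr(a, h$query_span[1], h$query_span[2]))
    expect_equal(gsub("-", "", h$aligned_target),
                 substr(b, h$target_span[1], h$target_span[2]))
  }
})

test_that("E-value follows the Karlin-Altschul expectation", {
  # bit score with 2^(-S) m n = 1 gives E = 1 exactly
  expect_equal(e_value(log2(200 * 1e6), 200, 1e6), 1)
  # linear in database size
  expect_equal(e_value(50, 200, 2e6), 2 * e_value(50, 200, 1e6))
  # 200 bits, m = 200, n = 1e6: far below the survey cutoff
  expect_equal(e_value(200, 200, 1e6), 2e8 * 2^-200)
  expect_lt(e_value(200, 200, 1e6), 1e-40)
  expect_error(e_value(10, 0, 100), "positive")
})

test_that("search returns qualifying best hits invariant to database order", {
  set.seed(41)
  self <- protein_records("q1", random_aa(200))
  db <- rbind(
    protein_records("t_self", self$sequence),
    protein_records(paste0("r", 1:5),
                    vapply(1:5, function(i) random_aa(200), character(1))))
  hits <- search(self, db, e_threshold = 1e-40)
  expect_equal(hits$target_id, "t_self")  # only the identical entry

  # shuffled unrelated sequence never reaches the cutoff
  shuf <- protein_records("shuf", paste(
    sample(strsplit(self$sequence, "")[[1]]), collapse = ""))
  expect_equal(nrow(search(shuf, db[-1, ], e_threshold = 1e-40)), 0L)

  # empty database
  expect_equal(nrow(search(self, db[0, ], 1e-2)), 0L)

  # database input order leaves results identical
  loose <- search(self, db, e_threshold = 1e6)
  perm <- search(self, db[sample(nrow(db)), ], e_threshold = 1e6)
  expect_equal(loose, perm)
})

test_that("discovery finds exactly the implanted homologs", {
  spec <- simulation_spec(seqs_per_family = 10, seed = 51)
  fam <- simulate_family(spec, prefix = "fcp", family_label = "lhcf")
  set.seed(52)
  bg <- protein_records(paste0("bg", 1:50),
                        vapply(1:50, function(i) random_aa(210),
                               character(1)))
  proteome <- validate_records(rbind(fam$records[1:5, ], bg))
  queries <- fam$records[6:10, ]
  found <- discover_fcp(proteome, queries, e_threshold = 1e-40)
  expect_setequal(found$id, fam$records$id[1:5])
  expect_true(all(found$evidence_e_value < 1e-40))

  # a zero threshold admits nothing
  expect_equal(nrow(discover_fcp(proteome, queries, e_threshold = 0)), 0L)
  expect_error(discover_fcp(proteome, queries[0, ]), "empty")
})

test_that("best-hit family assignment flags weak and missing evidence", {
  panel <- simulate_classification_panel(simulation_spec(seed = 61))
  p <- panel$panels

  # self-hit dominates: unambiguous call of the true family
  cand <- p$lhcf[1, , drop = FALSE]
  cand$family_label <- NA_character_
  a <- assign_family(cand, p)
  expect_equal(a$best_family, "lhcf")
  expect_false(a$ambiguous)
  expect_true(is.na(a$final_family))

  # unrelated sequence: no qualifying hit at the strict cutoff
  set.seed(62)
  stray <- protein_records("stray", random_aa(210))
  a2 <- assign_family(stray, p, e_threshold = 1e-40)
  expect_equal(a2$best_family, "unclassified")
  expect_true(a2$ambiguous)

  # a single weak qualifying hit is ambiguous (the Lhcf23 situation)
  a3 <- assign_family(stray, p, e_threshold = 1e6)
  expect_true(a3$ambiguous)
})

test_that("clade reconciliation resolves ambiguity by labeled majority", {
  tree <- ape::read.tree(text = paste0(
    "((q1:1,(f1:1,(f2:1,f3:1):1):1):1,((r1:1,(r2:1,r3:1):1):1,",
    "(q2:1,(x1:1,(r4:1,(x2:1,x3:1):1):1):1):1):1);"))
  labels <- c(f1 = "lhcf", f2 = "lhcf", f3 = "lhcf", r1 = "lhcr",
              r2 = "lhcr", r3 = "lhcr", x1 = "lhcx", x2 = "lhcx",
              x3 = "lhcx", r4 = "lhcr")
  amb <- function(id, fam) data.frame(
    seq_id = id, best_family = fam, best_hit_id = "h", best_e_value = 1e-50,
    margin = 2, ambiguous = TRUE, final_family = NA_character_,
    evidence = "weak", stringsAsFactors = FALSE)
  firm <- function(id, fam) {
    d <- amb(id, fam); d$ambiguous <- FALSE; d$margin <- 100; d
  }

  # ambiguous lhcr-best candidate inside an all-lhcf clade flips to lhcf
  res <- reconcile_with_clades(amb("q1", "lhcr"), tree, labels, k = 3)
  expect_equal(res$final_family, "lhcf")
  expect_match(res$evidence, "clade vote lhcf")

  # unambiguous assignment ignores the tree
  res2 <- reconcile_with_clades(firm("q1", "lhcr"), tree, labels, k = 3)
  expect_equal(res2$final_family, "lhcr")

  # a tied clade vote leaves the sequence unclassified
  res3 <- reconcile_with_clades(amb("q2", "lhcx"), tree,
                                labels[c("x1", "r4")], k = 2)
  expect_equal(res3$final_family, "unclassified")
  expect_match(res3$evidence, "tied")

  expect_error(reconcile_with_clades(amb("nope", "lhcf"), tree, labels),
               "nope")
})
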