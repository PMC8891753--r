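test_that("p-distance uses pairwise deletion", {
  m <- msa(c("a", "b", "c", "d"),
           c("AAAA", "AAAT", "A-CD", "AXCD"))
  expect_equal(p_distance(m, "a", "a"), 0)
  expect_equal(p_distance(m, "a", "b"), 0.25)
  # three shared ungapped columns, all equal
  expect_equal(p_distance(m, "c", "d"), 0)
  g <- msa(c("x", "y"), c("AA--", "--AA"))
  expect_error(p_distance(g, "x", "y"), "no ungapped column")
})

test_that("20-state Jukes-Cantor matches its closed form and domain", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.5), 0.95 * log(19 / 9))
  expect_error(jukes_cantor(0.95), "saturated")
  expect_error(jukes_cantor(-0.1), "saturated|lie")
  p <- seq(0, 0.9, by = 0.05)
  expect_true(all(jukes_cantor(p) >= p))
  expect_true(all(diff(jukes_cantor(p)) > 0))
})

test_that("neighbor-joining recovers additive trees exactly", {
  # hand-built additive matrix: split AB|CD with exact branch lengths
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  nj <- neighbor_joining(cophenetic(tr))
  expect_true(same_topology(tr, nj))
  # total tree length is preserved (10 on the unrooted tree, internal 2)
  expect_equal(sum(nj$edge.length), 12)
  expect_equal(attr(nj, "clamped_deficit"), 0)

  # 3 taxa: closed-form star resolution
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nj3 <- neighbor_joining(D3)
  vA <- nj3$edge.length[nj3$edge[, 2] == match("A", nj3$tip.label)]
  expect_equal(vA, (3 + 4 - 5) / 2)

  # all-equal distances: deterministic lexicographic tie-break
  De <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(De) <- 0
  t1 <- neighbor_joining(De)
  t2 <- neighbor_joining(De)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))

  expect_error(neighbor_joining(De[1:2, 1:2]), "at least 3")

  # cross-check against the independent ape implementation
  set.seed(91)
  for (k in 1:10) {
    ra <- random_additive(sample(5:8, 1))
    mine <- neighbor_joining(ra$D)
    expect_true(same_topology(mine, ra$tree))
    expect_true(same_topology(mine, ape::nj(as.dist(ra$D))))
  }
})

test_that("bootstrap supports behave as bipartition frequencies", {
  # two identical sisters distinct from the rest: their clade always there
  spec <- simulation_spec(seqs_per_family = 5, rate = 0.4, seed = 101)
  fam <- simulate_family(spec)
  recs <- fam$records
  twin <- recs[1, , drop = FALSE]; twin$id <- "twin"
  recs <- validate_records(rbind(recs, twin))
  aln <- msa(recs$id, recs$sequence)   # substitution-only: already aligned
  tr <- bootstrap_support(aln, n_reps = 50, seed = 7)
  key <- fcptools:::split_key(c(recs$id[1], "twin"), aln$ids)
  sup <- attr(tr, "split_supports")
  expect_equal(unname(sup[key]), 100)
  expect_true(all(sup >= 0 & sup <= 100))

  # reproducible for a fixed seed
  tr2 <- bootstrap_support(aln, n_reps = 50, seed = 7)
  expect_identical(attr(tr2, "split_supports"), sup)

  # degenerate inputs
  same <- msa(paste0("s", 1:4), rep(strrep("ACDE", 5), 4))
  expect_error(bootstrap_support(same, 10, 1), "no signal")
  expect_error(bootstrap_support(msa(c("a", "b", "c"),
                                     c("ACD", "ACE", "AGD")), 10, 1),
               "at least 4")
})

test_that("Lhcf groups follow clade lineage composition", {
  # hand-built cladogram: pure haptophyte (B), pure diatom (C), pure
  # seaweed (D), and a mixed 7-haptophyte + 2-diatom clade (A)
  nwk <- paste0(
    "(((h1:1,h2:1):1,(h3:1,(h4:1,h5:1):1):1)90:1,",
    "((d1:1,(d2:1,d3:1):1)95:1,",
    "((s1:1,(s2:1,s3:1):1)88:1,",
    "((m1:1,(m2:1,m3:1):1):1,((m4:1,(m5:1,m6:1):1):1,",
    "(m7:1,(e1:1,e2:1):1):1):1)92:1):1):1);")
  tree <- ape::read.tree(text = nwk)
  cls <- c(setNames(rep("haptophyte", 5), paste0("h", 1:5)),
           setNames(rep("diatom", 3), paste0("d", 1:3)),
           setNames(rep("seaweed", 3), paste0("s", 1:3)),
           setNames(rep("haptophyte", 7), paste0("m", 1:7)),
           setNames(rep("diatom", 2), paste0("e", 1:2)))
  g <- assign_lhcf_groups(tree, cls, min_support = 50, min_size = 3)
  expect_true(all(g[paste0("h", 1:5)] == "B"))
  expect_true(all(g[paste0("d", 1:3)] == "C"))
  expect_true(all(g[paste0("s", 1:3)] == "D"))
  expect_true(all(g[c(paste0("m", 1:7), "e1", "e2")] == "A"))

  expect_error(assign_lhcf_groups(tree, cls[-1]), "without lineage")
})

test_that("the Lhcz sub-clade is the smallest clade holding the references", {
  nwk <- paste0("(((r1:1,r2:1):1,(r3:1,r4:1):1):1,",
                "((z1:1,(zr1:1,zr2:1):1):1,(z2:1,zr3:1):1):1);")
  tree <- ape::read.tree(text = nwk)
  members <- identify_lhcz(tree, c("zr1", "zr2", "zr3"))
  expect_setequal(members, c("z1", "z2"))
  expect_error(identify_lhcz(tree, "nope"), "missing")
})
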