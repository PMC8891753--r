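test_that("the generator honours its degenerate parameter limits", {
  # zero substitution rate: every family member equals the root
  spec0 <- simulation_spec(seqs_per_family = 6, rate = 0, seed = 3)
  fam0 <- simulate_family(spec0)
  expect_equal(length(unique(fam0$records$sequence)), 1L)
  expect_equal(fam0$records$sequence[1], fam0$truth$root)

  # full retention, no shift: downstream presence is 100% at every site
  ss <- site_spec_table(position = c(20, 50, 80), residue = c("Y", "K", "W"),
                        retention = 1)
  spec1 <- simulation_spec(seqs_per_family = 10, site_spec = ss, seed = 5)
  fam1 <- simulate_family(spec1)
  expect_true(all(fam1$truth$sites$present))
  aln <- msa(c("root", fam1$records$id),
             c(fam1$truth$root, fam1$records$sequence))
  for (k in 1:3) {
    ann <- structure(data.frame(
      site_id = ss$site_id[k], pigment_class = "fx",
      ligand_class = "central", ref_seq_id = "root",
      ref_pos = ss$position[k], primary_residue = ss$residue[k],
      alternate_residues = I(list(character(0))), conserved_flag = TRUE),
      class = c("binding_sites", "data.frame"))
    s <- summarize_site(transfer_site(aln, ann, fam1$records$id), ann)
    expect_equal(s$percent, 100L)
  }

  # invalid specs are rejected
  expect_error(simulation_spec(site_spec = site_spec_table(c(10, 10),
                                                           c("A", "C"))),
               "two sites")
  expect_error(simulation_spec(root_length = 50,
                               site_spec = site_spec_table(60, "A")),
               "within the root")
  expect_error(simulation_spec(seqs_per_family = 1), ">= 2")
})

test_that("identical seeds give identical FASTA and truth output", {
  spec <- simulation_spec(seqs_per_family = 8, seed = 17,
                          site_spec = site_spec_table(30, "Y",
                                                      retention = 0.7))
  a <- simulate_family(spec)
  b <- simulate_family(spec)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$sites, b$truth$sites)
  fa <- withr::local_tempfile(fileext = ".fasta")
  fb <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(a$records, fa); write_fasta(b$records, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("within-family divergence increases with the substitution rate", {
  mean_pdist <- function(rate, seed) {
    fam <- simulate_family(simulation_spec(seqs_per_family = 10,
                                           rate = rate, seed = seed))
    aln <- msa(fam$records$id, fam$records$sequence)
    D <- distance_matrix(aln, model = "p")
    mean(D[upper.tri(D)])
  }
  rates <- c(0.05, 0.15, 0.3, 0.5)
  means <- vapply(rates, function(r)
    mean(vapply(1:3, function(s) mean_pdist(r, s), numeric(1))),
    numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("binomial retention recovers its probability", {
  # empirical presence over many seeds stays inside the central 99%
  # binomial band for n draws at the specified retention
  r <- 0.8; n_seq <- 50; n_seeds <- 30
  present <- vapply(seq_len(n_seeds), function(s) {
    fam <- simulate_family(simulation_spec(
      seqs_per_family = n_seq, seed = 1000 + s,
      site_spec = site_spec_table(40, "W", retention = r)))
    sum(fam$truth$sites$present)
  }, numeric(1))
  total <- sum(present); draws <- n_seq * n_seeds
  band <- qbinom(c(0.005, 0.995), draws, r)
  expect_gte(total, band[1])
  expect_lte(total, band[2])
})

test_that("classification panels hold out queries with complete truth", {
  spec <- simulation_spec(seqs_per_family = 20, n_query = 5, seed = 23)
  panel <- simulate_classification_panel(spec)
  expect_named(panel$panels, c("lhcf", "lhcr", "lhcx"))
  expect_equal(vapply(panel$panels, nrow, integer(1)),
               c(lhcf = 15L, lhcr = 15L, lhcx = 15L))
  expect_equal(nrow(panel$queries), 15L)
  expect_equal(nrow(panel$truth), 60L)
  expect_setequal(c(panel$queries$id,
                    unlist(lapply(panel$panels, `[[`, "id"))),
                  panel$truth$id)

  # identical family roots (and no within-family divergence) collapse the
  # classifier margin: top scores tie across families
  deg <- simulate_classification_panel(
    simulation_spec(seqs_per_family = 8, n_query = 2, rate = 0,
                    between_divergence = 0, seed = 29))
  a <- assign_family(deg$queries[1, , drop = FALSE], deg$panels,
                     e_threshold = 1e-10)
  expect_true(a$ambiguous)
})
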