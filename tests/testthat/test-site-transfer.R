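# small annotated fixture: reference row plus targets in known states
fixture_ann <- function(site_id = "Fx302_Y", primary = "Y",
                        alternates = character(0), pigment = "fx",
                        ligand = "central", pos = 5L) {
  structure(data.frame(site_id = site_id, pigment_class = pigment,
                       ligand_class = ligand, ref_seq_id = "ref",
                       ref_pos = pos, primary_residue = primary,
                       alternate_residues = I(list(alternates)),
                       conserved_flag = TRUE, stringsAsFactors = FALSE),
            class = c("binding_sites", "data.frame"))
}

test_that("site transfer finds exact, shifted and alternate matches", {
  #            123456789012
  aln <- msa(c("ref", "t_exact", "t_shift3", "t_absent", "t_alt", "t_x"),
             c("AAAAYAAAAAAA",
               "AAAAYAAAAAAA",    # primary in the mapped column
               "AAAAGAAYAAAA",    # Y three residues downstream
               "AAAAGAAAAAAA",    # no allowed residue anywhere near
               "AAAAFAAAAAAA",    # alternate residue in the column
               "AAAAXAAAAAAA"))   # X never matches
  ann <- fixture_ann(alternates = "F")
  targets <- c("t_exact", "t_shift3", "t_absent", "t_alt", "t_x")

  calls <- transfer_site(aln, ann, targets, shift_window = 3)
  expect_equal(calls$present,
               c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(calls$offset, c(0L, 3L, NA, 0L, NA))
  expect_equal(calls$via_alternate, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(calls$matched_residue, c("Y", "Y", NA, "F", NA))

  # the +3 shift is recognized only when the window allows it
  w2 <- transfer_site(aln, ann, "t_shift3", shift_window = 2)
  expect_false(w2$present)
  w3 <- transfer_site(aln, ann, "t_shift3", shift_window = 3)
  expect_true(w3$present)
  expect_equal(w3$offset, 3L)

  # offsets are counted in target residues, skipping gaps
  g <- msa(c("ref", "tg"), c("AAAAYAAAA", "AAA--AYAA"))
  cg <- transfer_site(g, fixture_ann(pos = 5L), "tg", shift_window = 3)
  expect_true(cg$present)
  expect_equal(cg$offset, 2L)   # two residues beyond the mapped point
})

test_that("presence is invariant to unrelated rows and call order", {
  aln <- msa(c("ref", "t1", "t2"),
             c("AAAAYAAAA", "AAAAYAAAA", "AAAAGAAAA"))
  ann <- fixture_ann()
  base <- transfer_site(aln, ann, c("t1", "t2"))
  wider <- msa(c(aln$ids, "zz"),
               c(unname(aln$seqs), "CCCCCCCCC"))
  again <- transfer_site(wider, ann, c("t1", "t2"))
  expect_equal(base, again)

  s1 <- summarize_site(base, ann)
  s2 <- summarize_site(base[2:1, ], ann)
  expect_equal(s1$percent, s2$percent)
})

test_that("site summaries round half-up to printed integers", {
  mk <- function(n_present, n_total) {
    data.frame(site_id = "a406_K",
               target_id = paste0("t", seq_len(n_total)),
               present = c(rep(TRUE, n_present),
                           rep(FALSE, n_total - n_present)),
               matched_residue = NA, offset = NA, via_alternate = FALSE,
               stringsAsFactors = FALSE)
  }
  ann <- fixture_ann("a406_K", "K", pigment = "chl_a", ligand = "h_bond")
  expect_equal(summarize_site(mk(25, 28), ann)$percent, 89L)  # 89.29
  expect_equal(summarize_site(mk(0, 12), ann)$percent, 0L)
  expect_equal(summarize_site(mk(2, 3), ann)$percent, 67L)    # 66.67
  expect_equal(summarize_site(mk(1, 8), ann)$percent, 13L)    # 12.5 up
  expect_error(summarize_site(mk(2, 3)[0, ], ann), "no calls")
})

test_that("site report groups ligand rows and applies default exclusions", {
  sums <- rbind(
    summarize_site(data.frame(site_id = "a401_P", target_id = "t1",
                              present = TRUE, matched_residue = "P",
                              offset = 0L, via_alternate = FALSE),
                   fixture_ann("a401_P", "P", pigment = "chl_a")),
    summarize_site(data.frame(site_id = "Fx306_W", target_id = "t1",
                              present = TRUE, matched_residue = "W",
                              offset = 0L, via_alternate = FALSE),
                   fixture_ann("Fx306_W", "W")))
  rep1 <- build_site_report(sums)
  expect_equal(rep1$site, "a401")           # Fx306 excluded by default
  rep2 <- build_site_report(sums, exclude_sites = character(0))
  expect_equal(nrow(rep2), 2L)

  empty <- build_site_report(sums[0, ])
  expect_equal(nrow(empty), 0L)
  expect_true("percent" %in% names(empty))

  expect_error(build_site_report(rbind(sums, sums)), "duplicate")
})

test_that("found-site counting needs one present ligand per pigment site", {
  mk_sum <- function(site_id, pigment, percent)
    data.frame(site_id = site_id, pigment_class = pigment,
               ligand_class = "central", residues = "K",
               conserved_flag = TRUE, n_present = percent %/% 10,
               n_total = 10L, percent = percent, stringsAsFactors = FALSE)
  sums <- rbind(mk_sum("a401_P", "chl_a", 60),
                mk_sum("a401_Q", "chl_a", 0),
                mk_sum("c408_Q", "chl_c", 0),
                mk_sum("c408_NH", "chl_c", 90),
                mk_sum("Fx302_Y", "fx", 50),
                mk_sum("Fx302_T", "fx", 0),
                mk_sum("Fx305_L", "fx", 0))
  n <- count_sites_found(sums)
  expect_equal(n[["n_chl"]], 2L)   # both chl sites have one present ligand
  expect_equal(n[["n_fx"]], 1L)    # Fx305 has none
  expect_equal(count_sites_found(sums[0, ]), c(n_chl = 0L, n_fx = 0L))

  # a site whose only evidence is a shifted alternate match still counts
  aln <- msa(c("ref", "t1"), c("AAAAYAAAA", "AAFAAAAAA"))
  ann <- fixture_ann(alternates = "F")
  calls <- transfer_site(aln, ann, "t1", shift_window = 3)
  expect_true(calls$present && calls$via_alternate && calls$offset != 0)
  s <- summarize_site(calls, ann)
  expect_equal(count_sites_found(s)[["n_fx"]], 1L)
})
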