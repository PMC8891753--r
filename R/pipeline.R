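#' Pipeline configuration
#'
#' Collects every tunable of the annotation pipeline with its survey
#' default: the discovery E-value cutoff (`1e-40`), BLOSUM62 with gap open
#' 11 / extend 1, a 10-bit family margin below which best-hit calls are
#' ambiguous, 100 bootstrap replicates, a 3-residue shift window for site
#' transfer, clade thresholds for Lhcf group assignment, and the
#' Karlin-Altschul constants of the scoring system.
#'
#' @param e_threshold E-value cutoff for discovery and qualifying hits.
#' @param matrix substitution matrix name.
#' @param gap_open,gap_extend affine gap penalties.
#' @param margin_bits bit-score family margin for unambiguous assignment.
#' @param bootstrap_reps bootstrap replicates for cladogram supports.
#' @param shift_window residue shift window for site transfer.
#' @param min_support,min_size clade thresholds for Lhcf groups A-D.
#' @param k_clade labeled leaves required of a reconciling clade.
#' @param lambda,K Karlin-Altschul constants (gapped BLOSUM62 defaults).
#' @param seed integer seed for the bootstrap.
#' @return A list of class `fcp_config`.
#' @export
fcp_config <- function(e_threshold = 1e-40, matrix = "BLOSUM62",
                       gap_open = 11, gap_extend = 1, margin_bits = 10,
                       bootstrap_reps = 100L, shift_window = 3L,
                       min_support = 50, min_size = 3L, k_clade = 3L,
                       lambda = 0.267, K = 0.041, seed = 1L) {
  cfg <- list(e_threshold = e_threshold, matrix = matrix,
              gap_open = gap_open, gap_extend = gap_extend,
              margin_bits = margin_bits,
              bootstrap_reps = as.integer(bootstrap_reps),
              shift_window = as.integer(shift_window),
              min_support = min_support, min_size = as.integer(min_size),
              k_clade = as.integer(k_clade), lambda = lambda, K = K,
              seed = as.integer(seed))
  stopifnot(cfg$e_threshold >= 0, cfg$gap_open > 0, cfg$gap_extend > 0,
            cfg$bootstrap_reps >= 1L, cfg$shift_window >= 0L,
            cfg$min_support >= 0, cfg$min_support <= 100,
            cfg$min_size >= 1L, cfg$k_clade >= 1L, cfg$lambda > 0,
            cfg$K > 0)
  structure(cfg, class = "fcp_config")
}

#' Run the full annotation pipeline
#'
#' Orchestrates discovery, best-hit family classification, cladogram
#' construction with bootstrap supports, clade reconciliation of ambiguous
#' assignments, Lhcf group A-D assignment, Lhcz sub-clade detection and
#' binding-site transfer, and optionally writes every result table to
#' `output_dir` together with a run manifest.
#'
#' @param proteome target proteome ([protein_records()]).
#' @param panels named list of labeled reference panels (at least `lhcf`,
#'   `lhcr`, `lhcx`).
#' @param site_annotations optional `binding_sites` table (see
#'   [read_site_annotations()]).
#' @param ref_lhcf reference Lhcf records carrying the annotated sites
#'   (required with `site_annotations`).
#' @param lhcf_panel optional multi-species Lhcf panel for the group A-D
#'   cladogram; target Lhcf candidates it contains are recognized by id.
#' @param species_class named lineage vector for `lhcf_panel` ids
#'   (`haptophyte`/`diatom`/`seaweed`).
#' @param lhcz_refs optional reference Lhcz-like records for sub-clade
#'   detection among the Lhcr candidates.
#' @param config an [fcp_config()].
#' @param output_dir optional directory for result files.
#' @return An object of class `fcp_run`: `candidates`, `assignments`,
#'   `tree` (FCP cladogram with supports), `lhcf_tree`, `lhcf_groups`,
#'   `lhcz_members`, `site_calls`, `site_report`, `sites_found`,
#'   `manifest`.
#' @export
run_pipeline <- function(proteome, panels, site_annotations = NULL,
                         ref_lhcf = NULL, lhcf_panel = NULL,
                         species_class = NULL, lhcz_refs = NULL,
                         config = fcp_config(), output_dir = NULL) {
  stopifnot(inherits(config, "fcp_config"))
  sc <- function(f, ...) f(..., matrix = config$matrix,
                           gap_open = config$gap_open,
                           gap_extend = config$gap_extend)

  # stage 1: discovery
  queries <- do.call(rbind, lapply(names(panels), function(f) {
    p <- as.data.frame(panels[[f]]); p$family_label <- f; p
  }))
  queries <- validate_records(queries)
  candidates <- sc(discover_fcp, proteome, queries,
                   e_threshold = config$e_threshold)

  # stage 2: best-hit classification
  assignments <- do.call(rbind, lapply(seq_len(nrow(candidates)),
    function(i) sc(assign_family, candidates[i, , drop = FALSE], panels,
                   e_threshold = config$e_threshold,
                   margin_bits = config$margin_bits)))

  # stage 3: cladogram of candidates + panels, reconciliation
  tree <- NULL
  if (nrow(candidates) > 0L) {
    pool <- validate_records(rbind(
      candidates[, c("id", "species", "family_label", "sequence",
                     "description")], queries))
    aln <- sc(progressive_align, pool)
    tree <- if (length(aln$ids) >= 4L)
      bootstrap_support(aln, n_reps = config$bootstrap_reps,
                        seed = config$seed)
    else neighbor_joining(distance_matrix(aln))
    panel_labels <- setNames(queries$family_label, queries$id)
    assignments <- reconcile_with_clades(assignments, tree, panel_labels,
                                         k = config$k_clade)
  }

  # stage 4: Lhcf group A-D cladogram
  lhcf_tree <- NULL; lhcf_groups <- NULL
  if (!is.null(lhcf_panel)) {
    if (is.null(species_class))
      stop("lhcf_panel requires species_class")
    lhcf_aln <- sc(progressive_align, lhcf_panel)
    lhcf_tree <- bootstrap_support(lhcf_aln,
                                   n_reps = config$bootstrap_reps,
                                   seed = config$seed + 1L)
    lhcf_groups <- assign_lhcf_groups(lhcf_tree, species_class,
                                      min_support = config$min_support,
                                      min_size = config$min_size)
  }

  # stage 5: Lhcz sub-clade among the Lhcr candidates
  lhcz_members <- NULL
  if (!is.null(lhcz_refs) && !is.null(tree)) {
    lhcr_ids <- assignments$seq_id[assignments$final_family == "lhcr"]
    if (length(lhcr_ids) >= 2L) {
      lhcr_pool <- validate_records(rbind(
        candidates[match(lhcr_ids, candidates$id),
                   c("id", "species", "family_label", "sequence",
                     "description")],
        as.data.frame(lhcz_refs)))
      lhcr_aln <- sc(progressive_align, lhcr_pool)
      lhcr_tree <- if (length(lhcr_aln$ids) >= 4L)
        bootstrap_support(lhcr_aln, n_reps = config$bootstrap_reps,
                          seed = config$seed + 2L)
      else neighbor_joining(distance_matrix(lhcr_aln))
      lhcz_members <- identify_lhcz(lhcr_tree, lhcz_refs$id)
    }
  }

  # stage 6: binding-site transfer onto the Lhcf candidates
  site_calls <- NULL; site_report <- NULL; sites_found <- NULL
  if (!is.null(site_annotations)) {
    if (is.null(ref_lhcf))
      stop("site_annotations require ref_lhcf reference records")
    target_ids <- assignments$seq_id[assignments$final_family == "lhcf"]
    if (length(target_ids) > 0L) {
      pool <- validate_records(rbind(
        as.data.frame(ref_lhcf),
        candidates[match(target_ids, candidates$id),
                   c("id", "species", "family_label", "sequence",
                     "description")]))
      site_aln <- sc(progressive_align, pool)
      res <- transfer_all_sites(site_aln, site_annotations, target_ids,
                                shift_window = config$shift_window)
      site_calls <- res$calls
      site_report <- build_site_report(res$summaries)
      sites_found <- count_sites_found(res$summaries)
    }
  }

  fam_counts <- if (nrow(candidates)) table(assignments$final_family)
    else table(character(0))
  manifest <- list(
    package_version = as.character(utils::packageVersion("fcptools")),
    seed = config$seed, config = unclass(config),
    n_proteome = nrow(proteome),
    n_panel = nrow(queries),
    n_candidates = nrow(candidates),
    family_counts = as.list(fam_counts),
    n_ambiguous = sum(assignments$ambiguous %||% logical(0)),
    n_lhcf_panel = if (is.null(lhcf_panel)) 0L else nrow(lhcf_panel),
    n_lhcz = length(lhcz_members %||% character(0)),
    sites_found = as.list(sites_found %||% integer(0)))

  run <- structure(list(candidates = candidates,
                        assignments = assignments, tree = tree,
                        lhcf_tree = lhcf_tree, lhcf_groups = lhcf_groups,
                        lhcz_members = lhcz_members,
                        site_calls = site_calls,
                        site_report = site_report,
                        sites_found = sites_found, manifest = manifest,
                        config = config), class = "fcp_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

write_run <- function(run, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  if (nrow(run$candidates))
    write_fasta(run$candidates[, c("id", "species", "family_label",
                                   "sequence", "description")],
                p("candidates.fasta"))
  write.table(run$assignments, p("assignments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(run$tree)) ape::write.tree(run$tree, p("fcp_tree.nwk"))
  if (!is.null(run$lhcf_tree)) {
    ape::write.tree(run$lhcf_tree, p("lhcf_tree.nwk"))
    write.table(data.frame(id = names(run$lhcf_groups),
                           group = run$lhcf_groups),
                p("lhcf_groups.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(run$site_report)) {
    write.table(run$site_report, p("site_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(run$site_calls, p("site_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  flat <- unlist(run$manifest)
  writeLines(paste(names(flat), flat, sep = "\t"), p("manifest.tsv"))
  invisible(output_dir)
}

#' @export
print.fcp_run <- function(x, ...) {
  m <- x$manifest
  cat("FCP annotation run\n")
  cat(sprintf("  proteome: %d sequences; panel: %d; candidates: %d\n",
              m$n_proteome, m$n_panel, m$n_candidates))
  if (length(m$family_counts))
    cat("  families:",
        paste(sprintf("%s=%s", names(m$family_counts), m$family_counts),
              collapse = ", "), "\n")
  if (!is.null(x$lhcf_groups)) {
    tg <- table(x$lhcf_groups)
    cat("  lhcf groups:",
        paste(sprintf("%s=%d", names(tg), as.integer(tg)),
              collapse = ", "), "\n")
  }
  if (!is.null(x$lhcz_members))
    cat("  lhcz sub-clade members:",
        paste(x$lhcz_members, collapse = ", "), "\n")
  if (!is.null(x$sites_found))
    cat(sprintf("  binding sites found: %d chlorophyll, %d fucoxanthin\n",
                x$sites_found[["n_chl"]], x$sites_found[["n_fx"]]))
  invisible(x)
}

#' @export
summary.fcp_run <- function(object, ...) {
  print(object)
  if (!is.null(object$site_report) && nrow(object$site_report)) {
    cat("\nSite presence among target Lhcf:\n")
    print(object$site_report[, c("site", "ligand_class", "residues",
                                 "n_present", "n_total", "percent")],
          row.names = FALSE)
  }
  invisible(object)
}
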