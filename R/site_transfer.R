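round_half_up <- function(x) floor(x + 0.5)

# pigment site group: the part of site_id before the first underscore, so
# rows "Fx302_R", "Fx302_Y" belong to one pigment site "Fx302"
site_group <- function(site_id) sub("_.*$", "", site_id)

#' Transfer a binding-site annotation onto target sequences
#'
#' Homology transfer through alignment columns: the reference residue's
#' column is located in the MSA, and each target is called *present* when it
#' carries the primary residue (or an allowed alternate) at that column —
#' or, failing that, within a window of `shift_window` residues around it.
#' Offsets are measured in target residues (gaps skipped), nearest first
#' with the negative side preferred on ties, which is how a residue
#' conserved "3 aa shifted" is still recognized. `X` never matches.
#'
#' @param aln an [msa()] object containing the reference and all targets.
#' @param ann one row of a `binding_sites` table (see
#'   [read_site_annotations()]).
#' @param target_ids ids of the target rows to call.
#' @param shift_window maximum residue shift `w >= 0` (default 3, the
#'   largest shift observed in practice).
#' @return A data frame of site calls: `site_id`, `target_id`, `present`,
#'   `matched_residue`, `offset`, `via_alternate`.
#' @export
transfer_site <- function(aln, ann, target_ids, shift_window = 3L) {
  ann <- as.data.frame(ann)
  if (nrow(ann) != 1L) stop("transfer_site expects a single annotation row")
  col <- column_of(aln, ann$ref_seq_id, ann$ref_pos)
  if (residue_at(aln, ann$ref_seq_id, col) == GAP_CHAR)
    stop("site ", ann$site_id, ": reference residue maps to a gap")
  allowed <- setdiff(c(ann$primary_residue, ann$alternate_residues[[1]]), "X")
  offsets <- 0L
  if (shift_window > 0L)
    for (w in seq_len(shift_window)) offsets <- c(offsets, -w, w)
  calls <- lapply(target_ids, function(tid) {
    ch <- strsplit(aln$seqs[match_id(aln, tid)], "")[[1]]
    res_pos <- cumsum(ch != GAP_CHAR)
    n_res <- res_pos[length(res_pos)]
    pos0 <- res_pos[col]              # residue at or left of the column
    residues <- ch[ch != GAP_CHAR]
    hit <- NULL
    for (off in offsets) {
      p <- pos0 + off
      if (p < 1L || p > n_res) next
      if (residues[p] %in% allowed) {
        hit <- list(residue = residues[p], offset = off); break
      }
    }
    data.frame(site_id = ann$site_id, target_id = tid,
               present = !is.null(hit),
               matched_residue = if (is.null(hit)) NA_character_ else
                 hit$residue,
               offset = if (is.null(hit)) NA_integer_ else hit$offset,
               via_alternate = if (is.null(hit)) FALSE else
                 hit$residue %in% ann$alternate_residues[[1]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, calls)
}

#' Summarize site calls into a presence percentage
#'
#' @param calls calls for one site (from [transfer_site()]).
#' @param ann the matching annotation row.
#' @return One-row data frame: `site_id`, `pigment_class`, `ligand_class`,
#'   `residues` (primary plus alternates, " or "-joined), `conserved_flag`,
#'   `n_present`, `n_total`, `percent` (integer, rounded half-up).
#' @export
summarize_site <- function(calls, ann) {
  ann <- as.data.frame(ann)
  if (nrow(calls) == 0L) stop("no calls to summarize for ", ann$site_id)
  if (!all(calls$site_id == ann$site_id))
    stop("calls do not all belong to site ", ann$site_id)
  n <- nrow(calls); np <- sum(calls$present)
  data.frame(site_id = ann$site_id,
             pigment_class = ann$pigment_class,
             ligand_class = ann$ligand_class,
             residues = paste(c(ann$primary_residue,
                                ann$alternate_residues[[1]]),
                              collapse = " or "),
             conserved_flag = ann$conserved_flag,
             n_present = np, n_total = n,
             percent = as.integer(round_half_up(100 * np / n)),
             stringsAsFactors = FALSE)
}

#' Transfer and summarize a whole annotation table
#'
#' Convenience wrapper running [transfer_site()] and [summarize_site()] for
#' every annotation row.
#'
#' @inheritParams transfer_site
#' @param sites a `binding_sites` table.
#' @return `list(calls = <all calls>, summaries = <one row per site>)`.
#' @export
transfer_all_sites <- function(aln, sites, target_ids, shift_window = 3L) {
  calls <- list(); sums <- list()
  for (k in seq_len(nrow(sites))) {
    ann <- sites[k, , drop = FALSE]
    cl <- transfer_site(aln, ann, target_ids, shift_window)
    calls[[k]] <- cl
    sums[[k]] <- summarize_site(cl, ann)
  }
  list(calls = do.call(rbind, calls), summaries = do.call(rbind, sums))
}

#' Per-site presence report
#'
#' Assembles site summaries into the report layout of the pigment-binding
#' tables: one row per ligand residue, grouped by pigment site, with the
#' ligand class and conserved/not-conserved status alongside the presence
#' percentage. Fucoxanthin sites outside the comparable span (Fx306, Fx307
#' by default) are excluded.
#'
#' @param summaries rows from [summarize_site()].
#' @param exclude_sites pigment-site groups to drop from the report.
#' @return A data frame sorted by pigment class, site and ligand class, with
#'   a `site` column naming the pigment site group.
#' @export
build_site_report <- function(summaries,
                              exclude_sites = c("Fx306", "Fx307")) {
  cols <- c("site", "site_id", "pigment_class", "ligand_class", "residues",
            "conserved_flag", "n_present", "n_total", "percent")
  if (is.null(summaries) || nrow(summaries) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols))
    return(out)
  }
  summaries$site <- site_group(summaries$site_id)
  summaries <- summaries[!summaries$site %in% exclude_sites, , drop = FALSE]
  key <- paste(summaries$site, summaries$residues)
  if (anyDuplicated(key))
    stop("duplicate site/residue rows: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  o <- order(summaries$pigment_class, summaries$site,
             summaries$ligand_class, summaries$site_id)
  out <- summaries[o, cols]
  rownames(out) <- NULL
  out
}

#' Count pigment sites found
#'
#' A pigment site counts as found when at least one of its ligand residues
#' is present above `min_percent` ("for multiple sites, at least one is
#' found"). Chlorophyll (a and c) and fucoxanthin sites are counted
#' separately.
#'
#' @param summaries rows from [summarize_site()].
#' @param min_percent presence threshold (default 0: any presence counts).
#' @param exclude_sites pigment-site groups excluded from the count.
#' @return `c(n_chl = ..., n_fx = ...)`.
#' @export
count_sites_found <- function(summaries, min_percent = 0,
                              exclude_sites = c("Fx306", "Fx307")) {
  if (is.null(summaries) || nrow(summaries) == 0L)
    return(c(n_chl = 0L, n_fx = 0L))
  summaries$site <- site_group(summaries$site_id)
  summaries <- summaries[!summaries$site %in% exclude_sites, , drop = FALSE]
  found <- tapply(summaries$percent > min_percent, summaries$site, any)
  pig <- tapply(summaries$pigment_class, summaries$site,
                function(x) x[1])
  c(n_chl = sum(found & pig %in% c("chl_a", "chl_c")),
    n_fx = sum(found & pig == "fx"))
}
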