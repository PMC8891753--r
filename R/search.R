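#' Search queries against a protein database
#'
#' Runs Smith-Waterman for every query x target pair, converts raw scores to
#' bit scores and Karlin-Altschul E-values (query length x total database
#' residues), and keeps hits below the E-value threshold — the in-package
#' equivalent of a BLASTP survey. Each database target is reported at most
#' once per query (its optimal local alignment). Results are sorted by
#' ascending E-value, then query id, then target id, so output is invariant
#' to database input order.
#'
#' @param queries,database [protein_records()] data frames; `database` may
#'   be empty.
#' @param e_threshold E-value cutoff (hits with `e_value < e_threshold` are
#'   kept); the survey default is `1e-40`.
#' @param matrix,gap_open,gap_extend scoring scheme (see [smith_waterman()]).
#' @return A data frame: `query_id`, `target_id`, `raw_score`, `bit_score`,
#'   `e_value`, `q_start`, `q_end`, `t_start`, `t_end`.
#' @export
search <- function(queries, database, e_threshold = 1e-40,
                   matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (nrow(queries) == 0L) stop("no query sequences")
  empty <- data.frame(query_id = character(0), target_id = character(0),
                      raw_score = numeric(0), bit_score = numeric(0),
                      e_value = numeric(0), q_start = integer(0),
                      q_end = integer(0), t_start = integer(0),
                      t_end = integer(0), stringsAsFactors = FALSE)
  if (nrow(database) == 0L) return(empty)
  m <- substitution_matrix(matrix)
  db_res <- sum(nchar(database$sequence))
  enc_db <- lapply(database$sequence, encode_seq, matrix = m)
  rows <- vector("list", nrow(queries) * nrow(database))
  n <- 0L
  for (qi in seq_len(nrow(queries))) {
    eq <- encode_seq(queries$sequence[qi], m)
    qlen <- length(eq)
    for (ti in seq_len(nrow(database))) {
      score <- cpp_sw_score(eq, enc_db[[ti]], m, gap_open, gap_extend)
      bits <- bit_score(score)
      ev <- e_value(bits, qlen, db_res)
      if (ev < e_threshold) {
        res <- cpp_sw_affine(eq, enc_db[[ti]], m, gap_open, gap_extend)
        n <- n + 1L
        rows[[n]] <- data.frame(
          query_id = queries$id[qi], target_id = database$id[ti],
          raw_score = res$score, bit_score = bits, e_value = ev,
          q_start = res$q_start, q_end = res$q_end,
          t_start = res$t_start, t_end = res$t_end,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n == 0L) return(empty)
  hits <- do.call(rbind, rows[seq_len(n)])
  hits <- hits[order(hits$e_value, hits$query_id, hits$target_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Discover FCP candidates in a proteome
#'
#' Searches a panel of known FCP sequences (e.g. diatom Lhcf/Lhcr/Lhcx) as
#' queries against a target proteome and returns the deduplicated set of
#' proteome sequences hit below the E-value threshold, each annotated with
#' its best supporting hit.
#'
#' @param proteome [protein_records()] to scan.
#' @param fcp_queries labeled FCP query panel ([protein_records()]).
#' @param e_threshold discovery E-value cutoff (default `1e-40`).
#' @param ... scoring arguments passed to [search()].
#' @return The hit subset of `proteome` with extra columns `evidence_query`,
#'   `evidence_bit_score`, `evidence_e_value` (best hit per candidate).
#' @export
discover_fcp <- function(proteome, fcp_queries, e_threshold = 1e-40, ...) {
  if (nrow(fcp_queries) == 0L) stop("empty FCP query panel")
  hits <- search(fcp_queries, proteome, e_threshold = e_threshold, ...)
  if (nrow(hits) == 0L) {
    out <- proteome[integer(0), , drop = FALSE]
    out$evidence_query <- character(0)
    out$evidence_bit_score <- numeric(0)
    out$evidence_e_value <- numeric(0)
    return(out)
  }
  best <- hits[order(hits$target_id, -hits$bit_score, hits$query_id), ]
  best <- best[!duplicated(best$target_id), ]
  out <- proteome[match(best$target_id, proteome$id), , drop = FALSE]
  out$evidence_query <- best$query_id
  out$evidence_bit_score <- best$bit_score
  out$evidence_e_value <- best$e_value
  rownames(out) <- NULL
  out
}

#' Assign a candidate to an FCP family by best similarity match
#'
#' Searches the candidate against labeled family panels and assigns the
#' family of the single best bit-score hit. The assignment is flagged
#' ambiguous when fewer than two qualifying hits exist, when the bit-score
#' margin between the best and second-best family falls below `margin_bits`,
#' or when the top score is tied across families — the situation the
#' cladogram later resolves (see [reconcile_with_clades()]).
#'
#' @param candidate one-row [protein_records()] (or sequence string).
#' @param panels named list mapping family (`lhcf`, `lhcr`, `lhcx`, ...) to
#'   a [protein_records()] panel.
#' @param e_threshold qualifying-hit E-value cutoff.
#' @param margin_bits minimum best-vs-second-family bit margin for an
#'   unambiguous call (default 10 bits).
#' @param ... scoring arguments passed to [search()].
#' @return One-row data frame of class `family_assignment`: `seq_id`,
#'   `best_family`, `best_hit_id`, `best_e_value`, `margin`, `ambiguous`,
#'   `final_family` (`NA` until reconciliation), `evidence`.
#' @export
assign_family <- function(candidate, panels, e_threshold = 1e-40,
                          margin_bits = 10, ...) {
  stopifnot(all(c("lhcf", "lhcr", "lhcx") %in% names(panels)))
  cand <- if (is.data.frame(candidate)) candidate else
    protein_records("candidate", seq_of(candidate))
  db <- do.call(rbind, lapply(names(panels), function(f) {
    p <- as.data.frame(panels[[f]])
    p$family_label <- f
    p
  }))
  db <- validate_records(db)
  hits <- search(cand, db, e_threshold = e_threshold, ...)
  mk <- function(best_family, best_hit_id, best_e, margin, ambiguous, evidence)
    structure(data.frame(seq_id = cand$id, best_family = best_family,
                         best_hit_id = best_hit_id, best_e_value = best_e,
                         margin = margin, ambiguous = ambiguous,
                         final_family = NA_character_, evidence = evidence,
                         stringsAsFactors = FALSE),
              class = c("family_assignment", "data.frame"))
  if (nrow(hits) == 0L)
    return(mk("unclassified", NA_character_, NA_real_, NA_real_, TRUE,
              "no hit below E-value threshold"))
  hits$family <- db$family_label[match(hits$target_id, db$id)]
  per_fam <- tapply(hits$bit_score, hits$family, max)
  per_fam <- sort(per_fam, decreasing = TRUE)
  top <- hits[hits$bit_score == max(hits$bit_score), , drop = FALSE]
  tied_families <- length(unique(top$family)) > 1L
  best <- top[order(top$target_id), , drop = FALSE][1, ]
  margin <- if (length(per_fam) > 1L) per_fam[[1]] - per_fam[[2]] else Inf
  ambiguous <- nrow(hits) < 2L || tied_families || margin < margin_bits
  evidence <- if (tied_families)
    "best bit score tied across families"
  else if (nrow(hits) < 2L)
    "single qualifying hit"
  else if (!is.na(margin) && margin < margin_bits)
    sprintf("family margin %.1f bits < %.1f", margin, margin_bits)
  else
    sprintf("best hit %s (%s), margin %.1f bits", best$target_id,
            best$family, margin)
  mk(best$family, best$target_id, best$e_value, margin, ambiguous, evidence)
}

#' Reconcile ambiguous family assignments with a cladogram
#'
#' Best-hit classification can mislabel a sequence on the strength of one
#' weak match; the cladogram provides the corrective. For each ambiguous
#' assignment the smallest enclosing clade holding at least `k` labeled
#' reference leaves votes by majority family; a tie leaves the sequence
#' `unclassified` (flagged in `evidence`). Unambiguous assignments keep
#' their best-hit family regardless of the tree.
#'
#' @param assignments data frame of [assign_family()] rows.
#' @param tree an `ape` `phylo` tree containing all assignment ids and
#'   labeled panel ids as tips.
#' @param panel_labels named character vector mapping panel tip ids to
#'   families.
#' @param k minimum number of labeled leaves in the voting clade (default 3).
#' @return `assignments` with `final_family` filled and `evidence` updated.
#' @export
reconcile_with_clades <- function(assignments, tree, panel_labels, k = 3L) {
  missing <- setdiff(assignments$seq_id, tree$tip.label)
  if (length(missing))
    stop("id(s) missing from tree: ", paste(missing, collapse = ", "))
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  tips_below <- clade_tips(tree)
  for (r in seq_len(nrow(assignments))) {
    if (!isTRUE(assignments$ambiguous[r])) {
      assignments$final_family[r] <- assignments$best_family[r]
      assignments$evidence[r] <- paste0(assignments$evidence[r],
                                        "; accepted by best-hit rule")
      next
    }
    node <- match(assignments$seq_id[r], tree$tip.label)
    verdict <- "unclassified"
    note <- sprintf("no enclosing clade with >= %d labeled leaves", k)
    while (parent[node] != 0L) {
      node <- parent[node]
      labs <- panel_labels[intersect(tips_below[[node]], names(panel_labels))]
      if (length(labs) >= k) {
        tab <- sort(table(labs), decreasing = TRUE)
        if (length(tab) > 1L && tab[1] == tab[2]) {
          note <- "enclosing clade vote tied; left unclassified"
        } else {
          verdict <- names(tab)[1]
          note <- sprintf("clade vote %s (%d/%d labeled leaves)",
                          verdict, tab[[1]], length(labs))
        }
        break
      }
    }
    assignments$final_family[r] <- verdict
    assignments$evidence[r] <- paste0(assignments$evidence[r], "; ", note)
  }
  assignments
}

# tip labels below every node (tips themselves included), by postorder sweep
clade_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  out <- vector("list", n_node)
  for (i in seq_len(n_tip)) out[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}
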