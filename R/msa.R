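#' Multiple sequence alignments
#'
#' An `msa` object holds gapped rows of identical length plus the row ids.
#' Removing gaps from any row reproduces the input sequence of that id — an
#' invariant checked on construction.
#'
#' @param ids character vector of row ids.
#' @param seqs gapped sequences (gap character `-`), equal lengths.
#' @return An object of class `msa` with fields `ids`, `seqs`, `n_columns`.
#' @export
msa <- function(ids, seqs) {
  ids <- as.character(ids); seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (anyDuplicated(ids)) stop("duplicate ids in MSA")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("MSA rows differ in length")
  structure(list(ids = ids, seqs = setNames(seqs, ids), n_columns = L),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d columns\n", length(x$ids), x$n_columns))
  invisible(x)
}

#' @rdname msa
#' @param x an `msa` object.
#' @param ... unused.
#' @export
as.matrix.msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(unname(x$seqs), ""))
  rownames(m) <- x$ids
  m
}

ungap <- function(s) gsub("-", "", s, fixed = TRUE)

# character MSA matrix -> integer codes (1..21 for alphabet, 0 for gap)
msa_codes <- function(x) {
  m <- as.matrix.msa(x)
  codes <- match(m, AA_ALPHABET)
  codes[is.na(codes)] <- 0L
  matrix(codes, nrow = nrow(m), dimnames = dimnames(m))
}

#' Column of a residue / residue at a column
#'
#' `column_of()` maps a 1-based residue position of a row to its 1-based
#' alignment column; `residue_at()` is its inverse and returns the gap
#' character `-` when the row is gapped at that column (never a residue).
#'
#' @param aln an [msa()] object.
#' @param seq_id row id.
#' @param pos 1-based residue position in the ungapped sequence.
#' @param column 1-based alignment column.
#' @return `column_of()`: integer column index. `residue_at()`: a single
#'   character.
#' @examples
#' a <- msa(c("r1", "r2"), c("A-CD", "AXCD"))
#' column_of(a, "r1", 2)    # 3
#' residue_at(a, "r1", 2)   # "-"
#' @export
column_of <- function(aln, seq_id, pos) {
  row <- aln$seqs[match_id(aln, seq_id)]
  ch <- strsplit(row, "")[[1]]
  res_idx <- cumsum(ch != GAP_CHAR)
  if (pos < 1L || pos > max(res_idx))
    stop("position ", pos, " out of range for ", seq_id)
  match(pos, res_idx * (ch != GAP_CHAR))
}

#' @rdname column_of
#' @export
residue_at <- function(aln, seq_id, column) {
  if (column < 1L || column > aln$n_columns)
    stop("column ", column, " out of range")
  unname(substr(aln$seqs[match_id(aln, seq_id)], column, column))
}

match_id <- function(aln, seq_id) {
  i <- match(seq_id, aln$ids)
  if (is.na(i)) stop("unknown sequence id: ", seq_id)
  i
}

#' Progressive multiple alignment
#'
#' Generic progressive aligner: all-against-all global pairwise alignments
#' give p-distances, a neighbor-joining guide tree orders the merges, and
#' profiles are merged leaf-to-root by global profile-profile alignment
#' (mean sum-of-pairs column scores, affine gaps). Deterministic for a fixed
#' input order; no iterative refinement.
#'
#' @param seqs [protein_records()] (>= 1 row; a single sequence comes back
#'   as a 1-row MSA).
#' @param matrix,gap_open,gap_extend scoring scheme.
#' @return An [msa()] object.
#' @export
progressive_align <- function(seqs, matrix = "BLOSUM62", gap_open = 11,
                              gap_extend = 1) {
  n <- nrow(seqs)
  if (n == 0L) stop("no sequences to align")
  if (n == 1L) return(msa(seqs$id, seqs$sequence))
  m <- substitution_matrix(matrix)
  if (n == 2L) {
    g <- global_align(seqs$sequence[1], seqs$sequence[2], m,
                      gap_open, gap_extend)
    return(msa(seqs$id, c(g$aligned_a, g$aligned_b)))
  }
  # guide distances from pairwise global alignments (pairwise deletion)
  enc <- lapply(seqs$sequence, encode_seq, matrix = m)
  D <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      colscore <- m[enc[[i]] + 1L, enc[[j]] + 1L, drop = FALSE]
      path <- cpp_nw_affine(colscore, gap_open, gap_extend)
      pa <- path$a_path; pb <- path$b_path
      both <- pa > 0 & pb > 0
      diffs <- enc[[i]][pa[both]] != enc[[j]][pb[both]]
      D[i, j] <- D[j, i] <- mean(diffs)
    }
  }
  guide <- neighbor_joining(D)
  # postorder profile merge over the guide tree
  nodes <- vector("list", max(guide$edge))
  for (i in seq_len(n)) {
    k <- match(guide$tip.label[i], seqs$id)
    nodes[[i]] <- list(ids = seqs$id[k], rows = seqs$sequence[k])
  }
  ord <- ape::reorder.phylo(guide, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    nodes[[p]] <- if (is.null(nodes[[p]])) nodes[[ch]] else
      merge_profiles(nodes[[p]], nodes[[ch]], m, gap_open, gap_extend)
  }
  root <- ord$edge[nrow(ord$edge), 1]
  prof <- nodes[[root]]
  # restore input row order
  o <- match(seqs$id, prof$ids)
  out <- msa(prof$ids[o], prof$rows[o])
  stopifnot(identical(unname(vapply(out$seqs, ungap, character(1))),
                      unname(seqs$sequence[match(out$ids, seqs$id)])))
  out
}

profile_counts <- function(rows, matrix) {
  ch <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(ch)
  letters <- rownames(matrix)
  counts <- matrix(0, nrow = length(letters), ncol = L,
                   dimnames = list(letters, NULL))
  code <- matrix(match(ch, letters), nrow = nrow(ch))   # NA for gaps
  for (k in seq_len(L)) {
    ck <- code[, k]
    tab <- tabulate(ck[!is.na(ck)], nbins = length(letters))
    counts[, k] <- tab
  }
  counts
}

merge_profiles <- function(a, b, matrix, gap_open, gap_extend) {
  CA <- profile_counts(a$rows, matrix)
  CB <- profile_counts(b$rows, matrix)
  na <- length(a$ids); nb <- length(b$ids)
  colscore <- crossprod(CA, matrix %*% CB) / (na * nb)
  path <- cpp_nw_affine(colscore, gap_open, gap_extend)
  pa <- path$a_path; pb <- path$b_path
  expand <- function(rows, p) {
    mat <- do.call(rbind, strsplit(rows, ""))
    out <- matrix(GAP_CHAR, nrow = nrow(mat), ncol = length(p))
    out[, p > 0] <- mat[, p[p > 0], drop = FALSE]
    apply(out, 1, paste, collapse = "")
  }
  list(ids = c(a$ids, b$ids),
       rows = c(expand(a$rows, pa), expand(b$rows, pb)))
}

#' Sum-of-pairs score of an alignment
#'
#' Simple sum-of-pairs: substitution score for every residue pair per
#' column; pairs involving a gap contribute zero (no affine bookkeeping).
#' Used as a determinism / sanity diagnostic, not as an objective.
#'
#' @param aln an [msa()] object.
#' @param matrix substitution matrix or name.
#' @return Numeric score.
#' @export
msa_sp_score <- function(aln, matrix = "BLOSUM62") {
  m <- substitution_matrix(matrix)
  C <- profile_counts(unname(aln$seqs), m)
  tot <- 0
  for (k in seq_len(ncol(C))) {
    ck <- C[, k]
    pair <- tcrossprod(ck)
    score <- sum(pair * m) - sum(diag(m) * ck)  # unordered pairs, no self
    tot <- tot + score / 2
  }
  tot
}

#' Read / write aligned FASTA
#'
#' @param path file path.
#' @return `read_msa()`: an [msa()] object. `write_msa()`: `path`,
#'   invisibly.
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  msa(sub("\\s.*$", "", names(aa)), as.character(aa))
}

#' @rdname read_msa
#' @param aln an [msa()] object.
#' @export
write_msa <- function(aln, path) {
  aa <- Biostrings::AAStringSet(unname(aln$seqs))
  names(aa) <- aln$ids
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}
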