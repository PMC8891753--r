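#' Substitution matrices
#'
#' Returns a validated amino-acid substitution matrix. `"BLOSUM62"` (the
#' default used throughout the pipeline, with gap open 11 / extend 1 — the
#' classic BLASTP parameterization) is taken from Biostrings. A custom matrix
#' may be supplied anywhere a matrix name is accepted: it must be symmetric,
#' cover the 20 canonical letters plus `X`, and have positive diagonal
#' entries for the canonical letters.
#'
#' @param name matrix name (currently `"BLOSUM45"`, `"BLOSUM50"`,
#'   `"BLOSUM62"`, `"BLOSUM80"`, `"BLOSUM100"`, `"PAM30"`, `"PAM40"`,
#'   `"PAM70"`, `"PAM120"`, `"PAM250"`) or a numeric matrix.
#' @return A numeric matrix with an attribute `name`.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  if (is.matrix(name)) {
    m <- name
    attr(m, "name") <- attr(name, "name") %||% "custom"
  } else {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    m <- get(name, envir = e)
    attr(m, "name") <- name
  }
  validate_matrix(m)
}

validate_matrix <- function(m) {
  missing <- setdiff(AA_ALPHABET, rownames(m))
  if (length(missing) || !identical(rownames(m), colnames(m)))
    stop("substitution matrix must cover letters: ",
         paste(missing, collapse = ", "))
  if (!isSymmetric(unname(m[AA_ALPHABET, AA_ALPHABET])))
    stop("substitution matrix must be symmetric")
  if (any(diag(m[AA_LETTERS, AA_LETTERS]) <= 0))
    stop("substitution matrix diagonal must be positive for canonical letters")
  m
}

encode_seq <- function(seq, matrix) {
  ch <- strsplit(seq, "")[[1]]
  code <- match(ch, rownames(matrix))
  if (anyNA(code))
    stop("substitution matrix lacks letter(s): ",
         paste(unique(ch[is.na(code)]), collapse = ", "))
  code - 1L
}

# Karlin-Altschul constants for gapped BLOSUM62 (11/1); part of the default
# config, overridable there.
KARLIN_GAPPED_BLOSUM62 <- c(lambda = 0.267, K = 0.041)

#' Bit score from a raw alignment score
#'
#' Standard Karlin-Altschul normalization: `(lambda * S - ln K) / ln 2`.
#'
#' @param raw_score raw alignment score.
#' @param lambda,K Karlin-Altschul statistical parameters for the scoring
#'   system; defaults are the standard gapped BLOSUM62 (11/1) constants.
#' @return Bit score (numeric).
#' @export
bit_score <- function(raw_score,
                      lambda = KARLIN_GAPPED_BLOSUM62[["lambda"]],
                      K = KARLIN_GAPPED_BLOSUM62[["K"]]) {
  (lambda * raw_score - log(K)) / log(2)
}

#' Karlin-Altschul expectation (E-value)
#'
#' `E = m * n * 2^(-bit_score)`: the expected number of chance local
#' alignments reaching the given bit score when a query of `query_len`
#' residues is searched against a database of `db_residues` residues.
#'
#' @param bit_score normalized bit score.
#' @param query_len query length in residues (m), positive.
#' @param db_residues total residues in the database (n), positive.
#' @return E-value (numeric, >= 0).
#' @export
e_value <- function(bit_score, query_len, db_residues) {
  if (any(query_len <= 0) || any(db_residues <= 0))
    stop("query_len and db_residues must be positive")
  as.numeric(query_len) * as.numeric(db_residues) * 2^(-bit_score)
}

seq_of <- function(x) {
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single protein record")
    return(x$sequence)
  }
  if (is.list(x) && !is.null(x$sequence)) return(x$sequence)
  stop("cannot interpret input as a protein sequence")
}

id_of <- function(x, fallback) {
  if (is.data.frame(x) || (is.list(x) && !is.null(x$id))) return(x$id)
  fallback
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment under affine gap penalties (a gap of length L
#' costs `gap_open + L * gap_extend`). Ties among equal-scoring optima break
#' deterministically to the lowest-coordinate end cell. The raw score is
#' floored at zero; two sequences with no positively scoring residue pair
#' yield score 0 and empty spans.
#'
#' @param a,b query and target: single sequences as strings, or one-row
#'   [protein_records()].
#' @param matrix substitution matrix name or matrix (see
#'   [substitution_matrix()]).
#' @param gap_open,gap_extend positive gap penalties.
#' @return A list of class `hit_result`: `query_id`, `target_id`,
#'   `raw_score`, `bit_score`, `e_value` (`NA` until a database search
#'   supplies sizes), 1-based inclusive `query_span`/`target_span`, and
#'   equal-length gapped strings `aligned_query`/`aligned_target`.
#' @examples
#' smith_waterman("ACDEFGH", "ACDEFGH")$raw_score  # 44 under BLOSUM62
#' @export
smith_waterman <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1) {
  sa <- seq_of(a); sb <- seq_of(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("sequences must be non-empty")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive")
  m <- substitution_matrix(matrix)
  res <- cpp_sw_affine(encode_seq(sa, m), encode_seq(sb, m), m,
                       gap_open, gap_extend)
  ap <- res$a_path; bp <- res$b_path
  cha <- strsplit(sa, "")[[1]]; chb <- strsplit(sb, "")[[1]]
  aligned_a <- if (length(ap)) paste(ifelse(ap > 0, cha[pmax(ap, 1)],
                                            GAP_CHAR), collapse = "") else ""
  aligned_b <- if (length(bp)) paste(ifelse(bp > 0, chb[pmax(bp, 1)],
                                            GAP_CHAR), collapse = "") else ""
  empty <- res$score <= 0
  structure(list(
    query_id = id_of(a, "query"), target_id = id_of(b, "target"),
    raw_score = res$score,
    bit_score = bit_score(res$score),
    e_value = NA_real_,
    query_span = if (empty) integer(0) else c(res$q_start, res$q_end),
    target_span = if (empty) integer(0) else c(res$t_start, res$t_end),
    aligned_query = aligned_a, aligned_target = aligned_b
  ), class = "hit_result")
}

#' @export
print.hit_result <- function(x, ...) {
  cat(sprintf("local alignment %s vs %s: raw %g, bits %.1f, E %s\n",
              x$query_id, x$target_id, x$raw_score, x$bit_score,
              ifelse(is.na(x$e_value), "NA", format(x$e_value, digits = 3))))
  invisible(x)
}

# Global (Needleman-Wunsch, affine) alignment of two sequences; used for
# guide-tree distances and gapped fixtures. Same gap convention as SW.
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                         gap_extend = 1) {
  sa <- seq_of(a); sb <- seq_of(b)
  m <- substitution_matrix(matrix)
  ea <- encode_seq(sa, m); eb <- encode_seq(sb, m)
  colscore <- m[ea + 1L, eb + 1L, drop = FALSE]
  res <- cpp_nw_affine(colscore, gap_open, gap_extend)
  cha <- strsplit(sa, "")[[1]]; chb <- strsplit(sb, "")[[1]]
  list(score = res$score,
       aligned_a = paste(ifelse(res$a_path > 0, cha[pmax(res$a_path, 1)],
                                GAP_CHAR), collapse = ""),
       aligned_b = paste(ifelse(res$b_path > 0, chb[pmax(res$b_path, 1)],
                                GAP_CHAR), collapse = ""))
}
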