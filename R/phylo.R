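#' Pairwise p-distance
#'
#' Fraction of differing residues over columns where neither row is gapped
#' (pairwise deletion). Errors when the two rows share no ungapped column.
#'
#' @param aln an [msa()] object.
#' @param i,j row ids.
#' @return p-distance in `[0, 1]`.
#' @export
p_distance <- function(aln, i, j) {
  codes <- msa_codes(aln)
  a <- codes[match_id(aln, i), ]; b <- codes[match_id(aln, j), ]
  both <- a != 0L & b != 0L
  if (!any(both))
    stop("rows ", i, " and ", j, " share no ungapped column")
  mean(a[both] != b[both])
}

#' 20-state Jukes-Cantor distance
#'
#' Model-corrected evolutionary distance for proteins under equal exchange
#' rates among the 20 amino acids:
#' `d = -(19/20) * log(1 - (20/19) * p)`. Defined for `0 <= p < 19/20`;
#' larger p means the observed divergence is saturated and errors.
#'
#' @param p observed proportion of differing sites.
#' @return Corrected distance `d >= p` (vectorized).
#' @examples
#' jukes_cantor(0.5)  # 0.95 * log(19/9) ~ 0.7098
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0 | p >= 19 / 20))
    stop("p must lie in [0, 19/20); larger values are saturated")
  -(19 / 20) * log(1 - (20 / 19) * p)
}

#' Pairwise distance matrix from an alignment
#'
#' @param aln an [msa()] object.
#' @param model `"jc"` (20-state Jukes-Cantor correction, default) or `"p"`
#'   (uncorrected p-distance). Pairwise deletion throughout.
#' @return Symmetric numeric matrix with id dimnames.
#' @export
distance_matrix <- function(aln, model = c("jc", "p")) {
  model <- match.arg(model)
  codes <- msa_codes(aln)
  res <- cpp_pdist(codes, 0L)
  if (any(res$shared[upper.tri(res$shared)] == 0L))
    stop("some sequence pairs share no ungapped column")
  p <- res$p
  d <- if (model == "jc") {
    if (any(p[upper.tri(p)] >= 19 / 20))
      stop("saturated p-distance (>= 19/20); Jukes-Cantor undefined")
    jc <- -(19 / 20) * log(1 - (20 / 19) * p)
    diag(jc) <- 0
    jc
  } else p
  dimnames(d) <- list(aln$ids, aln$ids)
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining (Saitou-Nei Q-criterion) with a deterministic
#' tie-break: among equal-minimum Q pairs the lexicographically smallest id
#' pair is joined. Negative branch lengths are clamped to zero and the total
#' clamped deficit is recorded in attribute `clamped_deficit`. Exact on
#' additive distance matrices.
#'
#' @param D symmetric distance matrix with id dimnames (>= 3 taxa).
#' @return An unrooted `ape` `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  ids <- rownames(D)
  if (is.null(ids) || is.null(colnames(D)))
    stop("distance matrix needs id dimnames")
  n <- nrow(D)
  if (n < 3L) stop("neighbor-joining needs at least 3 taxa")
  if (!isSymmetric(unname(D))) stop("distance matrix must be symmetric")
  deficit <- 0
  clamp <- function(v) {
    if (v < 0) { deficit <<- deficit - v; 0 } else v
  }
  fmt <- function(x) sprintf("%.10g", x)
  labels <- ids          # current Newick fragment per active node
  d <- D
  while (length(labels) > 3L) {
    k <- length(labels)
    r <- rowSums(d)
    Q <- (k - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    minQ <- min(Q)
    cand <- which(Q - minQ <= 1e-12 * max(1, abs(minQ)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(rownames(d)[cand[, 1]], colnames(d)[cand[, 2]]),
                 pmax(rownames(d)[cand[, 1]], colnames(d)[cand[, 2]]))
    pick <- cand[order(key)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    vi <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2)))
    vj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))))
    new_label <- sprintf("(%s:%s,%s:%s)", labels[i], fmt(vi),
                         labels[j], fmt(vj))
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    nm <- c(rownames(d)[keep], paste0("u", k))
    dimnames(d2) <- list(nm, nm)
    d <- d2
    labels <- c(labels[keep], new_label)
  }
  va <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  vb <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  vc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", labels[1], fmt(va),
                    labels[2], fmt(vb), labels[3], fmt(vc))
  tree <- ape::read.tree(text = newick)
  attr(tree, "clamped_deficit") <- deficit
  tree
}

# canonical key of the bipartition separating `tips` from the rest:
# the side containing the alphabetically first taxon, sorted and joined
split_key <- function(tips, all_tips) {
  anchor <- sort(all_tips)[1]
  side <- if (anchor %in% tips) tips else setdiff(all_tips, tips)
  paste(sort(side), collapse = "|")
}

tree_splits <- function(tree) {
  n_tip <- length(tree$tip.label)
  below <- clade_tips(tree)
  internal <- setdiff(seq_along(below), seq_len(n_tip))
  keys <- character(0)
  for (nd in internal) {
    tips <- below[[nd]]
    if (length(tips) <= 1L || length(tips) >= n_tip - 1L) next
    keys <- c(keys, split_key(tips, tree$tip.label))
  }
  unique(keys)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Jukes-Cantor/NJ tree per replicate, and scores every internal edge of the
#' full-alignment tree by the percentage of replicates containing the same
#' bipartition. Supports are stored as internal node labels and, keyed by
#' bipartition, in attribute `split_supports`. Reproducible for a fixed
#' seed (per-replicate substreams are drawn from the root seed).
#'
#' @param aln an [msa()] object with >= 4 rows.
#' @param n_reps number of replicates (the classic cladogram setting is
#'   100).
#' @param seed integer root seed.
#' @param model distance model passed to [distance_matrix()].
#' @return The NJ tree (`phylo`) with `node.label` supports in `[0, 100]`.
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L, model = "jc") {
  if (length(aln$ids) < 4L)
    stop("bootstrap supports need at least 4 sequences")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  codes <- msa_codes(aln)
  full <- distance_matrix(aln, model = model)
  if (all(full[upper.tri(full)] == 0))
    stop("alignment carries no signal (all rows identical)")
  main <- neighbor_joining(full)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  counts <- setNames(numeric(length(tree_splits(main))), tree_splits(main))
  L <- ncol(codes)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    cols <- sample.int(L, L, replace = TRUE)
    sub <- codes[, cols, drop = FALSE]
    res <- cpp_pdist(sub, 0L)
    p <- res$p
    if (any(res$shared[upper.tri(res$shared)] == 0L)) next
    p <- pmin(p, 19 / 20 - 1e-9)  # guard saturation in resampled columns
    dm <- -(19 / 20) * log(1 - (20 / 19) * p)
    diag(dm) <- 0
    dimnames(dm) <- dimnames(full)
    rep_tree <- neighbor_joining(if (model == "jc") dm else {
      pp <- res$p; dimnames(pp) <- dimnames(full); pp
    })
    seen <- tree_splits(rep_tree)
    hit <- names(counts) %in% seen
    counts[hit] <- counts[hit] + 1
  }
  pct <- 100 * counts / n_reps
  # attach supports as node labels of the main tree
  n_tip <- length(main$tip.label)
  below <- clade_tips(main)
  labs <- character(main$Nnode)
  for (nd in seq.int(n_tip + 1L, n_tip + main$Nnode)) {
    tips <- below[[nd]]
    if (length(tips) <= 1L || length(tips) >= n_tip - 1L) {
      labs[nd - n_tip] <- ""
    } else {
      labs[nd - n_tip] <- sprintf("%d",
        as.integer(round(pct[[split_key(tips, main$tip.label)]])))
    }
  }
  main$node.label <- labs
  attr(main, "split_supports") <- pct
  main
}

support_lookup <- function(tree) {
  sp <- attr(tree, "split_supports")
  if (!is.null(sp)) return(sp)
  if (is.null(tree$node.label)) return(NULL)  # no bootstrap: treat as firm
  n_tip <- length(tree$tip.label)
  below <- clade_tips(tree)
  out <- numeric(0)
  for (nd in seq.int(n_tip + 1L, n_tip + tree$Nnode)) {
    lab <- tree$node.label[nd - n_tip]
    tips <- below[[nd]]
    if (length(tips) <= 1L || length(tips) >= n_tip - 1L) next
    val <- suppressWarnings(as.numeric(lab))
    if (!is.na(val)) out[split_key(tips, tree$tip.label)] <- val
  }
  out
}

#' Assign Lhcf sequences to lineage groups A-D
#'
#' Clade-based sub-classification of the Lhcf family: on a (midpoint-rooted)
#' cladogram, maximal well-supported clades are labeled by the lineage of
#' their leaves — haptophyte-only clades form group B, diatom-only group C,
#' brown-seaweed-only group D, and mixed clades with a haptophyte majority,
#' at least one diatom and no seaweed form group A ("mainly haptophyte").
#' Leaves outside any qualifying clade are `unassigned`.
#'
#' @param tree `phylo` cladogram, ideally with bootstrap node labels (see
#'   [bootstrap_support()]); trees without support labels treat every clade
#'   as firm.
#' @param species_class named character vector mapping every tip to
#'   `"haptophyte"`, `"diatom"` or `"seaweed"`.
#' @param min_support minimum bootstrap percentage for a clade to qualify
#'   (default 50).
#' @param min_size minimum clade size (default 3).
#' @return Named character vector tip -> `"A"`, `"B"`, `"C"`, `"D"` or
#'   `"unassigned"`.
#' @export
assign_lhcf_groups <- function(tree, species_class, min_support = 50,
                               min_size = 3L) {
  tips <- tree$tip.label
  unclassified <- setdiff(tips, names(species_class))
  if (length(unclassified))
    stop("leaf(s) without lineage class: ",
         paste(unclassified, collapse = ", "))
  bad <- !species_class[tips] %in% c("haptophyte", "diatom", "seaweed")
  if (any(bad)) stop("invalid lineage class for: ",
                     paste(tips[bad], collapse = ", "))
  supports <- support_lookup(tree)
  rooted <- if (ape::is.rooted(tree)) tree else phangorn::midpoint(tree)
  n_tip <- length(tips)
  below <- clade_tips(rooted)
  internal <- seq.int(n_tip + 1L, n_tip + rooted$Nnode)
  sizes <- lengths(below[internal])
  ord <- internal[order(-sizes)]        # big clades first => maximal wins
  out <- setNames(rep("unassigned", n_tip), tips)
  labeled <- character(0)
  for (nd in ord) {
    members <- below[[nd]]
    if (length(members) < min_size) next
    if (any(members %in% labeled)) next  # nested in a labeled clade
    if (!is.null(supports) && length(members) < n_tip - 1L &&
        length(members) > 1L) {
      s <- supports[split_key(members, tips)]
      if (is.na(s) || s < min_support) next
    }
    cls <- species_class[members]
    n_h <- sum(cls == "haptophyte"); n_d <- sum(cls == "diatom")
    n_s <- sum(cls == "seaweed")
    grp <- if (n_d == 0L && n_s == 0L) "B"
      else if (n_h == 0L && n_s == 0L) "C"
      else if (n_h == 0L && n_d == 0L) "D"
      else if (n_s == 0L && n_d >= 1L && n_h > length(members) / 2) "A"
      else NA_character_
    if (is.na(grp)) next
    out[members] <- grp
    labeled <- c(labeled, members)
  }
  out
}

#' Locate the Lhcz sub-clade within Lhcr
#'
#' The Lhcz family is recognized as the Lhcr sub-clade that co-clusters
#' with reference Lhcz-like sequences: the smallest clade of the tree
#' containing every reference id. Returns the non-reference members of that
#' clade.
#'
#' @param tree `phylo` cladogram of Lhcr-family sequences.
#' @param lhcz_ref_ids tip ids of the reference Lhcz-like sequences.
#' @return Character vector of putative Lhcz member ids.
#' @export
identify_lhcz <- function(tree, lhcz_ref_ids) {
  missing <- setdiff(lhcz_ref_ids, tree$tip.label)
  if (length(missing))
    stop("reference id(s) missing from tree: ",
         paste(missing, collapse = ", "))
  rooted <- if (ape::is.rooted(tree)) tree else phangorn::midpoint(tree)
  below <- clade_tips(rooted)
  n_tip <- length(rooted$tip.label)
  candidates <- Filter(function(nd) all(lhcz_ref_ids %in% below[[nd]]),
                       seq.int(n_tip + 1L, n_tip + rooted$Nnode))
  if (!length(candidates)) return(setdiff(rooted$tip.label, lhcz_ref_ids))
  best <- candidates[which.min(lengths(below[candidates]))]
  setdiff(below[[best]], lhcz_ref_ids)
}
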