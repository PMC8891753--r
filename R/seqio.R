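#' Protein records
#'
#' A protein record set is a plain data frame with one row per sequence and
#' columns `id`, `species`, `family_label`, `sequence`, `description`.
#' Sequences are uppercase strings over the 20 amino-acid letters plus `X`
#' (`X` never matches a binding-site residue downstream). Residue coordinates
#' are 1-based everywhere in the package.
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of amino-acid sequences.
#' @param species species of origin (recycled).
#' @param family_label optional FCP family (`"lhcf"`, `"lhcr"`, `"lhcx"`,
#'   `"lhcz"`, `"unclassified"`) or `NA` when unknown.
#' @param description free-text description.
#' @return A `data.frame` of class `protein_records`.
#' @examples
#' protein_records(c("p1", "p2"), c("MKV", "ACDE"))
#' @export
protein_records <- function(id, sequence, species = NA_character_,
                            family_label = NA_character_,
                            description = "") {
  recs <- data.frame(id = as.character(id),
                     species = as.character(species),
                     family_label = as.character(family_label),
                     sequence = toupper(as.character(sequence)),
                     description = as.character(description),
                     stringsAsFactors = FALSE)
  validate_records(recs)
}

validate_records <- function(recs) {
  if (any(is.na(recs$id) | !nzchar(recs$id)))
    stop("protein record ids must be non-empty")
  dup <- recs$id[duplicated(recs$id)]
  if (length(dup))
    stop("duplicate protein ids: ", paste(unique(dup), collapse = ", "))
  if (any(nchar(recs$sequence) < 1L))
    stop("empty sequence for record(s): ",
         paste(recs$id[nchar(recs$sequence) < 1L], collapse = ", "))
  bad <- vapply(strsplit(recs$sequence, ""),
                function(ch) any(!ch %in% AA_ALPHABET), logical(1))
  if (any(bad)) {
    offending <- vapply(strsplit(recs$sequence[bad], ""), function(ch)
      paste(unique(ch[!ch %in% AA_ALPHABET]), collapse = ""), character(1))
    stop("non-amino-acid characters in record(s): ",
         paste(sprintf("%s ('%s')", recs$id[bad], offending), collapse = ", "))
  }
  ok_fam <- is.na(recs$family_label) | recs$family_label %in% FCP_FAMILIES
  if (!all(ok_fam))
    stop("unknown family label(s): ",
         paste(unique(recs$family_label[!ok_fam]), collapse = ", "))
  class(recs) <- c("protein_records", "data.frame")
  recs
}

#' Read a protein FASTA file
#'
#' Headers are parsed into `id` (first whitespace-delimited token) and
#' `description` (the remainder). The species is taken from a `species=<name>`
#' key in the description when present; otherwise from an optional two-column
#' sidecar TSV (`id <TAB> species`, no header). Sequences are uppercased;
#' any character outside the 20 amino acids plus `X` is rejected with the
#' offending record named.
#'
#' @param path path to a FASTA file.
#' @param species_table optional path to a sidecar TSV mapping id to species.
#' @return A [protein_records()] data frame.
#' @export
read_fasta <- function(path, species_table = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no FASTA records in ", path)
  headers <- names(aa)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  species <- ifelse(grepl("species=", desc),
                    sub(".*species=([^ ]+).*", "\\1", desc), NA_character_)
  if (!is.null(species_table)) {
    st <- read.delim(species_table, header = FALSE, stringsAsFactors = FALSE)
    lookup <- setNames(as.character(st[[2]]), as.character(st[[1]]))
    species <- ifelse(is.na(species) & id %in% names(lookup),
                      lookup[id], species)
  }
  protein_records(id = id, sequence = as.character(aa),
                  species = species, description = desc)
}

#' Write protein records as FASTA
#'
#' Headers are `id description`, with `species=<name>` injected into the
#' description when the record carries a species and the description does not
#' already name one. Lines wrap at 60 columns.
#'
#' @param recs a [protein_records()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(recs, path) {
  recs <- validate_records(as.data.frame(recs))
  desc <- recs$description
  need_sp <- !is.na(recs$species) & !grepl("species=", desc)
  desc[need_sp] <- trimws(paste(desc[need_sp],
                                paste0("species=", recs$species[need_sp])))
  aa <- Biostrings::AAStringSet(recs$sequence)
  names(aa) <- trimws(paste(recs$id, desc))
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read binding-site annotations
#'
#' Reads the reference binding-site table: one row per ligand residue of a
#' pigment site, as characterized crystallographically on the reference
#' species. Columns (tab-separated, header required): `site_id`,
#' `pigment_class` (`chl_a`/`chl_c`/`fx`), `ligand_class`
#' (`central`/`h_bond`), `ref_seq_id`, `ref_pos` (1-based), `primary_residue`,
#' `alternate_residues` (comma-joined, may be empty), `conserved_flag`
#' (true/false). Every row is cross-checked against the reference sequence:
#' the residue at `ref_pos` must equal `primary_residue`.
#'
#' @param path path to the annotation TSV.
#' @param refs [protein_records()] containing every referenced sequence.
#' @return A data frame of class `binding_sites` with `alternate_residues`
#'   as a list column of character vectors.
#' @export
read_site_annotations <- function(path, refs) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  needed <- c("site_id", "pigment_class", "ligand_class", "ref_seq_id",
              "ref_pos", "primary_residue", "alternate_residues",
              "conserved_flag")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  tab$ref_pos <- as.integer(tab$ref_pos)
  tab$conserved_flag <- tolower(tab$conserved_flag) %in% c("true", "t", "1")
  alt <- lapply(strsplit(tab$alternate_residues, ","),
                function(x) toupper(trimws(x[nzchar(trimws(x))])))
  tab$alternate_residues <- alt
  tab$primary_residue <- toupper(tab$primary_residue)
  validate_site_annotations(tab, refs)
}

validate_site_annotations <- function(tab, refs) {
  refs <- as.data.frame(refs)
  if (!all(tab$pigment_class %in% c("chl_a", "chl_c", "fx")))
    stop("invalid pigment_class value(s)")
  if (!all(tab$ligand_class %in% c("central", "h_bond")))
    stop("invalid ligand_class value(s)")
  for (k in seq_len(nrow(tab))) {
    sid <- tab$site_id[k]
    rid <- tab$ref_seq_id[k]
    if (!rid %in% refs$id)
      stop("site ", sid, ": reference sequence ", rid, " not found")
    seq <- refs$sequence[match(rid, refs$id)]
    pos <- tab$ref_pos[k]
    if (is.na(pos) || pos < 1L || pos > nchar(seq))
      stop("site ", sid, ": ref_pos ", pos, " out of range for ", rid)
    res <- substr(seq, pos, pos)
    if (res != tab$primary_residue[k])
      stop("site ", sid, ": reference residue mismatch at position ", pos,
           " (sequence has ", res, ", table says ", tab$primary_residue[k], ")")
    if (tab$primary_residue[k] %in% tab$alternate_residues[[k]])
      stop("site ", sid, ": primary residue listed among alternates")
  }
  class(tab) <- c("binding_sites", "data.frame")
  tab
}

#' Write binding-site annotations
#'
#' @param sites a `binding_sites` data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_annotations <- function(sites, path) {
  out <- as.data.frame(sites)
  out$alternate_residues <- vapply(sites$alternate_residues, paste,
                                   character(1), collapse = ",")
  out$conserved_flag <- ifelse(sites$conserved_flag, "true", "false")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
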