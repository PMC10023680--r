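## Curation of candidate nanobody chains before docking.
##
## Mirrors the five inclusion criteria used to assemble a camelid
## single-domain antibody chain library: X-ray structures at better than
## 2.5 A resolution, all three CDR loops resolved, camelid species only,
## chain mass under 20 kDa, and exact-sequence deduplication.

CAMELID_SPECIES <- c("camelidae", "camelus dromedarius", "lama",
                     "lama glama", "vicugna pacos")

#' Curation criteria
#'
#' @param max_resolution strict upper bound on X-ray resolution (Angstrom).
#' @param require_xray require `method == "X-RAY"` (case-insensitive,
#'   "X-RAY DIFFRACTION" also accepted).
#' @param require_cdr_complete require all three CDR loops resolved.
#' @param allowed_species camelid taxon strings (case-insensitive exact
#'   match).
#' @param max_mw strict upper bound on chain molecular weight (Da).
#' @param dedupe drop later records with a sequence already seen.
#' @return list of class `curation_criteria`.
#' @export
curation_criteria <- function(max_resolution = 2.5,
                              require_xray = TRUE,
                              require_cdr_complete = TRUE,
                              allowed_species = CAMELID_SPECIES,
                              max_mw = 20000,
                              dedupe = TRUE) {
  structure(list(max_resolution = max_resolution,
                 require_xray = require_xray,
                 require_cdr_complete = require_cdr_complete,
                 allowed_species = tolower(allowed_species),
                 max_mw = max_mw,
                 dedupe = dedupe),
            class = "curation_criteria")
}

is_xray <- function(method) {
  grepl("^x-?ray", tolower(trimws(method)))
}

#' Filter candidate nanobody chains
#'
#' Applies the five curation predicates to a chain-metadata table and
#' deduplicates on exact sequence identity, keeping the first occurrence in
#' input order. X-ray records with a missing resolution fail the resolution
#' test (with a warning).
#'
#' @param records data frame with columns `pdb_id`, `chain_id`, `method`,
#'   `resolution` (NA allowed for non-X-ray entries), `species`, `sequence`,
#'   and logical `cdr1_complete`, `cdr2_complete`, `cdr3_complete`.
#' @param criteria a [curation_criteria()] object.
#' @return the retained subset of `records`, in input order, with an added
#'   `mw` column.
#' @export
curate_chains <- function(records, criteria = curation_criteria()) {
  if (nrow(records) == 0L) stop("curate_chains: empty record table")
  need <- c("pdb_id", "chain_id", "method", "resolution", "species",
            "sequence", "cdr1_complete", "cdr2_complete", "cdr3_complete")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("metadata table lacks column(s): ", paste(miss, collapse = ", "))

  keep <- rep(TRUE, nrow(records))
  if (criteria$require_xray) keep <- keep & is_xray(records$method)
  res_na <- is.na(records$resolution)
  if (any(res_na & is_xray(records$method)))
    warning("X-ray record(s) with missing resolution fail the resolution ",
            "criterion: ",
            paste(records$pdb_id[res_na & is_xray(records$method)],
                  collapse = ", "))
  keep <- keep & !res_na & records$resolution < criteria$max_resolution
  if (criteria$require_cdr_complete)
    keep <- keep & records$cdr1_complete & records$cdr2_complete &
      records$cdr3_complete
  keep <- keep & tolower(trimws(records$species)) %in%
    criteria$allowed_species
  mw <- vapply(records$sequence, chain_molecular_weight, numeric(1),
               USE.NAMES = FALSE)
  keep <- keep & mw < criteria$max_mw
  out <- records[keep, , drop = FALSE]
  out$mw <- mw[keep]
  if (criteria$dedupe)
    out <- out[!duplicated(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a chain-metadata TSV
#' @param path tab-separated file with the columns listed in
#'   [curate_chains()].
#' @return data frame.
#' @export
read_chain_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (cc in c("cdr1_complete", "cdr2_complete", "cdr3_complete"))
    if (cc %in% names(df)) df[[cc]] <- as.logical(df[[cc]])
  df
}

#' Write sequences to FASTA
#' @param sequences character vector of one-letter sequences.
#' @param names sequence names.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, names, path) {
  seqinr::write.fasta(as.list(sequences), names, path, as.string = TRUE,
                      nbchar = 60)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  stats::setNames(toupper(vapply(fa, `[[`, character(1), 1L)), names(fa))
}
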