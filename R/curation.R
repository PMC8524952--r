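# Record selection, origin-label resolution and molecular profiling for
# natural-product tables (id, smiles, taxonomy, doi).

PEPTIDE_SMARTS <- "[NX3,NX4+][CH1,CH2][CX3](=[OX1])[NX3,NX4+][CH1,CH2][CX3](=[OX1])[O,N]"
GLYCOSIDE_SMARTS <- "[CR][OR][CHR]([OR0,NR0])[CR]"

ORIGIN_KEYWORDS <- list(
  human    = c("human", "homo"),
  animal   = c("animal", "animals"),
  bacteria = c("bacteria", "bacillus", "bacta"),
  fungi    = c("fungi", "aspergillus"),
  plant    = c("plant", "plants"),
  marine   = c("marine")
)
# resolution order when several origins match
ORIGIN_PRIORITY <- c("human", "animal", "bacteria", "fungi", "plant", "marine")

CATEGORY_LEVELS <- c("glycoside", "peptide", "high_MW", "high_Fsp3",
                     "low_Fsp3", "low_MW", "none")

#' Keep records with a sufficiently long DOI annotation
#'
#' Retains records whose DOI string, after trimming surrounding whitespace,
#' is at least ten characters long. A missing `doi` column or `NA` entries
#' are treated as empty strings.
#'
#' @param records Data frame with (at least) a `doi` column.
#' @return The filtered data frame, row order preserved.
#' @export
filter_by_doi <- function(records) {
  doi <- if ("doi" %in% names(records)) records$doi else rep("", nrow(records))
  doi[is.na(doi)] <- ""
  records[nchar(trimws(doi)) >= 10, , drop = FALSE]
}

#' Resolve an origin label from free-text taxonomy
#'
#' Splits the annotation on commas, lower-cases and trims each token, and
#' tests substring containment against the keyword sets for human, animal,
#' bacteria, fungi, plant and marine. When several origins match, the
#' highest-priority one wins (human > animal > bacteria > fungi > plant >
#' marine). Unmatched strings give `"unresolved"`.
#'
#' @param taxonomy_raw Character vector of free-text taxonomy annotations.
#' @return Character vector of origin labels.
#' @examples
#' resolve_origin(c("plants", "aspergillus, plant", "coral reef"))
#' @export
resolve_origin <- function(taxonomy_raw) {
  vapply(taxonomy_raw, function(tx) {
    if (is.na(tx)) return("unresolved")
    tokens <- trimws(tolower(strsplit(tx, ",", fixed = TRUE)[[1]]))
    for (origin in ORIGIN_PRIORITY) {
      kws <- ORIGIN_KEYWORDS[[origin]]
      hit <- any(vapply(tokens, function(tok)
        any(vapply(kws, function(k) grepl(k, tok, fixed = TRUE), logical(1))),
        logical(1)))
      if (hit) return(origin)
    }
    "unresolved"
  }, character(1), USE.NAMES = FALSE)
}

#' Restrict records to the plant / fungi / bacteria classes
#'
#' @param records Data frame with an `origin` column of resolved labels.
#' @return Records whose origin is one of `plant`, `fungi`, `bacteria`,
#'   order preserved.
#' @export
select_three_class_subset <- function(records) {
  stopifnot("origin" %in% names(records))
  records[records$origin %in% c("plant", "fungi", "bacteria"), , drop = FALSE]
}

#' Detect a dipeptide substructure
#'
#' Matches the two-consecutive-amide SMARTS pattern used to flag peptidic
#' natural products.
#'
#' @param smiles Character vector of SMILES.
#' @return Logical vector.
#' @export
match_peptide <- function(smiles) {
  smarts_flag(smiles, PEPTIDE_SMARTS)
}

#' Detect a glycoside (cyclic N- or O-acetal) substructure
#'
#' @inheritParams match_peptide
#' @return Logical vector.
#' @export
match_glycoside <- function(smiles) {
  smarts_flag(smiles, GLYCOSIDE_SMARTS)
}

smarts_flag <- function(smiles, smarts) {
  can <- canonical_smiles(smiles)
  if (anyNA(can))
    stop("unparseable SMILES at position(s): ",
         paste(which(is.na(can)), collapse = ", "))
  if (length(can) == 0) return(logical(0))
  smarts_flag_sdf(smiles_to_sdfset(can), smarts)
}

smarts_flag_sdf <- function(sdf, smarts) {
  counts <- ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = FALSE)
  unname(counts > 0)
}

#' Compute the molecular profile used for categorization and modeling
#'
#' Returns, per molecule: average molecular weight (Da), fraction of sp3
#' carbons, atom-contribution logP (AlogP), hydrogen-bond donor and acceptor
#' counts, topological polar surface area (A^2), element and bond counts,
#' the glycoside/peptide flags and the prioritized category.
#'
#' @param smiles Character vector of SMILES.
#' @return Data frame with one row per molecule and columns `smiles`, `mw`,
#'   `fsp3`, `alogp`, `hbd`, `hba`, `tpsa`, `n_carbon`, `n_oxygen`,
#'   `n_nitrogen`, `n_atoms`, `n_bonds`, `is_glycoside`, `is_peptide`,
#'   `category`.
#' @examples
#' compute_profile(c("c1ccccc1", "C1CCCCC1"))[, c("mw", "fsp3")]
#' @export
compute_profile <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (anyNA(can))
    stop("unparseable SMILES at position(s): ",
         paste(which(is.na(can)), collapse = ", "))
  sdf <- smiles_to_sdfset(can)
  pr <- ChemmineR::propOB(sdf)
  graphs <- graphs_from_sdfset(sdf)
  counts <- t(vapply(graphs, function(g) {
    sp3 <- 0L
    carbons <- which(g$symbols == "C")
    for (a in carbons) {
      orders <- g$order[g$from == a | g$to == a]
      if (length(orders) == 0 || all(orders == 1L)) sp3 <- sp3 + 1L
    }
    c(n_carbon = length(carbons),
      n_oxygen = sum(g$symbols == "O"),
      n_nitrogen = sum(g$symbols == "N"),
      n_atoms = g$n,
      n_bonds = length(g$from),
      n_sp3 = sp3)
  }, numeric(6)))
  fsp3 <- ifelse(counts[, "n_carbon"] > 0,
                 counts[, "n_sp3"] / counts[, "n_carbon"], 0)
  out <- data.frame(
    smiles = smiles,
    mw = pr$MW,
    fsp3 = fsp3,
    alogp = pr$logP,
    hbd = pr$HBD,
    hba = pr$HBA2,
    tpsa = pr$TPSA,
    n_carbon = counts[, "n_carbon"],
    n_oxygen = counts[, "n_oxygen"],
    n_nitrogen = counts[, "n_nitrogen"],
    n_atoms = counts[, "n_atoms"],
    n_bonds = counts[, "n_bonds"],
    is_glycoside = smarts_flag_sdf(sdf, GLYCOSIDE_SMARTS),
    is_peptide = smarts_flag_sdf(sdf, PEPTIDE_SMARTS),
    stringsAsFactors = FALSE
  )
  out$category <- categorize(out)
  rownames(out) <- NULL
  out
}

#' Assign the prioritized structural category
#'
#' First match wins, in the order glycoside > peptide > high_MW (MW >= 800)
#' > high_Fsp3 (Fsp3 >= 0.8) > low_Fsp3 (Fsp3 <= 0.2) > low_MW (MW <= 200)
#' > none.
#'
#' @param profile Data frame with columns `is_glycoside`, `is_peptide`,
#'   `mw`, `fsp3` (as produced by [compute_profile()]).
#' @return Character vector of categories.
#' @export
categorize <- function(profile) {
  stopifnot(all(c("is_glycoside", "is_peptide", "mw", "fsp3") %in% names(profile)))
  ifelse(profile$is_glycoside, "glycoside",
  ifelse(profile$is_peptide, "peptide",
  ifelse(profile$mw >= 800, "high_MW",
  ifelse(profile$fsp3 >= 0.8, "high_Fsp3",
  ifelse(profile$fsp3 <= 0.2, "low_Fsp3",
  ifelse(profile$mw <= 200, "low_MW", "none"))))))
}

#' Run the full curation pipeline on raw records
#'
#' Applies the DOI filter, resolves origin labels from taxonomy, keeps the
#' plant/fungi/bacteria subset and appends the molecular profile columns.
#' Records whose SMILES cannot be parsed are dropped with a warning; the
#' count of skipped records is attached as attribute `n_skipped`.
#'
#' @param records Data frame with columns `id`, `smiles`, `taxonomy`, `doi`.
#' @return Curated data frame with profile columns appended; attributes
#'   `n_input`, `n_after_doi`, `n_skipped` record the funnel.
#' @export
curate_records <- function(records) {
  stopifnot(all(c("id", "smiles", "taxonomy") %in% names(records)))
  n_input <- nrow(records)
  kept <- filter_by_doi(records)
  kept$origin <- resolve_origin(kept$taxonomy)
  kept <- select_three_class_subset(kept)
  parsed <- canonical_smiles(kept$smiles)
  bad <- is.na(parsed)
  if (any(bad)) {
    warning(sum(bad), " record(s) with unparseable SMILES skipped: ",
            paste(kept$id[bad], collapse = ", "))
    kept <- kept[!bad, , drop = FALSE]
  }
  profile <- if (nrow(kept) > 0) compute_profile(kept$smiles) else NULL
  out <- if (is.null(profile)) kept else cbind(kept, profile[, -1, drop = FALSE])
  rownames(out) <- NULL
  attr(out, "n_input") <- n_input
  attr(out, "n_after_doi") <- nrow(filter_by_doi(records))
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Read raw natural-product records from CSV/TSV
#'
#' @param path File path; `.tsv`/`.txt` are read tab-separated, anything
#'   else comma-separated.
#' @param columns Named character vector mapping the canonical names
#'   `id`, `smiles`, `taxonomy`, `doi` to the file's column names.
#' @return Data frame with canonical column names.
#' @export
read_records <- function(path,
                         columns = c(id = "id", smiles = "smiles",
                                     taxonomy = "taxonomy", doi = "doi")) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(unname(columns), names(raw))
  if (length(missing))
    stop("file ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  out <- raw[, unname(columns), drop = FALSE]
  names(out) <- names(columns)
  out
}

#' Read records from an SDF file
#'
#' Structures are taken from the connection tables; taxonomy and DOI from
#' the named data fields.
#'
#' @param path SDF file path.
#' @param tags Named character vector mapping `id`, `taxonomy`, `doi` to the
#'   SDF data-field tags.
#' @return Data frame with columns `id`, `smiles`, `taxonomy`, `doi`.
#' @export
read_records_sdf <- function(path,
                             tags = c(id = "id", taxonomy = "taxonomy",
                                      doi = "doi")) {
  sdf <- ChemmineR::read.SDFset(path)
  smi <- ChemmineR::sdf2smiles(sdf)
  get_tag <- function(blk, tag) if (tag %in% names(blk)) blk[[tag]] else ""
  meta <- t(vapply(ChemmineR::datablock(sdf), function(blk)
    c(get_tag(blk, tags[["id"]]), get_tag(blk, tags[["taxonomy"]]),
      get_tag(blk, tags[["doi"]])), character(3)))
  data.frame(id = meta[, 1], smiles = as.character(smi),
             taxonomy = meta[, 2], doi = meta[, 3], stringsAsFactors = FALSE)
}

#' Write curated records (with profiles) as CSV
#'
#' @param curated Data frame from [curate_records()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curated <- function(curated, path) {
  utils::write.csv(curated, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
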