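# SMILES handling built on OpenBabel (ChemmineOB/ChemmineR). All structure
# input is canonicalized once here so that every downstream encoding is a
# function of the molecular graph, not of the input atom ordering.

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form. Invalid strings yield `NA`
#' with a warning naming the offending position.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @examples
#' canonical_smiles(c("OCC", "CCO"))
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)
  res <- ob_convert_lines(smiles[ok])
  out[ok] <- res
  if (anyNA(out[ok])) {
    bad <- which(ok)[is.na(out[ok])]
    warning("unparseable SMILES at position(s): ", paste(bad, collapse = ", "))
  }
  out
}

# batch SMI -> CAN through OpenBabel; falls back to per-line conversion when
# the batch output misaligns (OpenBabel drops lines it cannot parse)
ob_convert_lines <- function(smiles) {
  conv <- function(x) {
    txt <- paste0(paste(x, collapse = "\n"), "\n")
    res <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", txt),
      error = function(e) ""
    )
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    sub("\t.*$", "", lines)
  }
  res <- conv(smiles)
  if (length(res) == length(smiles) && !any(res == "")) return(res)
  vapply(smiles, function(s) {
    r <- conv(s)
    if (length(r) == 1 && nzchar(r)) r else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Remove stereochemistry from SMILES
#'
#' Drops tetrahedral (`@`) and double-bond (`/`, `\`) stereo marks and
#' re-canonicalizes, mirroring how queries are normalized before prediction.
#'
#' @inheritParams canonical_smiles
#' @return Canonical SMILES without stereo descriptors.
#' @export
strip_stereo <- function(smiles) {
  flat <- gsub("@", "", smiles, fixed = TRUE)
  flat <- gsub("[/\\\\]", "", flat)
  canonical_smiles(flat)
}

# parse SMILES (assumed pre-canonicalized) into light molecular graphs:
# list(n, symbols, from, to, order) with 1-based atom indices and kekulized
# bond orders as stored in the SDF bond block
mol_graphs <- function(smiles) {
  stopifnot(length(smiles) > 0, !anyNA(smiles))
  graphs_from_sdfset(smiles_to_sdfset(smiles))
}

graphs_from_sdfset <- function(sdf) {
  lapply(seq_along(ChemmineR::cid(sdf)), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    bb <- ChemmineR::bondblock(sdf[[i]])
    sym <- sub("_\\d+$", "", rownames(ab))
    if (!is.null(bb) && is.null(dim(bb)) && length(bb) >= 3)
      bb <- matrix(bb, nrow = 1)
    if (!is.null(bb) && !is.null(dim(bb)) && nrow(bb) > 0 && ncol(bb) >= 3) {
      list(n = length(sym), symbols = sym,
           from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
           order = as.integer(bb[, 3]))
    } else {
      list(n = length(sym), symbols = sym,
           from = integer(0), to = integer(0), order = integer(0))
    }
  })
}

# shared SDF parse used by descriptor and SMARTS code
smiles_to_sdfset <- function(smiles) {
  ChemmineR::smiles2sdf(stats::setNames(smiles, paste0("m", seq_along(smiles))))
}
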