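# MinHashed atom-pair fingerprint: every unordered pair of heavy atoms
# contributes, per radius, one shingle "<envA>|<bond distance>|<envB>" built
# from canonical rooted SMILES of the two circular atom environments; the
# deduplicated shingle set is MinHashed to a fixed dimensionality.

MERSENNE31 <- 2147483647  # 2^31 - 1, modulus of the universal hash family

# canonical rooted environment SMILES for every atom of every molecule.
# Returns a list (one per molecule) of n_atoms x length(radii) matrices.
# Naive subgraph SMILES (root marked as isotope 99) are canonicalized in one
# batched OpenBabel call over the unique strings.
atom_environments <- function(graphs, radii) {
  naive <- lapply(graphs, function(g) {
    vapply(radii, function(r)
      env_smiles_cpp(g$n, g$symbols, g$from, g$to, g$order, as.integer(r)),
      character(g$n))
  })
  uniq <- unique(unlist(naive, use.names = FALSE))
  canon <- ob_convert_lines(uniq)
  # a fragment OpenBabel cannot parse keeps its (still deterministic) naive
  # form; the parent SMILES was canonicalized so the encoding stays stable
  canon[is.na(canon)] <- uniq[is.na(canon)]
  cmap <- stats::setNames(canon, uniq)
  lapply(naive, function(m) {
    out <- matrix(cmap[m], nrow = nrow(m), ncol = ncol(m))
    out
  })
}

shingle_sets <- function(can_smiles, radii) {
  graphs <- mol_graphs(can_smiles)
  small <- vapply(graphs, function(g) g$n < 2L, logical(1))
  if (any(small))
    stop("degenerate input: molecule(s) with fewer than 2 heavy atoms at position(s): ",
         paste(which(small), collapse = ", "))
  envs <- atom_environments(graphs, radii)
  lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    D <- pair_distances_cpp(g$n, g$from, g$to, g$order)
    shingle_set_cpp(envs[[i]], D)
  })
}

#' Enumerate the atom-pair shingles of a molecule
#'
#' Lists, for every unordered pair of connected heavy atoms and every radius,
#' the string `"<envA>|<distance>|<envB>"` where the two entries are the
#' canonical rooted SMILES of the circular atom environments (lexicographically
#' ordered) and the distance is the shortest bond path. Atom pairs spanning
#' disconnected fragments are skipped. The result is deduplicated.
#'
#' @param smiles A single SMILES string.
#' @param radii Integer vector of environment radii (default `c(1, 2)`).
#' @return Character vector: the shingle set.
#' @examples
#' enumerate_shingles("CCO")
#' @export
enumerate_shingles <- function(smiles, radii = c(1L, 2L)) {
  stopifnot(length(smiles) == 1)
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop("unparseable SMILES: ", smiles)
  shingle_sets(can, radii)[[1]]
}

minhash_params <- function(d, seed) {
  with_local_seed(seed, list(
    a = as.numeric(sample.int(MERSENNE31 - 1L, d, replace = TRUE)),
    b = as.numeric(sample.int(MERSENNE31, d, replace = TRUE) - 1)
  ))
}

#' MinHash a shingle set to a fixed-length fingerprint
#'
#' Each shingle string is pre-hashed with a stable 32-bit string hash; `d`
#' universal hash functions `(a_k x + b_k) mod (2^31 - 1)` (coefficients
#' drawn from a seeded RNG) then record the minimum over the set.
#'
#' @param shingles Character vector, a non-empty shingle set.
#' @param d Fingerprint dimensionality.
#' @param seed Seed for the hash-function coefficients.
#' @return Integer vector of length `d`.
#' @export
minhash <- function(shingles, d = 1024L, seed = 42L) {
  stopifnot(d >= 1)
  if (length(shingles) == 0) stop("degenerate input: empty shingle set")
  par <- minhash_params(d, seed)
  minhash_cpp(list(hash_strings_cpp(shingles)), par$a, par$b)[1, ]
}

#' Compute MAP4 fingerprints for a set of molecules
#'
#' Canonicalizes the input, enumerates the atom-pair shingles at the given
#' radii and MinHashes each shingle set. The fingerprint is a function of
#' the molecular graph only: equivalent SMILES spellings give identical
#' rows.
#'
#' @param smiles Character vector of SMILES.
#' @param d Dimensionality (default 1024).
#' @param radii Environment radii (default `c(1, 2)`).
#' @param seed Seed for the MinHash coefficients (default 42).
#' @return Integer matrix, one row per molecule, with attributes `d`,
#'   `radii`, `seed`.
#' @export
map4_fingerprint <- function(smiles, d = 1024L, radii = c(1L, 2L), seed = 42L) {
  can <- canonical_smiles(smiles)
  if (anyNA(can))
    stop("unparseable SMILES at position(s): ",
         paste(which(is.na(can)), collapse = ", "))
  sets <- shingle_sets(can, radii)
  par <- minhash_params(d, seed)
  fp <- minhash_cpp(lapply(sets, hash_strings_cpp), par$a, par$b)
  structure(fp, d = as.integer(d), radii = as.integer(radii),
            seed = as.integer(seed))
}

#' MAP4 similarity (MinHash match fraction)
#'
#' The number of positions at which the two fingerprints carry the same
#' MinHash value, divided by the fingerprint length — an unbiased estimator
#' of the Jaccard similarity of the underlying shingle sets.
#'
#' @param a,b Integer fingerprint vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
map4_similarity <- function(a, b) {
  if (length(a) != length(b))
    stop("fingerprint dimensionality mismatch: ", length(a), " vs ", length(b))
  mean(a == b)
}

#' Comparator fingerprints: folded circular-substructure or atom-pair bits
#'
#' `kind = "circular"` hashes the canonical atom-environment SMILES of radii
#' 0-2 (the same environments MAP4 pairs up) into 1024 bits, an ECFP4-class
#' encoding. `kind = "atom_pair"` folds the topological atom-pair descriptor
#' set to 1024 bits.
#'
#' @param smiles Character vector of SMILES.
#' @param kind `"circular"` or `"atom_pair"`.
#' @param nbits Number of bits (default 1024).
#' @return 0/1 integer matrix, one row per molecule.
#' @export
comparator_fingerprint <- function(smiles, kind = c("circular", "atom_pair"),
                                   nbits = 1024L) {
  kind <- match.arg(kind)
  can <- canonical_smiles(smiles)
  if (anyNA(can))
    stop("unparseable SMILES at position(s): ",
         paste(which(is.na(can)), collapse = ", "))
  if (kind == "circular") {
    graphs <- mol_graphs(can)
    envs <- atom_environments(graphs, radii = c(0L, 1L, 2L))
    bits <- t(vapply(envs, function(m) {
      idx <- (hash_strings_cpp(unique(as.vector(m))) %% nbits) + 1
      v <- integer(nbits)
      v[idx] <- 1L
      v
    }, integer(nbits)))
  } else {
    sdf <- smiles_to_sdfset(can)
    ap <- ChemmineR::sdf2ap(sdf)
    # fold onto the most common atom-pair descriptors shipped with
    # ChemmineR (resolved explicitly: desc2fp's own lookup requires the
    # package to be attached, not merely imported)
    e <- new.env(parent = emptyenv())
    utils::data("apfp", package = "ChemmineR", envir = e)
    descnames <- as.character(e$apfp$AP)[seq_len(nbits)]
    fp <- ChemmineR::desc2fp(ap, descnames = descnames, type = "FPset")
    bits <- unname(fp@fpma) * 1L
  }
  structure(bits, kind = kind)
}

#' Tanimoto similarity between two bit vectors
#'
#' @param a,b 0/1 integer vectors of equal length.
#' @return `|a & b| / |a | b|`.
#' @export
tanimoto_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(0)
  inter / uni
}

#' The 11-descriptor property vector
#'
#' Fixed order: MW, Fsp3, HBD, HBA, AlogP, number of carbons, oxygens and
#' nitrogens, heavy-atom count, bond count, TPSA. Scaling to zero mean and
#' unit variance is the classifier's job (fit on training data only).
#'
#' @param smiles Character vector of SMILES.
#' @return Numeric matrix, one row per molecule, 11 named columns.
#' @export
property_vector <- function(smiles) {
  pr <- compute_profile(smiles)
  as.matrix(pr[, c("mw", "fsp3", "hbd", "hba", "alogp", "n_carbon",
                   "n_oxygen", "n_nitrogen", "n_atoms", "n_bonds", "tpsa")])
}

#' Persist a fingerprint matrix as CSV with a JSON manifest
#'
#' @param fp Fingerprint matrix from [map4_fingerprint()].
#' @param path Output CSV path; the manifest is written alongside as
#'   `<path>.json`.
#' @param ids Optional molecule identifiers (row names of the CSV).
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fp, path, ids = NULL) {
  df <- as.data.frame(fp)
  if (!is.null(ids)) df <- cbind(id = ids, df)
  utils::write.csv(df, path, row.names = FALSE)
  manifest <- list(d = attr(fp, "d"), radii = attr(fp, "radii"),
                   seed = attr(fp, "seed"), n = nrow(fp))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read back a fingerprint matrix written by [write_fingerprints()]
#'
#' @param path CSV path.
#' @return Integer matrix with manifest attributes restored; molecule ids
#'   (if present) as row names.
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- NULL
  if ("id" %in% names(df)) {
    ids <- df$id
    df$id <- NULL
  }
  fp <- as.matrix(df)
  rownames(fp) <- ids
  manifest_path <- paste0(path, ".json")
  if (file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    attr(fp, "d") <- as.integer(man$d)
    attr(fp, "radii") <- as.integer(man$radii)
    attr(fp, "seed") <- as.integer(man$seed)
  }
  fp
}
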