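# Seed-reproducible generator of labeled natural-product-like molecules.
# The three classes carry the categorical signals reported for plant, fungal
# and bacterial natural products: plants are polyphenol/terpenoid scaffolds
# with frequent O-glycosylation, bacteria are linear or head-to-tail cyclic
# peptides, fungi are small aromatic / polyketide-like molecules with a
# characteristic share of very small (MW <= 200) structures.

# 20 proteinogenic residues as SMILES fragments "N C(alpha) C(=O)";
# proline carries its own ring (digit 3), aromatic side chains use digits 1-2
AA_FRAGMENTS <- c(
  G = "NCC(=O)",
  A = "NC(C)C(=O)",
  V = "NC(C(C)C)C(=O)",
  L = "NC(CC(C)C)C(=O)",
  I = "NC(C(C)CC)C(=O)",
  P = "N3CCCC3C(=O)",
  F = "NC(Cc1ccccc1)C(=O)",
  W = "NC(Cc1c[nH]c2ccccc12)C(=O)",
  Y = "NC(Cc1ccc(O)cc1)C(=O)",
  S = "NC(CO)C(=O)",
  T = "NC(C(C)O)C(=O)",
  C = "NC(CS)C(=O)",
  M = "NC(CCSC)C(=O)",
  N = "NC(CC(N)=O)C(=O)",
  Q = "NC(CCC(N)=O)C(=O)",
  D = "NC(CC(O)=O)C(=O)",
  E = "NC(CCC(O)=O)C(=O)",
  K = "NC(CCCCN)C(=O)",
  R = "NC(CCCNC(N)=N)C(=O)",
  H = "NC(Cc1c[nH]cn1)C(=O)"
)

# plant-like cores: polyphenols, phenylpropanoids, terpenoids; "%s" slots are
# decoration sites filled with OH / OMe / Me
PLANT_SCAFFOLDS <- c(
  flavone    = "O=C1C=C(c2ccc(%s)cc2)Oc2cc(%s)cc(%s)c12",
  flavanone  = "O=C1CC(c2ccc(%s)cc2)Oc2cc(%s)ccc12",
  chalcone   = "O=C(c1ccc(%s)cc1)C=Cc1ccc(%s)cc1",
  coumarin   = "O=C1C=Cc2cc(%s)c(%s)cc2O1",
  stilbene   = "C(=Cc1ccc(%s)cc1)c1cc(%s)cc(%s)c1",
  catechin   = "OC1Cc2c(%s)cc(%s)cc2OC1c1ccc(%s)c(O)c1",
  gallate    = "O=C(OCC)c1cc(%s)c(%s)c(%s)c1",
  cinnamate  = "O=C(O)C=Cc1ccc(%s)c(%s)c1",
  menthane   = "CC1CCC(C(C)C)C(%s)C1",
  eudesmane  = "CC1(C)CCCC2(C)CCC(%s)CC12",
  xanthone   = "O=C1c2cc(%s)ccc2Oc2ccc(%s)cc12",
  lignan     = "COc1cc(CC(C)C(C)Cc2ccc(%s)c(OC)c2)ccc1%s",
  steroidal  = "CC12CCC3C(CCC4CC(%s)CCC34C)C1CCC2%s",
  iridoid    = "CC1CC(%s)C2C(C)OC(C)C(C(=O)OC)C12"
)

# fungal-like: small aromatics guaranteed MW <= 200 under the allowed
# decorations, and mid-size polyketide-like scaffolds guaranteed MW > 200
FUNGAL_SMALL_SCAFFOLDS <- c(
  phenol       = "Oc1ccc(%s)cc1",
  orcinol      = "Cc1cc(O)cc(%s)c1",
  msa          = "Cc1cccc(O)c1C(=O)O",
  furanone     = "CC1=CC(=O)OC1",
  pyranone     = "CC1=CC(=O)C=CO1",
  salicylal    = "O=Cc1ccc(O)c(%s)c1",
  benzofuran   = "Cc1cc2ccccc2o1",
  acetophenone = "CC(=O)c1ccc(O)cc1%s",
  maltol       = "CC1=C(O)C(=O)C=CO1",
  butenolide   = "CC1=CC(=O)OC1C"
)
FUNGAL_LARGE_SCAFFOLDS <- c(
  anthraquinone    = "O=C1c2cc(%s)ccc2C(=O)c2cc(%s)ccc12",
  citrinin_like    = "CC1OC(C)c2cc(O)c(C(=O)O)c(%s)c2C1%s",
  depside          = "Cc1cc(O)cc(C(=O)Oc2cc(C)cc(%s)c2C(=O)O)c1%s",
  diketopiperazine = "O=C1NC(Cc2ccccc2)C(=O)NC1C%s",
  drimane          = "CC1(C)CCC2(C)CCC(=O)C(C)(%s)C2C1",
  resorcylate      = "CCCCCc1cc(O)cc(O)c1C(=O)O%s",
  mellein_like     = "CC1Cc2c(O)cc(%s)c(%s)c2C(=O)O1",
  chromone         = "CC1=CC(=O)c2c(O)cc(%s)c(%s)c2O1"
)

# O-linked pyranose attached by replacing one hydroxyl: the anomeric carbon
# becomes a cyclic O-acetal, which is the operational glycoside definition
GLUCOSE_FRAGMENT <- "(OC8OC(CO)C(O)C(O)C8O)"

DECORATIONS <- c("O", "OC", "C")

#' Configuration for the synthetic natural-product generator
#'
#' Defaults reproduce the categorical class structure reported for curated
#' natural-product collections: about 24% of plant molecules glycosylated
#' versus 5% elsewhere, all bacterial molecules peptidic, and 31% of fungal
#' molecules at MW <= 200.
#'
#' @param n_per_class Number of molecules per origin class (>= 1).
#' @param seed Integer RNG seed; identical configs give byte-identical output.
#' @param peptide_length_range Integer pair, residue-count bounds for
#'   bacterial-like peptides (min >= 2).
#' @param glycosylation_prob_plant Probability of O-glycosylating a
#'   plant-class molecule.
#' @param glycosylation_prob_other Probability of O-glycosylating a
#'   fungal-class molecule bearing a free hydroxyl.
#' @param small_mol_fraction_fungal Fraction of fungal-class molecules drawn
#'   from the small (MW <= 200) scaffold library.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 200L,
                         seed = 7L,
                         peptide_length_range = c(3L, 12L),
                         glycosylation_prob_plant = 0.24,
                         glycosylation_prob_other = 0.05,
                         small_mol_fraction_fungal = 0.31) {
  cfg <- list(
    n_per_class = as.integer(n_per_class),
    seed = as.integer(seed),
    peptide_length_range = as.integer(peptide_length_range),
    glycosylation_prob_plant = glycosylation_prob_plant,
    glycosylation_prob_other = glycosylation_prob_other,
    small_mol_fraction_fungal = small_mol_fraction_fungal
  )
  probs <- c(cfg$glycosylation_prob_plant, cfg$glycosylation_prob_other,
             cfg$small_mol_fraction_fungal)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("invalid configuration: probabilities must lie in [0, 1]")
  if (is.na(cfg$n_per_class) || cfg$n_per_class < 1L)
    stop("invalid configuration: n_per_class must be >= 1")
  if (length(cfg$peptide_length_range) != 2L ||
      anyNA(cfg$peptide_length_range) ||
      cfg$peptide_length_range[1] < 2L ||
      cfg$peptide_length_range[1] > cfg$peptide_length_range[2])
    stop("invalid configuration: peptide_length_range must be an increasing pair with min >= 2")
  if (is.na(cfg$seed)) stop("invalid configuration: seed must be an integer")
  class(cfg) <- "synth_config"
  cfg
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

fill_template <- function(template, subs) {
  n_slots <- lengths(regmatches(template, gregexpr("%s", template, fixed = TRUE)))
  do.call(sprintf, c(list(template), as.list(subs[seq_len(n_slots)])))
}

# replace one random hydroxyl "(O)" with the O-linked pyranose
glycosylate <- function(smiles) {
  hits <- gregexpr("(O)", smiles, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(smiles)
  pos <- hits[sample.int(length(hits), 1)]
  paste0(substr(smiles, 1, pos - 1), GLUCOSE_FRAGMENT,
         substr(smiles, pos + 3, nchar(smiles)))
}

decorate_scaffold <- function(template, force_hydroxyl = FALSE) {
  n_slots <- lengths(regmatches(template, gregexpr("%s", template, fixed = TRUE)))
  if (n_slots == 0) return(template)
  subs <- sample(DECORATIONS, n_slots, replace = TRUE)
  if (force_hydroxyl) subs[1] <- "O"
  fill_template(template, subs)
}

gen_plant <- function(n, p_glyco) {
  vapply(seq_len(n), function(i) {
    tpl <- PLANT_SCAFFOLDS[[sample.int(length(PLANT_SCAFFOLDS), 1)]]
    glyco <- runif(1) < p_glyco
    smi <- decorate_scaffold(tpl, force_hydroxyl = glyco)
    if (glyco) smi <- glycosylate(smi)
    smi
  }, character(1))
}

gen_fungal <- function(n, small_fraction, p_glyco) {
  vapply(seq_len(n), function(i) {
    small <- runif(1) < small_fraction
    lib <- if (small) FUNGAL_SMALL_SCAFFOLDS else FUNGAL_LARGE_SCAFFOLDS
    smi <- decorate_scaffold(lib[[sample.int(length(lib), 1)]])
    # glycosylation would push small scaffolds far above 200 Da, so only
    # mid-size fungal molecules are eligible
    if (!small && runif(1) < p_glyco) smi <- glycosylate(smi)
    smi
  }, character(1))
}

gen_bacterial <- function(n, length_range, p_cyclic = 0.3) {
  vapply(seq_len(n), function(i) {
    len <- sample(seq(length_range[1], length_range[2]), 1)
    res <- AA_FRAGMENTS[sample.int(length(AA_FRAGMENTS), len, replace = TRUE)]
    chain <- paste0(res, collapse = "")
    if (runif(1) < p_cyclic) {
      # head-to-tail macrolactamization via a high ring-closure label
      chain <- sub("^N", "N%99", chain)
      sub("C\\(=O\\)$", "C%99(=O)", chain)
    } else {
      paste0(chain, "O")
    }
  }, character(1))
}

TAXONOMY_TEXTS <- list(
  plant = c("plants", "plant, angiosperms", "medicinal plants, herbarium",
            "plant"),
  fungi = c("fungi", "aspergillus sp.", "fungi, ascomycota",
            "endophytic fungi, culture"),
  bacteria = c("bacteria", "bacillus subtilis, soil isolate",
               "actinobacta, fermentation", "marine sediment, bacteria")
)

#' Generate a labeled synthetic natural-product dataset
#'
#' Produces `3 * n_per_class` molecules with origin labels `plant`, `fungi`,
#' `bacteria`, plus synthesized free-text taxonomy and DOI fields so that the
#' curation stage can be exercised end to end. Identical configurations give
#' byte-identical output; the caller's RNG stream is left untouched.
#'
#' @param config A [synth_config()] object.
#' @return A data.frame with columns `id`, `smiles`, `taxonomy`, `doi`,
#'   `origin`.
#' @examples
#' head(generate_dataset(synth_config(n_per_class = 5, seed = 1)))
#' @export
generate_dataset <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  with_local_seed(config$seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, 4L)
    plant <- with_local_seed(sub_seeds[1],
      gen_plant(config$n_per_class, config$glycosylation_prob_plant))
    fungi <- with_local_seed(sub_seeds[2],
      gen_fungal(config$n_per_class, config$small_mol_fraction_fungal,
                 config$glycosylation_prob_other))
    bact <- with_local_seed(sub_seeds[3],
      gen_bacterial(config$n_per_class, config$peptide_length_range))
    origin <- rep(c("plant", "fungi", "bacteria"), each = config$n_per_class)
    smiles <- c(plant, fungi, bact)
    tax <- with_local_seed(sub_seeds[4], vapply(origin, function(o) {
      opts <- TAXONOMY_TEXTS[[o]]
      opts[sample.int(length(opts), 1)]
    }, character(1), USE.NAMES = FALSE))
    data.frame(
      id = sprintf("SYN%05d", seq_along(smiles)),
      smiles = smiles,
      taxonomy = tax,
      doi = sprintf("10.5555/synthetic.%05d", seq_along(smiles)),
      origin = origin,
      stringsAsFactors = FALSE
    )
  })
}

#' Write a synthetic dataset as CSV
#'
#' @param dataset Data frame from [generate_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Hand-built fixture for the curation rules
#'
#' A fixed set of records exercising the DOI-length filter, every origin
#' keyword, the multi-origin priority order and an unmatched taxonomy string.
#' `expected_kept` marks records surviving the DOI filter; `expected_origin`
#' is the label the keyword/priority rules must assign.
#'
#' @return A data.frame with columns `id`, `smiles`, `taxonomy`, `doi`,
#'   `expected_kept`, `expected_origin`.
#' @export
generate_curation_fixture <- function() {
  rec <- function(id, smiles, taxonomy, doi, kept, origin)
    data.frame(id = id, smiles = smiles, taxonomy = taxonomy, doi = doi,
               expected_kept = kept, expected_origin = origin,
               stringsAsFactors = FALSE)
  rbind(
    rec("FX01", "c1ccccc1O",            "plants",              "10.5555/fx.0001", TRUE,  "plant"),
    rec("FX02", "CC(=O)Oc1ccccc1C(=O)O","plant",               "10.5555/fx.0002", TRUE,  "plant"),
    rec("FX03", "CCO",                  "fungi",               "10.5555/fx.0003", TRUE,  "fungi"),
    rec("FX04", "CC1=CC(=O)OC1",        "aspergillus flavus",  "10.5555/fx.0004", TRUE,  "fungi"),
    rec("FX05", "NCC(=O)NCC(=O)O",      "bacteria",            "10.5555/fx.0005", TRUE,  "bacteria"),
    rec("FX06", "NCC(=O)NC(C)C(=O)O",   "bacillus subtilis",   "10.5555/fx.0006", TRUE,  "bacteria"),
    rec("FX07", "CC(C)CC(N)C(=O)O",     "actinobacta",         "10.5555/fx.0007", TRUE,  "bacteria"),
    rec("FX08", "COC1OC(CO)C(O)C(O)C1O","plants, bacteria",    "10.5555/fx.0008", TRUE,  "bacteria"),
    rec("FX09", "Cc1cc(O)cc(O)c1",      "aspergillus, plant",  "10.5555/fx.0009", TRUE,  "fungi"),
    rec("FX10", "NC(C)C(=O)O",          "human, plants",       "10.5555/fx.0010", TRUE,  "human"),
    rec("FX11", "OCC(O)CO",             "animal, fungi",       "10.5555/fx.0011", TRUE,  "animal"),
    rec("FX12", "OC1CCCCC1",            "marine, plant",       "10.5555/fx.0012", TRUE,  "plant"),
    rec("FX13", "C1CCOC1",              "coral reef",          "10.5555/fx.0013", TRUE,  "unresolved"),
    rec("FX14", "CCN",                  "plants",              "",                FALSE, "plant"),
    rec("FX15", "CCC",                  "bacteria",            "12345678",        FALSE, "bacteria"),
    rec("FX16", "CCCC",                 "fungi",               "  10.1/ab  ",     FALSE, "fungi")
  )
}
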