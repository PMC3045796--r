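#' Tokenize free text into terms
#'
#' A term is any maximal run of at least 3 alphanumeric characters; runs
#' consisting only of digits are discarded. Hyphens and every other
#' non-alphanumeric character act as separators, so "Bcl2-associated" yields
#' `bcl2`, `associated`. Output is lower-cased. Within-document multiplicity
#' is preserved; deduplication happens when document-level frequencies are
#' computed.
#'
#' @param text Character vector; elements are tokenized independently and
#'   concatenated.
#' @return Character vector of lower-case terms (possibly empty).
#' @examples
#' tokenize("fatty acid desaturase 1")   # "1" dropped: purely numeric
#' tokenize("HL60 cells")                # mixed alphanumeric tokens kept
#' @export
tokenize <- function(text) {
  if (length(text) == 0L) return(character())
  toks <- unlist(strsplit(tolower(paste(text, collapse = " ")),
                          "[^a-z0-9]+"), use.names = FALSE)
  toks <- toks[nchar(toks) >= 3L]
  toks[!grepl("^[0-9]+$", toks)]
}

# Singular words that end like plurals and must not be stripped.
.keep_as_is <- c(
  "analysis", "apoptosis", "atherosclerosis", "axis", "basis", "crisis",
  "diagnosis", "dialysis", "emphasis", "fibrosis", "hypothesis", "meiosis",
  "metastasis", "mitosis", "necrosis", "prognosis", "psoriasis", "sclerosis",
  "stenosis", "synthesis", "thesis", "cirrhosis", "homeostasis", "sepsis",
  "pertussis", "thrombosis", "stimulus", "locus", "nucleus", "fungus",
  "virus", "consensus", "status", "corpus", "status", "versus", "conway",
  "species", "series", "caries", "rabies", "diabetes", "herpes", "pancreas",
  "bias", "atlas", "canvas", "alias", "gas", "les", "this", "his", "its",
  "was", "has", "plus", "minus", "thus", "lens", "molasses", "measles",
  "news", "mumps", "physics", "genomics", "proteomics", "kinetics",
  "dynamics", "genetics", "statistics", "bioinformatics", "mathematics",
  "electrophoresis", "elisa", "pancreatitis", "hepatitis", "arthritis",
  "meningitis", "colitis", "dermatitis", "bronchitis", "gastritis",
  "mastitis", "vasculitis", "encephalitis", "iris", "pelvis", "testis",
  "epididymis", "glottis", "cannabis", "tennis", "debris", "cosmos",
  "chaos", "pathos", "ethos", "asbestos"
)

# Irregular plural -> singular pairs; includes Latin/Greek forms common in
# biomedical abstracts.
.irregular_plurals <- c(
  analyses = "analysis", hypotheses = "hypothesis", diagnoses = "diagnosis",
  prognoses = "prognosis", metastases = "metastasis", syntheses = "synthesis",
  theses = "thesis", axes = "axis", crises = "crisis", bases = "basis",
  mitoses = "mitosis", meioses = "meiosis", stenoses = "stenosis",
  fibroses = "fibrosis", necroses = "necrosis", scleroses = "sclerosis",
  viruses = "virus", fungi = "fungus", nuclei = "nucleus", loci = "locus",
  stimuli = "stimulus", foci = "focus", radii = "radius", genera = "genus",
  corpora = "corpus", bacteria = "bacterium", mitochondria = "mitochondrion",
  criteria = "criterion", phenomena = "phenomenon", ganglia = "ganglion",
  mice = "mouse", men = "man", women = "woman", children = "child",
  feet = "foot", teeth = "tooth", geese = "goose", people = "person",
  matrices = "matrix", indices = "index", appendices = "appendix",
  vertices = "vertex", cortices = "cortex", helices = "helix",
  apices = "apex", vortices = "vortex", testes = "testis",
  larvae = "larva", antennae = "antenna", vertebrae = "vertebra",
  formulae = "formula", alumni = "alumnus", cacti = "cactus",
  sera = "serum", genomes = "genome", media = "medium", millennia = "millennium",
  epididymides = "epididymis", oases = "oasis", lives = "life",
  knives = "knife", leaves = "leaf", halves = "half", wolves = "wolf",
  calves = "calf", shelves = "shelf", wives = "wife"
)

#' Reduce a term to its canonical singular form
#'
#' Singular and plural occurrences of the same term are merged before
#' frequencies are computed. The mapping is a deterministic rule table:
#' an irregular-form lookup (Latin/Greek plurals common in the biomedical
#' literature, `-ices`/`-ae`/`-a` classes, suppletives like mice/mouse),
#' an exception list of singular words that merely look plural
#' (analysis, virus, species, ...), then suffix rules (`-ies` -> `-y`,
#' `-ches`/`-shes`/`-sses`/`-xes`/`-zes`/`-oes` -> strip `es`, final `-s`
#' stripped otherwise). The mapping is idempotent:
#' `singularize(singularize(x)) == singularize(x)`.
#'
#' @param terms Character vector of lower-case terms.
#' @return Character vector of canonical forms, same length.
#' @examples
#' singularize(c("cells", "cell", "analyses", "viruses", "species"))
#' @export
singularize <- function(terms) {
  out <- terms
  irr <- .irregular_plurals[out]
  hit <- !is.na(irr)
  out[hit] <- irr[hit]
  todo <- !hit & !(out %in% .keep_as_is) & grepl("s$", out) & nchar(out) > 3L
  w <- out[todo]
  w <- ifelse(grepl("ies$", w) & nchar(w) > 4L, sub("ies$", "y", w),
       ifelse(grepl("(ch|sh|ss|x|z|o)es$", w), sub("es$", "", w),
       ifelse(grepl("(ss|us|is)$", w), w,  # glass, bonus, pelvis stay put
              sub("s$", "", w))))
  out[todo] <- w
  out
}

#' Map terms to canonical forms, merging inflections
#'
#' Thin named-map wrapper around [singularize()]: returns, for each distinct
#' input term, its canonical singular form.
#'
#' @param terms Character vector of terms (tokenized, lower-case).
#' @return Named character vector: `names()` are the distinct input terms,
#'   values their canonical forms.
#' @export
merge_inflections <- function(terms) {
  u <- unique(terms)
  stats::setNames(singularize(u), u)
}

# Canonical document-level term set: tokenize then merge inflections,
# keeping one occurrence per distinct canonical term.
document_terms <- function(text) {
  unique(singularize(tokenize(text)))
}
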