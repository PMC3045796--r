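# Shared fixture builders. Everything is generated in code; no binary data.

# Quick collection from raw texts; ids default to sequential integers.
make_collection <- function(name, texts, ids = as.character(seq_along(texts))) {
  abstract_collection(name, ids, texts)
}

# A tiny hand-written two-group corpus with transparent topic structure:
# GA's literature is about lipids, GB's about neurons. GA's alias A1 is a
# synonym (lipid literature), alias A2 is ambiguous (neuron literature).
tiny_corpus <- function() {
  terminology <- aliasprofiler:::new_terminology(data.frame(
    group_id = c("GA", "GA", "GA", "GB", "GB"),
    name = c("GA", "A1", "A2", "GB", "B1"),
    role = c("official", "alias", "alias", "official", "alias"),
    stringsAsFactors = FALSE))
  lipid <- c("lipid desaturase membrane fatty acids metabolism",
             "fatty acid desaturase lipid pathway enzyme",
             "membrane lipid composition desaturase activity",
             "desaturase enzyme fatty metabolism regulation")
  neuron <- c("neuron synapse dendrite axon signaling",
              "synaptic neuron plasticity axon terminal",
              "dendrite spine neuron excitability channel",
              "axon guidance neuron growth cone")
  collections <- list(
    GA = make_collection("GA", lipid),
    A1 = make_collection("A1", rev(lipid), ids = as.character(5:8)),
    A2 = make_collection("A2", neuron, ids = as.character(9:12)),
    GB = make_collection("GB", neuron, ids = as.character(13:16)),
    B1 = make_collection("B1", rev(neuron), ids = as.character(17:20)))
  list(terminology = terminology, collections = collections)
}

# Empty baseline: every term has baseline frequency 0.
empty_baseline <- function() {
  structure(list(freqs = stats::setNames(numeric(), character()),
                 n_docs = 0L),
            class = "baseline_frequencies")
}

# Baseline from explicit term -> frequency pairs.
baseline_from <- function(...) {
  f <- c(...)
  structure(list(freqs = f, n_docs = 100L), class = "baseline_frequencies")
}

# Small generator settings used where the test only needs pipeline shape,
# not the full default study conditions.
small_params <- function(seed = 1L, ...) {
  generator_params(n_groups = 4L, aliases_per_group = 3L,
                   docs_per_name = 10L, doc_length = 40L,
                   topic_vocab_size = 15L, background_vocab_size = 300L,
                   n_baseline_docs = 120L, seed = seed, ...)
}
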