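# Shared fixtures: tiny hand-built corpora and the printed-table data
# shipped under extdata.

paper_histograms <- function() {
  utils::read.delim(system.file("extdata", "success_histograms.tsv",
                                package = "ppidiag"))
}

paper_stratum_tables <- function() {
  utils::read.delim(system.file("extdata", "stratum_tables.tsv",
                                package = "ppidiag"))
}

histogram_for <- function(df, corpus_name, setting_name) {
  h <- df[df$corpus == corpus_name & df$setting == setting_name, ]
  h <- h[order(h$level), ]
  stats::setNames(h$total, h$level)
}

# one-sentence, one-pair document
tiny_corpus <- function(name = "SimTiny") {
  text <- "ProtA binds ProtB strongly ."
  s <- ppi_sentence(
    id = paste0(name, ".d0.s0"), text = text,
    entities = data.frame(
      id = paste0(name, ".d0.s0.e", 0:1),
      start = c(0L, 12L), end = c(5L, 17L),
      text = c("ProtA", "ProtB"), type = "protein",
      stringsAsFactors = FALSE),
    pairs = data.frame(
      id = paste0(name, ".d0.s0.p0"),
      e1 = paste0(name, ".d0.s0.e0"), e2 = paste0(name, ".d0.s0.e1"),
      gold = TRUE, stringsAsFactors = FALSE)
  )
  ppi_corpus(name, list(list(id = paste0(name, ".d0"), sentences = list(s))))
}

# sentence with explicit token, dependency-chain and tree layers:
# ProtA -nsubj-> binds -dobj-> ProtB
parsed_sentence <- function() {
  text <- "ProtA binds ProtB"
  ppi_sentence(
    id = "SimP.d0.s0", text = text,
    entities = data.frame(
      id = c("SimP.d0.s0.e0", "SimP.d0.s0.e1"),
      start = c(0L, 12L), end = c(5L, 17L),
      text = c("ProtA", "ProtB"), type = "protein",
      stringsAsFactors = FALSE),
    pairs = data.frame(
      id = "SimP.d0.s0.p0", e1 = "SimP.d0.s0.e0", e2 = "SimP.d0.s0.e1",
      gold = TRUE, stringsAsFactors = FALSE),
    tokens = data.frame(
      index = 0:2, text = c("ProtA", "binds", "ProtB"),
      pos = c("NNP", "VBZ", "NNP"),
      start = c(0L, 6L, 12L), end = c(5L, 11L, 17L),
      stringsAsFactors = FALSE),
    deps = data.frame(from = c(0L, 1L), to = c(1L, 2L),
                      label = c("nsubj", "dobj"), stringsAsFactors = FALSE),
    tree = list(label = "S", children = list(
      list(label = "NP", children = list(list(token = 0L))),
      list(label = "VP", children = list(list(token = 1L),
                                         list(token = 2L)))))
  )
}

# prediction set built from an explicit logical matrix
pset_from <- function(m, setting = "CV") {
  prediction_set(m, setting)
}

# a small seeded corpus + CV/CL predictions reused across tests
small_suite <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_corpus_config(target_pairs = 400,
                               target_positive_ratio = 0.3, seed = 71)
      corp <- generate_corpus(cfg)
      pc <- sim_prediction_config(seed = 72)
      cache <<- list(
        corpus = corp,
        gold = gold_labels(corp),
        cv = generate_predictions(corp, default_profiles("CV"), pc, "CV"),
        cl = generate_predictions(corp, default_profiles("CL"), pc, "CL"))
    }
    cache
  }
})
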