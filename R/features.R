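# Surface and parse feature extraction per candidate pair, plus aggregate
# difficulty statistics.
#
# Scope letters for clue features follow the usual fore-between-after
# reading: s = anywhere in the sentence, b = strictly before the earlier
# entity, w = strictly between the two entities, a = strictly after the
# later entity.

#' Default clue lexicons
#'
#' Word lists (lowercased) of interaction trigger words, negation words
#' and hedge words, shipped as plain-text files under
#' `inst/extdata/lexicons/` and overridable by the user.
#'
#' @return list of class `ppi_lexicons` with character vectors
#'   `interaction`, `negation`, `hedge`.
#' @export
default_lexicons <- function() {
  dir <- system.file("extdata", "lexicons", package = "ppidiag")
  read_lex <- function(f) {
    x <- readLines(file.path(dir, f), warn = FALSE)
    x <- trimws(x)
    tolower(x[nzchar(x) & !startsWith(x, "#")])
  }
  structure(list(interaction = read_lex("interaction_words.txt"),
                 negation = read_lex("negation_words.txt"),
                 hedge = read_lex("hedge_words.txt")),
            class = "ppi_lexicons")
}

#' Tokenize a sentence with entity blinding
#'
#' Whitespace/punctuation tokenization of the sentence text in which each
#' entity span is collapsed to a single blinded token: `ENT1`/`ENT2` for
#' the focus pair's entities, `PROT` for any other entity. Token spans are
#' 0-based half-open into the original text.
#'
#' @param sentence a [ppi_sentence()].
#' @param pair optional pair id or one-row pair data.frame selecting the
#'   focus pair; without it all entities blind to `PROT`.
#' @return data.frame with columns `token` (blinded text), `raw`, `start`,
#'   `end`, `entity_id` (`NA` for non-entity tokens).
#' @export
tokenize <- function(sentence, pair = NULL) {
  ents <- sentence$entities
  if (nrow(ents) > 1) {
    o <- order(ents$start)
    se <- ents[o, ]
    if (any(se$start[-1] < se$end[-nrow(se)])) {
      stop("overlapping entity spans in sentence ", sentence$id)
    }
  }
  e1 <- NA_character_; e2 <- NA_character_
  if (!is.null(pair)) {
    if (is.character(pair)) {
      row <- sentence$pairs[sentence$pairs$id == pair, ]
      if (!nrow(row)) stop("pair ", pair, " not in sentence ", sentence$id)
    } else row <- pair
    e1 <- row$e1; e2 <- row$e2
    if (!all(c(e1, e2) %in% ents$id)) {
      stop("pair entities not in sentence ", sentence$id)
    }
  }
  blind_name <- function(eid) {
    if (!is.na(e1) && eid == e1) "ENT1"
    else if (!is.na(e2) && eid == e2) "ENT2"
    else "PROT"
  }

  text <- sentence$text
  segments <- list()
  cursor <- 0L
  ord <- if (nrow(ents)) order(ents$start) else integer()
  for (i in ord) {
    if (ents$start[i] > cursor) {
      segments[[length(segments) + 1L]] <-
        list(kind = "text", start = cursor, end = ents$start[i])
    }
    segments[[length(segments) + 1L]] <-
      list(kind = "entity", start = ents$start[i], end = ents$end[i],
           id = ents$id[i])
    cursor <- ents$end[i]
  }
  if (cursor < nchar(text)) {
    segments[[length(segments) + 1L]] <-
      list(kind = "text", start = cursor, end = nchar(text))
  }

  tok <- character(); raw <- character()
  st_ <- integer(); en_ <- integer(); eid <- character()
  for (seg in segments) {
    if (seg$kind == "entity") {
      tok <- c(tok, blind_name(seg$id))
      raw <- c(raw, substring(text, seg$start + 1L, seg$end))
      st_ <- c(st_, seg$start); en_ <- c(en_, seg$end)
      eid <- c(eid, seg$id)
    } else {
      chunk <- substring(text, seg$start + 1L, seg$end)
      m <- gregexpr("[[:alnum:]_'-]+|[^[:alnum:]_'[:space:]-]", chunk)[[1]]
      if (m[1] == -1L) next
      len <- attr(m, "match.length")
      words <- substring(chunk, m, m + len - 1L)
      tok <- c(tok, words); raw <- c(raw, words)
      st_ <- c(st_, seg$start + m - 1L)
      en_ <- c(en_, seg$start + m - 1L + len)
      eid <- c(eid, rep(NA_character_, length(m)))
    }
  }
  data.frame(token = tok, raw = raw, start = st_, end = en_,
             entity_id = eid, stringsAsFactors = FALSE)
}

#' Surface features of a candidate pair
#'
#' Sentence lengths, token distance between the entities, protein count,
#' clue-word flags per scope, comma-between and `-ing`-after-first-entity
#' flags, computed on the blinded token sequence.
#'
#' @param sentence a [ppi_sentence()].
#' @param pair pair id or one-row pair data.frame.
#' @param lexicons a [default_lexicons()]-shaped list.
#' @return named list of surface features.
#' @export
surface_features <- function(sentence, pair, lexicons = default_lexicons()) {
  toks <- tokenize(sentence, pair)
  i1 <- which(toks$token == "ENT1")
  i2 <- which(toks$token == "ENT2")
  if (!length(i1) || !length(i2)) {
    stop("pair entities not found in tokenization of ", sentence$id)
  }
  lo <- min(i1, i2); hi <- max(i1, i2)
  low <- tolower(toks$token)
  scopes <- list(
    s = seq_len(nrow(toks)),
    b = if (lo > 1) 1:(lo - 1) else integer(),
    w = if (hi - lo > 1) (lo + 1):(hi - 1) else integer(),
    a = if (hi < nrow(toks)) (hi + 1):nrow(toks) else integer()
  )
  out <- list(
    sentence_length_char = nchar(sentence$text),
    sentence_length_word = nrow(toks),
    entity_word_distance = hi - lo - 1L,
    n_proteins = nrow(sentence$entities)
  )
  for (clue in c("negation", "hedge", "interaction")) {
    words <- lexicons[[clue]]
    for (sc in names(scopes)) {
      out[[paste0(clue, "_", sc)]] <-
        as.integer(any(low[scopes[[sc]]] %in% words))
    }
  }
  out$comma_between <- as.integer(any(toks$token[scopes$w] == ","))
  out$ing_after_e1 <- as.integer(
    lo < nrow(toks) && grepl("ing$", low[lo + 1]) && nchar(low[lo + 1]) > 4)
  out
}

#' Dependency-graph features of a candidate pair
#'
#' Shortest path between the two entity head tokens on the undirected view
#' of the dependency graph (unit edge weights; deterministic tie-break by
#' the lexicographically smallest token-index sequence), plus label
#' occurrence counts, relative frequencies and Shannon entropies for the
#' whole graph and the path.
#'
#' @param sentence a [ppi_sentence()] with token and dependency layers.
#' @param pair pair id or one-row pair data.frame.
#' @return named list: `dg_path_length`, `dg_connected`, `dg_entropy`,
#'   `dg_path_entropy`, and per-label `dg_count_*` / `dg_freq_*` /
#'   `dgp_count_*` / `dgp_freq_*` entries.
#' @export
dg_features <- function(sentence, pair) {
  if (is.null(sentence$deps) || is.null(sentence$tokens)) {
    stop("dependency layer absent in sentence ", sentence$id)
  }
  row <- resolve_pair(sentence, pair)
  h1 <- entity_head_token(sentence, row$e1)
  h2 <- entity_head_token(sentence, row$e2)
  deps <- sentence$deps
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(deps$from), to = as.character(deps$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(sort(sentence$tokens$index))))
  igraph::E(g)$label <- deps$label

  whole <- table(deps$label)
  out <- list(dg_entropy = entropy_bits(whole))
  for (lb in names(whole)) {
    out[[paste0("dg_count_", lb)]] <- as.integer(whole[[lb]])
    out[[paste0("dg_freq_", lb)]] <- unname(whole[[lb]] / sum(whole))
  }

  v1 <- as.character(h1); v2 <- as.character(h2)
  sp <- suppressWarnings(igraph::all_shortest_paths(g, from = v1, to = v2))
  if (!length(sp$res)) {
    out$dg_connected <- 0L
    out$dg_path_length <- NA_integer_
    out$dg_path_entropy <- NA_real_
    return(out)
  }
  seqs <- lapply(sp$res, function(p) as.integer(names(p)))
  key <- vapply(seqs, function(s) paste(sprintf("%06d", s), collapse = "."), "")
  path <- seqs[[order(key)[1]]]
  out$dg_connected <- 1L
  out$dg_path_length <- length(path) - 1L
  plabs <- path_edge_labels(deps, path)
  pt <- table(plabs)
  out$dg_path_entropy <- entropy_bits(pt)
  for (lb in names(pt)) {
    out[[paste0("dgp_count_", lb)]] <- as.integer(pt[[lb]])
    out[[paste0("dgp_freq_", lb)]] <- unname(pt[[lb]] / sum(pt))
  }
  out
}

path_edge_labels <- function(deps, path) {
  vapply(seq_len(length(path) - 1L), function(i) {
    a <- path[i]; b <- path[i + 1L]
    hit <- (deps$from == a & deps$to == b) | (deps$from == b & deps$to == a)
    deps$label[hit][1]
  }, "")
}

resolve_pair <- function(sentence, pair) {
  if (is.character(pair)) {
    row <- sentence$pairs[sentence$pairs$id == pair, ]
    if (!nrow(row)) stop("pair ", pair, " not in sentence ", sentence$id)
    row
  } else pair
}

# entity head token = last token whose span lies inside the entity span
entity_head_token <- function(sentence, entity_id) {
  e <- sentence$entities[sentence$entities$id == entity_id, ]
  toks <- sentence$tokens
  inside <- toks$start >= e$start & toks$end <= e$end
  if (!any(inside)) {
    inside <- toks$start < e$end & toks$end > e$start   # fall back: overlap
  }
  if (!any(inside)) stop("entity ", entity_id, " aligns to no token")
  max(toks$index[inside])
}

#' Syntax-tree features of a candidate pair
#'
#' Path between the two entity leaves through their lowest common
#' ancestor; length in edges. Constituent-label counts, relative
#' frequencies and Shannon entropies for the whole tree and the path
#' (internal node labels from each leaf up to and including the LCA).
#'
#' @param sentence a [ppi_sentence()] with token and tree layers.
#' @param pair pair id or one-row pair data.frame.
#' @return named list: `st_path_length`, `st_entropy`, `st_path_entropy`,
#'   and per-label `st_count_*` / `st_freq_*` / `stp_freq_*` entries.
#' @export
st_features <- function(sentence, pair) {
  if (is.null(sentence$tree)) {
    stop("syntax tree layer absent in sentence ", sentence$id)
  }
  row <- resolve_pair(sentence, pair)
  h1 <- entity_head_token(sentence, row$e1)
  h2 <- entity_head_token(sentence, row$e2)

  nodes <- flatten_tree(sentence$tree)
  leaf_node <- function(tok) {
    hit <- which(vapply(nodes, function(n)
      identical(n$token, as.integer(tok)), TRUE))
    if (!length(hit)) stop("entity leaf not found for token ", tok)
    hit[1]
  }
  n1 <- leaf_node(h1); n2 <- leaf_node(h2)
  anc <- function(i) {
    out <- integer()
    while (!is.na(i)) { out <- c(out, i); i <- nodes[[i]]$parent }
    out
  }
  a1 <- anc(n1); a2 <- anc(n2)
  lca <- intersect(a1, a2)[1]
  d1 <- which(a1 == lca) - 1L
  d2 <- which(a2 == lca) - 1L

  labels_all <- unlist(lapply(nodes, function(n)
    if (is.null(n$token)) n$label else NULL))
  wt <- table(labels_all)
  path_nodes <- union(a1[seq_len(d1 + 1L)], a2[seq_len(d2 + 1L)])
  plabs <- unlist(lapply(nodes[path_nodes], function(n)
    if (is.null(n$token)) n$label else NULL))
  pt <- table(plabs)

  out <- list(st_path_length = d1 + d2,
              st_entropy = entropy_bits(wt),
              st_path_entropy = entropy_bits(pt))
  for (lb in names(wt)) {
    out[[paste0("st_count_", lb)]] <- as.integer(wt[[lb]])
    out[[paste0("st_freq_", lb)]] <- unname(wt[[lb]] / sum(wt))
  }
  for (lb in names(pt)) {
    out[[paste0("stp_freq_", lb)]] <- unname(pt[[lb]] / sum(pt))
  }
  out
}

# flatten a nested tree into a node list with parent pointers
flatten_tree <- function(tree) {
  nodes <- list()
  walk <- function(node, parent) {
    i <- length(nodes) + 1L
    nodes[[i]] <<- list(label = node$label,
                        token = if (!is.null(node$token))
                          as.integer(node$token) else NULL,
                        parent = parent)
    if (!is.null(node$children)) {
      for (ch in node$children) walk(ch, i)
    }
  }
  walk(tree, NA_integer_)
  nodes
}

#' Shannon entropy of a count vector, in bits
#'
#' @param counts non-negative counts (e.g. a `table`).
#' @return entropy in bits; 0 for empty or single-category input.
#' @export
entropy_bits <- function(counts) {
  counts <- as.numeric(counts)
  counts <- counts[counts > 0]
  if (!length(counts)) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Kullback-Leibler divergence between label distributions, in bits
#'
#' Divergence of a local label distribution from a reference (e.g. the
#' corpus-wide background); categories absent locally contribute 0,
#' categories absent in the reference are smoothed.
#'
#' @param counts local counts (named).
#' @param reference reference counts (named) over a superset of labels.
#' @return KL divergence in bits.
#' @export
kl_divergence_bits <- function(counts, reference) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(0)
  p <- counts / sum(counts)
  ref <- reference[names(p)]
  ref[is.na(ref) | ref == 0] <- 0.5
  q <- ref / sum(reference)
  sum(p * log2(p / q))
}

#' Feature table over all pairs of a corpus collection
#'
#' One feature vector per candidate pair: surface features always;
#' dependency-graph and syntax-tree features where the layers are present
#' (absent layers yield `NA`, flagged by the `dg_connected` /
#' `has_dg` / `has_st` indicators, not zeros). The per-label column
#' registry is closed over all labels observed in the collection.
#'
#' @param corpus a [ppi_corpus()] or list of corpora.
#' @param lexicons clue lexicons, see [default_lexicons()].
#' @param entropy_mode `"shannon"` (default) computes Shannon entropies of
#'   label distributions; `"kl"` computes Kullback-Leibler divergence from
#'   the corpus-wide label background instead.
#' @return data.frame with `pair_id`, `sentence_id`, `document_id`,
#'   `corpus`, `gold` and one column per feature.
#' @export
feature_table <- function(corpus, lexicons = default_lexicons(),
                          entropy_mode = c("shannon", "kl")) {
  entropy_mode <- match.arg(entropy_mode)
  if (inherits(corpus, "ppi_corpus")) corpus <- list(corpus)

  rows <- list()
  bg_dep <- integer(); bg_st <- integer()
  if (entropy_mode == "kl") {
    for (corp in corpus) for (d in corp$documents) for (s in d$sentences) {
      if (!is.null(s$deps)) {
        t1 <- table(s$deps$label)
        bg_dep <- merge_counts(bg_dep, t1)
      }
      if (!is.null(s$tree)) {
        t2 <- table(tree_labels(s$tree))
        bg_st <- merge_counts(bg_st, t2)
      }
    }
  }
  for (corp in corpus) for (d in corp$documents) for (s in d$sentences) {
    for (i in seq_len(nrow(s$pairs))) {
      row <- s$pairs[i, ]
      fv <- surface_features(s, row, lexicons)
      fv$has_dg <- as.integer(!is.null(s$deps))
      fv$has_st <- as.integer(!is.null(s$tree))
      if (fv$has_dg) fv <- c(fv, dg_features(s, row))
      if (fv$has_st) fv <- c(fv, st_features(s, row))
      if (entropy_mode == "kl") {
        if (fv$has_dg) fv$dg_entropy <-
            kl_divergence_bits(table(s$deps$label), bg_dep)
        if (fv$has_st) fv$st_entropy <-
            kl_divergence_bits(table(tree_labels(s$tree)), bg_st)
      }
      fv <- c(list(pair_id = row$id, sentence_id = s$id, document_id = d$id,
                   corpus = corp$name, gold = row$gold), fv)
      rows[[length(rows) + 1L]] <- fv
    }
  }
  if (!length(rows)) return(data.frame())
  # close the registry: union of all observed feature names
  all_names <- unique(unlist(lapply(rows, names)))
  cols <- lapply(all_names, function(nm) {
    unlist(lapply(rows, function(r) {
      v <- r[[nm]]
      if (is.null(v)) NA else v
    }))
  })
  names(cols) <- all_names
  out <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  names(out) <- all_names
  # absent labels within a present layer are genuine zero counts
  lab_cols <- grep("^(dg|dgp|st|stp)_(count|freq)_", all_names, value = TRUE)
  for (cl in lab_cols) {
    layer_ok <- if (startsWith(cl, "dgp")) {
      !is.na(out$dg_connected) & out$dg_connected == 1
    } else if (startsWith(cl, "dg")) out$has_dg == 1
    else out$has_st == 1
    fix <- is.na(out[[cl]]) & layer_ok
    out[[cl]][fix] <- 0
  }
  rownames(out) <- NULL
  out
}

merge_counts <- function(acc, tab) {
  for (nm in names(tab)) {
    acc[nm] <- (if (nm %in% names(acc)) acc[[nm]] else 0L) + tab[[nm]]
  }
  acc
}

#' Mean pair characteristics by six-way difficulty class
#'
#' Means of sentence length (words), entity token distance, and
#' dependency/syntax shortest-path lengths for the classes ND, NN, NE, PD,
#' PN, PE (gold sign x difficulty).
#'
#' @param ft feature table from [feature_table()].
#' @param classes data.frame with `pair_id` and `class` in `{D, N, E}`
#'   (e.g. from [combine_settings()]).
#' @return data.frame with one row per class; empty classes have `NA`
#'   means and `n = 0`.
#' @export
aggregate_by_difficulty <- function(ft, classes) {
  cl <- stats::setNames(classes$class, classes$pair_id)
  six <- paste0(ifelse(ft$gold, "P", "N"), cl[ft$pair_id])
  lvl <- c("ND", "NN", "NE", "PD", "PN", "PE")
  rows <- lapply(lvl, function(k) {
    sel <- which(six == k)
    data.frame(
      class = k, n = length(sel),
      sentence_length_word = mean(ft$sentence_length_word[sel]),
      entity_word_distance = mean(ft$entity_word_distance[sel]),
      dg_path_length = mean(ft$dg_path_length[sel], na.rm = TRUE),
      st_path_length = mean(ft$st_path_length[sel], na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Positive gold rate by sentence-length bin
#'
#' @param corpus a [ppi_corpus()] or list of corpora.
#' @param breaks bin breaks in words (passed to [cut()]); default decade
#'   bins.
#' @return data.frame with `bin`, `n_pairs`, `n_positive`, `rate`.
#' @export
positive_rate_by_length <- function(corpus,
                                    breaks = c(0, 10, 20, 30, 40, 50, 60, Inf)) {
  if (inherits(corpus, "ppi_corpus")) corpus <- list(corpus)
  lens <- numeric(); golds <- logical()
  for (corp in corpus) for (d in corp$documents) for (s in d$sentences) {
    if (!nrow(s$pairs)) next
    L <- if (!is.null(s$tokens)) nrow(s$tokens) else
      length(strsplit(s$text, "[[:space:]]+")[[1]])
    lens <- c(lens, rep(L, nrow(s$pairs)))
    golds <- c(golds, s$pairs$gold)
  }
  if (!length(lens)) stop("empty corpus")
  bin <- cut(lens, breaks, right = TRUE)
  agg <- tapply(golds, bin, function(g) c(length(g), sum(g)))
  rows <- lapply(levels(bin), function(b) {
    v <- agg[[b]]
    if (is.null(v)) v <- c(0, 0)
    data.frame(bin = b, n_pairs = v[1], n_positive = v[2],
               rate = if (v[1] > 0) v[2] / v[1] else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gold class distribution by protein count
#'
#' @param corpus a [ppi_corpus()] or list of corpora.
#' @return data.frame with `n_proteins`, `n_pairs`, `n_positive`,
#'   `n_negative`, `positive_rate`.
#' @export
class_dist_by_protein_count <- function(corpus) {
  if (inherits(corpus, "ppi_corpus")) corpus <- list(corpus)
  np <- integer(); golds <- logical()
  for (corp in corpus) for (d in corp$documents) for (s in d$sentences) {
    if (!nrow(s$pairs)) next
    np <- c(np, rep(nrow(s$entities), nrow(s$pairs)))
    golds <- c(golds, s$pairs$gold)
  }
  if (!length(np)) stop("empty corpus")
  rows <- lapply(sort(unique(np)), function(k) {
    sel <- np == k
    data.frame(n_proteins = k, n_pairs = sum(sel),
               n_positive = sum(golds[sel]),
               n_negative = sum(sel) - sum(golds[sel]),
               positive_rate = mean(golds[sel]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
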