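# Canonical data model for PPI corpora, prediction tables and fold files.
#
# Internal coordinate convention: all character spans are 0-based, half-open
# [start, end). The unified corpus XML dialect stores inclusive "a-b"
# character offsets; conversion happens at the read/write boundary only.

CORPUS_PREFIX_MAP <- c(
  A = "AIMed", B = "BioInfer", H = "HPRD50", I = "IEPA", L = "LLL"
)

#' Construct a sentence record
#'
#' A sentence carries its text, entity mentions with character spans,
#' candidate entity pairs with gold interaction labels, and optional parse
#' layers (tokens, dependency graph, constituency tree).
#'
#' @param id sentence identifier, unique corpus-wide.
#' @param text sentence text.
#' @param entities data.frame with columns `id`, `start`, `end` (0-based
#'   half-open span into `text`), `text`, `type`.
#' @param pairs data.frame with columns `id`, `e1`, `e2`, `gold` (logical).
#' @param tokens optional data.frame with columns `index` (0-based), `text`,
#'   `pos`, `start`, `end`.
#' @param deps optional data.frame with columns `from`, `to` (0-based token
#'   indices), `label` — a labeled directed dependency graph.
#' @param tree optional constituency tree: nested list with elements
#'   `label` and `children`; leaves are lists with element `token`
#'   (0-based token index).
#' @param extra_xml character vector of serialized unrecognized XML child
#'   elements, preserved opaquely on round-trip.
#' @return object of class `ppi_sentence`.
#' @export
ppi_sentence <- function(id, text, entities, pairs, tokens = NULL,
                         deps = NULL, tree = NULL, extra_xml = character()) {
  s <- structure(
    list(id = id, text = text, entities = entities, pairs = pairs,
         tokens = tokens, deps = deps, tree = tree, extra_xml = extra_xml),
    class = "ppi_sentence"
  )
  validate_sentence(s)
  s
}

validate_sentence <- function(s) {
  ents <- s$entities
  if (nrow(ents)) {
    bad <- ents$end <= ents$start
    if (any(bad)) {
      stop("entity ", ents$id[bad][1], ": span end must exceed start")
    }
    out <- ents$start < 0 | ents$end > nchar(s$text)
    if (any(out)) {
      stop("entity ", ents$id[out][1], ": span outside sentence text")
    }
    surf <- substring(s$text, ents$start + 1L, ents$end)
    mism <- surf != ents$text
    if (any(mism)) {
      stop("entity ", ents$id[mism][1],
           ": surface text does not match sentence substring")
    }
  }
  prs <- s$pairs
  if (nrow(prs)) {
    if (any(prs$e1 == prs$e2)) {
      stop("sentence ", s$id, ": self-interaction pair rejected")
    }
    dangling <- !(prs$e1 %in% ents$id) | !(prs$e2 %in% ents$id)
    if (any(dangling)) {
      stop("pair ", prs$id[dangling][1], ": dangling entity reference")
    }
    n <- nrow(ents)
    if (nrow(prs) > choose(n, 2)) {
      stop("sentence ", s$id, ": more pairs than entity combinations")
    }
  }
  if (!is.null(s$deps) && nrow(s$deps)) {
    if (is.null(s$tokens)) stop("sentence ", s$id,
                                ": dependency layer without tokens")
    idx <- s$tokens$index
    ok <- s$deps$from %in% idx & s$deps$to %in% idx
    if (!all(ok)) stop("sentence ", s$id,
                       ": dependency endpoint is not a token index")
  }
  if (!is.null(s$tree) && !is.null(s$tokens)) {
    leaves <- tree_leaves(s$tree)
    if (length(leaves) != nrow(s$tokens)) {
      stop("sentence ", s$id,
           ": tree leaf count differs from token count")
    }
  }
  invisible(s)
}

#' Construct a corpus
#'
#' @param name corpus name (also the long pair-id prefix).
#' @param documents list of documents; each document is a list with elements
#'   `id` and `sentences` (list of [ppi_sentence()] objects).
#' @return object of class `ppi_corpus`.
#' @export
ppi_corpus <- function(name, documents = list()) {
  corp <- structure(list(name = name, documents = documents),
                    class = "ppi_corpus")
  ids <- c(
    vapply(documents, `[[`, "", "id"),
    unlist(lapply(documents, function(d)
      lapply(d$sentences, function(s)
        c(s$id, s$entities$id, s$pairs$id))))
  )
  if (anyDuplicated(ids)) {
    stop("corpus ", name, ": duplicated id ", ids[duplicated(ids)][1])
  }
  corp
}

#' @export
print.ppi_corpus <- function(x, ...) {
  st <- corpus_stats(x)
  cat(sprintf(
    "<ppi_corpus '%s': %d documents, %d sentences, %d pairs (%.1f%% positive)>\n",
    x$name, st$documents, st$sentences, st$pairs, 100 * st$positive_ratio))
  invisible(x)
}

# ---- XML reading ----------------------------------------------------------

#' Parse a corpus in the unified PPI XML learning format
#'
#' Reads `corpus/document/sentence` XML with character-offset `entity`
#' elements (inclusive `charOffset="a-b"` converted to 0-based half-open
#' spans) and labeled `pair` elements. Optional `analyses` sub-elements
#' carry tokenization, dependency and constituency layers. Unrecognized
#' sentence children are preserved as opaque payload.
#'
#' @param source path to an XML file, or a literal XML string.
#' @return a [ppi_corpus()].
#' @export
parse_unified_corpus <- function(source) {
  doc <- tryCatch(xml2::read_xml(source), error = function(e)
    stop("malformed XML in corpus element: ", conditionMessage(e)))
  if (xml2::xml_name(doc) != "corpus") {
    stop("malformed XML: root element must be <corpus>, got <",
         xml2::xml_name(doc), ">")
  }
  name <- xml2::xml_attr(doc, "source")
  docs <- lapply(xml2::xml_find_all(doc, "./document"), parse_document_node)
  ppi_corpus(name, docs)
}

parse_document_node <- function(dnode) {
  list(
    id = xml2::xml_attr(dnode, "id"),
    sentences = lapply(xml2::xml_find_all(dnode, "./sentence"),
                       parse_sentence_node)
  )
}

parse_sentence_node <- function(snode) {
  sid <- xml2::xml_attr(snode, "id")
  text <- xml2::xml_attr(snode, "text")

  enodes <- xml2::xml_find_all(snode, "./entity")
  offs <- xml2::xml_attr(enodes, "charOffset")
  mt <- regmatches(offs, regexec("^([0-9]+)-([0-9]+)$", offs))
  bad <- vapply(mt, length, 0L) != 3L
  if (any(bad)) {
    stop("entity ", xml2::xml_attr(enodes, "id")[bad][1],
         ": malformed charOffset '", offs[bad][1], "'")
  }
  a <- vapply(mt, function(m) as.integer(m[2]), 0L)
  b <- vapply(mt, function(m) as.integer(m[3]), 0L)
  entities <- data.frame(
    id = xml2::xml_attr(enodes, "id"),
    start = a,                 # inclusive a-b  ->  half-open [a, b+1)
    end = b + 1L,
    text = xml2::xml_attr(enodes, "text"),
    type = ifelse(is.na(xml2::xml_attr(enodes, "type")), "protein",
                  xml2::xml_attr(enodes, "type")),
    stringsAsFactors = FALSE
  )

  pnodes <- xml2::xml_find_all(snode, "./pair")
  ilab <- xml2::xml_attr(pnodes, "interaction")
  if (length(ilab) && !all(ilab %in% c("True", "False"))) {
    stop("pair ", xml2::xml_attr(pnodes, "id")[!ilab %in% c("True", "False")][1],
         ": interaction attribute must be True or False")
  }
  pairs <- data.frame(
    id = xml2::xml_attr(pnodes, "id"),
    e1 = xml2::xml_attr(pnodes, "e1"),
    e2 = xml2::xml_attr(pnodes, "e2"),
    gold = ilab == "True",
    stringsAsFactors = FALSE
  )

  tokens <- NULL; deps <- NULL; tree <- NULL
  an <- xml2::xml_find_first(snode, "./analyses")
  if (!inherits(an, "xml_missing")) {
    tnodes <- xml2::xml_find_all(an, "./tokenization/token")
    if (length(tnodes)) {
      toffs <- xml2::xml_attr(tnodes, "charOffset")
      tm <- regmatches(toffs, regexec("^([0-9]+)-([0-9]+)$", toffs))
      tokens <- data.frame(
        index = as.integer(xml2::xml_attr(tnodes, "index")),
        text = xml2::xml_attr(tnodes, "text"),
        pos = xml2::xml_attr(tnodes, "POS"),
        start = vapply(tm, function(m) as.integer(m[2]), 0L),
        end = vapply(tm, function(m) as.integer(m[3]), 0L) + 1L,
        stringsAsFactors = FALSE
      )
    }
    dnodes <- xml2::xml_find_all(an, "./dependencies/dependency")
    if (length(dnodes)) {
      deps <- data.frame(
        from = as.integer(xml2::xml_attr(dnodes, "t1")),
        to = as.integer(xml2::xml_attr(dnodes, "t2")),
        label = xml2::xml_attr(dnodes, "type"),
        stringsAsFactors = FALSE
      )
    }
    cnode <- xml2::xml_find_first(an, "./constituents/constituent")
    if (!inherits(cnode, "xml_missing")) tree <- parse_constituent_node(cnode)
  }

  known <- c("entity", "pair", "analyses")
  kids <- xml2::xml_children(snode)
  extra <- kids[!xml2::xml_name(kids) %in% known]
  extra_xml <- vapply(extra, function(n) as.character(n), "")

  ppi_sentence(sid, text, entities, pairs, tokens, deps, tree, extra_xml)
}

parse_constituent_node <- function(node) {
  if (xml2::xml_name(node) == "leaf") {
    return(list(token = as.integer(xml2::xml_attr(node, "token"))))
  }
  list(label = xml2::xml_attr(node, "label"),
       children = lapply(xml2::xml_children(node), parse_constituent_node))
}

# ---- XML writing ----------------------------------------------------------

#' Write a corpus in the unified PPI XML learning format
#'
#' Inverse of [parse_unified_corpus()]: half-open spans are restored to the
#' dialect's inclusive `a-b` offsets; parse layers and preserved opaque
#' payload are re-emitted.
#'
#' @param corpus a [ppi_corpus()].
#' @param destination file path.
#' @export
write_unified_corpus <- function(corpus, destination) {
  root <- xml2::xml_new_root("corpus", source = corpus$name)
  for (d in corpus$documents) {
    dn <- xml2::xml_add_child(root, "document", id = d$id)
    for (s in d$sentences) write_sentence_node(dn, s)
  }
  xml2::write_xml(root, destination)
  invisible(NULL)
}

write_sentence_node <- function(dn, s) {
  sn <- xml2::xml_add_child(dn, "sentence", id = s$id, text = s$text)
  for (i in seq_len(nrow(s$entities))) {
    e <- s$entities[i, ]
    xml2::xml_add_child(sn, "entity", id = e$id,
                        charOffset = paste0(e$start, "-", e$end - 1L),
                        text = e$text, type = e$type)
  }
  for (i in seq_len(nrow(s$pairs))) {
    p <- s$pairs[i, ]
    xml2::xml_add_child(sn, "pair", id = p$id, e1 = p$e1, e2 = p$e2,
                        interaction = if (p$gold) "True" else "False")
  }
  if (!is.null(s$tokens) || !is.null(s$deps) || !is.null(s$tree)) {
    an <- xml2::xml_add_child(sn, "analyses")
    if (!is.null(s$tokens)) {
      tn <- xml2::xml_add_child(an, "tokenization")
      for (i in seq_len(nrow(s$tokens))) {
        tk <- s$tokens[i, ]
        xml2::xml_add_child(tn, "token", index = as.character(tk$index),
                            text = tk$text, POS = tk$pos,
                            charOffset = paste0(tk$start, "-", tk$end - 1L))
      }
    }
    if (!is.null(s$deps)) {
      pn <- xml2::xml_add_child(an, "dependencies")
      for (i in seq_len(nrow(s$deps))) {
        dp <- s$deps[i, ]
        xml2::xml_add_child(pn, "dependency", t1 = as.character(dp$from),
                            t2 = as.character(dp$to), type = dp$label)
      }
    }
    if (!is.null(s$tree)) {
      cn <- xml2::xml_add_child(an, "constituents")
      write_constituent_node(cn, s$tree)
    }
  }
  for (x in s$extra_xml) {
    xml2::xml_add_child(sn, xml2::read_xml(x))
  }
  invisible(NULL)
}

write_constituent_node <- function(parent, node) {
  if (!is.null(node$token)) {
    xml2::xml_add_child(parent, "leaf", token = as.character(node$token))
  } else {
    cn <- xml2::xml_add_child(parent, "constituent", label = node$label)
    for (ch in node$children) write_constituent_node(cn, ch)
  }
  invisible(NULL)
}

tree_leaves <- function(tree) {
  if (!is.null(tree$token)) return(tree$token)
  unlist(lapply(tree$children, tree_leaves))
}

# ---- Prediction sets ------------------------------------------------------

#' Construct a prediction set
#'
#' A complete (pair x classifier) table of predicted binary interaction
#' labels for one evaluation setting.
#'
#' @param table logical matrix, rows named by pair id, columns by
#'   classifier id.
#' @param setting `"CV"` (document-level cross-validation) or `"CL"`
#'   (cross-learning).
#' @return object of class `prediction_set` with fields `setting`,
#'   `roster`, `table`.
#' @export
prediction_set <- function(table, setting = c("CV", "CL")) {
  setting <- match.arg(setting)
  stopifnot(is.matrix(table), is.logical(table),
            !is.null(rownames(table)), !is.null(colnames(table)))
  if (anyNA(table)) stop("prediction table is incomplete")
  structure(list(setting = setting, roster = colnames(table), table = table),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set %s: %d classifiers x %d pairs>\n",
              x$setting, length(x$roster), nrow(x$table)))
  invisible(x)
}

#' Read a prediction table from TSV
#'
#' Expects a header `pair_id  classifier_id  setting  label` with labels in
#' `{0, 1}` and settings in `{CV, CL}`. Duplicate (pair, classifier) cells
#' are an error; the table must be complete over its roster.
#'
#' @param tsv_source path to a TSV file.
#' @param setting optional setting to select when the file mixes both.
#' @param corpus optional [ppi_corpus()] (or list of corpora) against which
#'   pair ids are validated.
#' @return a [prediction_set()].
#' @export
read_predictions <- function(tsv_source, setting = NULL, corpus = NULL) {
  df <- utils::read.delim(tsv_source, colClasses = "character")
  need <- c("pair_id", "classifier_id", "setting", "label")
  if (!all(need %in% names(df))) {
    stop("prediction TSV must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$setting), c("CV", "CL"))
  if (length(bad)) stop("unknown setting token: ", bad[1])
  if (!all(df$label %in% c("0", "1"))) {
    stop("non-binary label in prediction TSV: ",
         df$label[!df$label %in% c("0", "1")][1])
  }
  if (is.null(setting)) {
    us <- unique(df$setting)
    if (length(us) > 1) {
      stop("file mixes settings ", paste(us, collapse = "/"),
           "; pass `setting` to select one")
    }
    setting <- us
  }
  df <- df[df$setting == setting, , drop = FALSE]
  if (!nrow(df)) stop("no rows for setting ", setting)
  key <- paste(df$pair_id, df$classifier_id)
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1, ]
    stop("duplicate prediction cell (", d$pair_id, ", ", d$classifier_id, ")")
  }
  pairs <- sort(unique(df$pair_id))
  roster <- sort(unique(df$classifier_id))
  m <- matrix(NA, nrow = length(pairs), ncol = length(roster),
              dimnames = list(pairs, roster))
  m[cbind(match(df$pair_id, pairs), match(df$classifier_id, roster))] <-
    df$label == "1"
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("prediction table incomplete: missing cell (",
         pairs[idx[1]], ", ", roster[idx[2]], ")")
  }
  if (!is.null(corpus)) {
    gold <- gold_labels(corpus)
    unknown <- setdiff(pairs, names(gold))
    if (length(unknown)) {
      stop("prediction pair id does not resolve in corpus: ", unknown[1])
    }
  }
  prediction_set(m, setting)
}

#' Write a prediction set as TSV
#'
#' @param pset a [prediction_set()].
#' @param destination file path.
#' @export
write_predictions <- function(pset, destination) {
  df <- data.frame(
    pair_id = rep(rownames(pset$table), times = ncol(pset$table)),
    classifier_id = rep(colnames(pset$table), each = nrow(pset$table)),
    setting = pset$setting,
    label = as.integer(pset$table),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$pair_id, df$classifier_id), ]
  utils::write.table(df, destination, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

# ---- Pair ids -------------------------------------------------------------

#' Normalize pair identifiers to canonical long form
#'
#' Pair ids come in a long form (`"BioInfer.d267.s0.p14"`) and a short form
#' with a one-letter corpus initial (`"B.d267.s0.p14"`); initials map
#' A/B/H/I/L to AIMed/BioInfer/HPRD50/IEPA/LLL. Long-form ids are returned
#' unchanged (idempotent); unknown one-letter prefixes are an error.
#'
#' @param id_string character vector of pair ids.
#' @return character vector of canonical long-form ids.
#' @export
normalize_pair_id <- function(id_string) {
  ok <- grepl("^[^.]+\\.d[0-9]+\\.s[0-9]+\\.p[0-9]+$", id_string)
  if (!all(ok)) stop("malformed pair id: ", id_string[!ok][1])
  prefix <- sub("\\..*$", "", id_string)
  rest <- sub("^[^.]+", "", id_string)
  short <- nchar(prefix) == 1L
  if (any(short)) {
    mapped <- CORPUS_PREFIX_MAP[prefix[short]]
    if (anyNA(mapped)) {
      stop("unknown corpus prefix: ", prefix[short][is.na(mapped)][1])
    }
    prefix[short] <- mapped
  }
  paste0(prefix, rest)
}

#' Shorten pair identifiers for the five benchmark corpora
#'
#' Inverse of [normalize_pair_id()] on the five benchmark prefixes; other
#' prefixes are left unchanged.
#'
#' @param id_string character vector of long-form pair ids.
#' @return character vector with one-letter prefixes where applicable.
#' @export
shorten_pair_id <- function(id_string) {
  prefix <- sub("\\..*$", "", id_string)
  rest <- sub("^[^.]+", "", id_string)
  rev_map <- stats::setNames(names(CORPUS_PREFIX_MAP), CORPUS_PREFIX_MAP)
  hit <- prefix %in% names(rev_map)
  prefix[hit] <- rev_map[prefix[hit]]
  paste0(prefix, rest)
}

# ---- Flat views and summaries ---------------------------------------------

#' Flatten a corpus (or list of corpora) into a pair table
#'
#' @param corpus a [ppi_corpus()] or list of them.
#' @return data.frame with one row per candidate pair: `pair_id`,
#'   `sentence_id`, `document_id`, `corpus`, `e1`, `e2`, `gold`.
#' @export
pairs_table <- function(corpus) {
  if (inherits(corpus, "ppi_corpus")) corpus <- list(corpus)
  out <- lapply(corpus, function(corp) {
    rows <- lapply(corp$documents, function(d) {
      lapply(d$sentences, function(s) {
        if (!nrow(s$pairs)) return(NULL)
        data.frame(pair_id = s$pairs$id, sentence_id = s$id,
                   document_id = d$id, corpus = corp$name,
                   e1 = s$pairs$e1, e2 = s$pairs$e2, gold = s$pairs$gold,
                   stringsAsFactors = FALSE)
      })
    })
    do.call(rbind, unlist(rows, recursive = FALSE))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(pair_id = character(), sentence_id = character(),
                      document_id = character(), corpus = character(),
                      e1 = character(), e2 = character(), gold = logical())
  }
  rownames(out) <- NULL
  out
}

#' Gold interaction labels of a corpus collection
#'
#' @param corpus a [ppi_corpus()] or list of them.
#' @return named logical vector, names are pair ids.
#' @export
gold_labels <- function(corpus) {
  pt <- pairs_table(corpus)
  stats::setNames(pt$gold, pt$pair_id)
}

#' Summary counts for a corpus
#'
#' @param corpus a [ppi_corpus()].
#' @return list with `pairs`, `positives`, `negatives`, `positive_ratio`,
#'   `sentences`, `documents`.
#' @export
corpus_stats <- function(corpus) {
  pt <- pairs_table(corpus)
  n_sent <- sum(vapply(corpus$documents,
                       function(d) length(d$sentences), 0L))
  pos <- sum(pt$gold)
  list(
    pairs = nrow(pt),
    positives = pos,
    negatives = nrow(pt) - pos,
    positive_ratio = if (nrow(pt)) pos / nrow(pt) else NA_real_,
    sentences = n_sent,
    documents = length(corpus$documents)
  )
}

# ---- Folds ----------------------------------------------------------------

#' Read a document-level fold assignment
#'
#' TSV with header `document_id  fold`; folds are integers in `0..9` and the
#' assignment must be a partition (each document in exactly one fold).
#'
#' @param tsv_source path to a TSV file.
#' @return named integer vector (names are document ids).
#' @export
read_folds <- function(tsv_source) {
  df <- utils::read.delim(tsv_source, colClasses = "character")
  if (!all(c("document_id", "fold") %in% names(df))) {
    stop("fold TSV must have columns: document_id, fold")
  }
  if (anyDuplicated(df$document_id)) {
    stop("document assigned to more than one fold: ",
         df$document_id[duplicated(df$document_id)][1])
  }
  fold <- as.integer(df$fold)
  if (anyNA(fold) || any(fold < 0L | fold > 9L)) {
    stop("fold indices must be integers in 0..9")
  }
  stats::setNames(fold, df$document_id)
}

#' Write a document-level fold assignment as TSV
#'
#' @param folds named integer vector as returned by [read_folds()].
#' @param destination file path.
#' @export
write_folds <- function(folds, destination) {
  utils::write.table(
    data.frame(document_id = names(folds), fold = unname(folds)),
    destination, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
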