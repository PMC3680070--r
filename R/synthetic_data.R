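# Seeded generator for synthetic PPI corpora and prediction matrices.
#
# The generator does not attempt fluent English: sentence text is a
# template-based token sequence that is sufficient for tokenization,
# surface-clue extraction and the parse-layer features. What it does
# reproduce is statistical structure: class-conditional sentence lengths,
# class-conditional entity distances, positive-rate decay with sentence
# length and protein count, class-conditioned dependency/constituent label
# frequencies, per-pair latent difficulty shared across classifiers,
# representation-family error correlation, and a cross-learning correctness
# penalty.

FILLER_WORDS <- c(
  "the", "of", "and", "in", "to", "a", "was", "were", "that", "this",
  "cells", "protein", "expression", "analysis", "results", "domain",
  "complex", "signaling", "pathway", "levels", "human", "gene", "kinase",
  "receptor", "role", "function", "observed", "studies", "present",
  "specific", "effect", "addition", "data", "region", "using", "assay")

DEP_LABELS <- c("nsubj", "dobj", "nn", "appos", "conj_and", "dep", "det",
                "amod", "prep_with", "prep_in", "nsubjpass")

# class-conditioned dependency label weights (positive-context vs
# negative-context sentences); negative contexts are enumeration-heavy.
DEP_W_POS <- c(nsubj = 3, dobj = 3, nn = 1, appos = 0.5, conj_and = 0.7,
               dep = 0.8, det = 1.5, amod = 1, prep_with = 2, prep_in = 1.5,
               nsubjpass = 2)
DEP_W_NEG <- c(nsubj = 1, dobj = 1, nn = 3, appos = 2.5, conj_and = 3,
               dep = 2, det = 2, amod = 2, prep_with = 0.7, prep_in = 1,
               nsubjpass = 0.5)

CONST_LABELS <- c("NP", "VP", "PP", "ADJP", "ADVP", "SBAR")
CONST_W_POS <- c(NP = 2, VP = 2, PP = 2, ADJP = 1.5, ADVP = 1.5, SBAR = 1.5)
CONST_W_NEG <- c(NP = 5, VP = 1, PP = 1, ADJP = 0.4, ADVP = 0.3, SBAR = 0.3)

#' Configuration for the synthetic corpus generator
#'
#' Defaults encode the study conditions the generator emulates: mean
#' sentence lengths of 27.6 words for positive-context and 37.2 words for
#' negative-context sentences, mean entity token distances of 7.15
#' (positive pairs) and 9.67 (negative pairs), and a positive-pair odds
#' model that decays with protein count and sentence length.
#'
#' @param name corpus name (used as the pair-id prefix).
#' @param n_documents number of documents; ignored when `target_pairs` is
#'   given.
#' @param target_pairs if non-`NULL`, documents are generated until the
#'   corpus holds at least this many candidate pairs.
#' @param sentences_per_document mean of the (shifted Poisson) sentence
#'   count per document.
#' @param protein_count_probs probabilities of 2..6 protein mentions per
#'   sentence.
#' @param len_mean_pos,len_sd_pos,len_mean_neg,len_sd_neg class-conditional
#'   sentence length model, in words.
#' @param dist_mean_pos,dist_mean_neg target mean entity token distance
#'   (tokens strictly between the two mentions) for positive and negative
#'   pairs.
#' @param base_prob_pos,base_prob_neg per-pair positive probability in
#'   positive-context and negative-context sentences before decay terms.
#' @param decay_protein,decay_length log-odds decay of the positive
#'   probability per extra protein mention and per word of sentence length.
#' @param target_positive_ratio overall gold positive ratio in (0, 1); the
#'   generator calibrates a global intercept so the expected realized ratio
#'   equals the target.
#' @param lexicons word lists used to seed sentence text, see
#'   [default_lexicons()].
#' @param seed integer seed.
#' @return list of class `sim_corpus_config`.
#' @export
sim_corpus_config <- function(name = "SimCorpus",
                              n_documents = 100,
                              target_pairs = NULL,
                              sentences_per_document = 3,
                              protein_count_probs = c(`2` = 0.50, `3` = 0.22,
                                                      `4` = 0.13, `5` = 0.09,
                                                      `6` = 0.06),
                              len_mean_pos = 27.6, len_sd_pos = 7,
                              len_mean_neg = 37.2, len_sd_neg = 9,
                              dist_mean_pos = 7.15, dist_mean_neg = 9.67,
                              base_prob_pos = 0.92, base_prob_neg = 0.005,
                              decay_protein = 0.8, decay_length = 0.02,
                              target_positive_ratio = 0.25,
                              lexicons = default_lexicons(),
                              seed = 1L) {
  stopifnot(len_mean_pos > 0, len_mean_neg > 0,
            abs(sum(protein_count_probs) - 1) < 1e-8,
            dist_mean_pos > 0, dist_mean_neg > 0)
  if (target_positive_ratio <= 0 || target_positive_ratio > 1) {
    stop("target_positive_ratio must be in (0, 1]")
  }
  structure(as.list(environment()), class = "sim_corpus_config")
}

#' Generate a synthetic corpus
#'
#' All `choose(n, 2)` entity pairs of each sentence are enumerated as
#' candidate pairs. Gold labels are drawn from the configured positive-odds
#' model, with a global intercept calibrated so the expected positive ratio
#' equals the target. Token, dependency-chain and shallow constituency
#' layers are emitted with class-conditioned label frequencies so feature
#' analysis has a recoverable signal. Identical configuration and seed give
#' an identical corpus.
#'
#' @param config a [sim_corpus_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return a [ppi_corpus()].
#' @export
generate_corpus <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_corpus_config"))
  set.seed(seed)

  # -- pass 1: sentence skeletons (context flag, length, protein count) ----
  p1 <- config$base_prob_pos; p0 <- config$base_prob_neg
  tr <- config$target_positive_ratio
  if (tr < 0.001 || tr > 0.999) {
    stop("infeasible target ratio ", tr, "; achievable range is [0.001, 0.999]")
  }
  # positive-context sentences carry fewer protein mentions
  prot_tilt <- 0.45
  k_names <- as.integer(names(config$protein_count_probs))
  probs_z1 <- config$protein_count_probs * prot_tilt^(k_names - 2)
  probs_z1 <- probs_z1 / sum(probs_z1)

  # share of positive-context sentences, solved pair-weighted so the
  # expected gold ratio lands on target before the intercept refinement
  e_pairs_z1 <- sum(probs_z1 * choose(k_names, 2))
  e_pairs_z0 <- sum(config$protein_count_probs * choose(k_names, 2))
  w <- e_pairs_z0 * (tr - p0) /
    (e_pairs_z1 * (p1 - tr) + e_pairs_z0 * (tr - p0))
  w <- min(max(w, 0.02), 0.98)

  skel <- list(); total_pairs <- 0L; di <- 0L
  unlimited <- !is.null(config$target_pairs)
  n_docs <- if (unlimited) .Machine$integer.max else config$n_documents
  while (di < n_docs) {
    if (unlimited && total_pairs >= config$target_pairs) break
    di <- di + 1L
    n_sent <- 1L + stats::rpois(1, max(config$sentences_per_document - 1, 0))
    sents <- vector("list", n_sent)
    for (si in seq_len(n_sent)) {
      z <- stats::rbinom(1, 1, w)
      v <- stats::rnorm(1)              # latent verbosity, shifts length
      mu <- if (z == 1) config$len_mean_pos else config$len_mean_neg
      sdv <- if (z == 1) config$len_sd_pos else config$len_sd_neg
      L <- max(8L, as.integer(round(mu + sdv * v)))
      # mention count feasible for the drawn length at the expected
      # class-conditional spacing (longer sentences carry more mentions)
      spacing <- 1 + if (z == 1) config$dist_mean_pos else config$dist_mean_neg
      n_max <- max(2L, 1L + as.integer((L - 6L) %/% spacing))
      pw <- if (z == 1) probs_z1 else config$protein_count_probs
      pw <- pw[k_names <= n_max]
      n_prot <- as.integer(sample(names(pw), 1, prob = pw))
      sents[[si]] <- list(z = z, v = v, n_prot = n_prot,
                          n_pairs = choose(n_prot, 2), L = L)
      total_pairs <- total_pairs + choose(n_prot, 2)
    }
    skel[[di]] <- sents
  }
  if (!length(skel)) return(ppi_corpus(config$name, list()))

  # -- calibrate global intercept so E[positive ratio] = target ------------
  flat <- unlist(skel, recursive = FALSE)
  sd_len <- (config$len_sd_pos + config$len_sd_neg) / 2
  eta <- vapply(flat, function(s) {
    base <- if (s$z == 1) p1 else p0
    stats::qlogis(base) - config$decay_protein * (s$n_prot - 2) -
      config$decay_length * sd_len * s$v
  }, 0)
  npairs <- vapply(flat, `[[`, 0, "n_pairs")
  clamp01 <- function(p) pmin(pmax(p, 0.001), 0.999)
  f <- function(cc) sum(clamp01(stats::plogis(eta + cc)) * npairs) /
    sum(npairs) - tr
  intercept <- stats::uniroot(f, c(-30, 30))$root
  p_sent <- clamp01(stats::plogis(eta + intercept))

  # -- draw positive counts per sentence -----------------------------------
  k_pos <- stats::rbinom(length(flat), npairs, p_sent)

  # -- gold-weighted length calibration ------------------------------------
  # mention count grows with length, so pairs oversample long sentences;
  # sentences also mix gold classes. Two per-context offsets are solved
  # (linearized 2x2 system, one refinement pass) so the realized
  # pair-level means of sentence length conditional on the gold label hit
  # the configured class means.
  zs <- vapply(flat, `[[`, 0L, "z")
  vs <- vapply(flat, `[[`, 0, "v")
  k_neg <- npairs - k_pos
  mu_z <- ifelse(zs == 1L, config$len_mean_pos, config$len_mean_neg)
  sd_z <- ifelse(zs == 1L, config$len_sd_pos, config$len_sd_neg)
  if (sum(k_pos) > 0 && sum(k_neg) > 0) {
    d <- c(0, 0)   # offsets for z = 1, z = 0
    for (iter in 1:2) {
      L_cur <- pmax(8, round(mu_z + ifelse(zs == 1L, d[1], d[2]) + sd_z * vs))
      gp <- sum(k_pos * L_cur) / sum(k_pos) - config$len_mean_pos
      gn <- sum(k_neg * L_cur) / sum(k_neg) - config$len_mean_neg
      A <- rbind(
        c(sum(k_pos[zs == 1L]) / sum(k_pos), sum(k_pos[zs == 0L]) / sum(k_pos)),
        c(sum(k_neg[zs == 1L]) / sum(k_neg), sum(k_neg[zs == 0L]) / sum(k_neg)))
      step <- tryCatch(solve(A, -c(gp, gn)), error = function(e) c(0, 0))
      d <- d + step
    }
    d <- pmin(pmax(d, -15), 15)
    for (i in seq_along(flat)) {
      flat[[i]]$L <- max(8L, as.integer(round(
        mu_z[i] + (if (zs[i] == 1L) d[1] else d[2]) + sd_z[i] * vs[i])))
    }
  }

  # -- calibrate entity gap means (linear system, see vignette) ------------
  # every pair's token distance is a sum over consecutive entity gaps;
  # positives are assigned to consecutive entity pairs first, so solving a
  # 2x2 linear system in the two gap means reproduces the configured
  # class-conditional distance means in expectation.
  assign_positives <- function(n_prot, k) {
    cons <- cbind(seq_len(n_prot - 1), seq_len(n_prot - 1) + 1)
    others <- t(utils::combn(n_prot, 2))
    others <- others[others[, 2] - others[, 1] > 1, , drop = FALSE]
    ord <- rbind(cons, others)
    pos <- logical(nrow(ord))
    if (k > 0) pos[seq_len(min(k, nrow(ord)))] <- TRUE
    list(pairs = ord, pos = pos)
  }
  assignments <- lapply(seq_along(flat), function(i)
    assign_positives(flat[[i]]$n_prot, k_pos[i]))

  # coefficients: E[dist] = (#pos gaps)*m_pos + (#neg gaps)*m_neg + (#gaps-1)
  cPP <- 0; cPN <- 0; aP <- 0; nP <- 0
  cNP <- 0; cNN <- 0; aN <- 0; nN <- 0
  for (i in seq_along(flat)) {
    asg <- assignments[[i]]
    cons_pos <- asg$pos[seq_len(flat[[i]]$n_prot - 1)]
    for (j in seq_len(nrow(asg$pairs))) {
      segs <- asg$pairs[j, 1]:(asg$pairs[j, 2] - 1)
      np_seg <- sum(cons_pos[segs]); nn_seg <- length(segs) - np_seg
      extra <- length(segs) - 1
      if (asg$pos[j]) {
        cPP <- cPP + np_seg; cPN <- cPN + nn_seg; aP <- aP + extra
        nP <- nP + 1
      } else {
        cNP <- cNP + np_seg; cNN <- cNN + nn_seg; aN <- aN + extra
        nN <- nN + 1
      }
    }
  }
  m_pos <- config$dist_mean_pos; m_neg <- config$dist_mean_neg
  if (nP > 0 && nN > 0 && cPP > 0 && cNN > 0) {
    A <- rbind(c(cPP / nP, cPN / nP), c(cNP / nN, cNN / nN))
    b <- c(config$dist_mean_pos - aP / nP, config$dist_mean_neg - aN / nN)
    sol <- tryCatch(solve(A, b), error = function(e) c(m_pos, m_neg))
    m_pos <- min(max(sol[1], 0.5), 40)
    m_neg <- min(max(sol[2], 0.5), 40)
  }

  # -- pass 2: realize sentences -------------------------------------------
  documents <- vector("list", length(skel))
  idx <- 0L
  for (di in seq_along(skel)) {
    doc_id <- sprintf("%s.d%d", config$name, di - 1L)
    sents <- vector("list", length(skel[[di]]))
    for (si in seq_along(skel[[di]])) {
      idx <- idx + 1L
      sk <- flat[[idx]]
      sents[[si]] <- realize_sentence(
        config, doc_id, si - 1L, sk, assignments[[idx]], m_pos, m_neg)
    }
    documents[[di]] <- list(id = doc_id, sentences = sents)
  }
  ppi_corpus(config$name, documents)
}

# Build one synthetic sentence: place entities by class-conditioned gaps,
# fill remaining positions with lexicon/filler tokens, emit token, chain
# dependency and shallow constituency layers.
realize_sentence <- function(config, doc_id, si, sk, asg, m_pos, m_neg) {
  n_prot <- sk$n_prot
  cons_pos <- asg$pos[seq_len(n_prot - 1)]
  gaps <- integer(n_prot - 1)
  for (g in seq_len(n_prot - 1)) {
    gaps[g] <- 1L + stats::rpois(1, if (cons_pos[g]) m_pos else m_neg)
  }
  lead <- 1L + stats::rpois(1, 2)
  # entities must fit the drawn length; compress gaps proportionally when
  # crowded (keeps the class-conditional length calibration intact)
  room <- sk$L - 3L - lead
  if (n_prot > 1 && sum(gaps) > room) {
    if (room >= n_prot - 1) {
      scale <- room / sum(gaps)
      gaps <- pmax(1L, as.integer(floor(gaps * scale)))
    } else {
      gaps <- rep(1L, n_prot - 1)
    }
  }
  ent_pos <- lead + cumsum(c(0L, gaps))          # 0-based token positions
  L <- max(sk$L, ent_pos[n_prot] + 3L)

  lex <- config$lexicons
  tokens <- character(L)
  pos_tags <- character(L)
  # fillers, with class-conditioned clue words and commas
  p_comma <- if (sk$z == 1) 0.02 else 0.07
  for (i in seq_len(L)) {
    if (stats::runif(1) < p_comma) {
      tokens[i] <- ","; pos_tags[i] <- ","
    } else {
      tokens[i] <- sample(FILLER_WORDS, 1)
      pos_tags[i] <- sample(c("NN", "IN", "DT", "JJ", "VBD"), 1,
                            prob = c(4, 2, 2, 1, 1))
    }
  }
  # clue insertions (positions away from entity slots)
  free <- setdiff(seq_len(L), ent_pos + 1L)
  put <- function(word, tag) {
    if (length(free) == 0) return(invisible(NULL))
    at <- if (length(free) == 1) free else sample(free, 1)
    tokens[at] <<- word; pos_tags[at] <<- tag
    free <<- setdiff(free, at)
    invisible(NULL)
  }
  p_int <- if (sk$z == 1) 0.9 else 0.25
  p_negw <- if (sk$z == 1) 0.08 else 0.35
  p_hedge <- if (sk$z == 1) 0.10 else 0.30
  if (stats::runif(1) < p_int) put(sample(lex$interaction, 1), "VBZ")
  if (stats::runif(1) < p_negw) put(sample(lex$negation, 1), "RB")
  if (stats::runif(1) < p_hedge) put(sample(lex$hedge, 1), "MD")
  # entities
  ent_names <- sprintf("Prot%d", seq_len(n_prot))
  tokens[ent_pos + 1L] <- ent_names
  pos_tags[ent_pos + 1L] <- "NNP"
  tokens[L] <- "."; pos_tags[L] <- "."
  if ((L - 1L) %in% (ent_pos + 1L) == FALSE && tokens[L - 1L] == ",") {
    tokens[L - 1L] <- sample(FILLER_WORDS, 1); pos_tags[L - 1L] <- "NN"
  }

  starts <- cumsum(c(0L, nchar(tokens[-L]) + 1L))
  ends <- starts + nchar(tokens)
  text <- paste(tokens, collapse = " ")

  sid <- sprintf("%s.s%d", doc_id, si)
  entities <- data.frame(
    id = sprintf("%s.e%d", sid, seq_len(n_prot) - 1L),
    start = starts[ent_pos + 1L],
    end = ends[ent_pos + 1L],
    text = ent_names,
    type = "protein",
    stringsAsFactors = FALSE
  )
  pairs <- data.frame(
    id = sprintf("%s.p%d", sid, seq_len(nrow(asg$pairs)) - 1L),
    e1 = entities$id[asg$pairs[, 1]],
    e2 = entities$id[asg$pairs[, 2]],
    gold = asg$pos,
    stringsAsFactors = FALSE
  )

  token_df <- data.frame(index = seq_len(L) - 1L, text = tokens,
                         pos = pos_tags, start = starts, end = ends,
                         stringsAsFactors = FALSE)
  dep_w <- if (sk$z == 1) DEP_W_POS else DEP_W_NEG
  deps <- data.frame(
    from = 0:(L - 2L), to = 1:(L - 1L),
    label = sample(DEP_LABELS, L - 1L, replace = TRUE, prob = dep_w),
    stringsAsFactors = FALSE
  )
  tree <- build_shallow_tree(L, if (sk$z == 1) CONST_W_POS else CONST_W_NEG)

  ppi_sentence(sid, text, entities, pairs, token_df, deps, tree)
}

# shallow constituency tree: root S over chunk constituents of 3-5 tokens
build_shallow_tree <- function(L, const_w) {
  children <- list(); i <- 0L
  while (i < L) {
    size <- min(sample(3:5, 1), L - i)
    lab <- sample(CONST_LABELS, 1, prob = const_w)
    leaves <- lapply(i:(i + size - 1L), function(t) list(token = t))
    children[[length(children) + 1L]] <- list(label = lab, children = leaves)
    i <- i + size
  }
  list(label = "S", children = children)
}

# ---- classifier simulation ------------------------------------------------

#' Simulated classifier profile
#'
#' @param id classifier identifier.
#' @param family input representation family: `"tree"` (syntax tree),
#'   `"dep"` (dependency graph) or `"shallow"` (surface features only).
#' @param base_correctness probability of a correct label on a pair of
#'   average difficulty.
#' @param difficulty_sensitivity drop in correctness per unit of latent
#'   difficulty (>= 0).
#' @param family_coupling weight of the shared per-family error component
#'   in `[0, 1]`.
#' @param positive_bias signed correctness shift: `+bias` on gold-positive
#'   pairs, `-bias` on gold-negative pairs; drives the realized
#'   positive-prediction rate.
#' @return list of class `sim_classifier_profile`.
#' @export
sim_classifier_profile <- function(id, family = c("dep", "tree", "shallow"),
                                   base_correctness = 0.8,
                                   difficulty_sensitivity = 0.6,
                                   family_coupling = 0.7,
                                   positive_bias = 0) {
  family <- match.arg(family)
  stopifnot(base_correctness > 0, base_correctness < 1,
            difficulty_sensitivity >= 0,
            family_coupling >= 0, family_coupling <= 1)
  structure(list(id = id, family = family,
                 base_correctness = base_correctness,
                 difficulty_sensitivity = difficulty_sensitivity,
                 family_coupling = family_coupling,
                 positive_bias = positive_bias),
            class = "sim_classifier_profile")
}

#' Positive bias realizing a target positive-prediction rate
#'
#' Under the simulation model the expected positive-prediction rate of a
#' classifier is `r = bias + g * b_eff + (1 - g) * (1 - b_eff)` where `g`
#' is the gold positive ratio and `b_eff` the expected correctness
#' (`base_correctness - difficulty_sensitivity * E[delta]`). This inverts
#' that relation.
#'
#' @param target_r target positive rate as a fraction.
#' @param base_correctness,difficulty_sensitivity profile parameters.
#' @param gold_ratio gold positive ratio of the population.
#' @param delta_mean mean latent difficulty, default 0.5 (Beta(2,2)).
#' @return the `positive_bias` value.
#' @export
positive_bias_for_rate <- function(target_r, base_correctness,
                                   difficulty_sensitivity,
                                   gold_ratio = 0.25, delta_mean = 0.5) {
  b_eff <- base_correctness - difficulty_sensitivity * delta_mean
  target_r - (gold_ratio * b_eff + (1 - gold_ratio) * (1 - b_eff))
}

#' Expected positive-prediction rate of a simulated classifier
#'
#' Closed-form counterpart of [positive_bias_for_rate()], in percent;
#' serves as the oracle for the simulator's realized rates.
#'
#' @param profile a [sim_classifier_profile()].
#' @param gold_ratio gold positive ratio of the population.
#' @param pconfig a [sim_prediction_config()].
#' @param setting `"CV"` or `"CL"`.
#' @return expected rate in percent.
#' @export
expected_positive_rate <- function(profile, gold_ratio = 0.25,
                                   pconfig = sim_prediction_config(),
                                   setting = "CV") {
  b_eff <- expected_correctness(profile, pconfig, setting)
  100 * (profile$positive_bias + gold_ratio * b_eff +
           (1 - gold_ratio) * (1 - b_eff))
}

#' Default roster of 13 simulated classifiers in three families
#'
#' Mirrors the benchmark roster shape: four syntax-tree kernels, eight
#' dependency kernels and one shallow-feature classifier; the
#' cross-learning roster omits the slowest tree kernel (`PT`). Positive
#' biases are derived from per-classifier target positive rates at a 25%
#' gold ratio via [positive_bias_for_rate()].
#'
#' @param setting `"CV"` or `"CL"`.
#' @return list of [sim_classifier_profile()] objects.
#' @export
default_profiles <- function(setting = c("CV", "CL")) {
  setting <- match.arg(setting)
  spec <- list(                      #  id, family, b, lambda, target r
    list("ST",        "tree",    0.88, 0.40, 0.28),
    list("SST",       "tree",    0.89, 0.38, 0.27),
    list("PT",        "tree",    0.87, 0.42, 0.28),
    list("SpT",       "tree",    0.84, 0.46, 0.46),
    list("edit",      "dep",     0.91, 0.30, 0.18),
    list("cosine",    "dep",     0.89, 0.38, 0.25),
    list("kBSPS",     "dep",     0.90, 0.48, 0.37),
    list("APG",       "dep",     0.93, 0.34, 0.25),
    list("lexical",   "dep",     0.89, 0.36, 0.25),
    list("shallow",   "dep",     0.88, 0.40, 0.25),
    list("combined",  "dep",     0.89, 0.38, 0.25),
    list("syntactic", "dep",     0.89, 0.40, 0.24),
    list("SL",        "shallow", 0.92, 0.36, 0.30)
  )
  profs <- lapply(spec, function(s)
    sim_classifier_profile(
      s[[1]], s[[2]], s[[3]], s[[4]], family_coupling = 0.7,
      positive_bias = positive_bias_for_rate(s[[5]], s[[3]], s[[4]])))
  if (setting == "CL") {
    profs <- Filter(function(p) p$id != "PT", profs)
  }
  profs
}

#' Configuration for the prediction-matrix simulator
#'
#' @param delta_shape1,delta_shape2 Beta parameters of the per-pair latent
#'   difficulty.
#' @param tau standard deviation of the per-pair per-family shared error
#'   component.
#' @param cl_penalty correctness penalty applied in the cross-learning
#'   setting, default 0.12 (midpoint of the 10-15 percentage point
#'   cross-setting F-score gap the generator emulates).
#' @param difficulty_link `"latent"` draws difficulty independently from
#'   Beta(shape1, shape2); `"surface"` couples difficulty to sentence
#'   features (syntax-tree label entropy and sentence length) while keeping
#'   the same Beta marginal via a rank transform.
#' @param seed integer seed.
#' @return list of class `sim_prediction_config`.
#' @export
sim_prediction_config <- function(delta_shape1 = 2, delta_shape2 = 2,
                                  tau = 0.15, cl_penalty = 0.12,
                                  difficulty_link = c("latent", "surface"),
                                  seed = 1L) {
  difficulty_link <- match.arg(difficulty_link)
  stopifnot(cl_penalty >= 0, cl_penalty <= 1, tau >= 0)
  structure(list(delta_shape1 = delta_shape1, delta_shape2 = delta_shape2,
                 tau = tau, cl_penalty = cl_penalty,
                 difficulty_link = difficulty_link, seed = seed),
            class = "sim_prediction_config")
}

#' Generate a simulated prediction matrix
#'
#' For each pair p and classifier c the correctness probability is
#' `clamp(b_c - lambda_c * delta_p + rho_c * u_family(p) +/- positive_bias
#' - cl_penalty * [setting == CL], 0.02, 0.98)`; the prediction equals the
#' gold label with that probability and the flipped label otherwise.
#' Deterministic under the configured seed; the CL stream is seeded
#' independently of CV.
#'
#' @param corpus a [ppi_corpus()].
#' @param profiles non-empty list of [sim_classifier_profile()] objects.
#' @param pconfig a [sim_prediction_config()].
#' @param setting `"CV"` or `"CL"`.
#' @return a [prediction_set()].
#' @export
generate_predictions <- function(corpus, profiles,
                                 pconfig = sim_prediction_config(),
                                 setting = c("CV", "CL")) {
  setting <- match.arg(setting)
  if (!length(profiles)) stop("profiles must be non-empty")
  set.seed(pconfig$seed + if (setting == "CL") 1L else 0L)

  pt <- pairs_table(corpus)
  n <- nrow(pt)
  delta <- draw_difficulty(corpus, pt, pconfig)
  fams <- unique(vapply(profiles, `[[`, "", "family"))
  u <- matrix(stats::rnorm(n * length(fams), 0, pconfig$tau), nrow = n,
              dimnames = list(NULL, fams))

  roster <- vapply(profiles, `[[`, "", "id")
  m <- matrix(NA, nrow = n, ncol = length(roster),
              dimnames = list(pt$pair_id, roster))
  clpen <- if (setting == "CL") pconfig$cl_penalty else 0
  for (k in seq_along(profiles)) {
    pr <- profiles[[k]]
    # the bias term scales with difficulty (mean 1 under Beta(2,2)), so
    # easy positives stay classifiable while the rate expectation
    # r = bias + g*b_eff + (1-g)*(1-b_eff) is unchanged
    p_correct <- pr$base_correctness -
      pr$difficulty_sensitivity * delta +
      pr$family_coupling * u[, pr$family] +
      pr$positive_bias * (0.5 + delta) * ifelse(pt$gold, 1, -1) -
      clpen
    p_correct <- pmin(pmax(p_correct, 0.02), 0.98)
    correct <- stats::runif(n) < p_correct
    m[, k] <- ifelse(correct, pt$gold, !pt$gold)
  }
  prediction_set(m, setting)
}

draw_difficulty <- function(corpus, pt, pconfig) {
  n <- nrow(pt)
  if (pconfig$difficulty_link == "latent") {
    return(stats::rbeta(n, pconfig$delta_shape1, pconfig$delta_shape2))
  }
  # surface-linked: low difficulty (easy) for pairs in sentences with high
  # constituent-label entropy and longer sentences; Beta marginal preserved
  # through a rank -> quantile transform.
  sent_map <- new.env(parent = emptyenv())
  for (d in corpus$documents) for (s in d$sentences) {
    ent <- if (!is.null(s$tree)) {
      labs <- tree_labels(s$tree)
      entropy_bits(table(labs))
    } else 0
    len <- if (!is.null(s$tokens)) nrow(s$tokens) else
      length(strsplit(s$text, " ", fixed = TRUE)[[1]])
    assign(s$id, c(ent, len), envir = sent_map)
  }
  feats <- t(vapply(pt$sentence_id, function(id) get(id, envir = sent_map),
                    numeric(2)))
  score <- -(scale_safe(feats[, 1]) + 0.3 * scale_safe(feats[, 2])) +
    stats::rnorm(n, 0, 0.5)
  stats::qbeta(rank(score, ties.method = "first") / (n + 1),
               pconfig$delta_shape1, pconfig$delta_shape2)
}

scale_safe <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

tree_labels <- function(tree) {
  if (!is.null(tree$token)) return(character())
  c(tree$label, unlist(lapply(tree$children, tree_labels)))
}

#' Expected correctness of a simulated classifier
#'
#' Closed-form expectation of the correctness probability under the
#' simulation model (difficulty integrated over its Beta distribution,
#' family effect over its zero-mean normal), before clamping. Used as an
#' oracle for the simulator in tests.
#'
#' @param profile a [sim_classifier_profile()].
#' @param pconfig a [sim_prediction_config()].
#' @param setting `"CV"` or `"CL"`.
#' @param delta fixed difficulty; default integrates over the Beta mean.
#' @return expected correctness probability.
#' @export
expected_correctness <- function(profile, pconfig = sim_prediction_config(),
                                 setting = "CV", delta = NULL) {
  dmean <- if (is.null(delta)) {
    pconfig$delta_shape1 / (pconfig$delta_shape1 + pconfig$delta_shape2)
  } else delta
  profile$base_correctness - profile$difficulty_sensitivity * dmean -
    (setting == "CL") * pconfig$cl_penalty
}

# ---- benchmark suite ------------------------------------------------------

BENCHMARK_SIZES <- c(AIMed = 5834, BioInfer = 9666, HPRD50 = 433,
                     IEPA = 817, LLL = 330)
BENCHMARK_RATIOS <- c(AIMed = 0.171, BioInfer = 0.262, HPRD50 = 0.376,
                      IEPA = 0.410, LLL = 0.497)

#' Generate the five-corpus benchmark suite with CV and CL predictions
#'
#' Emulates the shape of the five standard PPI benchmarks: pair counts
#' 5834/9666/433/817/330 (scaled by `size_factor`) with gold positive
#' ratios 17.1/26.2/37.6/41.0/49.7 percent, a 13-classifier CV roster and a
#' 12-classifier CL roster in three representation families.
#'
#' @param seed integer seed.
#' @param size_factor multiplier on the per-corpus pair counts.
#' @param difficulty_link passed to [sim_prediction_config()].
#' @return list with `corpora` (named list of [ppi_corpus()]),
#'   `predictions_cv` and `predictions_cl` ([prediction_set()] objects over
#'   the pooled pairs of all five corpora), and `folds` (named integer
#'   vector of document-level fold indices).
#' @export
generate_benchmark_suite <- function(seed = 1L, size_factor = 1,
                                     difficulty_link = "latent") {
  corpora <- list()
  for (i in seq_along(BENCHMARK_SIZES)) {
    nm <- names(BENCHMARK_SIZES)[i]
    cfg <- sim_corpus_config(
      name = nm,
      target_pairs = max(2L, round(BENCHMARK_SIZES[[i]] * size_factor)),
      target_positive_ratio = BENCHMARK_RATIOS[[i]],
      seed = seed + i
    )
    corpora[[nm]] <- generate_corpus(cfg)
  }
  pcfg_cv <- sim_prediction_config(seed = seed + 101L,
                                   difficulty_link = difficulty_link)
  pcfg_cl <- sim_prediction_config(seed = seed + 101L,
                                   difficulty_link = difficulty_link)
  cv <- lapply(corpora, generate_predictions, profiles = default_profiles("CV"),
               pconfig = pcfg_cv, setting = "CV")
  cl <- lapply(corpora, generate_predictions, profiles = default_profiles("CL"),
               pconfig = pcfg_cl, setting = "CL")
  folds <- assign_folds(corpora, seed = seed + 202L)
  list(
    corpora = corpora,
    predictions_cv = prediction_set(do.call(rbind, lapply(cv, `[[`, "table")),
                                    "CV"),
    predictions_cl = prediction_set(do.call(rbind, lapply(cl, `[[`, "table")),
                                    "CL"),
    folds = folds
  )
}

#' Assign documents to 10 folds
#'
#' @param corpora list of [ppi_corpus()] objects.
#' @param seed integer seed.
#' @return named integer vector document id -> fold in 0..9.
#' @export
assign_folds <- function(corpora, seed = 1L) {
  if (inherits(corpora, "ppi_corpus")) corpora <- list(corpora)
  set.seed(seed)
  ids <- unlist(lapply(corpora, function(corp)
    vapply(corp$documents, `[[`, "", "id")))
  stats::setNames(sample(rep(0:9, length.out = length(ids))), ids)
}
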