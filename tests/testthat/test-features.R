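# Tokenization with entity blinding, surface/parse features, aggregates.

test_that("tokenize blinds entities and partitions non-space characters", {
  s <- parsed_sentence()
  toks <- tokenize(s, "SimP.d0.s0.p0")
  expect_equal(toks$token, c("ENT1", "binds", "ENT2"))
  expect_equal(toks$raw, c("ProtA", "binds", "ProtB"))

  # punctuation splits off; entity-free text tokenizes plainly
  s2 <- ppi_sentence("SimP.d1.s0", "No binding, none.",
                     entities = data.frame(id = character(), start = integer(),
                                           end = integer(), text = character(),
                                           type = character()),
                     pairs = data.frame(id = character(), e1 = character(),
                                        e2 = character(), gold = logical()))
  t2 <- tokenize(s2)
  expect_equal(t2$token, c("No", "binding", ",", "none", "."))
  # token spans cover exactly the non-space characters
  covered <- unlist(mapply(seq, t2$start + 1, t2$end, SIMPLIFY = FALSE))
  chars <- strsplit(s2$text, "")[[1]]
  expect_setequal(covered, which(chars != " "))

  # overlapping entity spans are rejected
  s3 <- tiny_corpus()$documents[[1]]$sentences[[1]]
  s3$entities$start <- c(0L, 3L); s3$entities$end <- c(5L, 8L)
  s3$entities$text <- c("ProtA", "tA bi")
  expect_error(tokenize(s3), "overlapping")
})

test_that("surface features follow the s/b/w/a scope definitions", {
  s <- parsed_sentence()
  fv <- surface_features(s, "SimP.d0.s0.p0")
  expect_equal(fv$entity_word_distance, 1L)
  expect_equal(fv$interaction_w, 1L)   # "binds" strictly between
  expect_equal(fv$interaction_s, 1L)
  expect_equal(fv$interaction_b, 0L)
  expect_equal(fv$n_proteins, 2L)
  expect_equal(fv$sentence_length_word, 3L)
  expect_equal(fv$sentence_length_char, nchar(s$text))
  expect_equal(fv$comma_between, 0L)

  # comma strictly between vs outside; -ing after first entity
  text <- "x , ProtA interacting ProtB ,"
  s2 <- ppi_sentence(
    "SimP.d2.s0", text,
    entities = data.frame(id = c("SimP.d2.s0.e0", "SimP.d2.s0.e1"),
                          start = c(4L, 22L), end = c(9L, 27L),
                          text = c("ProtA", "ProtB"), type = "protein",
                          stringsAsFactors = FALSE),
    pairs = data.frame(id = "SimP.d2.s0.p0", e1 = "SimP.d2.s0.e0",
                       e2 = "SimP.d2.s0.e1", gold = TRUE,
                       stringsAsFactors = FALSE))
  fv2 <- surface_features(s2, "SimP.d2.s0.p0")
  expect_equal(fv2$comma_between, 0L)    # commas are before/after only
  expect_equal(fv2$ing_after_e1, 1L)

  # no lexicon hits -> all clue flags zero
  lex0 <- structure(list(interaction = "zzz", negation = "zzz", hedge = "zzz"),
                    class = "ppi_lexicons")
  fv3 <- surface_features(s, "SimP.d0.s0.p0", lex0)
  clue <- grep("^(interaction|negation|hedge)_", names(fv3), value = TRUE)
  expect_true(all(unlist(fv3[clue]) == 0))
})

test_that("dependency features use the shortest path and Shannon entropy", {
  s <- parsed_sentence()
  fv <- dg_features(s, "SimP.d0.s0.p0")
  expect_equal(fv$dg_path_length, 2L)
  expect_equal(fv$dgp_freq_nsubj, 0.5)
  expect_equal(fv$dgp_freq_dobj, 0.5)
  expect_equal(fv$dg_path_entropy, 1)      # two equiprobable labels: 1 bit
  expect_equal(fv$dg_entropy, 1)

  # single-label graph has zero entropy
  s1 <- parsed_sentence()
  s1$deps$label <- "dep"
  expect_equal(dg_features(s1, "SimP.d0.s0.p0")$dg_entropy, 0)

  # disconnected entities flag path features absent
  s2 <- parsed_sentence()
  s2$deps <- s2$deps[1, , drop = FALSE]    # drop the edge to ENT2
  fv2 <- dg_features(s2, "SimP.d0.s0.p0")
  expect_equal(fv2$dg_connected, 0L)
  expect_true(is.na(fv2$dg_path_length))
})

test_that("dependency shortest path matches brute-force enumeration on random graphs", {
  # oracle: exhaustive path enumeration by adjacency-matrix powers
  brute_shortest <- function(deps, n, from, to) {
    adj <- matrix(FALSE, n, n)
    adj[cbind(deps$from + 1, deps$to + 1)] <- TRUE
    adj <- adj | t(adj)
    if (from == to) return(0)
    reach <- adj
    for (len in 1:(n - 1)) {
      if (reach[from + 1, to + 1]) return(len)
      reach <- (reach %*% adj) > 0
    }
    NA_integer_
  }
  for (seed in 1:8) {
    set.seed(seed)
    n <- 12
    deps <- unique(data.frame(
      from = sample(0:(n - 1), 16, replace = TRUE),
      to = sample(0:(n - 1), 16, replace = TRUE)))
    deps <- deps[deps$from != deps$to, ]
    deps$label <- sample(c("nsubj", "dobj", "nn"), nrow(deps), replace = TRUE)
    toks <- data.frame(index = 0:(n - 1),
                       text = sprintf("t%02d", 1:n), pos = "NN",
                       start = (0:(n - 1)) * 4L, end = (0:(n - 1)) * 4L + 3L)
    sent <- ppi_sentence(
      "SimG.d0.s0", paste(toks$text, collapse = " "),
      entities = data.frame(id = c("SimG.d0.s0.e0", "SimG.d0.s0.e1"),
                            start = c(0L, (n - 1L) * 4L),
                            end = c(3L, (n - 1L) * 4L + 3L),
                            text = c(toks$text[1], toks$text[n]),
                            type = "protein",
                            stringsAsFactors = FALSE),
      pairs = data.frame(id = "SimG.d0.s0.p0", e1 = "SimG.d0.s0.e0",
                         e2 = "SimG.d0.s0.e1", gold = TRUE,
                         stringsAsFactors = FALSE),
      tokens = toks, deps = deps)
    fv <- dg_features(sent, "SimG.d0.s0.p0")
    oracle <- brute_shortest(deps, n, 0L, n - 1L)
    if (is.na(oracle)) {
      expect_equal(fv$dg_connected, 0L)
    } else {
      expect_equal(fv$dg_path_length, oracle)
    }
  }
})

test_that("syntax-tree path goes through the lowest common ancestor", {
  s <- parsed_sentence()
  fv <- st_features(s, "SimP.d0.s0.p0")
  # ENT1 under NP (depth 2), ENT2 under VP (depth 2): path length 4
  expect_equal(fv$st_path_length, 4L)
  expect_gte(fv$st_entropy, 0)

  # both entities under one parent -> path length 2
  s2 <- parsed_sentence()
  s2$tree <- list(label = "S", children = list(
    list(label = "NP", children = list(list(token = 0L), list(token = 1L),
                                       list(token = 2L)))))
  expect_equal(st_features(s2, "SimP.d0.s0.p0")$st_path_length, 2L)

  # balanced depth-3 tree, entities at opposite ends -> path length 6
  leaf <- function(i) list(token = i)
  s3 <- parsed_sentence()
  s3$tokens <- data.frame(index = 0:7, text = c("ProtA", sprintf("w%d", 1:6),
                                                "ProtB"),
                          pos = "NN", start = 0:7 * 6L, end = 0:7 * 6L + 5L)
  s3$text <- paste(sprintf("%-5s", s3$tokens$text), collapse = " ")
  s3$text <- gsub("\\s+$", "", s3$text)
  s3$tokens$end <- s3$tokens$start + nchar(s3$tokens$text)
  s3$entities <- data.frame(
    id = c("SimP.d0.s0.e0", "SimP.d0.s0.e1"),
    start = c(0L, 42L), end = c(5L, 47L),
    text = c("ProtA", "ProtB"), type = "protein", stringsAsFactors = FALSE)
  s3$deps <- NULL
  pair2 <- function(a, b) list(label = "X", children = list(leaf(a), leaf(b)))
  s3$tree <- list(label = "S", children = list(
    list(label = "L", children = list(pair2(0L, 1L), pair2(2L, 3L))),
    list(label = "R", children = list(pair2(4L, 5L), pair2(6L, 7L)))))
  expect_equal(st_features(s3, "SimP.d0.s0.p0")$st_path_length, 6L)

  # single-label tree has zero whole-tree entropy
  s4 <- parsed_sentence()
  s4$tree <- list(label = "X", children = list(
    list(label = "X", children = list(list(token = 0L), list(token = 1L))),
    list(label = "X", children = list(list(token = 2L)))))
  expect_equal(st_features(s4, "SimP.d0.s0.p0")$st_entropy, 0)
})

test_that("feature_table is rectangular, pure, and flags absent layers", {
  corp <- generate_corpus(sim_corpus_config(n_documents = 15, seed = 44))
  ft <- feature_table(corp)
  expect_equal(nrow(ft), corpus_stats(corp)$pairs)
  expect_identical(feature_table(corp), ft)      # purity under same input

  # frequency distributions sum to one (or are absent)
  for (prefix in c("dg_freq_", "dgp_freq_", "st_freq_", "stp_freq_")) {
    cols <- grep(paste0("^", prefix), names(ft), value = TRUE)
    sums <- rowSums(ft[cols], na.rm = TRUE)
    present <- !apply(is.na(ft[cols]), 1, all)
    expect_true(all(abs(sums[present] - 1) < 1e-9))
  }
  # connected distinct entities have path length >= 1
  ok <- !is.na(ft$dg_path_length)
  expect_true(all(ft$dg_path_length[ok] >= 1))

  # removing the dependency layer flags DG features absent, surface intact
  corp2 <- corp
  for (i in seq_along(corp2$documents)) {
    for (j in seq_along(corp2$documents[[i]]$sentences)) {
      corp2$documents[[i]]$sentences[[j]]$deps <- NULL
    }
  }
  ft2 <- feature_table(corp2)
  expect_true(all(ft2$has_dg == 0))
  expect_true(all(is.na(ft2$dg_entropy)))
  expect_equal(ft2$sentence_length_word, ft$sentence_length_word)

  # sentence_length_char equals an independent character count
  one <- corp$documents[[1]]$sentences[[1]]
  expect_equal(ft$sentence_length_char[ft$sentence_id == one$id][1],
               nchar(one$text))
})

test_that("kl entropy mode measures divergence from the corpus background", {
  corp <- generate_corpus(sim_corpus_config(n_documents = 10, seed = 45))
  ft_sh <- feature_table(corp)
  ft_kl <- feature_table(corp, entropy_mode = "kl")
  expect_false(isTRUE(all.equal(ft_sh$dg_entropy, ft_kl$dg_entropy)))
  expect_true(all(ft_kl$dg_entropy >= -1e-9, na.rm = TRUE))
  # kl of the background against itself is zero
  expect_equal(kl_divergence_bits(c(a = 2, b = 2), c(a = 50, b = 50)), 0)
})

test_that("class-conditional aggregates recover the generator's configured means", {
  cfg <- sim_corpus_config(target_pairs = 2200, target_positive_ratio = 0.25,
                           seed = 61)
  corp <- generate_corpus(cfg)
  ft <- feature_table(corp)
  # with every pair neutral, the six-class table collapses to PN/NN
  classes <- data.frame(pair_id = ft$pair_id, class = "N",
                        stringsAsFactors = FALSE)
  agg <- aggregate_by_difficulty(ft, classes)
  expect_equal(agg$class, c("ND", "NN", "NE", "PD", "PN", "PE"))
  expect_equal(agg$n[agg$class == "ND"], 0)
  pn <- agg[agg$class == "PN", ]; nn <- agg[agg$class == "NN", ]
  expect_lt(abs(pn$sentence_length_word - 27.6), 1)
  expect_lt(abs(nn$sentence_length_word - 37.2), 1)
  expect_lt(abs(pn$entity_word_distance - 7.15), 0.5)
  expect_lt(abs(nn$entity_word_distance - 9.67), 0.5)
  # all-identical pairs give equal class means
  ft_id <- ft[rep(1, 10), ]
  cls_id <- data.frame(pair_id = ft_id$pair_id,
                       class = rep(c("D", "N", "E"), length.out = 10))
  agg_id <- aggregate_by_difficulty(ft_id, cls_id[!duplicated(cls_id$pair_id), ])
  got <- agg_id$sentence_length_word[agg_id$n > 0]
  expect_true(all(got == got[1]))
})

test_that("positive rate decays across sentence-length bins and counts are conserved", {
  cfg <- sim_corpus_config(target_pairs = 2200, target_positive_ratio = 0.3,
                           seed = 62)
  corp <- generate_corpus(cfg)
  tab <- positive_rate_by_length(corp)
  expect_equal(sum(tab$n_pairs), corpus_stats(corp)$pairs)
  rates <- tab$rate[!is.na(tab$rate) & tab$n_pairs >= 30]
  # monotone decreasing trend (generator expectation: positives live in
  # short sentences)
  expect_true(all(diff(rates) <= 0.02))
  expect_gt(rates[1], rates[length(rates)])

  tab2 <- class_dist_by_protein_count(corp)
  expect_equal(sum(tab2$n_pairs), corpus_stats(corp)$pairs)
  expect_equal(tab2$n_positive + tab2$n_negative, tab2$n_pairs)
  # more mentions, lower positive rate
  expect_gt(tab2$positive_rate[1], tab2$positive_rate[nrow(tab2)])
  expect_error(positive_rate_by_length(ppi_corpus("E")), "empty")
})
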