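# End-to-end orchestration: simulation to disk, and the full report
# bundle (difficulty, strata, agreement, features, information gain,
# difficulty model, ensembles) with a reproducibility manifest.

#' Write a simulated benchmark suite to disk
#'
#' Emits five corpus XML files, pooled CV/CL prediction TSVs, a
#' document-level fold TSV and the simulation configuration as YAML; the
#' files are directly consumable by [run_report()].
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param size_factor multiplier on the benchmark pair counts.
#' @param difficulty_link see [sim_prediction_config()].
#' @return invisibly, the list of written paths.
#' @export
simulate_suite <- function(out_dir, seed = 1L, size_factor = 0.1,
                           difficulty_link = "latent") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  suite <- generate_benchmark_suite(seed, size_factor, difficulty_link)
  paths <- character()
  for (nm in names(suite$corpora)) {
    p <- file.path(out_dir, paste0(nm, ".xml"))
    write_unified_corpus(suite$corpora[[nm]], p)
    paths <- c(paths, p)
  }
  pcv <- file.path(out_dir, "predictions_cv.tsv")
  pcl <- file.path(out_dir, "predictions_cl.tsv")
  write_predictions(suite$predictions_cv, pcv)
  write_predictions(suite$predictions_cl, pcl)
  pfold <- file.path(out_dir, "folds.tsv")
  write_folds(suite$folds, pfold)
  cfg <- file.path(out_dir, "simulation.yaml")
  yaml::write_yaml(list(seed = seed, size_factor = size_factor,
                        difficulty_link = difficulty_link,
                        corpora = names(suite$corpora)), cfg)
  invisible(c(paths, pcv, pcl, pfold, cfg))
}

write_table_with_json <- function(df, out_dir, stem) {
  tsv <- file.path(out_dir, paste0(stem, ".tsv"))
  jsn <- file.path(out_dir, paste0(stem, ".json"))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(df, jsn, dataframe = "rows", digits = NA,
                       pretty = TRUE, na = "null")
  c(tsv, jsn)
}

#' Run the full instance-level analysis and write a report bundle
#'
#' Orchestrates the whole pipeline on a corpus collection with CV and CL
#' prediction sets: success-level histograms, difficulty stratification
#' with overlap tests, CV-vs-CL success crosstab, per-stratum
#' observed-vs-expected tables, agreement matrix with Newick dendrogram,
#' the feature table with top-k information-gain ranking, the
#' difficulty-model report, the majority-vote ensemble report, and a
#' manifest with the configuration hash and seeds. Every table is written
#' as TSV with a JSON twin carrying identical numbers.
#'
#' @param corpora named list of [ppi_corpus()] objects, or a directory
#'   containing `<name>.xml` corpus files plus `predictions_cv.tsv` /
#'   `predictions_cl.tsv` (as written by [simulate_suite()]).
#' @param predictions_cv,predictions_cl [prediction_set()] objects (ignored
#'   when `corpora` is a directory).
#' @param out_dir output directory.
#' @param fraction difficulty cutoff fraction, default 0.10.
#' @param committee classifier ids for the majority-vote ensemble.
#' @param linkage clustering linkage, see [cluster_classifiers()].
#' @param top_k number of ranked features reported per class.
#' @param seed integer seed (difficulty-model folds).
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_report <- function(corpora, predictions_cv = NULL, predictions_cl = NULL,
                       out_dir, fraction = 0.10,
                       committee = c("APG", "SL", "kBSPS"),
                       linkage = "complete", top_k = 10, seed = 1L) {
  if (is.character(corpora) && length(corpora) == 1) {
    dir_in <- corpora
    xmls <- sort(list.files(dir_in, pattern = "\\.xml$", full.names = TRUE))
    corpora <- lapply(xmls, parse_unified_corpus)
    names(corpora) <- vapply(corpora, `[[`, "", "name")
    predictions_cv <- read_predictions(file.path(dir_in, "predictions_cv.tsv"))
    predictions_cl <- read_predictions(file.path(dir_in, "predictions_cl.tsv"))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", label, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  gold_all <- gold_labels(corpora)

  # success histograms (per corpus, both settings)
  hists <- stage("success-levels", {
    rows <- list()
    for (nm in names(corpora)) {
      g <- gold_labels(corpora[[nm]])
      for (ps in list(predictions_cv, predictions_cl)) {
        st <- compute_success_levels(g, ps)
        h <- success_histogram(st)
        rows[[paste(nm, ps$setting)]] <- data.frame(
          corpus = nm, setting = ps$setting,
          level = as.integer(names(h)), total = as.integer(h),
          positive = as.integer(success_histogram(
            st$levels[g], length(st$roster))),
          negative = as.integer(success_histogram(
            st$levels[!g], length(st$roster))),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
  written <- c(written, write_table_with_json(hists, out_dir,
                                              "success_histograms"))

  # difficulty stratification + overlaps
  strat <- stage("difficulty", stratify_difficulty(
    corpora, predictions_cv, predictions_cl, fraction))
  written <- c(written,
               write_table_with_json(strat$classes, out_dir,
                                     "difficulty_classes"),
               write_table_with_json(strat$overlaps, out_dir,
                                     "difficulty_overlap"))

  # CV vs CL success crosstab (pooled)
  xtab <- stage("crosstab", {
    scv <- compute_success_levels(gold_all, predictions_cv)
    scl <- compute_success_levels(gold_all, predictions_cl)
    crosstab_cv_cl(scv, scl)
  })
  xdf <- as.data.frame(as.table(xtab), stringsAsFactors = FALSE)
  names(xdf) <- c("cv_level", "cl_level", "pairs")
  written <- c(written, write_table_with_json(xdf, out_dir, "crosstab_cv_cl"))

  # stratum reports for the four signed classes, both settings
  strata <- stage("strata", {
    cls <- strat$classes
    rows <- list()
    for (sub in c("ND", "PD", "NE", "PE")) {
      ids <- cls$pair_id[cls$subclass == sub]
      if (!length(ids)) next
      pol <- if (startsWith(sub, "N")) "negative" else "positive"
      for (ps in list(predictions_cv, predictions_cl)) {
        tb <- stratum_table(ps, gold_all, ids, pol, sub)
        tb$setting <- ps$setting
        rows[[paste(sub, ps$setting)]] <- tb
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
  written <- c(written, write_table_with_json(strata, out_dir,
                                              "stratum_reports"))

  # agreement + dendrogram (CV setting)
  amat <- stage("agreement", agreement_matrix(predictions_cv))
  adf <- as.data.frame(as.table(amat), stringsAsFactors = FALSE)
  names(adf) <- c("classifier_1", "classifier_2", "agreement")
  written <- c(written, write_table_with_json(adf, out_dir,
                                              "agreement_matrix"))
  nwk <- stage("clustering",
               to_newick(cluster_classifiers(amat, linkage)))
  nwk_path <- file.path(out_dir, "dendrogram.nwk")
  writeLines(nwk, nwk_path)
  written <- c(written, nwk_path)

  # features + information gain
  ft <- stage("features", feature_table(corpora))
  written <- c(written, write_table_with_json(ft, out_dir, "feature_table"))
  ig <- stage("infogain", {
    cls_map <- stats::setNames(strat$classes$class, strat$classes$pair_id)
    rows <- list()
    for (k in c("D", "E")) {
      rk <- rank_features(ft, cls_map[ft$pair_id] == k, top_k)
      if (nrow(rk)) rk$class <- k
      rows[[k]] <- rk
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
  written <- c(written, write_table_with_json(ig, out_dir,
                                              "information_gain"))

  # difficulty model
  dm <- stage("difficulty-model", {
    rep_ <- evaluate_difficulty_model(ft, strat$classes, mode = "cv",
                                      seed = seed)
    per <- rep_$per_class
    per <- rbind(per, data.frame(class = "Total", P = rep_$total$P,
                                 R = rep_$total$R, F = rep_$total$F,
                                 support = sum(per$support)))
    per
  })
  written <- c(written, write_table_with_json(dm, out_dir,
                                              "difficulty_model"))

  # ensembles
  ens <- stage("ensemble", {
    committee_ok <- intersect(committee, predictions_cv$roster)
    votes <- majority_vote(predictions_cv, committee_ok)
    ee <- ensemble_eval(votes, gold_all)
    ee$combination <- paste(committee_ok, collapse = "+")
    ee
  })
  written <- c(written, write_table_with_json(ens, out_dir, "ensemble"))

  manifest <- stage("manifest", {
    cfg <- list(fraction = fraction, committee = committee,
                linkage = linkage, top_k = top_k, seed = seed,
                corpora = names(corpora),
                setting_rosters = list(CV = predictions_cv$roster,
                                       CL = predictions_cl$roster))
    cfg_file <- tempfile()
    writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE), cfg_file)
    list(tool = "ppidiag",
         version = as.character(utils::packageVersion("ppidiag")),
         config = cfg,
         config_md5 = unname(tools::md5sum(cfg_file)),
         output_md5 = {
           md5 <- tools::md5sum(sort(written))
           stats::setNames(as.list(unname(md5)), basename(names(md5)))
         })
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(histograms = hists, stratification = strat,
                 crosstab = xtab, strata = strata, agreement = amat,
                 newick = nwk, features = ft, infogain = ig,
                 difficulty_model = dm, ensemble = ens,
                 manifest = manifest))
}
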