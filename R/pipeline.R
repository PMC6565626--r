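#' @title End-to-end pipeline
#' @description Orchestrate preprocess -> embeddings -> density -> latent
#'   content -> prediction as reproducible runs with config hashing, stage
#'   logging, and a POS-shuffle control.
#' @name pipeline
NULL

#' Assemble a run configuration
#'
#' Inputs may be in-memory objects (utterance table / embedding space /
#' baseline document vector / named label vector) or file paths to the
#' corresponding text formats. All module parameters live here so a run is
#' fully determined by `(config, seed)`.
#'
#' @param transcripts utterance data.frame or transcript file path.
#' @param embeddings `embedding_space` or word2vec text file path.
#' @param baseline character vector of baseline documents or file path.
#' @param labels named 0/1 vector (participant -> outcome) or 2-column file.
#' @param holdout optional list with `transcripts` and `labels` for transfer
#'   evaluation.
#' @param unpacking an [unpacking_config()].
#' @param coverage probe-vocabulary cumulative frequency coverage.
#' @param topk contrast probes retained for clustering.
#' @param k_range candidate cluster counts.
#' @param concept_keys optional explicit concept-cluster keys; default: the
#'   cluster containing the top-weighted probe.
#' @param threshold classification probability cutoff.
#' @param speaker which speaker's sentences to analyze.
#' @param tagger tagger backend (default: dictionary backend over the
#'   embedding vocabulary, falling back to the rule tagger for unknown keys).
#' @param max_len maximum sentence length in tokens.
#' @param shuffle_scope `"participant"` (default) or `"cohort"`: whether the
#'   POS shuffle permutes words within each transcript or across the cohort.
#' @param seed integer seed for every stochastic stage.
#' @param out_dir optional output directory; when given, stage tables are
#'   written as UTF-8 delimited text stamped with the config hash.
#' @export
run_config <- function(transcripts, embeddings, baseline = NULL, labels = NULL,
                       holdout = NULL, unpacking = unpacking_config(),
                       coverage = 0.95, topk = 50, k_range = 2:10,
                       concept_keys = NULL, threshold = 0.5,
                       speaker = "participant", tagger = NULL, max_len = 60,
                       shuffle_scope = c("participant", "cohort"),
                       seed = 1L, out_dir = NULL) {
  structure(list(transcripts = transcripts, embeddings = embeddings,
                 baseline = baseline, labels = labels, holdout = holdout,
                 unpacking = unpacking, coverage = coverage, topk = topk,
                 k_range = k_range, concept_keys = concept_keys,
                 threshold = threshold, speaker = speaker, tagger = tagger,
                 max_len = max_len,
                 shuffle_scope = match.arg(shuffle_scope),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  drop_objects <- config[setdiff(names(config), c("tagger", "out_dir"))]
  txt <- paste(utils::capture.output(utils::str(drop_objects, digits.d = 10)),
               collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

resolve_inputs <- function(config) {
  utt <- config$transcripts
  if (is.character(utt)) utt <- read_transcripts(utt)
  space <- config$embeddings
  if (is.character(space)) space <- read_word2vec(space)
  labels <- config$labels
  if (is.character(labels)) {
    tab <- read.delim(labels, stringsAsFactors = FALSE)
    labels <- setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
  }
  baseline <- config$baseline
  if (is.character(baseline) && length(baseline) == 1 && file.exists(baseline))
    baseline <- readLines(baseline, warn = FALSE)
  list(utterances = utt, space = space, labels = labels, baseline = baseline)
}

stamp_write <- function(tab, path, hash, seed) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash, " seed: ", seed), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

density_stage <- function(content, space, config) {
  rows <- lapply(names(content), function(id) {
    pd <- participant_density(content[[id]], space, config$unpacking, id)
    cbind(participant_id = id, pd$details)
  })
  per_sentence <- do.call(rbind, rows)
  per_participant <- aggregate(density ~ participant_id, per_sentence, mean)
  names(per_participant)[2] <- "mean_density"
  per_participant$sentence_count <-
    aggregate(density ~ participant_id, per_sentence, length)$density
  list(per_sentence = per_sentence, per_participant = per_participant)
}

sentence_vectors_stage <- function(content, space) {
  lapply(content, function(tr) {
    vs <- lapply(tr, function(s)
      suppressWarnings(compose_sentence_vector(s, space)))
    vs[!vapply(vs, is.null, logical(1))]
  })
}

latent_stage <- function(content, baseline_content, space, labels, config) {
  probes <- probe_vocabulary(space, config$coverage)
  svecs <- sentence_vectors_stage(content, space)
  svecs <- svecs[lengths(svecs) > 0]
  profiles <- lapply(names(svecs), function(id)
    probe_profile(probes, svecs[[id]], space, id))
  names(profiles) <- names(svecs)
  pos_ids <- names(labels)[labels == 1]
  grp <- group_profile(profiles[intersect(names(profiles), pos_ids)],
                       "positive")
  base_vecs <- lapply(baseline_content, function(doc) {
    vs <- lapply(doc, function(s)
      suppressWarnings(compose_sentence_vector(s, space)))
    vs[!vapply(vs, is.null, logical(1))]
  })
  base_vecs <- base_vecs[lengths(base_vecs) > 0]
  base_profiles <- lapply(base_vecs, function(v)
    probe_profile(probes, v, space, "baseline-doc"))
  base <- group_profile(base_profiles, "baseline")
  cm <- contrast_weight(grp, base)
  top <- top_probes(cm, config$topk)
  sol <- if (length(top) >= 3)
    cluster_probes(top, space, config$k_range, seed = config$seed) else NULL
  keys <- config$concept_keys
  if (is.null(keys)) {
    if (!length(top)) stop("latent stage: no positively weighted probes")
    keys <- if (is.null(sol)) top else
      names(sol$labels)[sol$labels == sol$labels[[top[1]]]]
  }
  cv <- concept_vector(keys, space)
  pred <- vapply(svecs, function(v) concept_predictor(cv, v), numeric(1))
  list(contrast = cm, top = top, clusters = sol, concept = cv,
       predictor = pred, profiles = profiles)
}

fit_stage <- function(density_tab, concept_pred, labels, threshold) {
  ids <- density_tab$participant_id
  feats <- data.frame(density = density_tab$mean_density,
                      voices = concept_pred[ids], row.names = ids)
  y <- labels[ids]
  m_density <- fit_logistic(feats["density"], y)
  m_voices <- fit_logistic(feats["voices"], y)
  m_both <- fit_logistic(feats, y)
  metrics <- lapply(list(density = m_density, voices = m_voices,
                         combined = m_both),
                    function(m) {
                      f <- feats[m$predictor_names]
                      evaluate_transfer(m, f, y, threshold)
                    })
  list(features = feats, labels = y,
       models = list(density = m_density, voices = m_voices,
                     combined = m_both),
       training_metrics = metrics)
}

#' Run the full analysis pipeline
#'
#' Preprocess transcripts, compute per-participant semantic density and the
#' concept predictor, fit the single- and two-predictor logistic models, and
#' evaluate training (and optional holdout) metrics. Stage failures abort
#' with the stage name; every written artifact carries the config hash and
#' seed. Deterministic given `(config, seed)`.
#'
#' @param config a [run_config()].
#' @return list of class `run_report`: `density` (per-sentence and
#'   per-participant tables), `latent` (contrast matrix, top probes, cluster
#'   solution, concept predictor), `models`, `wald`, `boundaries`,
#'   `training_metrics`, `holdout_metrics` (if holdout given), `config_hash`,
#'   `seed`, `log`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  log <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  inp <- stage("inputs", resolve_inputs(config))
  if (is.null(inp$space)) stop("pipeline stage 'embeddings' failed: no embeddings")
  tagger <- config$tagger %||% dictionary_tagger(inp$space)

  prep <- stage("preprocess",
                preprocess_transcripts(inp$utterances, config$speaker, tagger,
                                       config$max_len))
  log <- c(log, sprintf("preprocess: %d participants, %d sentences dropped (backend %s)",
                        length(prep$content), prep$dropped, prep$backend))
  dens <- stage("density", density_stage(prep$content, inp$space, config))
  log <- c(log, sprintf("density: %d sentences analyzed", nrow(dens$per_sentence)))

  latent <- NULL
  if (!is.null(inp$baseline)) {
    bcontent <- stage("baseline",
                      baseline_sentences(inp$baseline, inp$space, tagger))
    latent <- stage("latent",
                    latent_stage(prep$content, bcontent, inp$space,
                                 inp$labels, config))
    log <- c(log, sprintf("latent: %d probes, %d retained, concept of %d keys",
                          nrow(latent$contrast), length(latent$top),
                          length(latent$concept$member_keys)))
  }

  fits <- wald <- boundaries <- holdout_metrics <- NULL
  if (!is.null(inp$labels)) {
    if (!is.null(latent)) {
      fits <- stage("predict",
                    fit_stage(dens$per_participant, latent$predictor,
                              inp$labels, config$threshold))
    } else {
      ids <- dens$per_participant$participant_id
      m <- stage("predict",
                 fit_logistic(data.frame(density = dens$per_participant$mean_density),
                              inp$labels[ids]))
      f <- data.frame(density = dens$per_participant$mean_density)
      fits <- list(features = f, labels = inp$labels[ids],
                   models = list(density = m),
                   training_metrics = list(density =
                     evaluate_transfer(m, f, inp$labels[ids], config$threshold)))
    }
    wald <- lapply(fits$models, function(m) {
      stats <- lapply(m$predictor_names, function(p) wald_chi2(m, p))
      setNames(stats, m$predictor_names)
    })
    boundaries <- lapply(fits$models, function(m)
      if (length(m$predictor_names) == 1) decision_boundary(m) else NA_real_)
    if (!is.null(config$holdout)) {
      hcfg <- config
      hcfg$transcripts <- config$holdout$transcripts
      hinp <- resolve_inputs(hcfg)
      hprep <- stage("holdout-preprocess",
                     preprocess_transcripts(hinp$utterances, config$speaker,
                                            tagger, config$max_len))
      hdens <- stage("holdout-density",
                     density_stage(hprep$content, inp$space, config))
      hfeats <- data.frame(density = hdens$per_participant$mean_density,
                           row.names = hdens$per_participant$participant_id)
      if (!is.null(latent)) {
        hsv <- sentence_vectors_stage(hprep$content, inp$space)
        hfeats$voices <- vapply(hsv[rownames(hfeats)], function(v)
          concept_predictor(latent$concept, v), numeric(1))
      }
      hlab <- config$holdout$labels[rownames(hfeats)]
      holdout_metrics <- lapply(fits$models, function(m)
        evaluate_transfer(m, hfeats[m$predictor_names], hlab, config$threshold))
    }
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp_write(dens$per_sentence,
                file.path(config$out_dir, "density_sentences.tsv"),
                hash, config$seed)
    stamp_write(dens$per_participant,
                file.path(config$out_dir, "density_participants.tsv"),
                hash, config$seed)
    if (!is.null(latent))
      stamp_write(latent$contrast,
                  file.path(config$out_dir, "contrast.tsv"), hash, config$seed)
    meta <- list(config_hash = hash, seed = config$seed,
                 backend = prep$backend, log = log)
    jsonlite::write_json(meta, file.path(config$out_dir, "run_meta.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  structure(list(density = dens, latent = latent, models = fits$models,
                 features = fits$features, labels = fits$labels,
                 wald = wald, boundaries = boundaries,
                 training_metrics = fits$training_metrics,
                 holdout_metrics = holdout_metrics,
                 config_hash = hash, seed = config$seed, log = log),
            class = "run_report")
}

#' POS-shuffle control run
#'
#' Recomputes per-participant densities on POS-shuffled transcripts and
#' refits the density-only logistic model for each shuffle, returning the
#' distribution of Wald statistics next to the unshuffled statistic. Words
#' are permuted within POS category, within each participant's transcript by
#' default (`shuffle_scope = "cohort"` permutes across the whole cohort).
#'
#' @param config a [run_config()] (labels required; baseline ignored).
#' @param n_shuffles number of shuffle replicates.
#' @return list of class `shuffle_report`: `original_wald`, `shuffle_wald`
#'   (length `n_shuffles`), `original_model`, `seed`.
#' @export
run_shuffle_control <- function(config, n_shuffles = 10) {
  stopifnot(inherits(config, "run_config"), n_shuffles >= 1)
  inp <- resolve_inputs(config)
  tagger <- config$tagger %||% dictionary_tagger(inp$space)
  prep <- preprocess_transcripts(inp$utterances, config$speaker, tagger,
                                 config$max_len)
  dens <- density_stage(prep$content, inp$space, config)
  ids <- dens$per_participant$participant_id
  y <- inp$labels[ids]
  m0 <- fit_logistic(data.frame(density = dens$per_participant$mean_density), y)
  w0 <- wald_chi2(m0)$statistic

  stats <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    shuffled <- if (config$shuffle_scope == "participant") {
      lapply(seq_along(prep$content), function(i)
        pos_shuffle(prep$content[[i]], config$seed + 1000L * s + i))
    } else {
      flat <- unlist(prep$content, recursive = FALSE)
      sh <- pos_shuffle(flat, config$seed + 1000L * s)
      split(sh, rep(seq_along(prep$content), lengths(prep$content)))
    }
    names(shuffled) <- names(prep$content)
    dsh <- density_stage(shuffled, inp$space, config)
    ysh <- inp$labels[dsh$per_participant$participant_id]
    msh <- fit_logistic(data.frame(density = dsh$per_participant$mean_density),
                        ysh)
    stats[s] <- wald_chi2(msh)$statistic
  }
  structure(list(original_wald = w0, shuffle_wald = stats,
                 original_model = m0, seed = config$seed),
            class = "shuffle_report")
}

#' Verify config-hash consistency of a run directory
#'
#' Every table written by [run_full_pipeline()] starts with a comment line
#' carrying the config hash; `verify_run` checks that all artifacts in the
#' directory share one hash.
#'
#' @param dir run output directory.
#' @return TRUE invisibly on success; otherwise an error naming mismatches.
#' @export
verify_run <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  meta_file <- file.path(dir, "run_meta.json")
  hashes <- vapply(files, function(f) {
    first <- readLines(f, n = 1)
    sub("^# config_hash: (\\S+).*$", "\\1", first)
  }, character(1))
  if (file.exists(meta_file))
    hashes <- c(hashes, meta = jsonlite::read_json(meta_file)$config_hash)
  if (length(unique(hashes)) > 1)
    stop("config hash mismatch across run directory: ",
         paste(unique(hashes), collapse = ", "))
  invisible(TRUE)
}
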