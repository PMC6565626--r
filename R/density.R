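#' @title Semantic density via vector unpacking
#' @description Compose unit-norm sentence vectors from content-word
#'   embeddings, decompose them into sparse weighted sums of word embeddings
#'   by gradient descent with a growing prune threshold, select the
#'   high-weight meaning components by F-ratio partitioning, and compute the
#'   density statistic and comparator measures.
#' @name density
NULL

#' Compose a sentence vector
#'
#' The sentence vector is the sum of the (unit-normalized) embeddings of the
#' sentence's in-vocabulary content keys, scaled to unit length. Out-of-
#' vocabulary keys are skipped and reported in the `oov` attribute. A sentence
#' with no in-vocabulary key, or whose resultant cancels to zero, raises a
#' `semdens_skip_sentence` warning and returns `NULL`; such sentences are
#' excluded from density and cosine analyses.
#'
#' @param sentence a `content_sentence` (or a character vector of keys).
#' @param space an [embedding_space()].
#' @return list of class `sentence_vector`: `vector` (unit norm), `word_keys`
#'   (the keys summed), `n_content` (tokens counted with repetition).
#' @export
compose_sentence_vector <- function(sentence, space) {
  keys <- if (inherits(sentence, "content_sentence")) sentence$keys else sentence
  lk <- space_lookup(space, keys)
  if (!nrow(lk$mat))
    return(skip_sentence("no in-vocabulary content words; sentence skipped"))
  M <- lk$mat / sqrt(rowSums(lk$mat^2))
  resultant <- colSums(M)
  if (vector_length(resultant) < 1e-12)
    return(skip_sentence("sentence resultant has zero norm; sentence skipped"))
  structure(list(vector = unit_normalize(resultant),
                 word_keys = keys[keys %in% rownames(space$vectors)],
                 n_content = nrow(M), oov = lk$missing),
            class = "sentence_vector")
}

#' Vector-unpacking configuration
#'
#' @param learning_rate gradient-descent step size (eta). The value is not
#'   dictated by the method; 0.01 is a stable default for unit-norm lexicons
#'   (instability sets in around 2 / largest eigenvalue of the candidate Gram
#'   matrix).
#' @param tau prune-schedule scale: after iteration `t` any weight below
#'   `t / (tau * max_iterations)` is set exactly to zero (default 100).
#' @param max_iterations number of gradient iterations (default 5000).
#' @param candidate_vocabulary keys to unpack over; `NULL` means the full
#'   embedding space.
#' @param low_density_cutoff densities at or below this trigger re-selection
#'   at the second-highest F ratio (default 0.25).
#' @param prune_magnitude prune on `|w|` instead of the signed value (the
#'   signed default also zeroes negative weights, which have no meaning-
#'   component reading).
#' @param trace_every record the cost every this many iterations (default 100).
#' @param seed integer, recorded (all-zero weight initialization is
#'   deterministic).
#' @export
unpacking_config <- function(learning_rate = 0.01, tau = 100,
                             max_iterations = 5000,
                             candidate_vocabulary = NULL,
                             low_density_cutoff = 0.25,
                             prune_magnitude = FALSE,
                             trace_every = 100, seed = 1L) {
  stopifnot(learning_rate > 0, tau > 0, max_iterations >= 1,
            low_density_cutoff > 0, low_density_cutoff < 1)
  structure(list(learning_rate = learning_rate, tau = tau,
                 max_iterations = as.integer(max_iterations),
                 candidate_vocabulary = candidate_vocabulary,
                 low_density_cutoff = low_density_cutoff,
                 prune_magnitude = prune_magnitude,
                 trace_every = as.integer(trace_every),
                 seed = as.integer(seed)),
            class = "unpacking_config")
}

#' Unpack a sentence vector over a word-embedding lexicon
#'
#' Gradient descent minimizes the Euclidean cost
#' `E = 1/2 * ||y - sum_i w_i x_i||^2` over per-word weights `w_i` (all
#' initialized to zero), with update `w_i := w_i + eta * sum_k (y - yhat)_k
#' x_ik`. After each iteration `t`, weights below the growing threshold
#' `t / (tau * max_iterations)` are set exactly to zero, pruning the lexicon
#' down to a small set of influential word embeddings.
#'
#' @param target a `sentence_vector` (or a unit-norm numeric vector).
#' @param space an [embedding_space()]; candidate vectors are unit-normalized.
#' @param config an [unpacking_config()].
#' @return list of class `unpacking_result`: `weights` (named, pruned entries
#'   exactly 0), `estimate`, `final_cost`, `cost_trace` (one value per
#'   `trace_every` iterations), `nonzero_count`, `iterations`.
#' @export
unpack <- function(target, space, config = unpacking_config()) {
  y <- if (inherits(target, "sentence_vector")) target$vector else target
  stopifnot(inherits(config, "unpacking_config"))
  if (abs(vector_length(y) - 1) > 1e-6)
    stop("unpack target must be unit-norm")
  cand <- config$candidate_vocabulary %||% rownames(space$vectors)
  cand <- cand[cand %in% rownames(space$vectors)]
  if (!length(cand)) stop("candidate vocabulary is empty")
  X <- space$vectors[cand, , drop = FALSE]
  X <- X / sqrt(rowSums(X^2))
  res <- unpack_gd_cpp(t(X), as.numeric(y), config$learning_rate, config$tau,
                       config$max_iterations, config$trace_every,
                       config$prune_magnitude)
  w <- setNames(res$weights, cand)
  structure(list(weights = w, estimate = res$estimate,
                 final_cost = res$final_cost, cost_trace = res$cost_trace,
                 nonzero_count = sum(w != 0),
                 iterations = res$iterations),
            class = "unpacking_result")
}

# two-group F ratio: between-group mean square / within-group mean square.
# A size-1 group contributes zero within-group sum of squares.
two_group_f <- function(high, low) {
  n1 <- length(high); n2 <- length(low); N <- n1 + n2
  g <- mean(c(high, low))
  ssb <- n1 * (mean(high) - g)^2 + n2 * (mean(low) - g)^2
  ssw <- sum((high - mean(high))^2) + sum((low - mean(low))^2)
  msb <- ssb / 1
  msw <- if (N > 2) ssw / (N - 2) else 0
  if (msw == 0) {
    if (msb == 0) return(NaN)
    return(Inf)
  }
  msb / msw
}

#' Select meaning components by F-ratio partitioning
#'
#' The nonzero weights are rank-ordered and every split into a high and a low
#' group is scored by a one-way two-group F ratio; the high group of the
#' best split is the set of meaning components, `m` its size, and density
#' `m / n_content`. When the resulting density falls at or below
#' `low_density_cutoff` (typical of heavy word repetition), selection is
#' redone at the split with the second-highest F ratio and the density
#' recomputed once. Ties between splits are broken toward the smaller high
#' group; if all nonzero weights are identical (F undefined) they are all
#' selected.
#'
#' @param weights named numeric weight vector (zeros allowed).
#' @param config an [unpacking_config()] (for `low_density_cutoff`).
#' @param n_content number of content tokens in the sentence (>= 1).
#' @return list: `selected_components` (keys), `m`, `density`, `repartitioned`.
#' @export
select_components <- function(weights, config = unpacking_config(), n_content) {
  stopifnot(n_content >= 1)
  nz <- weights[weights != 0]
  if (!length(nz))
    return(skip_sentence("no nonzero unpacking weights; sentence skipped"))
  ord <- order(-nz, names(nz))
  w <- nz[ord]
  k <- length(w)
  # degenerate cases: one or two nonzero weights are all selected, and so is
  # a set of (numerically) identical weights, for which F is undefined
  if (k <= 2 || diff(range(w)) < 1e-8 * max(abs(w))) {
    return(list(selected_components = names(w), m = k,
                density = k / n_content, repartitioned = FALSE))
  }
  f <- vapply(seq_len(k - 1), function(s)
    two_group_f(w[seq_len(s)], w[(s + 1):k]), numeric(1))
  f[is.nan(f)] <- -Inf
  pick <- function(rank) {
    ord_f <- order(-f, seq_along(f))   # ties -> smaller high group
    ord_f[rank]
  }
  s_best <- pick(1)
  m <- s_best
  dens <- m / n_content
  repart <- FALSE
  if (dens <= config$low_density_cutoff && k > 2) {
    s2 <- pick(2)
    if (!is.na(s2)) {
      m <- s2
      dens <- m / n_content
      repart <- TRUE
    }
  }
  list(selected_components = names(w)[seq_len(m)], m = m, density = dens,
       repartitioned = repart)
}

#' Semantic density of a sentence
#'
#' The number of meaning components divided by the number of content words,
#' `D = m / n`.
#'
#' @param m number of selected meaning components (>= 1).
#' @param n_content number of content tokens (>= 1; counted with repetition).
#' @export
semantic_density <- function(m, n_content) {
  if (n_content < 1)
    return(skip_sentence("sentence has no content words; density undefined"))
  stopifnot(m >= 1)
  m / n_content
}

#' Mean density of a language sample
#' @param densities numeric vector of per-sentence densities (non-empty).
#' @export
mean_density <- function(densities) {
  if (!length(densities)) stop("no sentences: mean density undefined")
  mean(densities)
}

#' Unpack one sentence end-to-end
#'
#' Convenience wrapper: compose the sentence vector, unpack it, select
#' components, attach `m`, `density`, `repartitioned` and `n_content` to the
#' unpacking result. Returns `NULL` (with a skip warning) for sentences that
#' cannot be composed or yield no nonzero weights.
#'
#' @inheritParams compose_sentence_vector
#' @param config an [unpacking_config()].
#' @export
sentence_density <- function(sentence, space, config = unpacking_config()) {
  sv <- compose_sentence_vector(sentence, space)
  if (!inherits(sv, "sentence_vector")) return(NULL)
  res <- unpack(sv, space, config)
  sel <- select_components(res$weights, config, sv$n_content)
  if (is.null(sel)) return(NULL)
  res$selected_components <- sel$selected_components
  res$m <- sel$m
  res$density <- sel$density
  res$repartitioned <- sel$repartitioned
  res$n_content <- sv$n_content
  res
}

#' Per-participant density over a transcript
#'
#' Applies [sentence_density()] to every content sentence of a transcript and
#' averages the per-sentence densities.
#'
#' @param transcript list of `content_sentence` objects.
#' @param space an [embedding_space()].
#' @param config an [unpacking_config()].
#' @param participant_id optional id carried into the result.
#' @return list of class `participant_density`: `participant_id`,
#'   `sentence_densities`, `mean_density`, `sentence_count`, `details`
#'   (per-sentence data.frame with n, m, density, cost, repartitioned).
#' @export
participant_density <- function(transcript, space,
                                config = unpacking_config(),
                                participant_id = NA_character_) {
  rows <- list()
  for (j in seq_along(transcript)) {
    r <- suppressWarnings(sentence_density(transcript[[j]], space, config))
    if (is.null(r)) next
    rows[[length(rows) + 1L]] <-
      data.frame(sentence = j, n = r$n_content, m = r$m, density = r$density,
                 cost = r$final_cost, repartitioned = r$repartitioned)
  }
  if (!length(rows)) stop("no analyzable sentences in transcript")
  det <- do.call(rbind, rows)
  structure(list(participant_id = participant_id,
                 sentence_densities = det$density,
                 mean_density = mean_density(det$density),
                 sentence_count = nrow(det),
                 details = det),
            class = "participant_density")
}

#' @export
print.participant_density <- function(x, ...) {
  cat("<participant_density> ", x$participant_id, ": mean D = ",
      round(x$mean_density, 4), " over ", x$sentence_count, " sentences\n",
      sep = "")
  invisible(x)
}

#' Idea density of a tagged sentence
#'
#' The comparator measure: verbs, adjectives, adverbs, prepositions and
#' conjunctions divided by total tokens.
#'
#' @param sentence a `tagged_sentence`.
#' @export
idea_density <- function(sentence) {
  if (!nrow(sentence))
    return(skip_sentence("empty sentence; idea density undefined"))
  sum(sentence$tag %in% c("VB", "JJ", "RB", "IN", "CC")) / nrow(sentence)
}

#' Information value of a sentence's content words
#'
#' The vector-length comparator, computed on unnormalized embeddings: the
#' mean word-vector length, and the length of the summed resultant.
#'
#' @param sentence a `content_sentence` (or character vector of keys).
#' @param space an [embedding_space()].
#' @return list: `mean_length`, `resultant_length`, `n_used`.
#' @export
information_value <- function(sentence, space) {
  keys <- if (inherits(sentence, "content_sentence")) sentence$keys else sentence
  lk <- space_lookup(space, keys)
  if (!nrow(lk$mat))
    return(skip_sentence("no in-vocabulary content words"))
  lens <- sqrt(rowSums(lk$mat^2))
  list(mean_length = mean(lens),
       resultant_length = vector_length(colSums(lk$mat)),
       n_used = nrow(lk$mat))
}
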