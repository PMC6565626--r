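#' @title Latent content analysis
#' @description Profile a speaker's sentence vectors against a probe
#'   vocabulary by maximum cosine, contrast the profile with a baseline
#'   corpus via tf-idf-style weighting, cluster the top probes, and build
#'   concept-vector predictors.
#' @name latent
NULL

# stack sentence_vector objects (or a numeric matrix) into rows of unit vectors
sentence_matrix <- function(sentences) {
  if (is.matrix(sentences)) return(sentences)
  if (inherits(sentences, "sentence_vector")) sentences <- list(sentences)
  vecs <- lapply(sentences, function(s)
    if (inherits(s, "sentence_vector")) s$vector else s)
  do.call(rbind, vecs)
}

#' Probe-word cosine profile of an entity
#'
#' For each probe word, the maximum cosine between the probe's embedding and
#' any of the entity's sentence vectors. Probes absent from the vocabulary
#' are dropped and reported in the `dropped` attribute. Because the profile
#' scans the entity's whole sentence set, it can surface word meanings the
#' entity never explicitly used.
#'
#' @param probes character vector of probe keys.
#' @param sentences list of `sentence_vector`s (or a matrix of unit row
#'   vectors); at least one.
#' @param space an [embedding_space()].
#' @param entity_id identifier carried into the result.
#' @return named numeric vector of class `probe_profile` (scores in
#'   `[-1, 1]`), attributes `entity_id`, `aggregation`, `dropped`.
#' @export
probe_profile <- function(probes, sentences, space, entity_id = NA_character_) {
  S <- sentence_matrix(sentences)
  if (is.null(S) || !nrow(S)) stop("probe_profile needs at least one sentence")
  lk <- space_lookup(space, probes)
  if (!nrow(lk$mat)) stop("no probe is in the embedding vocabulary")
  P <- lk$mat / sqrt(rowSums(lk$mat^2))
  S <- S / sqrt(rowSums(S^2))
  scores <- apply(P %*% t(S), 1, max)
  structure(scores, class = "probe_profile", entity_id = entity_id,
            aggregation = "max-over-sentences", dropped = lk$missing)
}

#' Average probe profiles across entities
#'
#' Per-probe arithmetic mean over a list of profiles sharing one probe set.
#'
#' @param profiles non-empty list of `probe_profile`s.
#' @param entity_id identifier for the averaged profile.
#' @export
group_profile <- function(profiles, entity_id = "group") {
  stopifnot(length(profiles) >= 1)
  keys <- names(profiles[[1]])
  for (p in profiles)
    if (!identical(names(p), keys))
      stop("probe sets differ across profiles")
  M <- do.call(rbind, lapply(profiles, unclass))
  structure(colMeans(M), class = "probe_profile", entity_id = entity_id,
            aggregation = "mean-over-entities", dropped = character(0))
}

#' Contrast a group profile against a baseline profile
#'
#' Weighs each probe's group cosine by how unusual the probe is relative to
#' the baseline corpus, so that high cosines are retained only when they are
#' high for one group and not the other. Three tf-idf-style weightings are
#' offered:
#'
#' * `"log-enrichment"` (default):
#'   `weighted(p) = c_group(p) * log(c_group(p) / c_base(p))` — the group
#'   cosine as the term-frequency analog, scaled by its log-enrichment over
#'   the baseline. Dividing by the probe's *own* baseline score cancels the
#'   per-probe geometric bias that makes some embeddings score high against
#'   every sentence, so the sign tracks genuine group elevation.
#' * `"tfidf-log-ratio"`:
#'   `weighted(p) = c_group(p) * log(mean(c_base) / c_base(p))` — the
#'   inverse-relative-baseline-prevalence analog of idf. Its sign is set by
#'   the baseline column alone, which makes it unreliable as a ranking when
#'   baseline scores vary for geometric rather than topical reasons; it is
#'   retained for sensitivity analysis.
#' * `"difference"`: `c_group(p) - c_base(p)`.
#'
#' Scores below `floor` are floored before any log.
#'
#' @param group,baseline `probe_profile`s over a common probe set.
#' @param method one of `"log-enrichment"`, `"tfidf-log-ratio"`,
#'   `"difference"`.
#' @param floor score floor for the log methods (default 1e-6).
#' @return data.frame of class `contrast_matrix`: `probe`, `group_score`,
#'   `baseline_score`, `weight`; attribute `method`.
#' @export
contrast_weight <- function(group, baseline,
                            method = c("log-enrichment", "tfidf-log-ratio",
                                       "difference"),
                            floor = 1e-6) {
  method <- match.arg(method)
  if (!identical(names(group), names(baseline)))
    stop("group and baseline profiles must share one probe set")
  g <- as.numeric(group); b <- as.numeric(baseline)
  bf <- pmax(b, floor)
  w <- switch(method,
    "difference" = g - b,
    "tfidf-log-ratio" = g * log(mean(b) / bf),
    "log-enrichment" = pmax(g, floor) * log(pmax(g, floor) / bf))
  structure(data.frame(probe = names(group), group_score = g,
                       baseline_score = b, weight = w,
                       stringsAsFactors = FALSE),
            class = c("contrast_matrix", "data.frame"), method = method)
}

#' Top positively weighted probes
#'
#' The `k` probes with the largest positive contrast weights, descending;
#' fewer if fewer positive weights exist. Ties broken lexicographically.
#'
#' @param matrix a `contrast_matrix`.
#' @param k number of probes to retain (default 50).
#' @export
top_probes <- function(matrix, k = 50) {
  stopifnot(k >= 1)
  pos <- matrix[matrix$weight > 0, , drop = FALSE]
  if (!nrow(pos)) return(character(0))
  pos <- pos[order(-pos$weight, pos$probe), , drop = FALSE]
  head(pos$probe, k)
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, later
# centers sampled with probability proportional to squared distance to the
# nearest chosen center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j] <- sample.int(n, 1, prob = prob)
    nd <- rowSums((X - matrix(X[centers[j], ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  X[centers, , drop = FALSE]
}

#' Cluster probe words in a 2-D embedding projection
#'
#' Reduces the probes' embeddings to two dimensions (default: PCA; any
#' function mapping a matrix to an n x 2 matrix can be supplied, e.g. a
#' stochastic-neighbor method), runs k-means with k-means++ seeding at every
#' `k` in `k_range` (several restarts each), and returns the labeling with
#' the highest mean silhouette width. Deterministic given `seed`.
#'
#' @param probes character vector (>= 3) of in-vocabulary keys.
#' @param space an [embedding_space()].
#' @param k_range candidate cluster counts (default `2:10`), clipped to
#'   `[2, n - 1]`.
#' @param seed integer seed.
#' @param reducer function(matrix) -> n x 2 coordinates; default PCA.
#' @param nstart k-means++ restarts per k (default 5).
#' @return list of class `cluster_solution`: `points` (n x 2), `labels`
#'   (named integer), `k`, `silhouette`.
#' @export
cluster_probes <- function(probes, space, k_range = 2:10, seed = 1L,
                           reducer = NULL, nstart = 5) {
  lk <- space_lookup(space, probes)
  if (nrow(lk$mat) < 3) stop("need at least 3 in-vocabulary probes to cluster")
  X <- lk$mat
  if (is.null(reducer))
    reducer <- function(M) prcomp(M, rank. = 2)$x[, 1:2, drop = FALSE]
  k_range <- k_range[k_range >= 2 & k_range <= nrow(X) - 1]
  if (!length(k_range)) stop("k_range empty after clipping to [2, n - 1]")
  with_seed(seed, {
    pts <- reducer(X)
    rownames(pts) <- rownames(X)
    D <- dist(pts)
    best <- NULL
    for (k in k_range) {
      for (r in seq_len(nstart)) {
        ctr <- kmeanspp_centers(pts, k)
        km <- suppressWarnings(
          kmeans(pts, centers = ctr, iter.max = 100, algorithm = "Lloyd"))
        if (length(unique(km$cluster)) < 2) next
        sil <- mean(cluster::silhouette(km$cluster, D)[, "sil_width"])
        if (is.null(best) || sil > best$silhouette)
          best <- list(points = pts,
                       labels = setNames(km$cluster, rownames(pts)),
                       k = k, silhouette = sil)
      }
    }
    if (is.null(best)) stop("clustering failed for every k in k_range")
    structure(best, class = "cluster_solution")
  })
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> k = ", x$k, ", mean silhouette = ",
      round(x$silhouette, 3), ", ", nrow(x$points), " probes\n", sep = "")
  invisible(x)
}

#' Concept vector from a probe cluster
#'
#' The unit-normalized sum of the member probes' (unit-normalized)
#' embeddings — e.g. a VOICES concept from `voice, sound, hear, chant, loud`.
#'
#' @param keys probe keys (>= 1 in vocabulary; misses dropped).
#' @param space an [embedding_space()].
#' @return list of class `concept_vector`: `member_keys`, `vector` (unit norm).
#' @export
concept_vector <- function(keys, space) {
  lk <- space_lookup(space, keys)
  if (!nrow(lk$mat)) stop("no concept key is in the embedding vocabulary")
  M <- lk$mat / sqrt(rowSums(lk$mat^2))
  structure(list(member_keys = rownames(M),
                 vector = unit_normalize(colSums(M))),
            class = "concept_vector")
}

#' Concept predictor for a participant
#'
#' The largest cosine between the concept vector and any of the participant's
#' sentence vectors.
#'
#' @param concept a [concept_vector()].
#' @param sentences list of `sentence_vector`s or a matrix of row vectors.
#' @export
concept_predictor <- function(concept, sentences) {
  S <- sentence_matrix(sentences)
  if (is.null(S) || !nrow(S)) stop("concept_predictor needs at least one sentence")
  S <- S / sqrt(rowSums(S^2))
  max(drop(S %*% concept$vector))
}
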