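test_that("probe_profile takes the max cosine over sentences", {
  sp <- orthonormal_space(8, 10, seed = 5)
  keys <- rownames(sp$vectors)
  s1 <- compose_sentence_vector(content_sentence(keys[1]), sp)
  s2 <- compose_sentence_vector(content_sentence(keys[2:4]), sp)
  prof <- probe_profile(keys, list(s1, s2), sp, "E1")
  expect_equal(unname(prof[keys[1]]), 1, tolerance = 1e-9)
  # exhaustive-max oracle over both sentences
  for (p in keys) {
    want <- max(cosine(sp$vectors[p, ], s1$vector),
                cosine(sp$vectors[p, ], s2$vector))
    expect_equal(unname(prof[p]), want, tolerance = 1e-12)
  }
  expect_true(all(prof >= -1 - 1e-9 & prof <= 1 + 1e-9))
  # missing probes dropped and reported
  prof2 <- probe_profile(c(keys[1], "NN_ghost"), list(s1), sp)
  expect_length(prof2, 1)
  expect_equal(attr(prof2, "dropped"), "NN_ghost")
  expect_error(probe_profile(keys, list(), sp), "at least one sentence")
})

test_that("probe_profile scores never decrease when sentences are added", {
  sp <- orthonormal_space(10, 12, seed = 9)
  keys <- rownames(sp$vectors)
  set.seed(1)
  sents <- lapply(1:6, function(i)
    compose_sentence_vector(content_sentence(sample(keys, 3)), sp))
  p_small <- probe_profile(keys, sents[1:3], sp)
  p_big <- probe_profile(keys, sents, sp)
  expect_true(all(p_big >= p_small - 1e-12))
})

test_that("group_profile averages per-probe over entities", {
  sp <- orthonormal_space(6, 8, seed = 7)
  keys <- rownames(sp$vectors)
  mk <- function(vals) structure(setNames(vals, keys), class = "probe_profile")
  one <- mk(runif(6, -1, 1))
  expect_equal(as.numeric(group_profile(list(one))), as.numeric(one))
  a <- mk(rep(0.2, 6)); b <- mk(rep(0.4, 6))
  expect_equal(unname(as.numeric(group_profile(list(a, b)))), rep(0.3, 6))
  set.seed(3)
  profs <- lapply(1:7, function(i) mk(runif(6, -1, 1)))
  got <- as.numeric(group_profile(profs))
  want <- colMeans(do.call(rbind, lapply(profs, as.numeric)))
  expect_equal(got, want)
  bad <- structure(setNames(runif(3), keys[1:3]), class = "probe_profile")
  expect_error(group_profile(list(a, bad)), "probe sets differ")
})

test_that("contrast_weight implements its three weighting methods", {
  keys <- paste0("NN_p", 1:5)
  mk <- function(vals) structure(setNames(vals, keys), class = "probe_profile")
  g <- mk(c(0.9, 0.9, 0.2, 0.5, 0.4))
  b <- mk(c(0.3, 0.6, 0.3, 0.5, 0.44))

  # difference: elementwise subtraction; identical profiles -> all zero
  cd <- contrast_weight(g, b, method = "difference")
  expect_equal(cd$weight, as.numeric(g) - as.numeric(b))
  expect_true(all(contrast_weight(g, g, method = "difference")$weight == 0))

  # spec'd tf-idf log-ratio variant: zero at the baseline mean, monotone
  # decreasing in baseline for equal group scores
  ct <- contrast_weight(g, b, method = "tfidf-log-ratio")
  oracle <- as.numeric(g) * log(mean(as.numeric(b)) / as.numeric(b))
  expect_equal(ct$weight, oracle)
  b_at_mean <- mk(rep(mean(as.numeric(b)), 5))
  expect_equal(contrast_weight(g, b_at_mean, method = "tfidf-log-ratio")$weight,
               rep(0, 5))
  expect_gt(ct$weight[1], ct$weight[2])  # same group score, smaller baseline

  # default log-enrichment: spreadsheet-style recomputation
  ce <- contrast_weight(g, b)
  tf <- pmax(as.numeric(g), 1e-6)
  expect_equal(ce$weight, tf * log(tf / pmax(as.numeric(b), 1e-6)))
  expect_gt(ce$weight[1], ce$weight[2])

  expect_error(contrast_weight(g, mk(runif(5))[-1]), "probe set")
})

test_that("top_probes sorts positive weights with lexicographic ties", {
  cm <- structure(data.frame(probe = c("b", "a", "c", "d"),
                             group_score = 0, baseline_score = 0,
                             weight = c(0.5, 0.5, -0.2, 0.9)),
                  class = c("contrast_matrix", "data.frame"))
  expect_equal(top_probes(cm, 3), c("d", "a", "b"))
  expect_equal(top_probes(cm, 50), c("d", "a", "b"))  # fewer positives
  cm$weight <- -abs(cm$weight)
  expect_length(top_probes(cm, 3), 0)
  # full-sort oracle on random weights
  set.seed(4)
  cm2 <- structure(data.frame(probe = paste0("p", sprintf("%02d", 1:20)),
                              group_score = 0, baseline_score = 0,
                              weight = round(runif(20, -1, 1), 3)),
                   class = c("contrast_matrix", "data.frame"))
  pos <- cm2[cm2$weight > 0, ]
  want <- head(pos$probe[order(-pos$weight, pos$probe)], 3)
  expect_equal(top_probes(cm2, 3), want)
})

test_that("cluster_probes recovers planted blobs and is deterministic", {
  set.seed(10)
  d <- 8
  centers <- qr.Q(qr(matrix(rnorm(d * d), d, d)))[, 1:3]
  V <- do.call(rbind, lapply(1:3, function(k)
    t(sapply(1:6, function(i)
      unit_normalize(centers[, k] + 0.05 * rnorm(d))))))
  rownames(V) <- paste0("NN_b", rep(1:3, each = 6), "w", 1:18)
  sp <- embedding_space(V, setNames(rep(1, 18), rownames(V)))
  hits <- 0
  for (s in 1:10) {
    sol <- cluster_probes(rownames(V), sp, k_range = 2:6, seed = s)
    ok <- sol$k == 3 && sol$silhouette > 0.5 &&
      all(vapply(split(names(sol$labels), sol$labels),
                 function(g) length(unique(sub("w.*", "", g))) == 1,
                 logical(1)))
    hits <- hits + ok
  }
  expect_gte(hits, 9)   # planted structure recovered across seeds
  expect_identical(cluster_probes(rownames(V), sp, 2:6, seed = 3)$labels,
                   cluster_probes(rownames(V), sp, 2:6, seed = 3)$labels)
  expect_error(cluster_probes(rownames(V)[1:2], sp, 2:6, 1), "at least 3")
})

test_that("concept_vector is the unit-normalized member sum", {
  sp <- orthonormal_space(8, 10, seed = 11)
  keys <- rownames(sp$vectors)
  cv <- concept_vector(keys[1:2], sp)
  expect_equal(vector_length(cv$vector), 1, tolerance = 1e-9)
  expect_equal(sum(cv$vector * sp$vectors[keys[1], ]), 1 / sqrt(2))
  one <- concept_vector(keys[3], sp)
  expect_equal(one$vector, unname(unit_normalize(sp$vectors[keys[3], ])))
  expect_error(concept_vector("NN_ghost", sp), "vocabulary")
})

test_that("concept_predictor is the max cosine, duplication-invariant", {
  sp <- orthonormal_space(8, 10, seed = 12)
  keys <- rownames(sp$vectors)
  cv <- concept_vector(keys[1:3], sp)
  sents <- lapply(list(keys[1:3], keys[4], keys[5:6]), function(k)
    compose_sentence_vector(content_sentence(k), sp))
  got <- concept_predictor(cv, sents)
  want <- max(vapply(sents, function(s) cosine(cv$vector, s$vector), numeric(1)))
  expect_equal(got, want)
  expect_equal(concept_predictor(cv, sents[c(1, 1, 2, 3, 3)]), got)
  # sentence equal to the concept vector scores 1; orthogonal sentences 0
  expect_equal(concept_predictor(cv, list(cv$vector)), 1, tolerance = 1e-9)
  orth <- compose_sentence_vector(content_sentence(keys[7]), sp)
  expect_equal(concept_predictor(cv, list(orth)), 0, tolerance = 1e-9)
})
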