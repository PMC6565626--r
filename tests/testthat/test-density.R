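test_that("compose_sentence_vector is the unit-normalized embedding sum", {
  sp <- orthonormal_space(8, 10, seed = 2)
  keys <- rownames(sp$vectors)
  sv <- compose_sentence_vector(content_sentence(keys[1:3]), sp)
  want <- unit_normalize(colSums(sp$vectors[keys[1:3], ]))
  expect_equal(sv$vector, want, tolerance = 1e-12)
  expect_equal(sv$n_content, 3)
  expect_equal(vector_length(sv$vector), 1, tolerance = 1e-9)

  # single word: that word's unit-normalized embedding
  one <- compose_sentence_vector(content_sentence(keys[5]), sp)
  expect_equal(one$vector, unname(unit_normalize(sp$vectors[keys[5], ])))

  # two orthonormal embeddings: coefficient 1/sqrt(2) on each
  two <- compose_sentence_vector(content_sentence(keys[1:2]), sp)
  expect_equal(sum(two$vector * sp$vectors[keys[1], ]), 1 / sqrt(2))
  expect_equal(sum(two$vector * sp$vectors[keys[2], ]), 1 / sqrt(2))

  # OOV-only sentence is skipped with a classed warning
  expect_warning(res <- compose_sentence_vector(content_sentence("NN_nope"), sp),
                 class = "semdens_skip_sentence")
  expect_null(res)
  # zero resultant (v and -v) is skipped
  V <- rbind(NN_a = c(1, 0), NN_b = c(-1, 0))
  sp2 <- embedding_space(V, c(NN_a = 1, NN_b = 1))
  expect_warning(compose_sentence_vector(content_sentence(c("NN_a", "NN_b")), sp2),
                 class = "semdens_skip_sentence")
})

test_that("unpack recovers exact representations on orthonormal lexicons", {
  sp <- orthonormal_space(10, 12, seed = 1)
  keys <- rownames(sp$vectors)
  cfg <- unpacking_config()

  # target equal to one lexicon vector
  r1 <- unpack(unname(sp$vectors[keys[1], ]), sp, cfg)
  expect_equal(unname(r1$weights[keys[1]]), 1, tolerance = 1e-3)
  expect_true(all(r1$weights[keys[-1]] == 0))
  expect_lt(r1$final_cost, 1e-4)

  # normalized sum of 4: least-squares projection gives 0.5 on each
  y <- unit_normalize(colSums(sp$vectors[keys[1:4], ]))
  r4 <- unpack(y, sp, cfg)
  proj <- drop(sp$vectors[keys[1:4], ] %*% y)   # projection oracle
  expect_equal(unname(r4$weights[keys[1:4]]), unname(proj), tolerance = 1e-3)
  expect_true(all(r4$weights[keys[5:10]] == 0))

  # weighted target 2a + b -> (2, 1)/sqrt(5)
  y2 <- unit_normalize(2 * sp$vectors[keys[1], ] + sp$vectors[keys[2], ])
  r2 <- unpack(y2, sp, cfg)
  expect_equal(unname(r2$weights[keys[1:2]]), c(2, 1) / sqrt(5),
               tolerance = 1e-3)
})

test_that("unpack cost trace is non-increasing and pruned weights exactly 0", {
  sp <- orthonormal_space(12, 16, seed = 6)
  keys <- rownames(sp$vectors)
  for (i in 1:5) {
    pick <- sample(keys, sample(2:6, 1))
    y <- unit_normalize(colSums(sp$vectors[pick, , drop = FALSE]))
    r <- unpack(y, sp, unpacking_config(trace_every = 50))
    expect_true(all(diff(r$cost_trace) <= 1e-12))
    off <- r$weights[setdiff(keys, pick)]
    expect_true(all(off == 0))        # exactly zero, never merely small
    expect_equal(r$nonzero_count, sum(r$weights != 0))
  }
  # divergent learning rate raises a numeric-instability error naming eta
  # (magnitude pruning keeps the oscillation alive instead of zeroing it)
  y <- unname(sp$vectors[keys[1], ])
  expect_error(unpack(y, sp, unpacking_config(learning_rate = 5,
                                              prune_magnitude = TRUE)),
               "eta")
  expect_error(unpack(c(2, rep(0, 15)), sp), "unit-norm")
})

test_that("select_components matches brute-force F enumeration", {
  w <- c(a = 0.9, b = 0.85, c = 0.1, d = 0.08)
  sel <- select_components(w, unpacking_config(), n_content = 4)
  expect_equal(sel$m, 2)
  expect_equal(sort(sel$selected_components), c("a", "b"))
  expect_false(sel$repartitioned)

  # exactly 2 nonzero -> both selected
  sel2 <- select_components(c(a = 0.9, b = 0.4, c = 0), unpacking_config(), 2)
  expect_equal(sel2$m, 2)

  # all-identical weights -> all selected
  sel3 <- select_components(c(a = .5, b = .5, c = .5), unpacking_config(), 3)
  expect_equal(sel3$m, 3)

  # no nonzero weight -> skip signal
  expect_warning(res <- select_components(c(a = 0, b = 0), unpacking_config(), 2),
                 class = "semdens_skip_sentence")
  expect_null(res)
})

test_that("F-ratio split selection agrees with an anova oracle on random weights", {
  set.seed(101)
  cfg <- unpacking_config(low_density_cutoff = 1e-9)  # isolate the F rule
  n_cases <- 300
  for (i in seq_len(n_cases)) {
    k <- sample(3:10, 1)
    w <- round(sort(runif(k, 0.01, 1), decreasing = TRUE), 6)
    w <- w * (1 + 1e-9 * seq_len(k))  # avoid exact ties in value
    names(w) <- paste0("k", sprintf("%02d", seq_len(k)))
    # oracle: two-group one-way ANOVA F for every split, via lm/anova
    f <- vapply(seq_len(k - 1), function(s) {
      g <- factor(rep(c("hi", "lo"), c(s, k - s)))
      suppressWarnings(anova(stats::lm(w ~ g))$`F value`[1])
    }, numeric(1))
    f[is.na(f)] <- Inf
    best <- which(f == max(f))[1]
    sel <- select_components(w, cfg, n_content = k)
    expect_equal(sel$m, best, info = paste("case", i))
  }
})

test_that("low-density repartition uses the second-highest F split", {
  # construct: huge first weight so best split is after position 1
  w <- c(a = 10, b = 1.30, c = 1.28, d = 0.02, e = 0.018)
  f <- vapply(1:4, function(s)
    semdens:::two_group_f(w[1:s], w[(s + 1):5]), numeric(1))
  expect_equal(which.max(f), 1)          # best split gives m = 1
  sel <- select_components(w, unpacking_config(low_density_cutoff = 0.25),
                           n_content = 5)
  second <- order(-f)[2]
  expect_true(sel$repartitioned)
  expect_equal(sel$m, second)
  # with a permissive cutoff the best split stands
  sel2 <- select_components(w, unpacking_config(low_density_cutoff = 0.01),
                            n_content = 5)
  expect_false(sel2$repartitioned)
  expect_equal(sel2$m, 1)
})

test_that("semantic_density and mean_density follow their formulas", {
  expect_equal(semantic_density(2, 4), 0.5)
  expect_equal(semantic_density(7, 7), 1)
  expect_warning(semantic_density(1, 0), class = "semdens_skip_sentence")
  expect_equal(mean_density(c(1, 0.5)), 0.75)
  expect_equal(mean_density(0.8), 0.8)
  set.seed(2)
  d <- runif(100)
  expect_equal(mean_density(d), sum(d) / 100)
  expect_error(mean_density(numeric(0)), "no sentences")
})

test_that("sentence_density: duplicate word halves density; order-free", {
  sp <- orthonormal_space(10, 12, seed = 3)
  keys <- rownames(sp$vectors)
  # one word repeated twice over an orthonormal lexicon -> m = 1, D = 0.5
  r <- sentence_density(content_sentence(c(keys[1], keys[1])), sp)
  expect_equal(r$m, 1)
  expect_equal(r$density, 0.5)

  # all-distinct sentence: density 1 (m = n)
  r2 <- sentence_density(content_sentence(keys[2:5]), sp)
  expect_equal(r2$density, 1)
  expect_equal(sort(r2$selected_components), sort(keys[2:5]))

  # density invariant to word order
  perm <- sentence_density(content_sentence(keys[c(4, 2, 5, 3)]), sp)
  expect_equal(perm$density, r2$density)
  expect_equal(sort(perm$selected_components), sort(r2$selected_components))
})

test_that("participant_density averages sentence densities", {
  sp <- orthonormal_space(10, 12, seed = 8)
  keys <- rownames(sp$vectors)
  tr <- list(content_sentence(keys[1:4]),
             content_sentence(c(keys[5], keys[5])),
             content_sentence("NN_out_of_vocab"))
  pd <- participant_density(tr, sp, participant_id = "P1")
  expect_equal(pd$sentence_count, 2)    # OOV sentence skipped
  expect_equal(pd$sentence_densities, c(1, 0.5))
  expect_equal(pd$mean_density, 0.75)
  expect_equal(pd$mean_density, mean(pd$details$density))
})

test_that("idea_density counts VB/JJ/RB/IN/CC over total tokens", {
  mk <- function(tags) data.frame(token = paste0("t", seq_along(tags)),
                                  tag = tags, lemma = paste0("t", seq_along(tags)))
  expect_equal(idea_density(mk(c("VB", "VB", "JJ", "IN", rep("NN", 6)))), 0.4)
  expect_equal(idea_density(mk(rep("NN", 5))), 0)
  s <- tokenize_and_tag("The dog ran quickly and barked.")[[1]]
  # hand count: ran(VB) quickly(RB) and(CC) barked(VB) over 6 tokens
  expect_equal(idea_density(s), 4 / 6)
  empty <- data.frame(token = character(0), tag = character(0),
                      lemma = character(0))
  expect_warning(idea_density(empty), class = "semdens_skip_sentence")
})

test_that("information_value returns mean and resultant vector lengths", {
  V <- rbind(NN_a = c(1, 1), NN_b = c(-1, -1), NN_c = c(3, 4))
  sp <- embedding_space(V, c(NN_a = 1, NN_b = 1, NN_c = 1))
  iv <- information_value(content_sentence("NN_a"), sp)
  expect_equal(iv$mean_length, sqrt(2))
  expect_equal(iv$resultant_length, sqrt(2))
  # opposite vectors cancel in the resultant but not the mean
  iv2 <- information_value(content_sentence(c("NN_a", "NN_b")), sp)
  expect_equal(iv2$resultant_length, 0)
  expect_equal(iv2$mean_length, sqrt(2))
  # random fixture against brute-force norms
  iv3 <- information_value(content_sentence(c("NN_a", "NN_c")), sp)
  expect_equal(iv3$mean_length, mean(c(sqrt(2), 5)))
  expect_equal(iv3$resultant_length, vector_length(c(4, 5)))
})
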