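#' @title Synthetic fixtures
#' @description Generate embedding spaces, cohorts and baseline corpora with
#'   known ground truth, so every stage of the pipeline can be exercised
#'   without clinical data.
#' @name fixtures
NULL

#' Specification for synthetic fixtures
#'
#' Defaults describe a small interview-like cohort: a 48-word vocabulary
#' organised into 12 semantic concepts of four words each (mean within-concept
#' cosine 0.7, concepts mutually orthogonal), 16 embedding dimensions, six
#' sentences of 4-8 content words per participant, and a 7-positive /
#' 23-negative group split matching a typical clinical-high-risk training
#' cohort. `density_effect` is the probability that a positive-group sentence
#' is built redundantly (all words drawn, with replacement, from a single
#' concept — literal repeats and near-duplicates both occur, so the density
#' reduction arises through the unpacking mechanism); `concept_effect` is a
#' softmax temperature pulling positive-group word draws toward a designated
#' target concept (0 = no pull). Both default to 0 (null cohort); the strong
#' settings used in recovery studies are `density_effect = 0.8` and
#' `concept_effect = 6`.
#'
#' @param n_words vocabulary size.
#' @param dimension embedding dimension (must be >= `n_concepts`).
#' @param n_concepts number of orthogonally seeded concepts.
#' @param within_concept_cosine target mean within-concept pairwise cosine.
#' @param sentences_per_participant sentences per transcript.
#' @param words_per_sentence integer range (length-2) of content words.
#' @param group_sizes `c(n_positive, n_negative)`.
#' @param density_effect fraction in `[0, 1]`.
#' @param concept_effect nonnegative real.
#' @param zipf_exponent exponent of the Zipf frequency law (default 1).
#' @param seed integer seed.
#' @export
fixture_spec <- function(n_words = 48, dimension = 16, n_concepts = 12,
                         within_concept_cosine = 0.7,
                         sentences_per_participant = 6,
                         words_per_sentence = c(4, 8),
                         group_sizes = c(7, 23),
                         density_effect = 0, concept_effect = 0,
                         zipf_exponent = 1, seed = 1L) {
  stopifnot(n_concepts <= n_words, n_words >= 1, dimension >= 1,
            sentences_per_participant >= 1,
            length(words_per_sentence) == 2,
            words_per_sentence[1] >= 1,
            words_per_sentence[2] >= words_per_sentence[1],
            density_effect >= 0, density_effect <= 1, concept_effect >= 0,
            within_concept_cosine >= 0, within_concept_cosine < 1)
  if (any(group_sizes < 1)) stop("group sizes must be positive")
  structure(list(n_words = n_words, dimension = dimension,
                 n_concepts = n_concepts,
                 within_concept_cosine = within_concept_cosine,
                 sentences_per_participant = sentences_per_participant,
                 words_per_sentence = words_per_sentence,
                 group_sizes = group_sizes,
                 density_effect = density_effect,
                 concept_effect = concept_effect,
                 zipf_exponent = zipf_exponent,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic embedding space
#'
#' Concept centers are orthonormal random directions (requires
#' `dimension >= n_concepts`); each word is
#' `sqrt(a) * center + sqrt(1 - a) * noise` with unit-norm noise orthogonal
#' to the center, so the expected within-concept pairwise cosine equals
#' `a = within_concept_cosine` and cross-concept cosines are near zero. Words
#' are assigned round-robin to concepts and given coarse POS tags cycling
#' through `NN, VB, JJ, RB` within each concept; keys look like `NN_c03w07`.
#' Token frequencies follow a Zipf law over a random rank order.
#' Deterministic for a fixed spec (which includes the seed).
#'
#' @param spec a [fixture_spec()].
#' @return an [embedding_space()]; attribute `concepts` maps key -> concept id.
#' @export
make_embedding_space <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$dimension < spec$n_concepts)
    stop("dimension must be >= n_concepts for orthogonal concept seeding")
  with_seed(spec$seed, {
    d <- spec$dimension; n <- spec$n_words; K <- spec$n_concepts
    centers <- qr.Q(qr(matrix(rnorm(d * K), d, K)))
    concept <- ((seq_len(n) - 1) %% K) + 1
    tags <- CONTENT_TAGS[((seq_len(n) - 1) %/% K) %% 4 + 1]
    a <- spec$within_concept_cosine
    V <- matrix(0, n, d)
    for (i in seq_len(n)) {
      c0 <- centers[, concept[i]]
      eps <- rnorm(d)
      eps <- eps - sum(eps * c0) * c0
      eps <- eps / vector_length(eps)
      V[i, ] <- sqrt(a) * c0 + sqrt(1 - a) * eps
    }
    word <- sprintf("c%02dw%02d", concept, seq_len(n))
    rownames(V) <- paste0(tags, "_", word)
    rank_order <- sample.int(n)
    freq <- pmax(1, round(1000 * rank_order^(-spec$zipf_exponent)))
    sp <- embedding_space(V, setNames(freq, rownames(V)))
    attr(sp, "concepts") <- setNames(concept, rownames(V))
    attr(sp, "target_concept") <- 1L
    sp
  })
}

# Allocate a participant's token pool to sentences. Redundant sentences are
# filled greedily with same-concept tokens (fewest concepts per sentence);
# the rest receive the remaining pool in random order. The pool multiset is
# preserved exactly, so redundancy is an organization effect that a POS
# shuffle undoes.
allocate_sentences <- function(pool, lens, redundant, concepts) {
  remaining <- pool
  out <- vector("list", length(lens))
  for (j in which(redundant)) {
    take <- character(0)
    while (length(take) < lens[j]) {
      cc <- concepts[remaining]
      k <- names(sort(table(cc), decreasing = TRUE))[1]
      idx <- which(cc == k)[seq_len(min(lens[j] - length(take), sum(cc == k)))]
      take <- c(take, remaining[idx])
      remaining <- remaining[-idx]
    }
    out[[j]] <- take
  }
  remaining <- sample(remaining)
  at <- 0L
  for (j in which(!redundant)) {
    out[[j]] <- remaining[(at + 1L):(at + lens[j])]
    at <- at + lens[j]
  }
  out
}

#' Generate a synthetic cohort with planted effects
#'
#' Every participant's token pool is drawn by the same null process
#' (independent draws from the vocabulary, with replacement), so the groups
#' are exchangeable at the word-inventory level. The planted differences are:
#' (1) *organization* — each positive-group sentence is, with probability
#' `density_effect`, built redundantly by filling it with same-concept tokens
#' from the pool (near-duplicates, and literal repeats when the pool holds
#' them), which lowers its measured semantic density while a POS shuffle of
#' the transcript restores the null; and (2) *content* — positive-group pools
#' are drawn with weight `exp(concept_effect * cos(word, target_concept))`,
#' pulling them toward the designated target concept. The ground-truth table
#' records, per sentence, the group, the planted redundancy flag and
#' distinct/total word counts — sufficient to recompute planted effect sizes
#' without re-running generation.
#'
#' @param spec a [fixture_spec()].
#' @param space an embedding space from [make_embedding_space()].
#' @return list: `transcripts` (named per-participant lists of
#'   `content_sentence`s), `labels` (named 0/1; positives first), `truth`
#'   (per-sentence data.frame), `utterances` (raw-text utterance table
#'   rendering each sentence, for exercising the preprocessing stage with a
#'   [dictionary_tagger()]).
#' @export
make_cohort <- function(spec, space) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(space, "embedding_space"))
  with_seed(spec$seed + 1L, {
    keys <- rownames(space$vectors)
    tconc <- attr(space, "target_concept") %||% 1L
    concepts <- attr(space, "concepts")
    centers_dir <- colMeans(space$vectors[concepts == tconc, , drop = FALSE])
    cosines <- drop((space$vectors / sqrt(rowSums(space$vectors^2))) %*%
                      unit_normalize(centers_dir))
    n_pos <- spec$group_sizes[1]; n_neg <- spec$group_sizes[2]
    ids <- sprintf("P%03d", seq_len(n_pos + n_neg))
    labels <- setNames(c(rep(1, n_pos), rep(0, n_neg)), ids)
    transcripts <- setNames(vector("list", length(ids)), ids)
    truth <- list()
    utt <- list()
    key_concept <- setNames(concepts, keys)
    n_sent <- spec$sentences_per_participant
    for (p in seq_along(ids)) {
      pos <- labels[[p]] == 1
      w <- if (pos && spec$concept_effect > 0)
        exp(spec$concept_effect * cosines) else rep(1, length(keys))
      w <- w / sum(w)
      lens <- sample(spec$words_per_sentence[1]:spec$words_per_sentence[2],
                     n_sent, replace = TRUE)
      pool <- sample(keys, sum(lens), replace = TRUE, prob = w)
      red <- pos & runif(n_sent) < spec$density_effect
      alloc <- allocate_sentences(pool, lens, red, key_concept)
      sents <- vector("list", n_sent)
      for (j in seq_len(n_sent)) {
        ks <- alloc[[j]]
        sents[[j]] <- structure(list(keys = ks, n_content = lens[j]),
                                class = "content_sentence")
        truth[[length(truth) + 1L]] <-
          data.frame(participant_id = ids[p], sentence = j,
                     label = labels[[p]], redundant = red[j],
                     n_total = lens[j], n_distinct = length(unique(ks)))
        utt[[length(utt) + 1L]] <-
          data.frame(participant_id = ids[p], speaker = "participant",
                     text = paste0(paste(sub("^[A-Z]+_", "", ks),
                                         collapse = " "), "."))
      }
      transcripts[[p]] <- sents
    }
    list(transcripts = transcripts, labels = labels,
         truth = do.call(rbind, truth), utterances = do.call(rbind, utt))
  })
}

#' Generate a baseline corpus
#'
#' Documents produced by the null (negative-group) process: uniform
#' independent word draws, one document per line, sentences separated by
#' periods. Stands in for a large conversational baseline.
#'
#' @param spec a [fixture_spec()].
#' @param space an embedding space.
#' @param n_docs number of documents (default 100).
#' @param path optional file to write (line-delimited, UTF-8).
#' @return character vector of documents (invisibly, if `path` given); the
#'   parsed form is available via [baseline_sentences()].
#' @export
make_baseline_corpus <- function(spec, space, n_docs = 100, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed + 2L, {
    keys <- rownames(space$vectors)
    docs <- character(n_docs)
    for (i in seq_len(n_docs)) {
      sents <- vapply(seq_len(spec$sentences_per_participant), function(j) {
        len <- sample(spec$words_per_sentence[1]:spec$words_per_sentence[2], 1)
        paste(sub("^[A-Z]+_", "", sample(keys, len, replace = TRUE)),
              collapse = " ")
      }, character(1))
      docs[i] <- paste0(paste(sents, collapse = ". "), ".")
    }
    if (!is.null(path)) {
      writeLines(docs, path, useBytes = TRUE)
      return(invisible(docs))
    }
    docs
  })
}

#' Parse a line-delimited baseline corpus into content sentences
#'
#' Each line is one contributor's document; sentences are split on periods
#' and tagged with the supplied backend (default: a dictionary tagger built
#' from the embedding space).
#'
#' @param docs character vector of documents, or a path to a line-delimited
#'   file.
#' @param space embedding space providing the key dictionary.
#' @param tagger optional tagger backend.
#' @return list (one element per document) of lists of `content_sentence`s.
#' @export
baseline_sentences <- function(docs, space, tagger = NULL) {
  if (length(docs) == 1 && file.exists(docs)) docs <- readLines(docs, warn = FALSE)
  tagger <- tagger %||% dictionary_tagger(space)
  lapply(docs, function(doc)
    lapply(tokenize_and_tag(doc, tagger, max_len = 10000, quiet = TRUE),
           extract_content))
}
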