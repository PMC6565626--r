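# Shared fixture builders. Everything is generated in code; nothing is read
# from disk.

# an embedding space whose n vectors are orthonormal (n <= d)
orthonormal_space <- function(n = 10, d = 12, tags = "NN", seed = 1) {
  set.seed(seed)
  V <- t(qr.Q(qr(matrix(rnorm(d * d), d, d)))[, seq_len(n)])
  rownames(V) <- paste0(rep_len(tags, n), "_w", seq_len(n))
  embedding_space(V, setNames(rep(5, n), rownames(V)))
}

content_sentence <- function(keys) {
  structure(list(keys = keys, n_content = length(keys)),
            class = "content_sentence")
}

# utterance table from a character vector (one utterance per element)
utt_table <- function(texts, id = "P1",
                      speaker = rep("participant", length(texts))) {
  data.frame(participant_id = id, speaker = speaker, text = texts,
             stringsAsFactors = FALSE)
}

# multiset equality, order-free
same_multiset <- function(a, b) identical(sort(a), sort(b))

# reconstruct a predicted/actual pair from confusion counts
counts_to_labels <- function(tp, fp, tn, fn) {
  list(predicted = c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn)),
       actual = c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn)))
}
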