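#' @title Embedding spaces
#' @description Train or load word embeddings keyed by POS-prefixed lemmas;
#'   expose lookup, frequency ranking, vector length and normalization.
#' @name embedding
NULL

#' Construct an embedding space
#'
#' @param vectors numeric matrix, one row per vocabulary key (rownames are the
#'   POS-prefixed lemma keys), `d` columns.
#' @param frequency named numeric vector of corpus token counts, one entry per
#'   key (values >= 1).
#' @return object of class `embedding_space` with elements `vectors`,
#'   `frequency`, `dim`.
#' @export
embedding_space <- function(vectors, frequency) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  keys <- rownames(vectors)
  if (anyDuplicated(keys)) stop("vocabulary keys must be unique")
  if (is.null(names(frequency))) stop("frequency must be named by key")
  frequency <- frequency[keys]
  if (anyNA(frequency) || any(frequency < 1))
    stop("every vocabulary key needs a frequency >= 1")
  structure(list(vectors = vectors, frequency = frequency,
                 dim = ncol(vectors)),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat("<embedding_space> ", nrow(x$vectors), " keys x ", x$dim,
      " dims; total tokens ", sum(x$frequency), "\n", sep = "")
  invisible(x)
}

#' Embedding training configuration
#'
#' Defaults mirror a conventional skip-gram setup: 200 dimensions, a symmetric
#' context window of five words, four passes over the corpus. The trainer
#' shipped with this package is count-based (see [train_embeddings()]), for
#' which `epochs` is recorded as metadata only.
#'
#' @param dimension embedding dimension (default 200).
#' @param window symmetric context window in words (default 5).
#' @param epochs training passes (default 4; metadata for the count trainer).
#' @param min_count minimum corpus frequency for a key to enter the vocabulary.
#' @param method embedding method; `"ppmi-svd"`.
#' @export
embedding_config <- function(dimension = 200, window = 5, epochs = 4,
                             min_count = 1, method = "ppmi-svd") {
  stopifnot(dimension >= 1, window >= 1, epochs >= 1, min_count >= 1)
  structure(list(dimension = dimension, window = window, epochs = epochs,
                 min_count = min_count, method = method),
            class = "embedding_config")
}

#' Train word embeddings from a tokenized corpus
#'
#' Builds distributional embeddings for POS-prefixed lemma keys with a
#' deterministic count-based method: symmetric windowed co-occurrence counts,
#' positive pointwise mutual information (PPMI) weighting, and truncated SVD
#' to `dimension` dimensions (rows scaled by the singular values' square
#' roots). Words sharing contexts receive similar vectors, the property the
#' downstream density and latent-content stages rely on.
#'
#' @param corpus list of character vectors, each a sentence of keys.
#' @param config an [embedding_config()].
#' @param seed integer seed (recorded; the trainer itself is deterministic).
#' @return an [embedding_space()] whose `frequency` table holds corpus counts.
#' @export
train_embeddings <- function(corpus, config = embedding_config(), seed = 1L) {
  if (!length(corpus) || !sum(lengths(corpus)))
    stop("corpus is empty")
  stopifnot(inherits(config, "embedding_config"))
  freq <- table(unlist(corpus, use.names = FALSE))
  vocab <- sort(names(freq[freq >= config$min_count]))
  if (!length(vocab)) stop("no key reaches min_count")
  n <- length(vocab)
  idx <- setNames(seq_len(n), vocab)

  C <- matrix(0, n, n, dimnames = list(vocab, vocab))
  for (sent in corpus) {
    pos <- idx[sent]
    keep <- !is.na(pos)
    pos <- pos[keep]
    L <- length(pos)
    if (L < 2) next
    for (i in seq_len(L - 1)) {
      jmax <- min(L, i + config$window)
      for (j in (i + 1):jmax) {
        C[pos[i], pos[j]] <- C[pos[i], pos[j]] + 1
        C[pos[j], pos[i]] <- C[pos[j], pos[i]] + 1
      }
    }
  }
  total <- sum(C)
  if (total == 0) stop("no co-occurrences within the window; corpus too sparse")
  rs <- rowSums(C)
  rs[rs == 0] <- 1
  pmi <- log((C * total) / outer(rs, rs))
  pmi[!is.finite(pmi) | pmi < 0] <- 0

  d <- min(config$dimension, n)
  sv <- svd(pmi, nu = d, nv = 0)
  V <- sv$u %*% diag(sqrt(sv$d[seq_len(d)]), d)
  # fix SVD sign indeterminacy for determinism across BLAS builds
  for (k in seq_len(d)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  if (d < config$dimension)
    V <- cbind(V, matrix(0, n, config$dimension - d))
  rownames(V) <- vocab
  sp <- embedding_space(V, setNames(as.numeric(freq[vocab]), vocab))
  attr(sp, "config") <- config
  attr(sp, "seed") <- seed
  sp
}

#' Frequency-ranked probe vocabulary
#'
#' Returns keys in descending corpus frequency, truncated at the smallest
#' prefix whose cumulative token frequency reaches `coverage` of all tokens
#' (the default reading of "the most commonly written words"), or at the top
#' `coverage` fraction of vocabulary types when `mode = "rank"`. Frequency
#' ties are broken lexicographically for determinism.
#'
#' @param space an `embedding_space`.
#' @param coverage fraction in (0, 1].
#' @param mode `"coverage"` (cumulative token frequency) or `"rank"`.
#' @export
probe_vocabulary <- function(space, coverage = 0.95,
                             mode = c("coverage", "rank")) {
  mode <- match.arg(mode)
  stopifnot(inherits(space, "embedding_space"), coverage > 0, coverage <= 1)
  if (!length(space$frequency)) stop("empty embedding space")
  ord <- order(-space$frequency, names(space$frequency))
  keys <- names(space$frequency)[ord]
  if (mode == "rank") return(head(keys, max(1L, ceiling(coverage * length(keys)))))
  cum <- cumsum(space$frequency[ord])
  cut <- which(cum >= coverage * sum(space$frequency))[1]
  keys[seq_len(cut)]
}

#' Euclidean length of a vector
#' @param v numeric vector.
#' @export
vector_length <- function(v) sqrt(sum(v^2))

#' Normalize a vector to unit length
#' @param v numeric vector with positive norm.
#' @export
unit_normalize <- function(v) {
  n <- vector_length(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

#' Cosine similarity
#' @param u,v numeric vectors of equal length with positive norms.
#' @export
cosine <- function(u, v) {
  nu <- vector_length(u); nv <- vector_length(v)
  if (nu == 0 || nv == 0) stop("cosine undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

# rows of the vocabulary matrix for a set of keys; missing keys reported
space_lookup <- function(space, keys) {
  present <- keys %in% rownames(space$vectors)
  list(mat = space$vectors[keys[present], , drop = FALSE],
       missing = keys[!present])
}

#' Read / write the word2vec text format
#'
#' Header line `n_words dim`, then one line per key: `key v1 ... vd`.
#' Frequencies travel in a companion two-column tab-separated file
#' (`<path>.freq` by default).
#'
#' @param path file path.
#' @param freq_path companion frequency table path.
#' @return an `embedding_space`.
#' @export
read_word2vec <- function(path, freq_path = paste0(path, ".freq")) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], "\\s+")[[1]])
  n <- hdr[1]; d <- hdr[2]
  parts <- strsplit(lines[1 + seq_len(n)], " ", fixed = TRUE)
  keys <- vapply(parts, `[[`, "", 1L)
  V <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(V) <- keys
  if (file.exists(freq_path)) {
    ft <- read.delim(freq_path, header = FALSE, stringsAsFactors = FALSE)
    freq <- setNames(as.numeric(ft[[2]]), ft[[1]])
  } else {
    freq <- setNames(rep(1, n), keys)
  }
  embedding_space(V, freq)
}

#' @rdname read_word2vec
#' @param space an `embedding_space` to write.
#' @param digits significant digits written (default 8).
#' @export
write_word2vec <- function(space, path, freq_path = paste0(path, ".freq"),
                           digits = 8) {
  V <- space$vectors
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(V), ncol(V)), con)
  rows <- apply(V, 1, function(r)
    paste(sprintf(paste0("%.", digits, "g"), r), collapse = " "))
  writeLines(paste(rownames(V), rows), con)
  ft <- data.frame(key = names(space$frequency), n = space$frequency)
  write.table(ft, freq_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
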