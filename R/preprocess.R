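#' @title Transcript preprocessing
#' @description Turn raw interview transcripts into speaker-separated,
#'   sentence-tokenized, POS-tagged, lemmatized content-word sequences, and
#'   provide the POS-preserving shuffle control.
#' @name preprocess
NULL

COARSE_TAGS <- c("NN", "VB", "JJ", "RB", "IN", "CC", "DT", "PR", "OTHER")
CONTENT_TAGS <- c("NN", "VB", "JJ", "RB")
SPEAKER_ROLES <- c("participant", "interviewer")

#' Read transcripts from disk
#'
#' Accepts either a UTF-8 delimited table with columns `participant_id`,
#' `speaker`, `utterance_text` (tab- or comma-separated), or plain text where
#' each line is prefixed `P:` (participant) or `I:` (interviewer); in the
#' plain-text form all lines belong to one participant named by `default_id`.
#'
#' @param path file path.
#' @param format `"auto"`, `"table"` or `"prefixed"`.
#' @param default_id participant id used for the prefixed plain-text form.
#' @return data.frame with columns `participant_id`, `speaker`, `text`.
#' @export
read_transcripts <- function(path, format = c("auto", "table", "prefixed"),
                             default_id = "P1") {
  format <- match.arg(format)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^[PI]:", lines))) "prefixed" else "table"
  }
  if (format == "prefixed") {
    lines <- lines[nzchar(trimws(lines))]
    role <- ifelse(startsWith(lines, "P:"), "participant",
                   ifelse(startsWith(lines, "I:"), "interviewer", NA))
    if (anyNA(role)) stop("prefixed transcript lines must start with 'P:' or 'I:'")
    out <- data.frame(participant_id = default_id, speaker = role,
                      text = trimws(sub("^[PI]:", "", lines)),
                      stringsAsFactors = FALSE)
  } else {
    sep <- if (grepl("\t", lines[1])) "\t" else ","
    tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                      fileEncoding = "UTF-8")
    need <- c("participant_id", "speaker", "utterance_text")
    if (!all(need %in% names(tab)))
      stop("transcript table needs columns: ", paste(need, collapse = ", "))
    out <- data.frame(participant_id = as.character(tab$participant_id),
                      speaker = tab$speaker, text = tab$utterance_text,
                      stringsAsFactors = FALSE)
  }
  validate_utterances(out)
}

#' Write a transcript table
#'
#' @param utterances data.frame as returned by [read_transcripts()].
#' @param path output path (tab-separated, UTF-8).
#' @export
write_transcripts <- function(utterances, path) {
  tab <- data.frame(participant_id = utterances$participant_id,
                    speaker = utterances$speaker,
                    utterance_text = utterances$text)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

validate_utterances <- function(utterances) {
  stopifnot(is.data.frame(utterances),
            all(c("participant_id", "speaker", "text") %in% names(utterances)))
  bad <- setdiff(unique(utterances$speaker), SPEAKER_ROLES)
  if (length(bad)) stop("unknown speaker role(s): ", paste(bad, collapse = ", "))
  if (any(!nzchar(trimws(utterances$text))))
    stop("utterance text must be non-empty after whitespace stripping")
  utterances
}

#' Filter utterances by speaker role
#'
#' Returns exactly the utterances with the requested role, in original order.
#'
#' @param utterances utterance data.frame.
#' @param role `"participant"` or `"interviewer"`.
#' @export
separate_speakers <- function(utterances, role = c("participant", "interviewer")) {
  role <- match.arg(role)
  validate_utterances(utterances)
  utterances[utterances$speaker == role, , drop = FALSE]
}

# ---- default rule/lexicon tagger backend -----------------------------------

.lex <- local({
  DT <- c("the", "a", "an", "this", "that", "these", "those", "some", "any",
          "no", "every", "each", "either", "neither")
  PR <- c("i", "you", "he", "she", "it", "we", "they", "me", "him", "her",
          "us", "them", "my", "your", "his", "its", "our", "their", "mine",
          "yours", "hers", "ours", "theirs", "myself", "yourself", "himself",
          "herself", "itself", "ourselves", "yourselves", "themselves",
          "who", "whom", "something", "anything", "nothing", "everything")
  IN <- c("in", "on", "at", "of", "to", "from", "with", "by", "for", "about",
          "into", "over", "under", "through", "after", "before", "between",
          "during", "without", "against", "within", "along", "across",
          "behind", "beyond", "near", "off", "out", "around", "since", "if",
          "because", "while", "than", "as")
  CC <- c("and", "or", "but", "nor", "so", "yet")
  RB <- c("not", "never", "always", "often", "sometimes", "usually", "here",
          "there", "now", "then", "too", "also", "just", "quite", "very",
          "really", "maybe", "perhaps", "almost", "already", "still", "again",
          "soon", "away", "entirely", "scarcely", "up", "down", "n't")
  MODAL <- c("will", "would", "can", "could", "may", "might", "must", "shall",
             "should", "wo", "ca")
  JJ <- c("good", "bad", "big", "small", "little", "loud", "quiet", "funny",
          "happy", "sad", "new", "old", "late", "early", "far", "digital",
          "entire", "last", "latest", "same", "right", "wrong", "other",
          "own", "high", "low")
  # irregular inflected form -> lemma (tagged VB)
  irr <- c(am = "be", is = "be", are = "be", was = "be", were = "be",
           been = "be", being = "be", has = "have", had = "have",
           having = "have", does = "do", did = "do", done = "do",
           doing = "do", said = "say", says = "say", went = "go",
           gone = "go", heard = "hear", saw = "see", seen = "see",
           got = "get", gotten = "get", made = "make", knew = "know",
           known = "know", thought = "think", took = "take", taken = "take",
           came = "come", felt = "feel", told = "tell", found = "find",
           gave = "give", given = "give", spoke = "speak", spoken = "speak",
           held = "hold", kept = "keep", ran = "run", sat = "sit",
           stood = "stand", left = "leave", meant = "mean", began = "begin",
           begun = "begin")
  VB <- c("be", "have", "do", "say", "go", "hear", "see", "get", "make",
          "know", "think", "take", "come", "feel", "tell", "find", "give",
          "speak", "hold", "keep", "run", "sit", "stand", "leave", "mean",
          "begin", "talk", "laugh", "want", "need", "view", "whisper",
          "utter", "chant")
  list(DT = DT, PR = PR, IN = IN, CC = CC, RB = RB, MODAL = MODAL, JJ = JJ,
       irr = irr, VB = VB)
})

strip_ed <- function(w) {
  s <- sub("ied$", "y", w)
  if (s != w) return(s)
  s <- sub("ed$", "", w)
  n <- nchar(s)
  if (n >= 3) {
    last2 <- substr(s, n - 1, n)
    if (substr(last2, 1, 1) == substr(last2, 2, 2) &&
        !last2 %in% c("ll", "ss", "ee", "oo")) s <- substr(s, 1, n - 1)
  }
  s
}

strip_ing <- function(w) {
  s <- sub("ing$", "", w)
  n <- nchar(s)
  if (n >= 3) {
    last2 <- substr(s, n - 1, n)
    if (substr(last2, 1, 1) == substr(last2, 2, 2) &&
        !last2 %in% c("ll", "ss", "ee", "oo")) return(substr(s, 1, n - 1))
  }
  # restore final e for CVC+e stems (make -> making)
  if (s %in% .lex$VB) s else if (paste0(s, "e") %in% .lex$VB) paste0(s, "e") else s
}

strip_plural <- function(w) {
  s <- sub("ies$", "y", w)
  if (s != w) return(s)
  if (grepl("(s|x|z|ch|sh)es$", w)) return(sub("es$", "", w))
  if (grepl("[^su]s$", w)) return(sub("s$", "", w))
  w
}

tag_one <- function(w) {
  lex <- .lex
  if (w %in% lex$DT) return(c("DT", w))
  if (w %in% lex$PR) return(c("PR", w))
  if (w %in% lex$CC) return(c("CC", w))
  if (w %in% lex$MODAL) return(c("OTHER", w))
  if (w %in% lex$RB) return(c("RB", w))
  if (w %in% lex$IN) return(c("IN", w))
  if (w %in% names(lex$irr)) return(c("VB", unname(lex$irr[[w]])))
  if (w %in% lex$VB) return(c("VB", w))
  if (w %in% lex$JJ) return(c("JJ", w))
  if (grepl("ly$", w) && nchar(w) > 3) return(c("RB", w))
  if (grepl("(ful|ous|ive|ible|able|ish|less)$", w)) return(c("JJ", w))
  if (grepl("ing$", w) && nchar(w) > 4) return(c("VB", strip_ing(w)))
  if (grepl("ed$", w) && nchar(w) > 3) return(c("VB", strip_ed(w)))
  if (grepl("[0-9]", w)) return(c("OTHER", w))
  if (grepl("s$", w) && nchar(w) > 3) {
    base <- strip_plural(w)
    if (base %in% lex$VB) return(c("VB", base))
    return(c("NN", base))
  }
  c("NN", w)
}

#' Rule/lexicon POS tagger-lemmatizer backend
#'
#' A small deterministic English tagger: closed-class word lists (determiners,
#' pronouns, prepositions, conjunctions, common adverbs), an irregular-verb
#' table, derivational/inflectional suffix rules (`-ly` adverbs, `-ed`/`-ing`
#' verbs with stem repair, plural nouns), and a noun fallback. Tags are the
#' coarse set `NN, VB, JJ, RB, IN, CC, DT, PR, OTHER`. Adequate for short
#' conversational sentences and for synthetic fixtures; any backend mapping to
#' the same coarse tags can be substituted.
#'
#' @return a tagger backend: `list(name, tag)` where `tag(tokens)` returns a
#'   data.frame with columns `token`, `tag`, `lemma`.
#' @export
rule_tagger <- function() {
  structure(list(
    name = "rule-lexicon",
    tag = function(tokens) {
      res <- vapply(tokens, tag_one, character(2))
      tag <- res[1, ]; lemma <- res[2, ]
      # context repair: a 3rd-person -s form after a pronoun is a verb, not a
      # plural noun ("he jumps")
      if (length(tokens) > 1) {
        fix <- which(tag == "NN" & grepl("[^su]s$", tokens) &
                       c("", tag[-length(tag)]) == "PR")
        if (length(fix)) tag[fix] <- "VB"
      }
      data.frame(token = tokens, tag = tag, lemma = lemma,
                 stringsAsFactors = FALSE, row.names = NULL)
    }), class = "semdens_tagger")
}

#' Dictionary tagger backend from a key lookup
#'
#' Builds a backend that tags each surface token by looking it up in a
#' `TAG_lemma` key table (for instance the vocabulary of an
#' [embedding_space()], whose keys are POS-prefixed lemmas). Unknown tokens
#' are tagged `OTHER`.
#'
#' @param keys character vector of `TAG_lemma` keys, or an `embedding_space`.
#' @export
dictionary_tagger <- function(keys) {
  if (inherits(keys, "embedding_space")) keys <- rownames(keys$vectors)
  tag <- sub("_.*$", "", keys)
  lemma <- sub("^[A-Z]+_", "", keys)
  lookup_tag <- setNames(tag, lemma)
  lookup_lemma <- setNames(lemma, lemma)
  structure(list(
    name = "dictionary",
    tag = function(tokens) {
      tg <- unname(lookup_tag[tokens])
      lm <- unname(lookup_lemma[tokens])
      tg[is.na(tg)] <- "OTHER"
      lm[is.na(lm)] <- tokens[is.na(lm)]
      data.frame(token = tokens, tag = tg, lemma = lm, stringsAsFactors = FALSE)
    }), class = "semdens_tagger")
}

split_sentences <- function(text) {
  parts <- unlist(strsplit(text, "(?<=[.!?])\\s+", perl = TRUE))
  parts <- trimws(gsub("\\s+", " ", parts))
  parts[nzchar(gsub("[^A-Za-z']", "", parts))]
}

tokenize_words <- function(sentence) {
  s <- tolower(sentence)
  s <- gsub("n't", " n't", s, fixed = TRUE)
  toks <- regmatches(s, gregexpr("[a-z0-9']+", s))[[1]]
  toks <- gsub("^'+|'+$", "", toks)
  toks[nzchar(toks)]
}

#' Tokenize an utterance into tagged sentences
#'
#' Splits an utterance into sentences, tokenizes each, and applies the tagger
#' backend. Sentences longer than `max_len` tokens are dropped (not truncated)
#' and reported via the `dropped` attribute and a message.
#'
#' @param text a character string (one utterance).
#' @param tagger a tagger backend; default [rule_tagger()].
#' @param max_len maximum sentence length in tokens (default 60).
#' @param quiet suppress the drop message.
#' @return list of `tagged_sentence` data.frames (`token`, `tag`, `lemma`),
#'   with attributes `backend` and `dropped` (count of over-length sentences).
#' @export
tokenize_and_tag <- function(text, tagger = rule_tagger(), max_len = 60,
                             quiet = FALSE) {
  stopifnot(inherits(tagger, "semdens_tagger"), max_len >= 1)
  sents <- split_sentences(text)
  out <- list()
  dropped <- 0L
  for (s in sents) {
    toks <- tokenize_words(s)
    if (!length(toks)) next
    if (length(toks) > max_len) {
      dropped <- dropped + 1L
      next
    }
    ts <- tagger$tag(toks)
    class(ts) <- c("tagged_sentence", class(ts))
    out[[length(out) + 1L]] <- ts
  }
  if (dropped > 0 && !quiet)
    message("dropped ", dropped, " sentence(s) exceeding ", max_len, " tokens")
  structure(out, backend = tagger$name, dropped = dropped)
}

#' Reduce a tagged sentence to its content words
#'
#' Keeps only nouns, verbs, adjectives and adverbs, in order and with
#' repetition, each re-expressed as a POS-prefixed lemma key such as
#' `NN_voice`. A sentence with no content words yields `n_content = 0` and is
#' skipped by downstream stages.
#'
#' @param sentence a `tagged_sentence`.
#' @return a `content_sentence`: `list(keys, n_content)`.
#' @export
extract_content <- function(sentence) {
  stopifnot(is.data.frame(sentence), all(c("tag", "lemma") %in% names(sentence)))
  keep <- which(sentence$tag %in% CONTENT_TAGS)
  keys <- if (length(keep))
    paste0(sentence$tag[keep], "_", sentence$lemma[keep]) else character(0)
  structure(list(keys = keys, n_content = length(keys)),
            class = "content_sentence")
}

#' POS-preserving shuffle of a transcript's content words
#'
#' Within one transcript (a list of content sentences), permutes the words of
#' each part-of-speech category across the whole transcript: verbs are
#' switched with verbs, nouns with nouns, and so on. Every sentence keeps its
#' length and its per-position POS pattern; the transcript-level word multiset
#' per POS is unchanged. Deterministic given `seed`.
#'
#' @param transcript list of `content_sentence` objects.
#' @param seed integer seed.
#' @return list of `content_sentence` objects, shuffled.
#' @export
pos_shuffle <- function(transcript, seed) {
  stopifnot(length(transcript) >= 1)
  keys <- lapply(transcript, function(s) s$keys)
  lens <- lengths(keys)
  flat <- unlist(keys, use.names = FALSE)
  if (!length(flat)) return(transcript)
  tags <- sub("_.*$", "", flat)
  shuffled <- flat
  with_seed(seed, {
    for (tg in unique(tags)) {
      idx <- which(tags == tg)
      if (length(idx) > 1) shuffled[idx] <- flat[sample(idx)]
    }
  })
  out <- vector("list", length(transcript))
  at <- 0L
  for (j in seq_along(transcript)) {
    k <- if (lens[j] > 0) shuffled[(at + 1L):(at + lens[j])] else character(0)
    at <- at + lens[j]
    out[[j]] <- structure(list(keys = k, n_content = lens[j]),
                          class = "content_sentence")
  }
  out
}

#' Preprocess an utterance table end to end
#'
#' Separates the requested speaker, tokenizes/tags each utterance, and reduces
#' sentences to content words, grouped by participant.
#'
#' @param utterances utterance data.frame (`participant_id`, `speaker`, `text`).
#' @param speaker role to keep.
#' @param tagger tagger backend.
#' @param max_len maximum sentence length.
#' @return list with `tagged` and `content` (named per-participant lists),
#'   `backend` and `dropped`.
#' @export
preprocess_transcripts <- function(utterances, speaker = "participant",
                                   tagger = rule_tagger(), max_len = 60) {
  utt <- separate_speakers(utterances, speaker)
  ids <- unique(utt$participant_id)
  tagged <- content <- setNames(vector("list", length(ids)), ids)
  dropped <- 0L
  for (id in ids) {
    rows <- utt[utt$participant_id == id, , drop = FALSE]
    ts <- list()
    for (txt in rows$text) {
      res <- tokenize_and_tag(txt, tagger, max_len, quiet = TRUE)
      dropped <- dropped + attr(res, "dropped")
      ts <- c(ts, res)
    }
    tagged[[id]] <- ts
    content[[id]] <- lapply(ts, extract_content)
  }
  list(tagged = tagged, content = content, backend = tagger$name,
       dropped = dropped)
}
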