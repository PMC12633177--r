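# CHAT-style transcripts: a generator driven by a latent verbal-ability
# scalar, a parser for the CHAT dialect, and the four child-language
# metrics (MLU in morphemes, TNW, WPS, CPS).

chat_vocab <- function() {
  list(subj = c("I", "you", "we", "she", "he"),
       verbs = c("play", "look", "want", "like", "help", "turn", "jump", "walk"),
       verbs_past_irreg = c("ran", "went", "saw", "made", "got"),
       nouns = c("ball", "dog", "cat", "puzzle", "piece", "house", "car",
                 "boat", "tree", "star"),
       adjs = c("big", "red", "blue", "little", "funny"),
       subs = c("because", "when", "if"),
       single = c("no", "yes", "more", "mine", "ball", "dog", "look", "there"),
       mot = c("what do you want to do ?", "tell me about the puzzle .",
               "that looks great !", "do you want the big one ?",
               "let's try another one .", "where does this piece go ?",
               "you are doing so well .", "what should we plan next ?"))
}

# words whose final s/ed/ing is not an inflection, and irregular forms that
# count as a single morpheme
chat_lexicon <- function() {
  list(
    irregular = c("ran", "went", "saw", "got", "made", "came", "said", "did",
                  "had", "was", "were", "been", "am", "is", "are", "has",
                  "does", "ate", "fell", "found", "gave", "heard", "held",
                  "kept", "knew", "left", "let", "lost", "meant", "met",
                  "put", "read", "sat", "sent", "set", "sold", "stood",
                  "took", "told", "thought", "threw", "woke", "won", "wrote",
                  "broke", "brought", "bought", "built", "caught", "chose",
                  "drank", "drove", "flew", "forgot", "grew", "hid", "hit",
                  "hurt", "children", "feet", "men", "women", "mice",
                  "teeth", "people"),
    ing_exceptions = c("thing", "something", "anything", "nothing",
                       "everything", "morning", "evening", "during", "king",
                       "ring", "sing", "bring", "spring", "string", "swing",
                       "wing", "sibling", "darling", "ceiling"),
    ed_exceptions = c("red", "bed", "need", "feed", "seed", "indeed",
                      "hundred"),
    s_exceptions = c("is", "was", "his", "hers", "its", "this", "thus",
                     "yes", "us", "bus", "plus", "gas", "lets", "perhaps",
                     "always"),
    clitics = c("'s", "'re", "'ll", "'ve", "'m", "'d", "n't"),
    fillers = c("um", "uh", "er", "eh", "hm", "hmm", "mhm"),
    subordinators = c("because", "that", "when", "who", "which", "if",
                      "while", "since", "until", "unless", "after", "before"))
}

#' Generate a CHAT-style mother-child transcript
#'
#' Child utterance length, inflection use, subordination rate, and utterance
#' count all increase monotonically (in expectation) with the latent verbal
#' ability scalar; at `latent_verbal = 0` the child produces mostly one- and
#' two-morpheme utterances.
#'
#' @param latent_verbal scalar in `[0, 1]`.
#' @param seed RNG seed.
#' @return object of class `transcript` (also carrying the CHAT text in
#'   `$lines`).
#' @export
generate_transcript <- function(latent_verbal, seed = 1L) {
  stopifnot(length(latent_verbal) == 1L, latent_verbal >= 0, latent_verbal <= 1)
  with_seed(seed, generate_transcript_impl(latent_verbal))
}

generate_transcript_impl <- function(lv) {
  v <- chat_vocab()
  n_child <- 18L + round(22 * lv) + stats::rpois(1, 2)
  utts <- list()
  lines <- c("@Begin", "@Languages:\teng",
             "@Participants:\tCHI Child, MOT Mother")
  pick <- function(x) x[sample.int(length(x), 1L)]
  for (k in seq_len(n_child)) {
    mot_text <- pick(v$mot)
    lines <- c(lines, paste0("*MOT:\t", mot_text))
    utts[[length(utts) + 1L]] <- parse_utterance_text("MOT", mot_text)

    if (stats::runif(1) < 0.7 * (1 - lv)) {
      toks <- pick(v$single)
    } else {
      subj <- pick(v$subj)
      if (stats::runif(1) < 0.3 * lv && subj %in% c("she", "he")) {
        toks <- c(paste0(subj, "'s"), paste0(pick(v$verbs), "ing"))
      } else if (stats::runif(1) < 0.25 * lv) {
        toks <- c(subj, pick(v$verbs_past_irreg))
      } else {
        vb <- pick(v$verbs)
        if (stats::runif(1) < 0.2 * lv)
          vb <- paste0(vb, if (endsWith(vb, "e")) "d" else "ed")
        toks <- c(subj, vb)
      }
      if (stats::runif(1) < 0.15 + 0.7 * lv) {
        np <- c("the", if (stats::runif(1) < 0.2 + 0.4 * lv) pick(v$adjs),
                paste0(pick(v$nouns),
                       if (stats::runif(1) < 0.15 + 0.25 * lv) "s" else ""))
        toks <- c(toks, np)
      }
      if (stats::runif(1) < 0.05 + 0.4 * lv) {
        toks <- c(toks, pick(v$subs), pick(v$subj), pick(v$verbs),
                  "the", pick(v$nouns))
      }
    }
    text <- paste(c(toks, "."), collapse = " ")
    lines <- c(lines, paste0("*CHI:\t", text))
    utts[[length(utts) + 1L]] <- parse_utterance_text("CHI", text)
  }
  lines <- c(lines, "@End")
  structure(list(utterances = utts, lines = lines), class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  spk <- vapply(x$utterances, `[[`, "", "speaker")
  cat(sprintf("transcript: %d utterances (%d CHI, %d MOT)\n",
              length(spk), sum(spk == "CHI"), sum(spk == "MOT")))
  invisible(x)
}

# clean and tokenize one utterance body; returns NULL if nothing remains
parse_utterance_text <- function(speaker, body) {
  s <- gsub("\\[[^]]*\\]", " ", body)         # bracketed annotation codes
  s <- gsub("[<>(),:;\"]", " ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks <- toks[toks != ""]
  toks <- toks[!grepl("^[&+%]", toks)]        # non-word / code tokens
  toks <- toks[!toks %in% c("xxx", "yyy", "www", "0")]
  term <- ""
  if (length(toks) && toks[length(toks)] %in% c(".", "!", "?")) {
    term <- toks[length(toks)]
    toks <- toks[-length(toks)]
  }
  toks <- toks[!toks %in% c(".", "!", "?")]
  if (!length(toks)) return(NULL)
  list(speaker = speaker, tokens = toks, terminator = term)
}

#' Parse a CHAT-dialect transcript
#'
#' Reads speaker tiers (`*CHI:`, `*MOT:`), skipping header (`@`) and
#' dependent (`%`) tiers. Bracketed annotation codes, `&`-prefixed
#' non-words, unintelligible markers (`xxx`, `yyy`, `www`) and the `0`
#' null-action marker are stripped from the token stream; sentence-final
#' `. ! ?` become the utterance terminator. Tab-indented continuation lines
#' extend the previous utterance. Utterances left with no tokens are
#' dropped.
#'
#' @param x path to a `.cha`-style file, or a character vector of lines.
#' @return object of class `transcript`.
#' @export
parse_chat <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  known <- c("CHI", "MOT")
  utts <- list()
  pending <- NULL
  flush <- function(pending, utts) {
    if (is.null(pending)) return(utts)
    u <- parse_utterance_text(pending$speaker, pending$body)
    if (!is.null(u)) utts[[length(utts) + 1L]] <- u
    utts
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*$", ln)) next
    if (startsWith(ln, "@") || startsWith(ln, "%")) next
    if (grepl("^[\t ]", ln) && !is.null(pending)) {
      pending$body <- paste(pending$body, trimws(ln))
      next
    }
    m <- regmatches(ln, regexec("^\\*([A-Za-z]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop(sprintf("line %d is not a recognised CHAT tier: %s", i, ln))
    if (!(m[2] %in% known))
      stop(sprintf("unknown speaker tier '%s' at line %d", m[2], i))
    utts <- flush(pending, utts)
    pending <- list(speaker = m[2], body = m[3])
  }
  utts <- flush(pending, utts)
  structure(list(utterances = utts, lines = lines), class = "transcript")
}

#' Count morphemes in a tokenized utterance
#'
#' Each token counts one morpheme for its base plus one for each detected
#' inflection, following a fixed approximation of Brown's counting
#' conventions: contracted auxiliaries and negations (`'s`, `'re`, `'ll`,
#' `'ve`, `'m`, `'d`, `n't`) count separately; regular plural/3rd-person
#' `-s`/`-es`, past `-ed`, and progressive `-ing` each add one when the
#' remaining stem is plausible (at least two characters containing a
#' vowel); irregular forms in the shipped lexicon count as a single
#' morpheme, as do entries in the per-suffix exception lists.
#'
#' @param tokens character vector of word tokens.
#' @param lexicon rule lexicon, see `chat_lexicon()`.
#' @return integer morpheme count.
#' @examples
#' count_morphemes(c("dogs", "ran"))            # 3
#' count_morphemes(c("she's", "running"))       # 4
#' @export
count_morphemes <- function(tokens, lexicon = chat_lexicon()) {
  total <- 0L
  has_vowel_stem <- function(stem)
    nchar(stem) >= 2L && grepl("[aeiouy]", stem)
  for (tok in tokens) {
    w <- tolower(tok)
    w <- gsub("[^a-z']", "", w)
    if (!nchar(w)) next
    # split off a contracted clitic
    for (cl in lexicon$clitics) {
      if (endsWith(w, cl) && nchar(w) > nchar(cl)) {
        total <- total + 1L
        w <- substr(w, 1L, nchar(w) - nchar(cl))
        break
      }
    }
    w <- gsub("'", "", w)
    if (!nchar(w)) next
    n_base <- 1L
    if (!(w %in% lexicon$irregular)) {
      if (endsWith(w, "ing") && !(w %in% lexicon$ing_exceptions) &&
          has_vowel_stem(substr(w, 1L, nchar(w) - 3L))) {
        n_base <- 2L
      } else if (endsWith(w, "ed") && !(w %in% lexicon$ed_exceptions) &&
                 has_vowel_stem(substr(w, 1L, nchar(w) - 2L))) {
        n_base <- 2L
      } else if (endsWith(w, "es") &&
                 has_vowel_stem(substr(w, 1L, nchar(w) - 2L)) &&
                 !(w %in% lexicon$s_exceptions)) {
        n_base <- 2L
      } else if (endsWith(w, "s") && !endsWith(w, "ss") &&
                 !(w %in% lexicon$s_exceptions) &&
                 has_vowel_stem(substr(w, 1L, nchar(w) - 1L))) {
        n_base <- 2L
      }
    }
    total <- total + n_base
  }
  total
}

#' Child communication metrics from a transcript
#'
#' Computes, for the given speaker: mean length of utterance in morphemes
#' (MLU), total number of words (TNW), words per sentence (WPS; sentences
#' are utterances with a sentence-final terminator), and clauses per
#' sentence (CPS; clauses = 1 + surface subordinating markers). Filler
#' tokens (`um`, `uh`, ...) are excluded from all counts by default.
#'
#' @param transcript a `transcript` object.
#' @param speaker speaker tier to score (default `"CHI"`).
#' @param exclude_fillers drop filler tokens before counting.
#' @param lexicon rule lexicon, see `chat_lexicon()`.
#' @return object of class `comm_metrics` with fields `MLU`, `TNW`, `WPS`,
#'   `CPS`, `n_utterances`, `n_sentences`.
#' @examples
#' tr <- parse_chat(c("*CHI:\tI run ."))
#' compute_metrics(tr)$MLU  # 2
#' @export
compute_metrics <- function(transcript, speaker = "CHI",
                            exclude_fillers = TRUE, lexicon = chat_lexicon()) {
  stopifnot(inherits(transcript, "transcript"))
  utts <- Filter(function(u) u$speaker == speaker, transcript$utterances)
  if (!length(utts))
    stop(sprintf("no utterances for speaker '%s'", speaker))
  toks <- lapply(utts, `[[`, "tokens")
  if (exclude_fillers)
    toks <- lapply(toks, function(tk) tk[!tolower(tk) %in% lexicon$fillers])
  keep <- vapply(toks, length, 1L) > 0L
  toks <- toks[keep]; utts <- utts[keep]
  if (!length(utts))
    stop(sprintf("no utterances with word tokens for speaker '%s'", speaker))

  morph <- vapply(toks, count_morphemes, 1L, lexicon = lexicon)
  words <- vapply(toks, length, 1L)
  is_sent <- vapply(utts, function(u) u$terminator %in% c(".", "!", "?"), TRUE)
  n_sent <- sum(is_sent)
  clauses <- vapply(toks, function(tk)
    1L + sum(tolower(tk) %in% lexicon$subordinators), 1L)

  structure(list(
    MLU = sum(morph) / length(utts),
    TNW = sum(words),
    WPS = if (n_sent > 0) sum(words[is_sent]) / n_sent else NA_real_,
    CPS = if (n_sent > 0) sum(clauses[is_sent]) / n_sent else NA_real_,
    n_utterances = length(utts), n_sentences = n_sent, speaker = speaker),
    class = "comm_metrics")
}

#' @export
print.comm_metrics <- function(x, ...) {
  cat(sprintf("comm_metrics (%s, %d utterances): MLU %.2f, TNW %d, WPS %.2f, CPS %.2f\n",
              x$speaker, x$n_utterances, x$MLU, x$TNW, x$WPS, x$CPS))
  invisible(x)
}

#' @rdname compute_metrics
#' @param ds a `study_dataset` whose dyads carry transcripts.
#' @return `cohort_metrics()`: data frame with one row per child (dyad,
#'   group, MLU, TNW, WPS, CPS).
#' @export
cohort_metrics <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  rows <- lapply(seq_along(ds$dyads), function(d) {
    tr <- ds$dyads[[d]]$transcript
    if (is.null(tr)) return(NULL)
    m <- compute_metrics(tr)
    data.frame(dyad = d, group = ds$dyads[[d]]$group, MLU = m$MLU,
               TNW = m$TNW, WPS = m$WPS, CPS = m$CPS)
  })
  do.call(rbind, rows)
}
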