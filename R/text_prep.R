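#' Segment a clinical note into named sections
#'
#' Splits note text at recognised section headers (see [section_lexicon()]):
#' an uppercase-or-mixed-case surface form followed by a colon, e.g.
#' `"HISTORY OF PRESENT ILLNESS:"`. Text before the first header (or a note
#' with no headers at all) is assigned to the pseudo-section `"OTHER"`. The
#' returned character spans partition the text: every character belongs to
#' exactly one span.
#'
#' @param text A single note string.
#' @param lexicon Named list mapping canonical section names to surface
#'   variants; defaults to [section_lexicon()].
#' @return A data.frame with columns `name` (canonical section name),
#'   `start`, `end` (half-open character span, 1-based) and `content_start`
#'   (first character after the header and colon; equals `start` for
#'   `"OTHER"`).
#' @export
#' @examples
#' segment_sections("CHIEF COMPLAINT: chest pain. FAMILY HISTORY: none.")
segment_sections <- function(text, lexicon = section_lexicon()) {
  stopifnot(is.character(text), length(text) == 1L)
  n <- nchar(text)
  hits <- list()
  for (canon in names(lexicon)) {
    for (surface in lexicon[[canon]]) {
      pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", surface), "\\s*:")
      m <- gregexpr(pat, text, ignore.case = TRUE, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      len <- attr(m, "match.length")
      for (j in seq_along(m)) {
        hits[[length(hits) + 1L]] <- list(pos = m[j], end = m[j] + len[j],
                                          name = canon)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(name = "OTHER", start = 1L, end = n + 1L,
                      content_start = 1L, stringsAsFactors = FALSE))
  }
  pos <- vapply(hits, `[[`, integer(1), "pos")
  hend <- vapply(hits, `[[`, integer(1), "end")
  nm <- vapply(hits, `[[`, character(1), "name")
  ord <- order(pos, -hend)
  pos <- pos[ord]; hend <- hend[ord]; nm <- nm[ord]
  # drop matches nested in an earlier (longer) match, e.g. "HISTORY:" inside
  # "FAMILY HISTORY:"
  keep <- rep(TRUE, length(pos))
  last_end <- 0L
  for (j in seq_along(pos)) {
    if (pos[j] < last_end) keep[j] <- FALSE else last_end <- hend[j]
  }
  pos <- pos[keep]; hend <- hend[keep]; nm <- nm[keep]

  starts <- pos
  ends <- c(pos[-1], n + 1L)
  out <- data.frame(name = nm, start = as.integer(starts),
                    end = as.integer(ends),
                    content_start = as.integer(hend),
                    stringsAsFactors = FALSE)
  if (pos[1] > 1L) {
    out <- rbind(data.frame(name = "OTHER", start = 1L,
                            end = as.integer(pos[1]), content_start = 1L,
                            stringsAsFactors = FALSE), out)
  }
  out
}

#' Tokenize note text
#'
#' Lowercases, strips punctuation and splits on whitespace, flagging each
#' token as a stop word or not. Deterministic; empty text yields zero tokens.
#'
#' @param text A single string.
#' @param stopwords Character vector of lowercase stop words; defaults to the
#'   shipped list ([stopword_list()]).
#' @return List with `tokens` (character) and `stopword` (logical, parallel).
#' @export
#' @examples
#' tokenize_text("Systolic Blood Pressure.")
tokenize_text <- function(text, stopwords = stopword_list()) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- tolower(text)
  x <- gsub("[^a-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  list(tokens = toks, stopword = toks %in% stopwords)
}

#' Pad or truncate a token sequence to fixed length
#'
#' Produces the fixed-length sequence consumed by the text encoder: the first
#' `L_max` tokens are kept (head-keeping, so history-note tokens survive
#' truncation) and shorter inputs are padded with the pad token. Section
#' token spans are clipped to the retained content.
#'
#' @param tokens Character vector of tokens (any length).
#' @param L_max Maximum sequence length (default 1000).
#' @param stopword_mask Logical vector parallel to `tokens`; recomputed
#'   against [stopword_list()] if `NULL`.
#' @param sections Optional data.frame with columns `name`, `start`, `end`
#'   giving half-open token spans (1-based) into `tokens`.
#' @param keep Which end survives truncation: `"head"` (default) or `"tail"`.
#' @return An object of class `"tokseq"`: list with `tokens` (length `L_max`,
#'   `""` at pad positions), `content_length`, `stopword_mask` (length
#'   `L_max`, `FALSE` at pads), `sections` (clipped spans), `L_max`.
#' @export
pad_or_truncate <- function(tokens, L_max = 1000L, stopword_mask = NULL,
                            sections = NULL, keep = c("head", "tail")) {
  stopifnot(L_max > 0)
  keep <- match.arg(keep)
  L_max <- as.integer(L_max)
  n_in <- length(tokens)
  if (is.null(stopword_mask)) {
    stopword_mask <- tokens %in% stopword_list()
  }
  stopifnot(length(stopword_mask) == n_in)
  offset <- 0L
  if (n_in > L_max) {
    if (keep == "head") {
      idx <- seq_len(L_max)
    } else {
      offset <- n_in - L_max
      idx <- (offset + 1L):n_in
    }
    tokens <- tokens[idx]
    stopword_mask <- stopword_mask[idx]
  }
  n_c <- length(tokens)
  out_tokens <- character(L_max)
  out_mask <- logical(L_max)
  if (n_c > 0L) {
    out_tokens[seq_len(n_c)] <- tokens
    out_mask[seq_len(n_c)] <- stopword_mask
  }
  sec <- NULL
  if (!is.null(sections) && nrow(sections) > 0L) {
    s <- pmax(sections$start - offset, 1L)
    e <- pmin(sections$end - offset, n_c + 1L)
    ok <- e > s
    sec <- data.frame(name = sections$name[ok], start = as.integer(s[ok]),
                      end = as.integer(e[ok]), stringsAsFactors = FALSE)
  }
  if (is.null(sec)) {
    sec <- data.frame(name = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(tokens = out_tokens, content_length = n_c,
                 stopword_mask = out_mask, sections = sec, L_max = L_max),
            class = "tokseq")
}

#' Assemble the text input of one patient from a note bundle
#'
#' Concatenates a patient's selected notes into one token sequence: history
#' notes first (in chart-time order) as the initial information for chronic
#' patients, then within-window notes in chart-time order. Each note is
#' segmented into sections, each section's content tokenized, and the result
#' padded or truncated to `L_max`.
#'
#' @param bundle A note bundle from [select_notes()].
#' @param L_max Maximum token sequence length.
#' @param lexicon,stopwords Passed to [segment_sections()] /
#'   [tokenize_text()].
#' @return A `"tokseq"` object (see [pad_or_truncate()]); an empty bundle
#'   yields an all-pad sequence.
#' @export
assemble_bundle_text <- function(bundle, L_max = 1000L,
                                 lexicon = section_lexicon(),
                                 stopwords = stopword_list()) {
  notes <- bundle$notes
  if (length(notes) == 0L) {
    return(pad_or_truncate(character(0), L_max,
                           stopword_mask = logical(0)))
  }
  hist_flag <- vapply(notes, function(x) isTRUE(x$history), logical(1))
  times <- vapply(notes, function(x) as.numeric(x$chart_time), numeric(1))
  ord <- c(which(hist_flag)[order(times[hist_flag])],
           which(!hist_flag)[order(times[!hist_flag])])
  toks <- character(0)
  mask <- logical(0)
  sec_name <- character(0); sec_start <- integer(0); sec_end <- integer(0)
  for (i in ord) {
    spans <- segment_sections(notes[[i]]$text, lexicon)
    for (j in seq_len(nrow(spans))) {
      content <- substr(notes[[i]]$text, spans$content_start[j],
                        spans$end[j] - 1L)
      tk <- tokenize_text(content, stopwords)
      if (length(tk$tokens) == 0L) next
      sec_name <- c(sec_name, spans$name[j])
      sec_start <- c(sec_start, length(toks) + 1L)
      toks <- c(toks, tk$tokens)
      mask <- c(mask, tk$stopword)
      sec_end <- c(sec_end, length(toks) + 1L)
    }
  }
  pad_or_truncate(toks, L_max, stopword_mask = mask,
                  sections = data.frame(name = sec_name, start = sec_start,
                                        end = sec_end,
                                        stringsAsFactors = FALSE))
}

#' Build a token vocabulary
#'
#' Builds the training vocabulary from token sequences, reserving id 1 for
#' the pad token and id 2 for unknown tokens; out-of-vocabulary tokens at
#' predict time map to UNK. Tokens are ordered by descending frequency
#' (alphabetical within ties) for reproducibility.
#'
#' @param seqs List of `"tokseq"` objects (or character vectors of tokens).
#' @param min_count Minimum corpus frequency for inclusion (default 1).
#' @param max_size Maximum vocabulary size including the two reserved ids.
#' @return Character vector: `c("<pad>", "<unk>", ...)`.
#' @export
build_vocab <- function(seqs, min_count = 1L, max_size = Inf) {
  toks <- unlist(lapply(seqs, function(s) {
    if (inherits(s, "tokseq")) s$tokens[seq_len(s$content_length)] else s
  }), use.names = FALSE)
  if (length(toks) == 0L) return(c("<pad>", "<unk>"))
  tab <- table(toks)
  tab <- tab[tab >= min_count]
  ord <- order(-as.integer(tab), names(tab))
  words <- names(tab)[ord]
  if (is.finite(max_size)) words <- utils::head(words, max(0L, max_size - 2L))
  c("<pad>", "<unk>", words)
}

#' Encode a token sequence against a vocabulary
#'
#' @param seq A `"tokseq"` object.
#' @param vocab Vocabulary from [build_vocab()].
#' @return The sequence with an added integer `ids` field (length `L_max`,
#'   pad id 1, unknown id 2).
#' @export
encode_tokens <- function(seq, vocab) {
  stopifnot(inherits(seq, "tokseq"))
  ids <- rep(1L, seq$L_max)
  n_c <- seq$content_length
  if (n_c > 0L) {
    m <- match(seq$tokens[seq_len(n_c)], vocab)
    m[is.na(m)] <- 2L
    ids[seq_len(n_c)] <- m
  }
  seq$ids <- ids
  seq
}

#' @export
print.tokseq <- function(x, ...) {
  cat("<tokseq> length", x$L_max, "content", x$content_length,
      "tokens,", nrow(x$sections), "section span(s)\n")
  if (x$content_length > 0) {
    shown <- utils::head(x$tokens[seq_len(x$content_length)], 12L)
    cat("  ", paste(shown, collapse = " "),
        if (x$content_length > 12L) "..." else "", "\n")
  }
  invisible(x)
}

#' Read word vectors in word2vec text format
#'
#' Parses the plain-text word2vec format: a header line `"vocab_size dim"`
#' followed by one `word v1 ... v_dim` line per word. Used to initialize the
#' model's word embeddings from pretrained vectors (e.g. biomedical-corpus
#' embeddings) via the `embeddings` argument of [mortnet()]; vocabulary
#' words absent from the file keep their random initialization.
#'
#' @param path Path to the embedding file.
#' @return Numeric matrix with one row per word, rownames set to the words.
#' @export
read_word2vec <- function(path) {
  if (!file.exists(path)) stop("read_word2vec: file not found: ", path)
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr)) {
    stop("read_word2vec: malformed header (expected 'vocab_size dim')")
  }
  n <- hdr[1]; d <- hdr[2]
  if (length(lines) < n + 1L) {
    stop("read_word2vec: header promises ", n, " rows, file has ",
         length(lines) - 1L)
  }
  words <- character(n)
  mat <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1]]
    if (length(parts) != d + 1L) {
      stop("read_word2vec: row ", i, " has ", length(parts) - 1L,
           " values, expected ", d)
    }
    words[i] <- parts[1]
    mat[i, ] <- as.numeric(parts[-1])
  }
  if (anyNA(mat)) stop("read_word2vec: non-numeric vector entries")
  rownames(mat) <- words
  mat
}
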