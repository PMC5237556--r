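# CHAT transcript ingestion.
#
# A pragmatic subset of the CHAT (CHILDES/TalkBank) transcription format is
# supported: *PAR main-tier lines, the retrace/repetition markers [/] and
# [//], word replacement [: word], word-internal noncompletion "(...)",
# fused filler prefixes "&-"/"&", trailing-off "+..." and retrace scoping
# "<...>".  Everything else (pauses "(.)", paralinguistic "[=! ...]",
# dependent tiers, ...) is stripped, not an error.

#' Marker kinds recognised by the CHAT reader
#'
#' @return Character vector of the five marker-event kinds plus the
#'   trailing-off terminator tallied by [marker_counts()].
#' @export
marker_kinds <- function() {
  c("repetition", "revision", "replacement", "incomplete_word", "filler")
}

.ld_terminators <- c("period", "question", "exclamation", "trailing_off",
                     "continuation")

new_utterance <- function(tokens = character(), incomplete = logical(length(tokens)),
                          events = empty_events(), terminator = "period") {
  stopifnot(terminator %in% .ld_terminators,
            length(incomplete) == length(tokens))
  structure(list(tokens = tokens, incomplete = incomplete,
                 events = events, terminator = terminator),
            class = "ld_utterance")
}

empty_events <- function() {
  data.frame(kind = character(), position = integer(), width = integer(),
             stringsAsFactors = FALSE)
}

#' Construct a transcript object
#'
#' @param utterances list of utterances as produced by the CHAT reader.
#' @param subject_id opaque subject identifier.
#' @param group one of `"PrADG"`, `"HEG"`, `"unknown"`.
#' @param age age in years or `NA`.
#' @return An object of class `ld_transcript`.
#' @export
new_transcript <- function(utterances = list(), subject_id = NA_character_,
                           group = "unknown", age = NA_real_) {
  group <- match.arg(group, c("PrADG", "HEG", "unknown"))
  structure(list(subject_id = subject_id, group = group, age = age,
                 utterances = utterances),
            class = "ld_transcript")
}

#' @export
print.ld_transcript <- function(x, ...) {
  cat(sprintf("<ld_transcript> subject=%s group=%s age=%s utterances=%d words=%d\n",
              x$subject_id, x$group,
              ifelse(is.na(x$age), "NA", format(x$age)),
              length(x$utterances),
              sum(vapply(x$utterances, function(u) length(u$tokens), 0L))))
  invisible(x)
}

# Tokens CHAT treats as unintelligible/null; they carry no lexical content.
.ld_nonwords <- c("xxx", "yyy", "www", "0")

# Scan one main-tier utterance body into tokens + marker events.
# Returns an ld_utterance.  `line_no` only feeds diagnostics.
parse_chat_utterance <- function(body, line_no = NA_integer_) {
  body <- trimws(body)
  terminator <- "period"
  # terminator codes sit at the end of the line
  if (grepl("\\+\\.\\.\\.$|\\+\\.\\.\\?$", body)) {
    terminator <- "trailing_off"
    body <- sub("\\+\\.\\.\\.$|\\+\\.\\.\\?$", "", body)
  } else if (grepl("\\+,$", body)) {
    terminator <- "continuation"
    body <- sub("\\+,$", "", body)
  } else if (grepl("\\?$", body)) {
    terminator <- "question"
    body <- sub("\\?$", "", body)
  } else if (grepl("!$", body)) {
    terminator <- "exclamation"
    body <- sub("(\\+/)?(//)?[.!]+$", "", body)
  } else {
    body <- sub("(\\+/)?(//)?\\.$", "", body)
  }

  m <- gregexpr("\\[[^][]*\\]|<|>|[^][<>[:space:]]+", body)[[1]]
  items <- if (m[1] == -1) character() else regmatches(body, list(m))[[1]]
  # any brackets left uncovered by the scan are malformed marker syntax
  residue <- body
  for (it in items) residue <- sub(it, "", residue, fixed = TRUE)
  if (grepl("\\[|\\]", residue)) {
    warning(ld_parse_warning(sprintf(
      "malformed CHAT marker group (unbalanced bracket) on line %s",
      ifelse(is.na(line_no), "?", line_no))))
  }

  tokens <- character()
  incomplete <- logical()
  ev_kind <- character(); ev_pos <- integer(); ev_width <- integer()
  ev_explicit <- logical()
  group_start <- NA_integer_
  scope <- integer()         # token indices the next marker applies to
  scope_is_group <- FALSE

  push_event <- function(kind, pos, width, explicit = TRUE) {
    ev_kind <<- c(ev_kind, kind)
    ev_pos <<- c(ev_pos, as.integer(pos))
    ev_width <<- c(ev_width, as.integer(width))
    ev_explicit <<- c(ev_explicit, explicit)
  }

  for (it in items) {
    if (it == "<") {
      group_start <- length(tokens) + 1L
    } else if (it == ">") {
      if (is.na(group_start)) {
        warning(ld_parse_warning(sprintf(
          "unmatched '>' on line %s", ifelse(is.na(line_no), "?", line_no))))
      } else {
        scope <- seq.int(group_start, length(tokens))
        scope_is_group <- TRUE
        group_start <- NA_integer_
      }
    } else if (startsWith(it, "[")) {
      code <- substr(it, 2L, nchar(it) - 1L)
      if (code == "/") {
        if (length(scope))
          push_event("repetition", scope[1], length(scope),
                     explicit = scope_is_group)
      } else if (code == "//") {
        if (length(scope)) push_event("revision", scope[1], length(scope))
      } else if (startsWith(code, ":")) {
        target <- trimws(substring(code, 2L))
        tgt <- strsplit(target, "[[:space:]]+")[[1]]
        tgt <- tgt[nzchar(tgt)]
        if (length(scope) && length(tgt)) {
          before <- if (scope[1] > 1L) seq_len(scope[1] - 1L) else integer()
          after <- if (max(scope) < length(tokens))
            seq.int(max(scope) + 1L, length(tokens)) else integer()
          tokens <- c(tokens[before], tgt, tokens[after])
          incomplete <- c(incomplete[before], rep(FALSE, length(tgt)),
                          incomplete[after])
          push_event("replacement", scope[1], length(tgt))
          scope <- seq.int(scope[1], scope[1] + length(tgt) - 1L)
        }
      }
      # all other bracketed codes ([* err], [% com], [x n], ...) are stripped
    } else {
      w <- it
      if (grepl("^\\(\\.+\\)$", w)) next            # timed/untimed pause
      if (grepl("^&=", w)) next                     # nonverbal event
      if (grepl("^&-|^&", w)) {                     # fused filler: &-uh, &uh
        push_event("filler", length(tokens) + 1L, 1L)
        next
      }
      inc <- FALSE
      if (grepl("\\(", w)) {                        # word-internal (...) = noncompletion
        inc <- TRUE
        w <- gsub("[()]", "", w)
      }
      w <- sub("@.*$", "", w)                       # special-form suffixes
      w <- gsub("[:ˌˈ‹›„‡⇗⇘^\"]", "", w)
      w <- gsub("[,;]+$", "", w)
      if (!nzchar(w) || w %in% .ld_nonwords) next
      tokens <- c(tokens, w)
      incomplete <- c(incomplete, inc)
      scope <- length(tokens)
      scope_is_group <- FALSE
    }
  }

  # a bare "[/]" scopes one word in CHAT, but transcribers often leave the
  # angle brackets off multi-word retraces; widen the scope to the longest
  # preceding sequence actually repeated after the marker
  n_tok <- length(tokens)
  for (r in seq_along(ev_kind)) {
    if (ev_kind[r] != "repetition" || ev_explicit[r]) next
    p <- ev_pos[r]
    for (w in rev(seq_len(min(p, n_tok - p)))) {
      if (identical(tokens[(p - w + 1L):p], tokens[(p + 1L):(p + w)])) {
        ev_pos[r] <- p - w + 1L
        ev_width[r] <- w
        break
      }
    }
  }

  ev <- data.frame(kind = ev_kind, position = ev_pos, width = ev_width,
                   stringsAsFactors = FALSE)
  # noncompletion marks become incomplete_word events, one per flagged token
  if (any(incomplete)) {
    ev <- rbind(ev, data.frame(kind = "incomplete_word",
                               position = which(incomplete), width = 1L,
                               stringsAsFactors = FALSE))
  }
  new_utterance(tokens, incomplete, ev, terminator)
}

ld_parse_warning <- function(msg) {
  structure(class = c("ld_chat_parse_warning", "warning", "condition"),
            list(message = msg, call = NULL))
}

#' Read a CHAT (.cha) transcript
#'
#' Parses participant (`*PAR:`) main-tier utterances, stripping dependent
#' tiers and investigator turns.  Group and age are taken from the `@ID`
#' header when present (fields 6 and 4 of the pipe-delimited record).
#'
#' @param file path to a `.cha` file, a connection, or a character vector of
#'   lines.
#' @param subject_id optional identifier; defaults to the file base name or
#'   the `@PID` header.
#' @return An [new_transcript()] object.
#' @examples
#' t <- read_chat(c("*PAR:\tthe boy [/] the boy is falling ."))
#' marker_counts(t)
#' @export
read_chat <- function(file, subject_id = NULL) {
  lines <- if (is.character(file) && length(file) > 1L) file
           else if (is.character(file) && !file.exists(file)) strsplit(file, "\n")[[1]]
           else readLines(file, warn = FALSE, encoding = "UTF-8")

  group <- "unknown"; age <- NA_real_; pid <- NA_character_
  utterances <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[[i]]
    if (startsWith(ln, "@ID:")) {
      f <- strsplit(sub("^@ID:[[:space:]]*", "", ln), "|", fixed = TRUE)[[1]]
      if (length(f) >= 3 && trimws(f[3]) == "PAR") {
        if (length(f) >= 4 && grepl("^[0-9]", trimws(f[4])))
          age <- as.numeric(sub("^([0-9]+).*$", "\\1", trimws(f[4])))
        if (length(f) >= 6) {
          g <- trimws(f[6])
          group <- if (g %in% c("PrADG", "AD", "ProbableAD", "Dementia")) "PrADG"
                   else if (g %in% c("HEG", "Control", "control")) "HEG"
                   else "unknown"
        }
      }
      i <- i + 1L
    } else if (startsWith(ln, "@PID:")) {
      pid <- trimws(sub("^@PID:[[:space:]]*", "", ln))
      i <- i + 1L
    } else if (startsWith(ln, "*PAR:")) {
      body <- sub("^\\*PAR:[[:space:]]*", "", ln)
      first_line <- i
      # tab-indented continuation lines belong to the same utterance
      while (i + 1L <= n && grepl("^[\t ]", lines[[i + 1L]]) &&
             !grepl("^[\t ]*[%@*]", lines[[i + 1L]])) {
        i <- i + 1L
        body <- paste(body, trimws(lines[[i]]))
      }
      utterances[[length(utterances) + 1L]] <-
        parse_chat_utterance(body, line_no = first_line)
      i <- i + 1L
    } else {
      i <- i + 1L  # headers, dependent tiers, other speakers
    }
  }

  if (is.null(subject_id)) {
    subject_id <- if (is.character(file) && length(file) == 1L && file.exists(file))
      sub("\\.cha$", "", basename(file)) else pid
  }
  new_transcript(utterances, subject_id = subject_id, group = group, age = age)
}

#' Tally marker events in a transcript
#'
#' Counts each CHAT marker kind across all utterances, plus trailing-off
#' terminators.  A pure function of the transcript.
#'
#' @param t an `ld_transcript`.
#' @return Named integer vector with elements `repetition`, `revision`,
#'   `replacement`, `incomplete_word`, `filler`, `trailing_off`.
#' @export
marker_counts <- function(t) {
  stopifnot(inherits(t, "ld_transcript"))
  out <- stats::setNames(integer(6), c(marker_kinds(), "trailing_off"))
  for (u in t$utterances) {
    if (nrow(u$events)) {
      tab <- table(u$events$kind)
      out[names(tab)] <- out[names(tab)] + as.integer(tab)
    }
    if (u$terminator == "trailing_off")
      out["trailing_off"] <- out["trailing_off"] + 1L
  }
  out
}

#' Load a directory of CHAT transcripts
#'
#' @param dir directory containing `.cha` files, either flat with a manifest
#'   or with one subdirectory per group.
#' @param manifest optional path to a CSV with columns `subject_id`, `group`,
#'   `age`, `path` (relative to `dir`); overrides header metadata.
#' @return List of `ld_transcript` objects.
#' @export
read_chat_dir <- function(dir, manifest = NULL) {
  if (!is.null(manifest)) {
    man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    stopifnot(all(c("subject_id", "group", "age", "path") %in% names(man)))
    out <- lapply(seq_len(nrow(man)), function(i) {
      t <- read_chat(file.path(dir, man$path[i]), subject_id = man$subject_id[i])
      t$group <- ifelse(man$group[i] %in% c("PrADG", "HEG"), man$group[i], "unknown")
      t$age <- as.numeric(man$age[i])
      t
    })
    return(out)
  }
  files <- list.files(dir, pattern = "\\.cha$", recursive = TRUE,
                      full.names = TRUE)
  if (!length(files)) stop("no .cha files found under ", dir)
  lapply(sort(files), function(f) {
    t <- read_chat(f)
    sub_dir <- basename(dirname(f))
    if (t$group == "unknown" && sub_dir %in% c("PrADG", "HEG"))
      t$group <- sub_dir
    t
  })
}

# Sentence grouping: utterances accumulate into a sentence until a true
# terminator (anything but "continuation") is seen.
sentence_groups <- function(t) {
  terms <- vapply(t$utterances, function(u) u$terminator, "")
  if (!length(terms)) return(list())
  ends <- which(terms != "continuation")
  if (!length(ends) || ends[length(ends)] != length(terms))
    ends <- c(ends, length(terms))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  mapply(function(s, e) seq.int(s, e), starts, ends, SIMPLIFY = FALSE)
}
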