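# Shared text utilities: tokenization, surface normalization, light stemming.

# Greek letters spelled out before indexing/lookup so "IFN-γ" and
# "IFN-gamma" collapse to the same key.
.greek_map <- c(
  "α" = "alpha", "β" = "beta", "γ" = "gamma",
  "δ" = "delta", "ε" = "epsilon", "κ" = "kappa",
  "λ" = "lambda", "μ" = "mu", "σ" = "sigma",
  "τ" = "tau", "ω" = "omega"
)

#' Normalize a surface form for dictionary lookup
#'
#' Lowercases, spells out Greek letters, and collapses runs of hyphens,
#' underscores and whitespace to a single space.
#'
#' @param x character vector of surface forms.
#' @return character vector of normalized keys.
#' @keywords internal
normSurface <- function(x) {
  x <- tolower(x)
  for (g in names(.greek_map)) x <- gsub(g, .greek_map[[g]], x, fixed = TRUE)
  x <- gsub("[-‐‑‒–—_[:space:]]+", " ", x)
  trimws(x)
}

# Token = maximal alphanumeric run (ASCII + Greek block). Returns a
# data.frame with 1-based inclusive character positions.
tokenizeText <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(token = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  m <- gregexpr("[A-Za-z0-9Ͱ-Ͽ]+", text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  start <- as.integer(m)
  end <- start + attr(m, "match.length") - 1L
  data.frame(token = substring(text, start, end), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Light stem for interaction-keyword matching
#'
#' Strips one terminal inflection ("ing", "ed", "es", "s") when the
#' remaining stem has at least 4 characters, then a trailing "e", so that
#' inflected sentence tokens and base-form keyword entries share one key
#' ("induced", "induces", "induce" -> "induc").
#'
#' @param w character vector of lowercase words.
#' @return character vector of stems.
#' @keywords internal
lightStem <- function(w) {
  w <- tolower(w)
  vapply(w, function(x) {
    for (suf in c("ing", "ed", "es", "s")) {
      if (suf == "s" && endsWith(x, "ss")) next  # keep "suppress" intact
      if (endsWith(x, suf) && nchar(x) - nchar(suf) >= 4L) {
        x <- substr(x, 1L, nchar(x) - nchar(suf))
        break
      }
    }
    if (endsWith(x, "e") && nchar(x) >= 5L) x <- substr(x, 1L, nchar(x) - 1L)
    x
  }, character(1), USE.NAMES = FALSE)
}

# Does `term` occur in `text` at token boundaries, case-insensitively?
# Multi-word terms allow any whitespace/hyphen run between words.
termBoundaryMatch <- function(text, term) {
  words <- strsplit(normSurface(term), " ", fixed = TRUE)[[1]]
  if (!length(words)) return(FALSE)
  pat <- paste0(
    "(?<![A-Za-z0-9])",
    paste(vapply(words, function(w) gsub("([\\W])", "\\\\\\1", w, perl = TRUE),
                 character(1)),
          collapse = "[-\\s]+"),
    "(?![A-Za-z0-9])"
  )
  grepl(pat, text, perl = TRUE, ignore.case = TRUE)
}

# Canonical unordered pair key "a||b" with a <= b.
pairKey <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "||"), paste(b, a, sep = "||"))
}

.emptyMentions <- function() {
  data.frame(doc_id = character(), sent_index = integer(),
             char_start = integer(), char_end = integer(),
             surface = character(), etype = character(),
             norm_id = character(), stringsAsFactors = FALSE)
}
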