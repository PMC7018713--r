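# ITS2 sequences with secondary structure: dot-bracket parsing and the
# 12-letter sequence-structure alphabet.

# Letter codes 1..12 are nucleotide (A, C, G, U = 1..4) plus 4 * structural
# state (0 unpaired, 1 pair-open, 2 pair-close).  Display characters:
# unpaired a c g u, opening A C G U, closing b d h v.
RIBO_NT <- c("A", "C", "G", "U")
RIBO_ALPHABET <- c("a", "c", "g", "u", "A", "C", "G", "U", "b", "d", "h", "v")
RIBO_GAP_CODE <- 13L

#' Parse a dot-bracket secondary structure
#'
#' Builds a pair table from a Vienna dot-bracket string. Only properly nested
#' round brackets are supported; pseudoknot bracket layers (`[]`, `{}`, ...)
#' are rejected.
#'
#' @param structure a string over the characters `(`, `)` and `.`.
#' @return an integer vector of the same length as `structure`; entry `i` is
#'   the 1-based partner position of `i`, or `NA` when position `i` is
#'   unpaired.
#' @examples
#' parse_dotbracket("(((...)))")
#' @export
parse_dotbracket <- function(structure) {
  stopifnot(is.character(structure), length(structure) == 1L)
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad)) {
    if (chars[bad[1]] %in% c("[", "]", "{", "}", "<", ">")) {
      stop("pseudoknot bracket layers are not supported (position ",
           bad[1], ")", call. = FALSE)
    }
    stop("invalid structure character '", chars[bad[1]], "' at position ",
         bad[1], call. = FALSE)
  }
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) {
        stop("unbalanced structure: unmatched ')' at position ", i,
             call. = FALSE)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[j] <- i
      partner[i] <- j
    }
  }
  if (length(stack)) {
    stop("unbalanced structure: unmatched '(' at position ", stack[1],
         call. = FALSE)
  }
  partner
}

#' Construct a structured RNA sequence
#'
#' Couples an ITS2 nucleotide string with its dot-bracket secondary
#' structure. `T` is read as `U`; lengths must match and the structure must
#' be balanced.
#'
#' @param id sequence identifier.
#' @param seq nucleotide string over `A`, `C`, `G`, `U`/`T` (case
#'   insensitive).
#' @param structure dot-bracket string of the same length.
#' @return an object of class `structured_seq` with elements `id`, `seq`
#'   (normalized to ACGU), `structure` and `pairs` (the pair table).
#' @export
structured_seq <- function(id, seq, structure) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L,
            is.character(structure), length(structure) == 1L)
  id <- unname(id); seq <- unname(seq); structure <- unname(structure)
  seq <- chartr("tT", "uU", seq)
  seq <- toupper(seq)
  if (nchar(seq) != nchar(structure)) {
    stop("sequence and structure lengths differ for '", id, "' (",
         nchar(seq), " vs ", nchar(structure), ")", call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% RIBO_NT)
  if (length(bad)) {
    stop("invalid nucleotide '", chars[bad[1]], "' at position ", bad[1],
         " in '", id, "'", call. = FALSE)
  }
  pairs <- parse_dotbracket(structure)
  structure(list(id = id, seq = seq, structure = structure, pairs = pairs),
            class = "structured_seq")
}

#' @export
print.structured_seq <- function(x, ...) {
  cat("<structured_seq> ", x$id, "  (", nchar(x$seq), " nt, ",
      sum(!is.na(x$pairs)) / 2, " base pairs)\n", sep = "")
  cat(" ", x$seq, "\n ", x$structure, "\n", sep = "")
  invisible(x)
}

#' Encode a structured sequence on the 12-letter alphabet
#'
#' Each position becomes one of 12 letters combining the nucleotide with its
#' structural state (unpaired, pair-opening, pair-closing), the encoding used
#' for simultaneous sequence-structure alignment. The encoding is lossless:
#' [decode12()] recovers the original sequence and structure.
#'
#' @param x a [structured_seq()].
#' @return an object of class `encoded_seq` with integer `codes` (1..12),
#'   the display string `letters`, and the source `id`.
#' @examples
#' encode12(structured_seq("ex", "ACGU", "(..)"))
#' @export
encode12 <- function(x) {
  stopifnot(inherits(x, "structured_seq"))
  nt <- match(strsplit(x$seq, "", fixed = TRUE)[[1]], RIBO_NT)
  sc <- strsplit(x$structure, "", fixed = TRUE)[[1]]
  state <- ifelse(sc == ".", 0L, ifelse(sc == "(", 1L, 2L))
  codes <- nt + 4L * state
  structure(list(id = x$id, codes = codes,
                 letters = paste(RIBO_ALPHABET[codes], collapse = "")),
            class = "encoded_seq")
}

#' Decode a 12-letter encoded sequence
#'
#' @param x an `encoded_seq` (or a display string over the 12-letter
#'   alphabet).
#' @param id identifier to attach when `x` is a bare string.
#' @return the corresponding [structured_seq()].
#' @export
decode12 <- function(x, id = "decoded") {
  if (is.character(x)) {
    codes <- match(strsplit(x, "", fixed = TRUE)[[1]], RIBO_ALPHABET)
    if (anyNA(codes)) {
      stop("invalid 12-letter alphabet character at position ",
           which(is.na(codes))[1], call. = FALSE)
    }
    x <- list(id = id, codes = codes)
  }
  nt <- RIBO_NT[(x$codes - 1L) %% 4L + 1L]
  state <- (x$codes - 1L) %/% 4L
  db <- c(".", "(", ")")[state + 1L]
  structured_seq(x$id, paste(nt, collapse = ""), paste(db, collapse = ""))
}

#' @export
print.encoded_seq <- function(x, ...) {
  cat("<encoded_seq> ", x$id, "  ", x$letters, "\n", sep = "")
  invisible(x)
}

# nucleotide index (1..4) of a 12-letter code; gaps (code 13 / 0) -> NA
.code_nt <- function(code) {
  out <- (code - 1L) %% 4L + 1L
  out[code <= 0L | code > 12L] <- NA_integer_
  out
}

# structural state (0 unpaired, 1 open, 2 close) of a code; gaps -> NA
.code_state <- function(code) {
  out <- (code - 1L) %/% 4L
  out[code <= 0L | code > 12L] <- NA_integer_
  out
}
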