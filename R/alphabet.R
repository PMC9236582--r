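# State spaces and ambiguity handling.
#
# Characters map to "contrast" rows: a 0/1 indicator over the compatible
# states.  The likelihood treats an ambiguous character as a partial vector of
# ones over its compatible states; a fully ambiguous character (gap, '?', 'x',
# DNA 'n') is compatible with every state.

.DNA_STATES <- c("a", "c", "g", "t")
.AA_STATES <- c("a", "r", "n", "d", "c", "q", "e", "g", "h", "i",
                "l", "k", "m", "f", "p", "s", "t", "w", "y", "v")

.dna_ambiguity <- list(
  u = "t",
  r = c("a", "g"), y = c("c", "t"), s = c("c", "g"), w = c("a", "t"),
  k = c("g", "t"), m = c("a", "c"),
  b = c("c", "g", "t"), d = c("a", "g", "t"), h = c("a", "c", "t"),
  v = c("a", "c", "g"),
  n = c("a", "c", "g", "t"), "-" = c("a", "c", "g", "t"),
  "?" = c("a", "c", "g", "t")
)

.aa_ambiguity <- list(
  b = c("n", "d"), z = c("q", "e"), j = c("i", "l"),
  u = "c",  # selenocysteine, read through as cysteine
  o = "k",  # pyrrolysine, read through as lysine
  x = .AA_STATES, "-" = .AA_STATES, "?" = .AA_STATES, "*" = .AA_STATES
)

#' Contrast matrix for an alphabet
#'
#' Rows are the recognized character codes (canonical states first), columns
#' the alphabet states; entry 1 marks a compatible state.
#'
#' @param alphabet `"dna"` or `"aa"`.
#' @return numeric 0/1 matrix with rownames = character codes.
#' @keywords internal
alphabet_contrast <- function(alphabet) {
  states <- if (alphabet == "dna") .DNA_STATES else .AA_STATES
  amb <- if (alphabet == "dna") .dna_ambiguity else .aa_ambiguity
  codes <- c(states, names(amb))
  ctr <- matrix(0, length(codes), length(states),
                dimnames = list(codes, states))
  for (s in states) ctr[s, s] <- 1
  for (a in names(amb)) ctr[a, amb[[a]]] <- 1
  ctr
}

#' @keywords internal
alphabet_states <- function(alphabet) {
  if (alphabet == "dna") .DNA_STATES else .AA_STATES
}

# TRUE for codes compatible with every state (gap-like).
.fully_ambiguous_codes <- function(alphabet) {
  ctr <- alphabet_contrast(alphabet)
  rownames(ctr)[rowSums(ctr) == ncol(ctr)]
}

# Map a character matrix to integer codes (row indices of the contrast
# matrix).  Unknown characters raise an error naming the offender.
.encode_matrix <- function(mat, alphabet) {
  ctr <- alphabet_contrast(alphabet)
  codes <- rownames(ctr)
  idx <- match(tolower(mat), codes)
  if (anyNA(idx)) {
    bad <- unique(mat[is.na(idx)])
    stop("unrecognized character(s) for alphabet '", alphabet, "': ",
         paste(bad, collapse = " "), call. = FALSE)
  }
  matrix(idx, nrow(mat), ncol(mat))
}

# Guess dna vs aa from the characters present.
.detect_alphabet <- function(mat) {
  chars <- unique(tolower(as.vector(mat)))
  chars <- setdiff(chars, c("-", "?", "n", "x", "*"))
  if (all(chars %in% c(.DNA_STATES, names(.dna_ambiguity)))) "dna" else "aa"
}
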