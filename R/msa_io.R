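# Alignment container, file I/O, undetermined-column removal, pattern
# compression and partition definitions.

#' Construct an alignment object
#'
#' An `msa` is a taxa-by-sites character matrix over a DNA or amino-acid
#' alphabet (plus gap/ambiguity codes), optionally carrying a site-to-partition
#' map.  Site indices are 0-based nowhere: all user-facing indices, including
#' `partition_map` names and selected-site reports, are 1-based.
#'
#' @param mat character matrix, rows = taxa (rownames = taxon names).
#' @param alphabet `"dna"`, `"aa"`, or `NULL` to auto-detect.
#' @param partition_map optional integer vector of length `ncol(mat)` mapping
#'   each site to a partition id.
#' @return an object of class `msa` with fields `taxa`, `mat`, `alphabet`,
#'   `partition_map`.
#' @export
msa <- function(mat, alphabet = NULL, partition_map = NULL) {
  stopifnot(is.matrix(mat), ncol(mat) >= 1, nrow(mat) >= 1)
  taxa <- rownames(mat)
  if (is.null(taxa) || any(!nzchar(taxa)))
    stop("alignment rows must be named by taxon", call. = FALSE)
  if (anyDuplicated(taxa))
    stop("duplicate taxon name(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "), call. = FALSE)
  mat[] <- tolower(mat)
  if (is.null(alphabet)) alphabet <- .detect_alphabet(mat)
  alphabet <- match.arg(alphabet, c("dna", "aa"))
  .encode_matrix(mat, alphabet)  # validates characters
  if (!is.null(partition_map) && length(partition_map) != ncol(mat))
    stop("partition_map length must equal the number of sites", call. = FALSE)
  structure(list(taxa = taxa, mat = mat, alphabet = alphabet,
                 partition_map = partition_map),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d taxa x %d sites (%s)%s\n",
              nrow(x$mat), ncol(x$mat), x$alphabet,
              if (is.null(x$partition_map)) "" else
                sprintf(", %d partitions", length(unique(x$partition_map)))))
  invisible(x)
}

#' Number of sites / taxa of an alignment
#' @param aln an `msa`.
#' @return integer count.
#' @export
n_sites <- function(aln) ncol(aln$mat)

#' @rdname n_sites
#' @export
n_taxa <- function(aln) nrow(aln$mat)

#' Read a multiple sequence alignment
#'
#' FASTA or relaxed (whitespace-delimited) PHYLIP, amino-acid or DNA.  Parsing
#' is delegated to [phangorn::read.phyDat()]; the patterns are expanded back to
#' the original site order.  Undetermined columns are retained; see
#' [remove_undetermined_columns()].
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"`; default guesses from the first
#'   non-empty line (`>` means FASTA).
#' @param alphabet `"dna"`, `"aa"`, or `NULL` to auto-detect.
#' @return an [msa] object.
#' @export
read_alignment <- function(path, format = NULL, alphabet = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty alignment file: ", path, call. = FALSE)
  if (is.null(format))
    format <- if (startsWith(trimws(lines[[1]]), ">")) "fasta" else "phylip"
  format <- match.arg(format, c("fasta", "phylip"))
  if (is.null(alphabet)) {
    body <- if (format == "fasta") lines[!startsWith(trimws(lines), ">")]
            else vapply(lines[-1], function(l) sub("^\\S+\\s*", "", l), "")
    alphabet <- .detect_alphabet(matrix(strsplit(paste(body, collapse = ""),
                                                 "")[[1]], nrow = 1))
  }
  type <- if (alphabet == "dna") "DNA" else "AA"
  pd <- tryCatch(
    phangorn::read.phyDat(path, format = format, type = type),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  mat <- tolower(as.character(pd))  # patterns expanded to original sites
  if (anyDuplicated(rownames(mat)))
    stop("duplicate taxon name(s) in ", path, call. = FALSE)
  msa(mat, alphabet = alphabet)
}

#' Write an alignment
#'
#' @param aln an [msa].
#' @param path output file.
#' @param format `"fasta"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(aln$taxa)) {
      writeLines(paste0(">", aln$taxa[i]), con)
      writeLines(paste(aln$mat[i, ], collapse = ""), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %d", n_taxa(aln), n_sites(aln)), con)
    for (i in seq_along(aln$taxa))
      writeLines(paste(aln$taxa[i], paste(aln$mat[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Remove fully undetermined columns
#'
#' Drops every column in which all characters are gaps or fully ambiguous
#' codes ('-', '?', 'x'/'n').  A column with at least one (even partially)
#' determined character is retained.
#'
#' @param aln an [msa].
#' @return the filtered [msa]; attribute `"kept"` holds the 1-based indices of
#'   the retained columns in the input.
#' @export
remove_undetermined_columns <- function(aln) {
  full <- .fully_ambiguous_codes(aln$alphabet)
  undet <- apply(aln$mat, 2, function(col) all(col %in% full))
  if (all(undet)) stop("all columns are fully undetermined", call. = FALSE)
  kept <- which(!undet)
  out <- msa(aln$mat[, kept, drop = FALSE], alphabet = aln$alphabet,
             partition_map = aln$partition_map[kept])
  attr(out, "kept") <- kept
  out
}

#' Compress alignment columns into unique site patterns
#'
#' Identical columns are collapsed to one pattern with a multiplicity weight.
#' Pattern compression is used internally for likelihood evaluation only;
#' Lasso training and site selection always operate on original site indices.
#'
#' @param aln an [msa].
#' @return an object of class `pattern_msa`: `patterns` (taxa x p matrix),
#'   `pattern_weights` (multiplicities, summing to the site count),
#'   `site_to_pattern` (length-m map), plus the source alphabet and taxa.
#' @export
compress_patterns <- function(aln) {
  key <- apply(aln$mat, 2, paste, collapse = "\r")
  first <- !duplicated(key)
  pat_id <- match(key, key[first])
  structure(list(
    patterns = aln$mat[, first, drop = FALSE],
    pattern_weights = as.vector(tabulate(pat_id, nbins = sum(first))),
    site_to_pattern = pat_id,
    taxa = aln$taxa, alphabet = aln$alphabet
  ), class = "pattern_msa")
}

#' Expand a pattern alignment back to the original site matrix
#' @param pat a `pattern_msa`.
#' @return character matrix of the original alignment.
#' @export
expand_patterns <- function(pat) {
  pat$patterns[, pat$site_to_pattern, drop = FALSE]
}

#' Parse a partition definition file
#'
#' One partition per line, RAxML style: an optional model token followed by
#' `name = start-end[,start-end...]`, e.g. `WAG+G4, gene1 = 1-450`.  Ranges are
#' 1-based inclusive, must not overlap, and must jointly cover every site.
#'
#' @param path partition file.
#' @param aln the [msa] the scheme applies to (for coverage validation).
#' @return object of class `partition_scheme`: a list with `partitions`
#'   (data.frame: name, model, ranges list) and `site_partition` (length-m
#'   integer map).
#' @export
parse_partitions <- function(path, aln) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty partition file", call. = FALSE)
  m <- n_sites(aln)
  names <- character(0); models <- character(0); ranges <- list()
  site_partition <- integer(m)
  for (ln in lines) {
    halves <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(halves) != 2)
      stop("malformed partition line: '", ln, "'", call. = FALSE)
    lhs <- trimws(halves[1]); rhs <- trimws(halves[2])
    lhs_parts <- trimws(strsplit(lhs, ",", fixed = TRUE)[[1]])
    if (length(lhs_parts) == 2) { model <- lhs_parts[1]; name <- lhs_parts[2] }
    else if (length(lhs_parts) == 1) { model <- NA_character_; name <- lhs_parts[1] }
    else stop("malformed partition name in '", ln, "'", call. = FALSE)
    rr <- lapply(trimws(strsplit(rhs, ",", fixed = TRUE)[[1]]), function(r) {
      mt <- regmatches(r, regexec("^([0-9]+)\\s*-\\s*([0-9]+)$", r))[[1]]
      if (length(mt) == 0) {
        mt1 <- regmatches(r, regexec("^([0-9]+)$", r))[[1]]
        if (length(mt1) == 0)
          stop("malformed range '", r, "' in partition '", name, "'",
               call. = FALSE)
        return(c(as.integer(mt1[2]), as.integer(mt1[2])))
      }
      c(as.integer(mt[2]), as.integer(mt[3]))
    })
    pid <- length(names) + 1L
    names <- c(names, name); models <- c(models, model)
    ranges[[pid]] <- rr
    for (r in rr) {
      if (r[1] > r[2]) stop("reversed range in partition '", name, "'",
                            call. = FALSE)
      if (r[2] > m) stop("partition '", name, "' range ", r[1], "-", r[2],
                         " exceeds alignment length ", m, call. = FALSE)
      if (any(site_partition[r[1]:r[2]] != 0))
        stop("overlapping partition ranges at sites ",
             r[1], "-", r[2], call. = FALSE)
      site_partition[r[1]:r[2]] <- pid
    }
  }
  if (anyDuplicated(names))
    stop("duplicate partition names", call. = FALSE)
  if (any(site_partition == 0))
    stop("partition scheme leaves ", sum(site_partition == 0),
         " site(s) uncovered", call. = FALSE)
  structure(list(
    partitions = data.frame(name = names, model = models,
                            stringsAsFactors = FALSE),
    ranges = ranges,
    site_partition = site_partition
  ), class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat(sprintf("partition_scheme: %d partitions over %d sites\n",
              nrow(x$partitions), length(x$site_partition)))
  invisible(x)
}

#' Extract the sites of one partition as a standalone alignment
#' @param aln an [msa].
#' @param scheme a `partition_scheme`.
#' @param id partition index.
#' @return an [msa] restricted to the partition's sites (original order).
#' @export
partition_slice <- function(aln, scheme, id) {
  sites <- which(scheme$site_partition == id)
  out <- msa(aln$mat[, sites, drop = FALSE], alphabet = aln$alphabet)
  attr(out, "sites") <- sites
  out
}
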