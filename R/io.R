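#' @useDynLib apoloc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dist rnorm runif setNames predict
#' @importFrom utils read.delim write.csv write.table combn head capture.output
NULL

#' PSI-BLAST residue column order
#'
#' The fixed 20-letter residue order of the score columns in an ASCII PSSM
#' emitted by PSI-BLAST (`-out_ascii_pssm`).
#'
#' @return Character vector of the 20 standard amino-acid one-letter codes.
#' @export
pssm_residues <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# observed range of log-odds scores in typical profiles; outside -> warning
.PSSM_SCORE_RANGE <- c(-9L, 11L)

#' Construct a raw PSSM object
#'
#' An L x 20 integer log-odds profile for one protein, with columns in the
#' fixed PSI-BLAST residue order. Values outside the typical [-9, 11] range
#' are accepted with a warning.
#'
#' @param id accession string.
#' @param scores L x 20 integer matrix (rows = sequence positions).
#' @param residues optional character vector of length L: the residue letter
#'   at each position (used for cross-checks against the FASTA sequence).
#' @return An object of class `raw_pssm` with elements `id`, `scores`,
#'   `residues`, `L`.
#' @export
raw_pssm <- function(id, scores, residues = NULL) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L)
    stop("PSSM must have exactly 20 score columns, got ", ncol(scores))
  if (nrow(scores) < 1L) stop("PSSM must have at least one row")
  storage.mode(scores) <- "integer"
  colnames(scores) <- pssm_residues()
  if (any(scores < .PSSM_SCORE_RANGE[1] | scores > .PSSM_SCORE_RANGE[2]))
    warning("PSSM '", id, "' has scores outside the typical range [-9, 11]")
  if (!is.null(residues) && length(residues) != nrow(scores))
    stop("residue annotation length does not match row count")
  structure(list(id = id, scores = scores, residues = residues,
                 L = nrow(scores)),
            class = "raw_pssm")
}

#' @export
print.raw_pssm <- function(x, ...) {
  cat(sprintf("<raw_pssm> %s: %d positions x 20 residues, scores in [%d, %d]\n",
              x$id, x$L, min(x$scores), max(x$scores)))
  invisible(x)
}

# map non-standard residues to standard ones; X/* fall back to the
# highest-scoring residue of the matching PSSM row when one is available
.map_nonstandard <- function(seq_chars, id, pssm = NULL) {
  subst <- c(B = "N", Z = "Q", U = "C", O = "K")
  bad <- which(!seq_chars %in% pssm_residues())
  for (i in bad) {
    ch <- seq_chars[i]
    if (ch %in% names(subst)) {
      repl <- subst[[ch]]
    } else if (ch %in% c("X", "*")) {
      repl <- if (!is.null(pssm) && i <= nrow(pssm$scores))
        pssm_residues()[which.max(pssm$scores[i, ])] else "A"
    } else {
      stop("sequence '", id, "' contains unknown character '", ch,
           "' at position ", i)
    }
    seq_chars[i] <- repl
  }
  if (length(bad))
    warning("sequence '", id, "': mapped ", length(bad),
            " non-standard residue(s) at position(s) ",
            paste(head(bad, 5), collapse = ", "),
            if (length(bad) > 5) ", ..." else "")
  seq_chars
}

#' Read a FASTA file of protein sequences
#'
#' Multi-line sequences are supported. Non-standard residues are remapped
#' (B to N, Z to Q, U to C, O to K; X and `*` to alanine in the absence of a
#' profile) with a warning naming the record and positions.
#'
#' @param path FASTA file.
#' @return A data.frame with columns `id` and `sequence`, one row per entry,
#'   input order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no sequences in FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1])
    stop("malformed FASTA: line 1 does not start with '>': ", lines[1])
  if (!any(hdr)) stop("no sequences in FASTA file: ", path)
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  if (length(seqs) != length(ids) || any(!nzchar(seqs)))
    stop("malformed FASTA: entry with empty sequence in ", path)
  seqs <- toupper(gsub("[ \t]", "", seqs))
  seqs <- vapply(seq_along(seqs), function(i) {
    paste0(.map_nonstandard(strsplit(seqs[i], "")[[1]], ids[i]), collapse = "")
  }, "")
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' Read a two-column label table
#'
#' @param path TSV file with columns `id` and `label` (class index >= 0);
#'   a header row is optional and detected from the second field.
#' @return data.frame with columns `id` (character), `label` (integer).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- read.delim(path, header = FALSE, nrows = 1,
                      stringsAsFactors = FALSE)
  has_header <- is.na(suppressWarnings(as.integer(first[[2]])))
  d <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("label table must have two columns (id, label)")
  out <- data.frame(id = as.character(d[[1]]), label = as.integer(d[[2]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$label) || any(out$label < 0))
    stop("labels must be non-negative integers")
  out
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Accepts the standard 40-column NCBI layout (20 log-odds columns followed
#' by 20 percentage columns) as well as a bare 20-column layout; the dialect
#' is autodetected from the field count. Only the 20 log-odds columns are
#' returned. Positions are 1-based in all messages.
#'
#' @param path PSSM file.
#' @param id protein id; defaults to the file name without extension.
#' @param sequence optional protein sequence; when given, the PSSM residue
#'   column is cross-checked against it and a warning names the first
#'   mismatching position.
#' @return A [raw_pssm()] object.
#' @export
parse_psiblast_pssm <- function(path, id = NULL, sequence = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  rows <- list(); letters_col <- character()
  for (k in seq_along(lines)) {
    toks <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(toks) < 2) next
    # data rows start with the 1-based position index then the residue letter
    pos <- suppressWarnings(as.integer(toks[1]))
    if (is.na(pos) || !grepl("^[A-Za-z*]$", toks[2])) next
    num <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (anyNA(num))
      stop("PSSM parse error in ", basename(path), ": row ", pos,
           " (line ", k, ") has non-numeric score fields")
    # 20 = bare score columns; 40(+2) = NCBI layout with percentage columns
    # and optional trailing information/weight statistics
    if (!(length(num) == 20L || (length(num) >= 40L && length(num) <= 42L)))
      stop("PSSM parse error in ", basename(path), ": row ", pos,
           " (line ", k, ") has ", length(num),
           " numeric fields; expected 20 or 40")
    rows[[length(rows) + 1L]] <- num[1:20]
    letters_col <- c(letters_col, toupper(toks[2]))
  }
  if (!length(rows))
    stop("no PSSM data rows found in ", basename(path))
  scores <- do.call(rbind, rows)
  p <- raw_pssm(id, scores, residues = letters_col)
  if (!is.null(sequence)) {
    sc <- strsplit(toupper(sequence), "")[[1]]
    if (length(sc) != p$L) {
      warning("PSSM '", id, "' has ", p$L, " rows but the sequence has ",
              length(sc), " residues")
    } else {
      mism <- which(sc != letters_col)
      if (length(mism))
        warning("PSSM '", id, "' residue column disagrees with the FASTA ",
                "sequence, first mismatch at position ", mism[1])
    }
  }
  p
}

#' Write a PSSM in the NCBI ASCII dialect
#'
#' Emits the 40-column layout that [parse_psiblast_pssm()] accepts, with the
#' percentage columns synthesized as zeros; the round trip through the parser
#' reproduces the score matrix exactly.
#'
#' @param p a [raw_pssm()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pssm_fixture <- function(p, path) {
  stopifnot(inherits(p, "raw_pssm"))
  res <- pssm_residues()
  letters_col <- if (!is.null(p$residues)) p$residues
                 else res[apply(p$scores, 1, which.max)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%3s", res), collapse = " "), "  ",
           paste(sprintf("%3s", res), collapse = " "))), con)
  for (i in seq_len(p$L)) {
    writeLines(sprintf("%5d %s %s  %s  0.00 0.00", i, letters_col[i],
                       paste(sprintf("%3d", p$scores[i, ]), collapse = " "),
                       paste(sprintf("%3d", integer(20)), collapse = " ")),
               con)
  }
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1340     0.3172"), con)
  invisible(path)
}

#' Sigmoid normalization of a PSSM
#'
#' Maps every log-odds score x to f(x) = 1 / (1 + exp(-x)), so all entries
#' lie strictly in (0, 1) while the profile shape is preserved.
#'
#' @param p a [raw_pssm()] object or a numeric L x 20 matrix.
#' @return An object of class `norm_pssm` (elements `id`, `values`, `L`), or
#'   a plain matrix when `p` is a matrix.
#' @export
sigmoid_normalize <- function(p) {
  if (is.matrix(p)) return(1 / (1 + exp(-p)))
  stopifnot(inherits(p, "raw_pssm"))
  structure(list(id = p$id, values = 1 / (1 + exp(-p$scores)), L = p$L),
            class = "norm_pssm")
}

# feature extractors accept either a norm_pssm or a bare numeric matrix
.pssm_values <- function(p) {
  if (inherits(p, "norm_pssm")) return(p$values)
  if (inherits(p, "raw_pssm"))
    stop("pass a sigmoid-normalized PSSM (see sigmoid_normalize())")
  if (is.matrix(p)) return(p)
  stop("expected a norm_pssm object or a numeric matrix")
}

.pssm_id <- function(p) if (inherits(p, "norm_pssm")) p$id else "<matrix>"
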