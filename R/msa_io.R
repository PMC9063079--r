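#' Read an aligned FASTA file
#'
#' Reads a multiple RNA sequence alignment. Sequences are normalized to
#' uppercase, `T` becomes `U`, and `.` or `_` gap characters become `-`.
#' Any residue outside `A`, `C`, `G`, `U`, `-` after normalization is an
#' error naming the record and column.
#'
#' @param path Path to an aligned FASTA file with at least two records of
#'   identical length.
#' @return An object of class `rna_alignment`: list with `ids` (character),
#'   `rows` (character vector of aligned sequences), `n` (number of
#'   sequences) and `n_a` (alignment length). The character matrix view is
#'   available through [alignment_matrix()].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    ids <- names(set)
    rows <- as.character(set)
  } else {
    parsed <- read_fasta_lines(readLines(path))
    ids <- parsed$ids
    rows <- parsed$rows
  }
  ids <- sub("\\s.*$", "", ids)
  rna_alignment(ids, rows)
}

# Minimal FASTA fallback used only when Biostrings is unavailable.
read_fasta_lines <- function(lines) {
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file (no '>' headers)", call. = FALSE)
  grp <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  rows <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  list(ids = ids, rows = unname(rows))
}

#' Construct an alignment from ids and rows
#'
#' @param ids Sequence identifiers.
#' @param rows Aligned sequences (equal lengths) over `A C G U T a c g u t
#'   - . _`; normalized as in [read_alignment()].
#' @return An `rna_alignment`.
#' @export
rna_alignment <- function(ids, rows) {
  stopifnot(length(ids) == length(rows))
  if (length(rows) < 1L) stop("alignment needs at least one record", call. = FALSE)
  rows <- toupper(rows)
  rows <- gsub("T", "U", rows, fixed = TRUE)
  rows <- unname(gsub("[._]", "-", rows))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("aligned rows have unequal lengths: ",
         paste(unique(widths), collapse = ", "), call. = FALSE)
  }
  n_a <- widths[1L]
  if (n_a < 1L) stop("alignment length must be >= 1", call. = FALSE)
  for (r in seq_along(rows)) {
    ch <- strsplit(rows[r], "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% c("A", "C", "G", "U", "-"))
    if (length(bad)) {
      stop(sprintf("illegal residue '%s' in record '%s' at column %d",
                   ch[bad[1L]], ids[r], bad[1L]), call. = FALSE)
    }
  }
  structure(list(ids = as.character(ids), rows = unname(rows),
                 n = length(rows), n_a = n_a),
            class = "rna_alignment")
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat("<rna_alignment> ", x$n, " sequences, alignment length ", x$n_a, "\n",
      sep = "")
  show <- utils::head(seq_len(x$n), 5L)
  for (r in show) {
    row <- if (x$n_a > 60L) paste0(substr(x$rows[r], 1L, 57L), "...") else x$rows[r]
    cat(format(substr(x$ids[r], 1L, 12L), width = 14L), row, "\n", sep = "")
  }
  if (x$n > 5L) cat("... ", x$n - 5L, " more\n", sep = "")
  invisible(x)
}

#' Character-matrix view of an alignment
#'
#' @param aln An `rna_alignment`.
#' @return `n x n_a` character matrix.
#' @export
alignment_matrix <- function(aln) {
  stopifnot(inherits(aln, "rna_alignment"))
  do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
}

#' Write an aligned FASTA file
#'
#' @param aln An `rna_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "rna_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(aln$n)) {
    writeLines(c(paste0(">", aln$ids[r]), aln$rows[r]), con)
  }
  invisible(path)
}

#' Write per-sequence structure predictions
#'
#' One block per record: a `>` header, the ungapped sequence, the
#' dot-bracket structure, and a line `# energy <kcal/mol>`. Records keep
#' their input order so output is deterministic.
#'
#' @param predictions A data frame with columns `id`, `sequence`,
#'   `structure` (dot-bracket strings) and `energy`, e.g. the output of
#'   [predict_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(all(c("id", "sequence", "structure", "energy") %in%
                  names(predictions)))
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(predictions))) {
    writeLines(c(paste0(">", predictions$id[r]),
                 predictions$sequence[r],
                 predictions$structure[r],
                 sprintf("# energy %.4f", predictions$energy[r])), con)
  }
  invisible(path)
}

#' Read a predictions file written by [write_predictions()]
#'
#' @param path Path to a predictions file.
#' @return A tibble with columns `id`, `sequence`, `structure`, `energy`.
#' @export
read_predictions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(id = character(0), sequence = character(0),
                          structure = character(0), energy = numeric(0)))
  }
  starts <- grep("^>", lines)
  if (!length(starts) || any(diff(starts) != 4L) ||
      starts[1L] != 1L || length(lines) %% 4L != 0L) {
    stop("malformed predictions file: expected 4-line blocks", call. = FALSE)
  }
  tibble::tibble(
    id = sub("^>", "", lines[starts]),
    sequence = lines[starts + 1L],
    structure = lines[starts + 2L],
    energy = as.numeric(sub("^# energy ", "", lines[starts + 3L]))
  )
}

#' Read reference structures in dot-bracket form
#'
#' Format: per record, a `>` header line followed by one dot-bracket line
#' (bracket layers allowed). A plain list of dot-bracket lines (no headers)
#' is also accepted.
#'
#' @param path Path to a dot-bracket file.
#' @return A named list of [rna_structure()] objects.
#' @export
read_structures <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (any(grepl("^>", lines))) {
    starts <- grep("^>", lines)
    ids <- sub("^>", "", lines[starts])
    sts <- lapply(lines[starts + 1L], parse_dotbracket)
    names(sts) <- ids
  } else {
    sts <- lapply(lines, parse_dotbracket)
    names(sts) <- paste0("structure_", seq_along(sts))
  }
  sts
}
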