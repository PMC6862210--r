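#' @keywords internal
"_PACKAGE"

#' The 21-letter amino-acid alphabet
#'
#' The 20 standard residues plus `X` for any residue that cannot be assigned
#' to a standard type. All sequence handling in the package is closed over
#' this alphabet.
#'
#' @return Character vector of 21 single-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
    "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")
}

# Ambiguity / non-standard codes folded into X on input.
.nonstandard_codes <- c("B", "Z", "J", "U", "O", "*")

#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file, upper-cases residues, strips
#' whitespace inside records, and maps non-standard letters (`B`, `Z`, `J`,
#' `U`, `O`, `*`) to `X` so that every sequence is closed over the 21-letter
#' alphabet of [aa_alphabet()]. The number of remapped residues is reported
#' with a warning so silent alphabet coercion never goes unnoticed.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `id` (the first whitespace-delimited
#'   token of each header) and `residues`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "AGAR", ">p2", "MKV"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  seqs <- toupper(gsub("[ \t\r]", "", as.character(set)))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for record(s): ", paste(ids[empty], collapse = ", "),
         call. = FALSE)
  }
  n_mapped <- 0L
  for (code in .nonstandard_codes) {
    n_mapped <- n_mapped +
      sum(vapply(gregexpr(code, seqs, fixed = TRUE),
                 function(m) sum(m > 0L), integer(1)))
    seqs <- gsub(code, "X", seqs, fixed = TRUE)
  }
  if (n_mapped > 0L) {
    warning(n_mapped, " non-standard residue letter(s) mapped to X",
            call. = FALSE)
  }
  bad <- grepl(paste0("[^", paste(aa_alphabet(), collapse = ""), "]"), seqs)
  if (any(bad)) {
    stop("invalid residue letters in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(id = unname(ids), residues = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs A `data.frame` with columns `id` and `residues`.
#' @param path Output path.
#' @param width Line-wrap width for residue lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$id[i]), con)
    s <- seqs$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read sequence class annotations
#'
#' Reads a two-column tab-separated table with header
#' `sequence_id<TAB>class_id`. A `class_id` is either an EC `class.subclass`
#' string (`"c.s"` with class digit 1--7 and a positive integer subclass,
#' e.g. `"3.4"`) or the literal `"non-enzyme"`.
#'
#' @param path Path to the annotation TSV.
#' @param sequences Optional `data.frame` from [read_fasta()]; if supplied,
#'   every annotated id must name a loaded sequence.
#' @return A `data.frame` with columns `sequence_id` and `class_id`.
#' @export
read_annotations <- function(path, sequences = NULL) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (!all(c("sequence_id", "class_id") %in% names(ann))) {
    stop("annotation file must have columns sequence_id and class_id",
         call. = FALSE)
  }
  ann <- ann[, c("sequence_id", "class_id")]
  bad <- which(!is_valid_class_id(ann$class_id))
  if (length(bad) > 0L) {
    stop("malformed class_id '", ann$class_id[bad[1]], "' at line ",
         bad[1] + 1L, call. = FALSE)
  }
  dup <- duplicated(ann$sequence_id)
  if (any(dup)) {
    stop("duplicate sequence_id(s): ",
         paste(unique(ann$sequence_id[dup]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(sequences)) {
    missing <- setdiff(ann$sequence_id, sequences$id)
    if (length(missing) > 0L) {
      stop("annotated id(s) not present in sequences: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  ann
}

#' Validate EC class identifiers
#'
#' @param class_id Character vector.
#' @return Logical vector: `TRUE` where the string is `"non-enzyme"` or a
#'   valid `"c.s"` EC class.subclass pair with 1 <= c <= 7.
#' @export
is_valid_class_id <- function(class_id) {
  ec <- grepl("^[1-7]\\.[0-9]+$", class_id) &
    !grepl("\\.0+$", class_id)
  ec | class_id == "non-enzyme"
}

#' Write annotations to TSV
#'
#' @param ann `data.frame` with `sequence_id`, `class_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann[, c("sequence_id", "class_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Validate a residue string over the package alphabet; returns it upper-cased.
check_residues <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("empty sequence", call. = FALSE)
  if (grepl(paste0("[^", paste(aa_alphabet(), collapse = ""), "]"), residues)) {
    stop("residues outside the 21-letter alphabet", call. = FALSE)
  }
  residues
}
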