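## Sequence containers and FASTA input/output.
##
## A `protein_alignment` is a character matrix (one row per sequence, one
## column per aligned position) over the 20 amino-acid letters plus '-' (gap)
## and 'X' (unknown), with unique rownames. Nucleotide sequences are kept as
## a named character vector over {A,C,G,T,N}. All coordinates reported by the
## package are 0-based, half-open.

AA_LETTERS <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                "P","S","T","W","Y","V")
AA_ALPHABET <- c(AA_LETTERS, "-", "X")
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read sequences from a FASTA file
#'
#' Reads protein or nucleotide FASTA. Identifiers and residues are preserved
#' verbatim except that surrounding whitespace is stripped and residues are
#' uppercased. Duplicate identifiers and empty records are errors.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`; controls validation only.
#' @return A named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- if (alphabet == "protein") {
    Biostrings::readBStringSet(path)
  } else {
    Biostrings::readBStringSet(path)
  }
  ids <- trimws(sub("\\s.*$", "", names(set)))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty record: ", ids[nchar(seqs) == 0L][1L])
  }
  ok <- if (alphabet == "protein") AA_ALPHABET else DNA_ALPHABET
  bad <- setdiff(unique(unlist(strsplit(seqs, "", fixed = TRUE))), ok)
  if (length(bad)) {
    stop("unexpected ", alphabet, " letter(s): ", paste(bad, collapse = ", "))
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param x Named character vector of sequences, or a [protein_alignment()].
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (inherits(x, "protein_alignment")) x <- alignment_strings(x)
  stopifnot(is.character(x), !is.null(names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a protein alignment
#'
#' @param seqs Named character vector of equal-length aligned sequences over
#'   the amino-acid alphabet plus `-` and `X`.
#' @return A `protein_alignment`: character matrix, sequences in rows.
#' @export
protein_alignment <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence id: ", names(seqs)[duplicated(names(seqs))][1L])
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("aligned sequences must share one length")
  if (lens[1L] < 1L) stop("alignment must have at least one column")
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  bad <- setdiff(unique(as.vector(m)), AA_ALPHABET)
  if (length(bad)) stop("unexpected residue(s): ", paste(bad, collapse = ", "))
  structure(m, class = "protein_alignment")
}

#' Read an aligned protein FASTA file
#'
#' @inheritParams read_fasta
#' @return A [protein_alignment()].
#' @export
read_protein_alignment <- function(path) {
  protein_alignment(read_fasta(path, "protein"))
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("protein alignment:", nrow(x), "sequences x", ncol(x), "positions\n")
  invisible(x)
}

## rows as strings, names preserved
alignment_strings <- function(aln) {
  stats::setNames(apply(unclass(aln), 1L, paste, collapse = ""), rownames(aln))
}

#' Drop gap-rich alignment columns
#'
#' Keeps columns whose gap fraction is at most `max_gap`, preserving column
#' order. This is a naive completeness filter, not a homoplasy filter;
#' externally refined alignments are consumed as given.
#'
#' @param aln A [protein_alignment()].
#' @param max_gap Maximum tolerated gap fraction per column, in `[0, 1]`.
#' @return The filtered `protein_alignment`, with the 0-based indices of the
#'   kept columns in attribute `"kept_columns"`.
#' @export
gap_fraction_filter <- function(aln, max_gap) {
  stopifnot(inherits(aln, "protein_alignment"),
            is.numeric(max_gap), max_gap >= 0, max_gap <= 1)
  gf <- colMeans(unclass(aln) == "-")
  keep <- which(gf <= max_gap)
  if (length(keep) == 0L) stop("gap filter removed every column")
  out <- unclass(aln)[, keep, drop = FALSE]
  class(out) <- "protein_alignment"
  attr(out, "kept_columns") <- keep - 1L
  out
}

#' Read a lineage metadata table
#'
#' Tab-separated text with header columns `lineage_id`, `species`, `clade`
#' (clade one of A, B, C, D or `unknown`).
#'
#' @param path Path to a TSV file.
#' @return A data frame with columns `lineage_id`, `species`, `clade`.
#' @export
read_lineage_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lineage_table(tab)
}

#' Validate a lineage table
#'
#' @param tab Data frame with columns `lineage_id`, `species`, `clade`.
#' @return The validated data frame.
#' @export
lineage_table <- function(tab) {
  need <- c("lineage_id", "species", "clade")
  if (!all(need %in% names(tab))) {
    stop("lineage table needs columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[, need]
  if (anyDuplicated(tab$lineage_id)) {
    stop("duplicate lineage_id: ", tab$lineage_id[duplicated(tab$lineage_id)][1L])
  }
  bad <- setdiff(unique(tab$clade), c("A", "B", "C", "D", "unknown"))
  if (length(bad)) stop("unknown clade label(s): ", paste(bad, collapse = ", "))
  tab
}
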