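## Structural annotation of R2 elements.
##
## The N-terminal zinc-finger (ZF) complement separates the four R2 clades:
## three motifs CCHH;CCHC;CCHH (positions I, II, III) for clade A, motifs
## II+III (CCHC;CCHH) for clade B, I+III (CCHH;CCHH) for clade C and a
## single motif III (CCHH) for clade D. R2 inserts into the 28S rRNA gene at
## 5'-TTAAGG|TAGCCA-3'; the junction detector pairs the two half-sites
## around an inserted element. All reported coordinates are 0-based,
## half-open.

#' Zinc-finger spacing grammar
#'
#' Spacing ranges for `C-x(a..b)-C-x(c..d)-H-x(e..f)-[H|C]`. The defaults
#' follow canonical C2H2 / CCHC spacings; only the residue types, not the
#' spacings, are diagnostic, so the grammar is configuration.
#'
#' @param c_spacer Range (min, max) of residues between the two cysteines.
#' @param h_spacer Range between the second cysteine and the first
#'   histidine.
#' @param end_spacer Range between the first histidine and the final
#'   coordinating residue (H for CCHH, C for CCHC).
#' @return A `zf_grammar` list.
#' @export
zf_grammar <- function(c_spacer = c(1L, 5L), h_spacer = c(8L, 17L),
                       end_spacer = c(2L, 6L)) {
  stopifnot(c_spacer[1L] >= 0L, c_spacer[1L] <= c_spacer[2L],
            h_spacer[1L] >= 0L, h_spacer[1L] <= h_spacer[2L],
            end_spacer[1L] >= 0L, end_spacer[1L] <= end_spacer[2L])
  structure(list(c_spacer = as.integer(c_spacer),
                 h_spacer = as.integer(h_spacer),
                 end_spacer = as.integer(end_spacer)),
            class = "zf_grammar")
}

#' Scan a protein for N-terminal zinc-finger motifs
#'
#' Greedy leftmost scan within the first `window` residues: at each
#' cysteine, the first (smallest-offset) completion of the grammar is
#' accepted and scanning resumes after the motif's end, so reported motifs
#' never overlap and appear in N-to-C order.
#'
#' @param protein Amino-acid string.
#' @param window Motifs must start within the first `window` residues.
#' @param grammar A [zf_grammar()].
#' @return Data frame with one motif per row: `type` (`CCHH`/`CCHC`),
#'   `start`, `end` (0-based half-open span), and the 0-based offsets of
#'   the four coordinating residues.
#' @export
scan_zinc_fingers <- function(protein, window = 450L, grammar = zf_grammar()) {
  if (!is.character(protein) || length(protein) != 1L || nchar(protein) == 0L) {
    stop("protein must be a single non-empty string")
  }
  res <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  n <- length(res)
  limit <- min(window, n)
  hits <- list()
  i <- 1L
  while (i <= limit) {
    if (res[i] == "C") {
      m <- .match_zf_at(res, i, n, grammar)
      if (!is.null(m)) {
        hits[[length(hits) + 1L]] <- m
        i <- m$end + 1L     # resume after motif end (m$end is 0-based open)
        next
      }
    }
    i <- i + 1L
  }
  if (length(hits) == 0L) {
    return(data.frame(type = character(0), start = integer(0), end = integer(0),
                      c1 = integer(0), c2 = integer(0),
                      h1 = integer(0), x4 = integer(0)))
  }
  do.call(rbind, lapply(hits, as.data.frame))
}

## first grammar completion anchored at 1-based position i, or NULL
.match_zf_at <- function(res, i, n, g) {
  for (s1 in g$c_spacer[1L]:g$c_spacer[2L]) {
    p2 <- i + 1L + s1
    if (p2 > n || res[p2] != "C") next
    for (s2 in g$h_spacer[1L]:g$h_spacer[2L]) {
      p3 <- p2 + 1L + s2
      if (p3 > n || res[p3] != "H") next
      for (s3 in g$end_spacer[1L]:g$end_spacer[2L]) {
        p4 <- p3 + 1L + s3
        if (p4 > n) next
        if (res[p4] == "H" || res[p4] == "C") {
          return(list(type = if (res[p4] == "H") "CCHH" else "CCHC",
                      start = i - 1L, end = p4,
                      c1 = i - 1L, c2 = p2 - 1L, h1 = p3 - 1L, x4 = p4 - 1L))
        }
      }
    }
  }
  NULL
}

#' Call the R2 clade from an ordered zinc-finger pattern
#'
#' `CCHH,CCHC,CCHH` (motifs I+II+III) is clade A; `CCHC,CCHH` (II+III) is
#' clade B; `CCHH,CCHH` (I+III) is clade C; a lone `CCHH` (III) is clade D.
#' Any other pattern yields `unknown` (a value, not an error).
#'
#' @param motifs Character vector of motif types in N-to-C order, or a data
#'   frame from [scan_zinc_fingers()].
#' @return A `zf_annotation` list: `motifs`, `classes` (subset of I/II/III),
#'   `clade`.
#' @export
call_clade <- function(motifs) {
  if (is.data.frame(motifs)) motifs <- motifs$type
  key <- paste(motifs, collapse = ",")
  map <- list(
    "CCHH,CCHC,CCHH" = list(clade = "A", classes = c("I", "II", "III")),
    "CCHC,CCHH"      = list(clade = "B", classes = c("II", "III")),
    "CCHH,CCHH"      = list(clade = "C", classes = c("I", "III")),
    "CCHH"           = list(clade = "D", classes = "III")
  )
  hit <- map[[key]]
  if (is.null(hit)) hit <- list(clade = "unknown", classes = character(0))
  structure(list(motifs = motifs, classes = hit$classes, clade = hit$clade),
            class = "zf_annotation")
}

#' @export
print.zf_annotation <- function(x, ...) {
  cat("zinc fingers:", if (length(x$motifs)) paste(x$motifs, collapse = "; ")
      else "none",
      "-> clade", x$clade,
      if (length(x$classes)) paste0("(", paste(x$classes, collapse = "+"), ")")
      else "", "\n")
  invisible(x)
}

R2_TARGET_MOTIF <- "TTAAGGTAGCCA"

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

## Hamming scan of `motif` over one strand; returns 0-based window starts
## and mismatch counts
.hamming_scan <- function(seqchars, motif, max_mismatch) {
  m <- nchar(motif)
  n <- length(seqchars)
  if (n < m) return(data.frame(start = integer(0), mismatches = integer(0)))
  mot <- strsplit(motif, "", fixed = TRUE)[[1]]
  mism <- integer(n - m + 1L)
  for (k in seq_len(m)) {
    mism <- mism + (seqchars[k:(n - m + k)] != mot[k])
  }
  keep <- which(mism <= max_mismatch)
  data.frame(start = keep - 1L, mismatches = mism[keep])
}

#' Find 28S target sites
#'
#' Reports every window of the sequence within Hamming distance
#' `max_mismatch` of the target motif. The cleavage coordinate is the
#' junction between the upstream (`TTAAGG`) and downstream (`TAGCCA`)
#' half-sites, i.e. window start + 6 on the forward strand. Flanks of
#' `flank` nucleotides are extracted on both sides of the cleavage point;
#' flanks shortened by a sequence end are flagged.
#'
#' @param seq A nucleotide string, or a named length-1 character vector.
#' @param motif Target motif (length >= 8).
#' @param max_mismatch Maximum Hamming mismatches (>= 0).
#' @param flank Flank width in nucleotides.
#' @param strand `"both"` (default) or `"plus"`.
#' @return Data frame sorted by coordinate: `cleavage` (0-based), `strand`,
#'   `mismatches`, `upstream_flank`, `downstream_flank`, `truncated`.
#' @export
find_target_sites <- function(seq, motif = R2_TARGET_MOTIF, max_mismatch = 0L,
                              flank = 20L, strand = c("both", "plus")) {
  strand <- match.arg(strand)
  stopifnot(max_mismatch >= 0L, nchar(motif) >= 8L)
  s <- toupper(if (is.null(names(seq))) seq else seq[[1L]])
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  half <- 6L  # cleavage offset inside the canonical motif (after TTAAGG)
  strands <- if (strand == "both") c("+", "-") else "+"
  rows <- list()
  for (st in strands) {
    pat <- if (st == "+") motif else revcomp(motif)
    hits <- .hamming_scan(chars, pat, max_mismatch)
    if (nrow(hits) == 0L) next
    cleav <- if (st == "+") hits$start + half else hits$start + (nchar(motif) - half)
    up0 <- pmax(cleav - flank, 0L)
    dn1 <- pmin(cleav + flank, n)
    rows[[st]] <- data.frame(
      cleavage = cleav, strand = st, mismatches = hits$mismatches,
      upstream_flank = substring(s, up0 + 1L, cleav),
      downstream_flank = substring(s, cleav + 1L, dn1),
      truncated = (cleav - up0 < flank) | (dn1 - cleav < flank),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(cleavage = integer(0), strand = character(0),
                      mismatches = integer(0), upstream_flank = character(0),
                      downstream_flank = character(0), truncated = logical(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cleavage, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect R2 insertion junctions in an rDNA-like locus
#'
#' An insertion leaves the two target half-sites separated:
#' `...TTAAGG + element + TAGCCA...`. Each upstream half-site hit (`AAGG`
#' exact, its `TT` context allowed up to `max_mismatch` mismatches) is
#' paired with the nearest downstream `TAGC` that is either adjacent
#' (an intact, uninserted site) or at least `min_element` away (an
#' insertion). A junction with a second upstream half-site between its two
#' half-sites is flagged ambiguous.
#'
#' @param locus Nucleotide string.
#' @param max_mismatch Mismatches tolerated in the `TT` context.
#' @param min_element Minimum element length for pairing (nt).
#' @return Data frame: `cleavage` (0-based junction coordinate),
#'   `insert_start`, `insert_end` (0-based half-open inserted interval),
#'   `element_length`, `uninserted`, `ambiguous`.
#' @export
detect_insertion_junctions <- function(locus, max_mismatch = 0L,
                                       min_element = 100L) {
  s <- toupper(if (is.null(names(locus))) locus else locus[[1L]])
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  up <- .hamming_scan(chars, "TTAAGG", max_mismatch + 4L)
  ## AAGG (positions 3..6 of the 6-mer) must be exact; TT may mismatch
  exact_aagg <- vapply(up$start, function(st) {
    identical(chars[(st + 3L):(st + 6L)], c("A", "A", "G", "G"))
  }, TRUE)
  tt_mism <- vapply(up$start, function(st) {
    sum(chars[(st + 1L):(st + 2L)] != c("T", "T"))
  }, 0L)
  up <- up[exact_aagg & tt_mism <= max_mismatch, , drop = FALSE]
  down_start <- .hamming_scan(chars, "TAGC", 0L)$start
  rows <- list()
  for (u in up$start) {
    cleav <- u + 6L
    cand <- down_start[down_start >= cleav]
    if (length(cand) == 0L) next
    d <- if (cand[1L] == cleav) cleav else {
      far <- cand[cand - cleav >= min_element]
      if (length(far) == 0L) next
      far[1L]
    }
    ambiguous <- any(up$start > u & up$start + 6L < d)
    rows[[length(rows) + 1L]] <- data.frame(
      cleavage = cleav, insert_start = cleav, insert_end = d,
      element_length = d - cleav, uninserted = d == cleav,
      ambiguous = ambiguous)
  }
  if (length(rows) == 0L) {
    return(data.frame(cleavage = integer(0), insert_start = integer(0),
                      insert_end = integer(0), element_length = integer(0),
                      uninserted = logical(0), ambiguous = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster sequences into families at an identity threshold
#'
#' Pairwise identity is matches over alignment columns of a global
#' (Needleman-Wunsch) alignment, indels counted in the denominator.
#' Single-linkage components of the graph with an edge wherever identity
#' exceeds `threshold` are the families; each family is named after its
#' lexicographically smallest member.
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param threshold Identity threshold; an edge requires identity strictly
#'   greater than it.
#' @return Data frame with columns `id` and `family`.
#' @export
cluster_families <- function(seqs, threshold = 0.90) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  ids <- names(seqs)
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        pa <- Biostrings::pairwiseAlignment(
          seqs[[i]], seqs[[j]], type = "global",
          substitutionMatrix = mat, gapOpening = 2, gapExtension = 1)
        ident <- Biostrings::pid(pa, type = "PID1") / 100
        if (ident > threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  fam <- vapply(split(ids, roots), min, "")
  data.frame(id = ids, family = unname(fam[as.character(roots)]),
             stringsAsFactors = FALSE)
}

#' Annotate an R2 protein end to end
#'
#' Convenience wrapper: scan the N-terminus for zinc fingers and call the
#' clade.
#'
#' @inheritParams scan_zinc_fingers
#' @return A `zf_annotation` with the motif table in attribute `"motifs_table"`.
#' @export
annotate_zinc_fingers <- function(protein, window = 450L, grammar = zf_grammar()) {
  tab <- scan_zinc_fingers(protein, window, grammar)
  ann <- call_clade(tab)
  attr(ann, "motifs_table") <- tab
  ann
}
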