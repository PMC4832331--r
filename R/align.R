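#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch dynamic programming under a substitution matrix and
#' affine gap model in which a gap of length k costs `gap_open + k *
#' gap_ext`. With `end_gaps = FALSE` terminal gap runs are free
#' (semi-global scoring, the convention behind most published percent
#' identities for near-full-length homologues).
#'
#' @param a,b Sequences: single (optionally named) amino-acid strings over
#'   the 20-letter alphabet plus X.
#' @param matrix Substitution matrix; defaults to [blosum62()].
#' @param gap_open,gap_ext Gap opening and extension penalties (positive).
#' @param end_gaps Penalize terminal gaps? Default `TRUE` (classic global
#'   alignment).
#' @return An object of class `pairwise_alignment`: a list with gapped
#'   strings `a` and `b`, `score`, sequence ids, and the scoring parameters.
#' @examples
#' aln <- global_align(c(s1 = "HEAGAWGHEE"), c(s2 = "PAWHEAE"))
#' percent_identity(aln)
#' @export
global_align <- function(a, b, matrix = blosum62(),
                         gap_open = 10, gap_ext = 0.5, end_gaps = TRUE) {
  id_a <- if (!is.null(names(a))) names(a)[1] else "a"
  id_b <- if (!is.null(names(b))) names(b)[1] else "b"
  a <- unname(a[1]); b <- unname(b[1])
  if (!nzchar(a) || !nzchar(b))
    stop("both sequences must be non-empty", call. = FALSE)
  check_aa(a, id_a); check_aa(b, id_b)
  S <- matrix[AA_ALPHA, AA_ALPHA]
  res <- nw_pair_cpp(aa_encode(a), aa_encode(b), S,
                     gap_open, gap_ext, end_gaps)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ga <- ifelse(res$ai == 0L, GAP, ca[pmax(res$ai, 1L)])
  gb <- ifelse(res$bi == 0L, GAP, cb[pmax(res$bi, 1L)])
  structure(list(a = paste(ga, collapse = ""),
                 b = paste(gb, collapse = ""),
                 score = res$score, id_a = id_a, id_b = id_b,
                 gap_open = gap_open, gap_ext = gap_ext,
                 end_gaps = end_gaps),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, width = 60, ...) {
  cat(sprintf("Global alignment  %s / %s  score = %.1f\n",
              x$id_a, x$id_b, x$score))
  cat(sprintf("identity %.1f%%  similarity %.1f%%  length %d\n",
              percent_identity(x), percent_similarity(x), nchar(x$a)))
  ca <- strsplit(x$a, "")[[1]]; cb <- strsplit(x$b, "")[[1]]
  for (s in seq(1, length(ca), by = width)) {
    e <- min(s + width - 1, length(ca))
    cat(substr(x$a, s, e), "\n")
    mid <- ifelse(ca[s:e] == cb[s:e] & ca[s:e] != GAP, "|", " ")
    cat(paste(mid, collapse = ""), "\n")
    cat(substr(x$b, s, e), "\n\n")
  }
  invisible(x)
}

aligned_pairs <- function(aln) {
  ca <- strsplit(aln$a, "")[[1]]
  cb <- strsplit(aln$b, "")[[1]]
  keep <- !(ca == GAP & cb == GAP)
  list(a = ca[keep], b = cb[keep])
}

#' Percent identity of a pairwise alignment
#'
#' Identical residue pairs over all alignment columns except those gapped in
#' both rows; a gap aligned to a residue counts in the denominator.
#'
#' @param aln A `pairwise_alignment`.
#' @return Percentage in \[0, 100\].
#' @export
percent_identity <- function(aln) {
  p <- aligned_pairs(aln)
  n <- length(p$a)
  if (n == 0) stop("alignment has no aligned columns", call. = FALSE)
  100 * sum(p$a == p$b & p$a != GAP) / n
}

#' Percent similarity of a pairwise alignment
#'
#' Residue pairs that are identical or score positively under the
#' substitution matrix, over the same denominator as [percent_identity()].
#'
#' @param aln A `pairwise_alignment`.
#' @param matrix Substitution matrix; defaults to [blosum62()].
#' @return Percentage in \[0, 100\].
#' @export
percent_similarity <- function(aln, matrix = blosum62()) {
  p <- aligned_pairs(aln)
  n <- length(p$a)
  if (n == 0) stop("alignment has no aligned columns", call. = FALSE)
  res <- p$a != GAP & p$b != GAP
  sim <- logical(n)
  idx <- which(res)
  sim[idx] <- p$a[idx] == p$b[idx] | matrix[cbind(p$a[idx], p$b[idx])] > 0
  100 * sum(sim) / n
}

#' Construct a multiple alignment object
#'
#' A thin container: a named character vector of equal-length gapped rows.
#'
#' @param rows Named character vector of gapped sequences, equal widths.
#' @return An object of class `ldc_msa`.
#' @export
ldc_msa <- function(rows) {
  stopifnot(is.character(rows), !is.null(names(rows)))
  w <- nchar(rows)
  if (length(unique(w)) != 1)
    stop("alignment rows must all have the same width", call. = FALSE)
  structure(rows, class = "ldc_msa")
}

#' @export
print.ldc_msa <- function(x, ...) {
  cat(sprintf("Multiple alignment: %d sequences x %d columns\n",
              length(x), nchar(x[1])))
  show <- utils::head(seq_along(x), 8)
  for (i in show)
    cat(sprintf("  %-12s %s%s\n", names(x)[i],
                substr(x[i], 1, 56), if (nchar(x[i]) > 56) "..." else ""))
  if (length(x) > 8) cat(sprintf("  ... and %d more\n", length(x) - 8))
  invisible(x)
}

#' Alignment as a character matrix (rows = sequences, columns = positions)
#' @param aln An `ldc_msa`.
#' @return Character matrix with row names.
#' @export
msa_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Map alignment columns to the residue numbering of a reference row
#'
#' Every non-gap position of the reference sequence receives exactly one
#' alignment column; gap columns of the reference are unmapped.
#'
#' @param aln An `ldc_msa`.
#' @param reference_id Name of the reference row.
#' @return A `reference_map`: data.frame with `column` (1-based alignment
#'   column) and `residue` (1-based reference residue number).
#' @export
map_to_reference <- function(aln, reference_id) {
  if (!reference_id %in% names(aln))
    stop(sprintf("reference '%s' not found in alignment", reference_id),
         call. = FALSE)
  chars <- strsplit(unclass(aln)[[reference_id]], "")[[1]]
  cols <- which(chars != GAP)
  structure(data.frame(column = cols, residue = seq_along(cols)),
            class = c("reference_map", "data.frame"),
            reference_id = reference_id)
}

# alignment columns holding the given reference residue numbers (NA if the
# residue is outside the mapped range)
ref_columns <- function(refmap, residues) {
  refmap$column[match(residues, refmap$residue)]
}

#' Write an alignment in Clustal format
#'
#' @param aln An `ldc_msa`.
#' @param file Output path.
#' @param width Residues per block line.
#' @return Invisibly, `file`.
#' @export
write_clustal <- function(aln, file, width = 60) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("CLUSTAL multiple sequence alignment\n", con)
  L <- nchar(aln[1])
  pad <- max(nchar(names(aln))) + 3
  for (s in seq(1, L, by = width)) {
    e <- min(s + width - 1, L)
    for (i in seq_along(aln))
      writeLines(sprintf("%-*s%s", pad, names(aln)[i],
                         substr(aln[i], s, e)), con)
    writeLines("", con)
  }
  invisible(file)
}

#' Pairwise percent-identity matrix for a set of sequences
#'
#' Aligns every pair globally and tabulates [percent_identity()]; the
#' `min` and `mean` over distinct pairs are attached as attributes, the
#' summary behind statements like "these genes share more than 65%
#' identity".
#'
#' @param seqs Named character vector of protein sequences.
#' @param ... Passed to [global_align()].
#' @return Symmetric numeric matrix (diagonal 100) with attributes
#'   `min` and `mean`.
#' @export
percent_identity_matrix <- function(seqs, ...) {
  n <- length(seqs)
  M <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n)) {
      pid <- percent_identity(global_align(seqs[i], seqs[j], ...))
      M[i, j] <- M[j, i] <- pid
    }
  vals <- M[upper.tri(M)]
  attr(M, "min") <- min(vals)
  attr(M, "mean") <- mean(vals)
  M
}

#' Write a reference map as TSV
#' @param refmap A `reference_map`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_reference_map <- function(refmap, file) {
  write.table(as.data.frame(refmap), file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file)
}
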