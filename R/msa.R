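# Progressive multiple alignment: UPGMA guide tree on k-mer distances,
# then leaf-to-root profile-profile merges under the affine-gap DP in
# src/dp.cpp. Deliberately minimal: no iterative refinement.

kmer_counts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(table(character(0)))
  starts <- seq_len(n - k + 1)
  table(substring(seq, starts, starts + k - 1))
}

# fraction of k-mers (counted with multiplicity) shared between two
# sequences, turned into a distance in [0, 1]
kmer_distance_matrix <- function(seqs, k = 3) {
  n <- length(seqs)
  tabs <- lapply(seqs, kmer_counts, k = k)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      common <- intersect(names(tabs[[i]]), names(tabs[[j]]))
      shared <- sum(pmin(tabs[[i]][common], tabs[[j]][common]))
      denom <- min(nchar(seqs[i]), nchar(seqs[j])) - k + 1
      d <- if (denom > 0) 1 - shared / denom else 1
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# residue frequency profile of a set of gapped rows: 20 x L, column sums
# equal the non-gap occupancy of each alignment column
msa_profile <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(m)
  P <- matrix(0, length(AA20), L, dimnames = list(AA20, NULL))
  nr <- nrow(m)
  for (j in seq_len(L)) {
    tab <- table(factor(m[, j], levels = AA20))
    P[, j] <- as.numeric(tab) / nr
  }
  P
}

insert_gaps <- function(rows, gap_mask) {
  # gap_mask: logical over output columns, TRUE = insert a gap column
  out_len <- length(gap_mask)
  vapply(rows, function(r) {
    chars <- character(out_len)
    chars[gap_mask] <- GAP
    chars[!gap_mask] <- strsplit(r, "")[[1]]
    paste(chars, collapse = "")
  }, character(1))
}

#' Progressive multiple sequence alignment
#'
#' Builds a UPGMA guide tree from k-mer distances, then merges alignments
#' leaf-to-root by profile-profile Needleman-Wunsch with affine gaps.
#' Degapping any output row reproduces the corresponding input sequence
#' exactly.
#'
#' @param seqs Named character vector of two or more protein sequences.
#' @param matrix Substitution matrix; defaults to [blosum62()].
#' @param gap_open,gap_ext Affine gap penalties for the profile merges.
#' @param k k-mer length for the guide-tree distance (default 3).
#' @return An [ldc_msa()] in the input row order.
#' @export
progressive_msa <- function(seqs, matrix = blosum62(),
                            gap_open = 10, gap_ext = 0.5, k = 3) {
  if (length(seqs) < 2)
    stop("need at least two sequences", call. = FALSE)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names", call. = FALSE)
  for (i in seq_along(seqs)) check_aa(seqs[i], names(seqs)[i])

  if (length(seqs) == 2) {
    pa <- global_align(seqs[1], seqs[2], matrix, gap_open, gap_ext,
                       end_gaps = TRUE)
    return(ldc_msa(setNames(c(pa$a, pa$b), names(seqs))))
  }

  D <- kmer_distance_matrix(seqs, k)
  hc <- hclust(as.dist(D), method = "average")
  S20 <- matrix[AA20, AA20]

  # clusters[[i]]: named character vector of gapped rows
  clusters <- lapply(seq_along(seqs),
                     function(i) setNames(seqs[i], names(seqs)[i]))
  merged <- vector("list", nrow(hc$merge))
  pick <- function(idx) if (idx < 0) clusters[[-idx]] else merged[[idx]]
  for (s in seq_len(nrow(hc$merge))) {
    A <- pick(hc$merge[s, 1])
    B <- pick(hc$merge[s, 2])
    PA <- msa_profile(A); PB <- msa_profile(B)
    res <- nw_profile_cpp(S20 %*% PA, PB, gap_open, gap_ext)
    merged[[s]] <- c(insert_gaps(A, res$gapA), insert_gaps(B, res$gapB))
  }
  out <- merged[[nrow(hc$merge)]]
  ldc_msa(out[names(seqs)])
}
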