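# Independent oracles used to cross-check the package implementations.
# These deliberately use different formulations from the code under test:
# the alignment oracle is a top-down memoized three-state recursion over
# suffixes, the superposition oracle is Horn's quaternion method.

AA20_T <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) {
  paste(sample(AA20_T, n, replace = TRUE), collapse = "")
}

# Optimal global affine-gap alignment score by memoized recursion.
# A gap run of length k costs open + k * ext; with end_gaps = FALSE a
# single leading run and any trailing run are free.
nw_oracle <- function(a, b, S, open = 10, ext = 0.5, end_gaps = TRUE) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(i, j, prev) {
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i > n && j > m) {
      0
    } else if (i > n) {
      if (!end_gaps) 0
      else -(if (prev == "Iy") 0 else open) - (m - j + 1) * ext
    } else if (j > m) {
      if (!end_gaps) 0
      else -(if (prev == "Ix") 0 else open) - (n - i + 1) * ext
    } else {
      best <- S[ca[i], cb[j]] + rec(i + 1, j + 1, "M")
      free_a <- !end_gaps && prev %in% c("start", "leadA")
      best <- max(best, if (free_a) rec(i + 1, j, "leadA")
                  else -(ext + if (prev == "Ix") 0 else open) +
                    rec(i + 1, j, "Ix"))
      free_b <- !end_gaps && prev %in% c("start", "leadB")
      best <- max(best, if (free_b) rec(i, j + 1, "leadB")
                  else -(ext + if (prev == "Iy") 0 else open) +
                    rec(i, j + 1, "Iy"))
      best
    }
    memo[[key]] <- val
    val
  }
  rec(1, 1, "start")
}

# Horn quaternion method: optimal proper-rotation RMSD between two
# matched point sets.
horn_rmsd <- function(P, Q) {
  n <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sq <- (sum(Pc^2) + sum(Qc^2) - 2 * lam) / n
  sqrt(max(0, sq))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# reduced-scale study conditions for fast end-to-end runs: 160-residue
# proteins with the two signature strands scaled to [60,69] / [120,138]
reduced_params <- function(seed, n_per_group = 20) {
  simulation_params(
    n_taxa_per_group = n_per_group,
    seq_length = 160,
    signature_regions = list(c(60, 69), c(120, 138)),
    signature_table = data.frame(
      position = c(60L, 61L, 63L, 65L, 69L, 120L, 124L, 128L, 133L, 138L),
      groupA = c("D", "E", "R", "F", "IV", "Y", "N", "K", "W", "LM"),
      groupB = c("N", "Q", "T", "D", "KR", "K", "L", "E", "S", "DE"),
      stringsAsFactors = FALSE),
    seed = seed)
}

reduced_sigdef <- function() {
  signature_definition(c(60, 69), c(120, 138), reference_length = 160)
}

reference_data_path <- function(...) {
  system.file("extdata", "reference", ..., package = "ldcsig")
}
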