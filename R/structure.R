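# Domain-wise comparison of decamer models: Calpha reading, Kabsch
# superposition, and the in-context RMSD vs RMSD_min analysis that
# distinguishes the anchored wing domains from the swinging C-terminal
# domains.

#' The five-domain partition of a lysine-decarboxylase monomer
#'
#' E. coli LdcI numbering: wing 1-129, linker 130-183, PLP-binding
#' subdomain 184-417, subdomain 4 418-563, C-terminal domain 564-715.
#' The core domain is the union linker + PLP-SD + subdomain 4.
#'
#' @return Named list of `c(start, end)` intervals.
#' @export
domain_partition <- function() {
  p <- list(wing = c(1, 129), linker = c(130, 183),
            plp_sd = c(184, 417), subdomain4 = c(418, 563),
            ctd = c(564, 715))
  starts <- vapply(p, `[`, numeric(1), 1)
  ends <- vapply(p, `[`, numeric(1), 2)
  stopifnot(all(starts[-1] == ends[-length(ends)] + 1))
  p
}

#' Construct a Calpha structure model
#'
#' @param df Data frame with columns `chain`, `resno`, `x`, `y`, `z` and
#'   optionally `aa` (1-letter residue code, default `"A"`).
#' @return A `structure_model` data.frame.
#' @export
structure_model <- function(df) {
  needed <- c("chain", "resno", "x", "y", "z")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("structure model lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"aa" %in% names(df)) df$aa <- "A"
  if (anyDuplicated(df[c("chain", "resno")]))
    stop("duplicate (chain, residue) keys", call. = FALSE)
  if (!all(is.finite(as.matrix(df[c("x", "y", "z")]))))
    stop("non-finite coordinates", call. = FALSE)
  df <- df[order(df$chain, df$resno), ]
  rownames(df) <- NULL
  structure(df[c("chain", "resno", "aa", "x", "y", "z")],
            class = c("structure_model", "data.frame"))
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Calpha model: %d residues in %d chain(s) [%s]\n",
              nrow(x), length(unique(x$chain)),
              paste(sort(unique(x$chain)), collapse = "")))
  invisible(x)
}

#' Read Calpha coordinates from a PDB or mmCIF file
#'
#' Keeps one Calpha per residue: alternate locations are resolved to the
#' highest occupancy (ties to altloc 'A'); insertion codes are rejected.
#'
#' @param file Path to a `.pdb` / `.ent` or `.cif` file.
#' @return A [structure_model()].
#' @export
read_structure <- function(file) {
  ext <- tolower(tools::file_ext(file))
  obj <- if (ext %in% c("cif", "mmcif"))
    bio3d::read.cif(file, rm.alt = FALSE)
  else bio3d::read.pdb(file, rm.alt = FALSE)
  at <- obj$atom
  at <- at[at$elety == "CA" & at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no Calpha atoms in ", file, call. = FALSE)
  ins <- at$insert
  if (any(!is.na(ins) & nzchar(ins)))
    stop("insertion codes are not supported: ", file, call. = FALSE)
  # altloc resolution: highest occupancy, ties to '' then 'A'
  key <- paste(at$chain, at$resno)
  if (anyDuplicated(key)) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    alt <- ifelse(is.na(at$alt), "", at$alt)
    ord <- order(key, -occ, alt != "", alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno)), , drop = FALSE]
  }
  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  aa1[is.na(aa1) | !(aa1 %in% AA_ALPHA)] <- "X"
  structure_model(data.frame(chain = at$chain, resno = at$resno,
                             aa = aa1, x = at$x, y = at$y, z = at$z,
                             stringsAsFactors = FALSE))
}

#' Write a Calpha-only model as PDB or minimal mmCIF
#'
#' @param model A [structure_model()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_ca_pdb <- function(model, file) {
  aa3 <- bio3d::aa123(model$aa)
  lines <- sprintf(
    "ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(model)), aa3, model$chain, model$resno,
    model$x, model$y, model$z, 1, 0)
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' @rdname write_ca_pdb
#' @export
write_ca_cif <- function(model, file) {
  aa3 <- bio3d::aa123(model$aa)
  hdr <- c("data_model", "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_entity_id",
           "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y",
           "_atom_site.Cartn_z", "_atom_site.occupancy",
           "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
           "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
           "_atom_site.pdbx_PDB_model_num")
  rows <- sprintf(
    paste("ATOM %d C CA . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ?",
          "%d %s %s CA 1"),
    seq_len(nrow(model)), aa3, model$chain, model$resno,
    model$x, model$y, model$z, model$resno, aa3, model$chain)
  writeLines(c(hdr, rows, "#"), file)
  invisible(file)
}

as_xyz <- function(x) {
  if (inherits(x, "structure_model"))
    return(as.matrix(x[c("x", "y", "z")]))
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3)
  x
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation and translation mapping `mobile` onto `target`;
#' reflections are excluded (the rotation determinant is forced to +1).
#'
#' @param mobile,target n x 3 coordinate matrices (or
#'   [structure_model()]s) with matched rows, n >= 3.
#' @return A `superposition`: list with `rotation` (3 x 3), `translation`
#'   (length-3), `rmsd` and `n`. Apply with [apply_superposition()].
#' @export
kabsch_superpose <- function(mobile, target) {
  P <- as_xyz(mobile); Q <- as_xyz(target)
  if (nrow(P) != nrow(Q))
    stop("coordinate sets differ in size", call. = FALSE)
  if (nrow(P) < 3) stop("need at least three points", call. = FALSE)
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  if (svd(Qc)$d[2] < 1e-8 || svd(Pc)$d[2] < 1e-8)
    stop("degenerate (collinear) point set", call. = FALSE)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(qc - R %*% pc)
  dev <- Pc %*% t(R) - Qc
  structure(list(rotation = R, translation = tr,
                 rmsd = sqrt(mean(rowSums(dev^2))), n = nrow(P)),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param sup A `superposition` from [kabsch_superpose()].
#' @param x n x 3 matrix or [structure_model()].
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, x) {
  X <- as_xyz(x)
  sweep(X %*% t(sup$rotation), 2, sup$translation, `+`)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition of %d atoms: RMSD %.3f A\n", x$n, x$rmsd))
  invisible(x)
}

#' Pair the Calpha atoms of two models
#'
#' `"same-numbering"` pairs identical residue numbers within
#' chain-equivalent chains (the i-th chain of each model in sorted
#' order); `"sequence-aligned"` aligns each chain pair's sequences
#' globally and pairs the non-gap columns (required when the two models
#' have different sequences, e.g. LdcI vs LdcC).
#'
#' @param a,b [structure_model()]s.
#' @param mode Pairing mode.
#' @return Data frame `chain_a`, `resno_a`, `chain_b`, `resno_b`.
#' @export
pair_residues <- function(a, b, mode = c("same-numbering",
                                         "sequence-aligned")) {
  mode <- match.arg(mode)
  ch_a <- sort(unique(a$chain)); ch_b <- sort(unique(b$chain))
  if (length(ch_a) != length(ch_b))
    stop("models have different numbers of chains", call. = FALSE)
  out <- NULL
  for (k in seq_along(ch_a)) {
    sa <- a[a$chain == ch_a[k], ]
    sb <- b[b$chain == ch_b[k], ]
    if (mode == "same-numbering") {
      common <- intersect(sa$resno, sb$resno)
      if (length(common) == 0) next
      out <- rbind(out, data.frame(chain_a = ch_a[k],
                                   resno_a = sort(common),
                                   chain_b = ch_b[k],
                                   resno_b = sort(common)))
    } else {
      seq_a <- paste(sa$aa, collapse = "")
      seq_b <- paste(sb$aa, collapse = "")
      pa <- global_align(setNames(seq_a, "a"), setNames(seq_b, "b"),
                         end_gaps = FALSE)
      ca <- strsplit(pa$a, "")[[1]]; cb <- strsplit(pa$b, "")[[1]]
      ia <- cumsum(ca != GAP); ib <- cumsum(cb != GAP)
      keep <- ca != GAP & cb != GAP
      out <- rbind(out, data.frame(chain_a = ch_a[k],
                                   resno_a = sa$resno[ia[keep]],
                                   chain_b = ch_b[k],
                                   resno_b = sb$resno[ib[keep]]))
    }
  }
  if (is.null(out) || nrow(out) < 3)
    stop("insufficient residue overlap between the models",
         call. = FALSE)
  rownames(out) <- NULL
  out
}

coords_for <- function(model, chain, resno) {
  idx <- match(paste(chain, resno), paste(model$chain, model$resno))
  as.matrix(model[idx, c("x", "y", "z")])
}

#' Per-domain in-context RMSD and RMSD_min between two models
#'
#' One global superposition at the stated scope (`"decamer"`: all paired
#' Calpha atoms at once; `"monomer"`: each chain pair separately) gives
#' the in-context RMSD of every domain with no per-domain refit; the
#' RMSD_min of a domain is its own optimal Kabsch superposition. The gap
#' between the two separates rigid-body domain motion (large in-context,
#' small RMSD_min - the swinging CTDs) from internal deformation.
#'
#' @param a,b [structure_model()]s (`a` is the mobile model; domains are
#'   defined on `a`'s residue numbering).
#' @param partition Named list of residue intervals; default
#'   [domain_partition()]. A `core` row (linker + PLP-SD + subdomain 4)
#'   is always added.
#' @param scope Global superposition scope.
#' @param mode Residue pairing mode, see [pair_residues()].
#' @return A `domain_rmsd_report`: data.frame `monomer`, `domain`, `n`,
#'   `in_context`, `rmsd_min`, with a per-domain min/max `summary`
#'   attribute.
#' @export
domain_rmsd_report <- function(a, b, partition = domain_partition(),
                               scope = c("decamer", "monomer"),
                               mode = c("same-numbering",
                                        "sequence-aligned")) {
  scope <- match.arg(scope); mode <- match.arg(mode)
  pairs <- pair_residues(a, b, mode)
  Xa <- coords_for(a, pairs$chain_a, pairs$resno_a)
  Xb <- coords_for(b, pairs$chain_b, pairs$resno_b)
  fitted <- matrix(NA_real_, nrow(Xa), 3)
  if (scope == "decamer") {
    fitted <- apply_superposition(kabsch_superpose(Xa, Xb), Xa)
  } else {
    for (ch in unique(pairs$chain_a)) {
      idx <- pairs$chain_a == ch
      fitted[idx, ] <- apply_superposition(
        kabsch_superpose(Xa[idx, , drop = FALSE],
                         Xb[idx, , drop = FALSE]),
        Xa[idx, , drop = FALSE])
    }
  }
  doms <- c(partition,
            list(core = c(min(partition$linker[1], partition$plp_sd[1]),
                          max(partition$subdomain4[2]))))
  rows <- NULL
  for (ch in unique(pairs$chain_a)) {
    in_ch <- pairs$chain_a == ch
    for (dn in names(doms)) {
      rg <- doms[[dn]]
      idx <- which(in_ch & pairs$resno_a >= rg[1] &
                     pairs$resno_a <= rg[2])
      if (length(idx) == 0) {
        warning(sprintf("domain %s empty after pairing in monomer %s",
                        dn, ch))
        next
      }
      dev <- fitted[idx, , drop = FALSE] - Xb[idx, , drop = FALSE]
      in_ctx <- sqrt(mean(rowSums(dev^2)))
      rmin <- if (length(idx) >= 3)
        kabsch_superpose(Xa[idx, , drop = FALSE],
                         Xb[idx, , drop = FALSE])$rmsd
      else NA_real_
      rows <- rbind(rows, data.frame(monomer = ch, domain = dn,
                                     n = length(idx),
                                     in_context = in_ctx,
                                     rmsd_min = rmin))
    }
  }
  rownames(rows) <- NULL
  summ <- do.call(rbind, lapply(split(rows, rows$domain), function(d)
    data.frame(domain = d$domain[1],
               in_context_min = min(d$in_context),
               in_context_max = max(d$in_context),
               rmsd_min_min = min(d$rmsd_min, na.rm = TRUE),
               rmsd_min_max = max(d$rmsd_min, na.rm = TRUE))))
  summ <- summ[match(names(doms)[names(doms) %in% summ$domain],
                     summ$domain), ]
  rownames(summ) <- NULL
  structure(rows, class = c("domain_rmsd_report", "data.frame"),
            scope = scope, summary = summ)
}

#' @export
print.domain_rmsd_report <- function(x, ...) {
  cat(sprintf("Domain RMSD report (%s-scope global fit, %d monomers)\n",
              attr(x, "scope"), length(unique(x$monomer))))
  s <- attr(x, "summary")
  cat(sprintf("%-11s %21s %21s\n", "", "in-context RMSD (A)",
              "RMSD_min (A)"))
  for (i in seq_len(nrow(s)))
    cat(sprintf("%-11s %9.2f - %9.2f %9.2f - %9.2f\n", s$domain[i],
                s$in_context_min[i], s$in_context_max[i],
                s$rmsd_min_min[i], s$rmsd_min_max[i]))
  invisible(x)
}

#' Write a domain RMSD report as TSV
#' @param report A `domain_rmsd_report`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_rmsd_tsv <- function(report, file) {
  write.table(as.data.frame(report), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Estimate the symmetry axis of a ring-shaped model
#'
#' The axis is taken as the direction of least coordinate variance
#' through the centroid (a D5 double ring spreads in the ring plane).
#'
#' @param model A [structure_model()] or n x 3 matrix.
#' @return List with `point` (centroid) and unit `direction`.
#' @export
estimate_symmetry_axis <- function(model) {
  X <- as_xyz(model)
  ctr <- colMeans(X)
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  dir <- ev$vectors[, 3]
  list(point = ctr, direction = dir / sqrt(sum(dir^2)))
}

dist_to_axis <- function(p, axis) {
  v <- p - axis$point
  perp <- v - sum(v * axis$direction) * axis$direction
  sqrt(sum(perp^2))
}

#' Centroid displacement of a residue segment between two models
#'
#' After the global superposition, reports per monomer the Euclidean
#' distance between the segment's Calpha centroids and, when a symmetry
#' axis is available, the radial (away-from-axis) component - the measure
#' behind active-site helix shifts away from the 5-fold axis.
#'
#' @param a,b [structure_model()]s (`a` mobile, segment defined on `a`'s
#'   numbering).
#' @param segment `c(start, end)` residue interval.
#' @param scope Global fit scope, as in [domain_rmsd_report()].
#' @param mode Pairing mode.
#' @param axis `NULL` (no radial component), `"estimate"` (principal
#'   axis of `b`), or a list with `point` and `direction`.
#' @return Data frame `monomer`, `n`, `shift`, `radial` (NA without an
#'   axis); radial is signed, positive = away from the axis in `b`
#'   relative to fitted `a`.
#' @export
segment_centroid_shift <- function(a, b, segment,
                                   scope = c("decamer", "monomer"),
                                   mode = c("same-numbering",
                                            "sequence-aligned"),
                                   axis = NULL) {
  scope <- match.arg(scope); mode <- match.arg(mode)
  pairs <- pair_residues(a, b, mode)
  Xa <- coords_for(a, pairs$chain_a, pairs$resno_a)
  Xb <- coords_for(b, pairs$chain_b, pairs$resno_b)
  fitted <- matrix(NA_real_, nrow(Xa), 3)
  if (scope == "decamer") {
    fitted <- apply_superposition(kabsch_superpose(Xa, Xb), Xa)
  } else {
    for (ch in unique(pairs$chain_a)) {
      idx <- pairs$chain_a == ch
      fitted[idx, ] <- apply_superposition(
        kabsch_superpose(Xa[idx, , drop = FALSE],
                         Xb[idx, , drop = FALSE]),
        Xa[idx, , drop = FALSE])
    }
  }
  if (identical(axis, "estimate")) axis <- estimate_symmetry_axis(b)
  rows <- NULL
  for (ch in unique(pairs$chain_a)) {
    idx <- which(pairs$chain_a == ch & pairs$resno_a >= segment[1] &
                   pairs$resno_a <= segment[2])
    if (length(idx) == 0)
      stop(sprintf("segment %d-%d unpaired in monomer %s",
                   segment[1], segment[2], ch), call. = FALSE)
    ca <- colMeans(fitted[idx, , drop = FALSE])
    cb <- colMeans(Xb[idx, , drop = FALSE])
    radial <- if (is.null(axis)) NA_real_
              else dist_to_axis(cb, axis) - dist_to_axis(ca, axis)
    rows <- rbind(rows, data.frame(monomer = ch, n = length(idx),
                                   shift = sqrt(sum((ca - cb)^2)),
                                   radial = radial))
  }
  rownames(rows) <- NULL
  rows
}
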