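# Toy D5-symmetric decamers with a known rigid-body CTD motion: the
# parameter-recovery fixture for the domain RMSD analysis. Five Gaussian
# point clouds stand in for the five domains of one monomer; the decamer
# is built by exact D5 replication, so the imposed CTD swing/stretch is
# the only difference between the reference and the moved model.

rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}
rot_x_pi <- function() diag(c(1, -1, -1))

# Rodrigues rotation about unit axis u by theta
rot_axis <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Specification of a toy decamer
#'
#' @param points_per_domain Calpha points per domain (3 to 54, so that
#'   domain point counts fit inside the residue-number intervals of
#'   [domain_partition()]).
#' @param ctd_swing_angle Rigid rotation of the CTD cloud about the
#'   radial axis through its centroid, in degrees.
#' @param ctd_stretch Rigid translation of the CTD cloud away from the
#'   symmetry axis, in Angstrom.
#' @param seed Integer seed for the Gaussian domain clouds.
#' @param domain_layout Optional custom monomer template: named list of
#'   five n x 3 matrices (`wing`, `linker`, `plp_sd`, `subdomain4`,
#'   `ctd`). Collinear clouds are rejected.
#' @return A `toy_decamer_spec` list.
#' @export
toy_decamer_spec <- function(points_per_domain = 20, ctd_swing_angle = 0,
                             ctd_stretch = 0, seed = 1,
                             domain_layout = NULL) {
  if (points_per_domain < 3)
    stop("points_per_domain must be >= 3", call. = FALSE)
  if (points_per_domain > 54)
    stop("points_per_domain must be <= 54 (linker interval width)",
         call. = FALSE)
  structure(list(points_per_domain = points_per_domain,
                 ctd_swing_angle = ctd_swing_angle,
                 ctd_stretch = ctd_stretch, seed = as.integer(seed),
                 domain_layout = domain_layout),
            class = "toy_decamer_spec")
}

toy_monomer_template <- function(spec) {
  doms <- names(domain_partition())
  if (!is.null(spec$domain_layout)) {
    lay <- spec$domain_layout
    if (!identical(sort(names(lay)), sort(doms)))
      stop("domain_layout must name the five domains", call. = FALSE)
    for (d in doms) {
      M <- as.matrix(lay[[d]])
      if (nrow(M) < 3 || ncol(M) != 3)
        stop("each domain cloud needs >= 3 points in 3D", call. = FALSE)
      if (svd(sweep(M, 2, colMeans(M)))$d[2] < 1e-8)
        stop("degenerate (collinear) domain template: ", d,
             call. = FALSE)
      lay[[d]] <- M
    }
    return(lay[doms])
  }
  set.seed(spec$seed)
  centers <- list(wing = c(12, 0, 6), linker = c(19, 3, 4),
                  plp_sd = c(26, -2, 8), subdomain4 = c(33, 3, 3),
                  ctd = c(42, 0, 6))
  lay <- lapply(centers, function(ctr)
    sweep(matrix(stats::rnorm(spec$points_per_domain * 3, sd = 1.5),
                 ncol = 3), 2, ctr, `+`))
  lay[doms]
}

assemble_decamer <- function(template) {
  # template: named list of domain point clouds for the top-ring monomer
  part <- domain_partition()
  rows <- NULL
  for (d in names(template)) {
    M <- template[[d]]
    rows <- rbind(rows, data.frame(
      resno = part[[d]][1] + seq_len(nrow(M)) - 1,
      x = M[, 1], y = M[, 2], z = M[, 3]))
  }
  chains <- LETTERS[1:10]
  out <- NULL
  for (k in 0:4) {
    for (ring in 1:2) {
      G <- rot_z(2 * pi * k / 5)
      if (ring == 2) G <- G %*% rot_z(pi / 5) %*% rot_x_pi()
      X <- as.matrix(rows[c("x", "y", "z")]) %*% t(G)
      out <- rbind(out, data.frame(chain = chains[2 * k + ring],
                                   resno = rows$resno, aa = "A",
                                   x = X[, 1], y = X[, 2], z = X[, 3]))
    }
  }
  structure_model(out)
}

#' Generate a reference / moved toy decamer pair
#'
#' The reference decamer is the D5 replication of the monomer template;
#' the moved decamer applies, before replication, a rigid-body transform
#' to the CTD cloud only: a swing rotation about the radial axis through
#' the CTD centroid followed by a radial (away-from-axis) translation.
#' Every monomer therefore carries the same known CTD motion and the
#' non-CTD domains are untouched.
#'
#' @param spec A [toy_decamer_spec()].
#' @return List of class `toy_decamer` with [structure_model()]s
#'   `reference` and `moved`, plus the `spec`.
#' @export
gen_toy_decamer <- function(spec = toy_decamer_spec()) {
  template <- toy_monomer_template(spec)
  ref <- assemble_decamer(template)

  ctd <- template$ctd
  ctr <- colMeans(ctd)
  radial <- c(ctr[1], ctr[2], 0)
  radial <- radial / sqrt(sum(radial^2))
  moved_ctd <- ctd
  if (spec$ctd_swing_angle != 0) {
    R <- rot_axis(radial, spec$ctd_swing_angle * pi / 180)
    moved_ctd <- sweep(sweep(moved_ctd, 2, ctr) %*% t(R), 2, ctr, `+`)
  }
  if (spec$ctd_stretch != 0)
    moved_ctd <- sweep(moved_ctd, 2, spec$ctd_stretch * radial, `+`)
  template$ctd <- moved_ctd
  mov <- assemble_decamer(template)

  structure(list(reference = ref, moved = mov, spec = spec),
            class = "toy_decamer")
}

#' @export
print.toy_decamer <- function(x, ...) {
  cat(sprintf(
    "Toy D5 decamer: %d points/domain, CTD swing %.1f deg, stretch %.2f A\n",
    x$spec$points_per_domain, x$spec$ctd_swing_angle,
    x$spec$ctd_stretch))
  invisible(x)
}
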