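# Parametric synthetic coordinates: ideal helices, polyline loops and stacked
# ANK-like folds. Fixtures are C-alpha-only poly-alanine — the detector never
# looks at side chains or sequence content — and are deterministic per seed,
# so tests regenerate them instead of storing coordinates.

#' Ideal helix specification
#'
#' Default geometry is the standard alpha-helix C-alpha trace: 1.5 Angstrom
#' rise and 100 degrees twist per residue on a 2.3 Angstrom radius, giving
#' consecutive C-alpha distances of ~3.8 Angstrom.
#'
#' @param n_res residue count.
#' @param rise rise per residue, Angstrom.
#' @param radius helix radius, Angstrom (0 gives collinear points).
#' @param twist twist per residue, degrees.
#' @param origin 3-vector: position of the axis at the first residue.
#' @param direction 3-vector: axis direction (normalized internally).
#' @param phase starting angle, degrees.
#' @return object of class `helix_spec`.
#' @export
helix_spec <- function(n_res, rise = 1.5, radius = 2.3, twist = 100,
                       origin = c(0, 0, 0), direction = c(0, 0, 1),
                       phase = 0) {
  stopifnot(n_res >= 1L, rise > 0, radius >= 0, sum(direction^2) > 0)
  structure(list(n_res = as.integer(n_res), rise = rise, radius = radius,
                 twist = twist, origin = origin,
                 direction = direction / sqrt(sum(direction^2)),
                 phase = phase),
            class = "helix_spec")
}

# orthonormal frame perpendicular to the axis
axis_frame <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

#' Generate C-alpha coordinates on a parametric helix
#'
#' @param spec a [helix_spec()].
#' @return numeric matrix `n_res` x 3; deterministic.
#' @export
build_helix <- function(spec) {
  stopifnot(inherits(spec, "helix_spec"))
  f <- axis_frame(spec$direction)
  t <- seq_len(spec$n_res) - 1L
  ang <- (spec$phase + spec$twist * t) * pi / 180
  axis_pt <- outer(spec$rise * t, spec$direction)
  circ <- spec$radius * (outer(cos(ang), f$u) + outer(sin(ang), f$v))
  sweep(axis_pt + circ, 2, spec$origin, `+`)
}

#' Resample a polyline at equally spaced interior points
#'
#' Utility for building turn and loop traces between secondary-structure
#' elements: returns `n_points` points equally spaced in arc length along the
#' waypoint polyline, excluding both endpoints.
#'
#' @param waypoints numeric matrix (m x 3) of waypoints, m >= 2.
#' @param n_points number of interior points to return.
#' @return numeric matrix `n_points` x 3.
#' @export
polyline_points <- function(waypoints, n_points) {
  w <- as.matrix(waypoints)
  stopifnot(nrow(w) >= 2L, n_points >= 1L)
  seg <- diff(w)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  s <- total * seq_len(n_points) / (n_points + 1)
  out <- matrix(0, n_points, 3)
  for (k in seq_len(n_points)) {
    j <- findInterval(s[k], cum, rightmost.closed = TRUE)
    frac <- (s[k] - cum[j]) / len[j]
    out[k, ] <- w[j, ] + frac * seg[j, ]
  }
  out
}

#' ANK-like fold specification
#'
#' Default lengths follow the observed composition of an ANK motif: a short
#' first helix (~8 residues), a 2-residue inner turn, a longer second helix
#' (~10 residues) and a loop completing a ~32-residue copy; copies stack
#' ~9.5 Angstrom apart (the packing distance of consecutive repeat units).
#' The first helix of each copy sits on the stack core
#' with the connecting loop packed against it, the second helix faces
#' outward, reproducing the buried-H1 asymmetry of the real fold.
#'
#' @param n_copies number of stacked copies, >= 1.
#' @param h1_len,h2_len,inner_turn_len,loop_len segment lengths, residues.
#' @param stack_offset Angstrom between consecutive copies along the stack.
#' @param seed integer seed for the coordinate jitter.
#' @param jitter_sd standard deviation of the Gaussian coordinate jitter,
#'   Angstrom.
#' @return object of class `ank_fixture_spec`.
#' @export
ank_fixture_spec <- function(n_copies, h1_len = 8L, h2_len = 10L,
                             inner_turn_len = 2L, loop_len = 12L,
                             stack_offset = 9.5, seed = 1L,
                             jitter_sd = 0.05) {
  stopifnot(n_copies >= 1L, h1_len > 0L, h2_len > 0L, inner_turn_len > 0L,
            loop_len > 0L, stack_offset > 0, jitter_sd >= 0)
  structure(list(n_copies = as.integer(n_copies), h1_len = as.integer(h1_len),
                 h2_len = as.integer(h2_len),
                 inner_turn_len = as.integer(inner_turn_len),
                 loop_len = as.integer(loop_len), stack_offset = stack_offset,
                 seed = as.integer(seed), jitter_sd = jitter_sd),
            class = "ank_fixture_spec")
}

#' Build a synthetic multi-copy ANK-like fold
#'
#' Stacks `n_copies` helix-turn-helix units on a curved solenoid: the first
#' helices form the inner (concave) column on a tighter arc than the outer
#' second-helix column, so the H1 helices of adjacent copies pack against
#' each other while the H2 helices splay apart — this is what buries H1 and
#' produces the centrality asymmetry of the real fold. The inner turn crosses
#' to the anti-parallel second helix ~9 Angstrom away, and the connecting
#' loop dives below the copy in a hairpin (its depth scales with `loop_len`)
#' before rising along the inner face to the next copy's first helix. The
#' geometry satisfies all four ANK detection criteria by construction.
#' A seeded Gaussian jitter is applied so fixtures are not perfectly
#' degenerate; the global RNG state is left untouched.
#'
#' @param spec an [ank_fixture_spec()].
#' @return a [chain_structure] (poly-alanine) of
#'   `n_copies * (h1_len + inner_turn_len + h2_len + loop_len)` residues.
#' @export
build_ank_fixture <- function(spec) {
  stopifnot(inherits(spec, "ank_fixture_spec"))
  r_in <- 20                     # arc radius of the inner (H1) column
  sep <- 9                       # helix-axis separation within a copy
  h1_top <- (spec$h1_len - 1) * 1.5
  dphi <- spec$stack_offset / r_in
  rot_z <- function(phi) matrix(c(cos(phi), sin(phi), 0,
                                  -sin(phi), cos(phi), 0,
                                  0, 0, 1), 3, 3)
  # template copy in the phi = 0 frame; every copy is this template rigidly
  # rotated about the stack axis, so all copies are congruent
  h1 <- build_helix(helix_spec(spec$h1_len, origin = c(r_in, 0, 0)))
  # the outer helix leans: its N-terminal end (top) splays away from the
  # inner column and its C-terminal end tucks back in, as in the real fold;
  # this keeps the outer helix less packed than the buried inner column
  h2 <- build_helix(helix_spec(spec$h2_len,
                               origin = c(r_in + sep + 2.5, 0, h1_top),
                               direction = c(-0.18, 0, -1), phase = 180))
  h1_end <- h1[spec$h1_len, ]
  h2_start <- h2[1, ]
  turn <- polyline_points(rbind(h1_end,
                                (h1_end + h2_start) / 2 + c(0, 0, 2.0),
                                h2_start),
                          spec$inner_turn_len)
  h2_end <- h2[spec$h2_len, ]
  nxt <- h1[1, ] %*% t(rot_z(dphi))   # next copy's first C-alpha
  # hairpin loop below the copy, hugging the inner column on the way back; it
  # arrives straight below the next first helix and rises vertically (the
  # kink keeps the approach from being mistaken for helix geometry), and the
  # hairpin deepens so point spacing stays helix-unlike when loop_len grows
  way <- rbind(h2_end,
               c(r_in + 10, 3.5, h2_end[3] - 3),
               c(r_in, 5.5, h2_end[3] - 4),
               c(r_in - 6, 5.0, h2_end[3] - 2),
               c(r_in - 6, 7.5, -4),
               nxt - c(0, 0, 4.3),
               nxt)
  l0 <- sum(sqrt(rowSums(diff(way)^2)))
  depth <- max(0, (3.5 * (spec$loop_len + 1) - l0) / 2)
  way[3, 3] <- way[3, 3] - depth   # hairpin tip, straight down and back up
  way[4, 3] <- way[4, 3] - depth
  loop <- polyline_points(way, spec$loop_len)
  template <- rbind(h1, turn, h2, loop)
  pts <- do.call(rbind, lapply(seq_len(spec$n_copies) - 1L, function(k)
    template %*% t(rot_z(k * dphi))))
  if (spec$jitter_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = .GlobalEnv)
      else if (exists(".Random.seed", envir = .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    })
    set.seed(spec$seed)
    pts <- pts + matrix(stats::rnorm(length(pts), sd = spec$jitter_sd),
                        nrow(pts), 3)
  }
  d <- as.matrix(stats::dist(pts))
  d[abs(row(d) - col(d)) <= 1L] <- Inf
  if (min(d) < 2.5)
    stop(sprintf(
      "fixture construction failed: non-bonded C-alpha pair at %.2f A (< 2.5)",
      min(d)))
  chain_structure(pts, chain_id = "A")
}

#' Write a chain as minimal PDB ATOM records
#'
#' C-alpha-only records re-readable by [read_structure()] and standard PDB
#' readers; coordinates are kept to 3 decimals.
#'
#' @param chain a [chain_structure].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fixture_pdb <- function(chain, path) {
  recs <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(chain$n), chain$resid, chain$chain_id, chain$resno,
    ifelse(chain$insert == "", " ", chain$insert),
    chain$xyz[, 1], chain$xyz[, 2], chain$xyz[, 3], 1.0, 0.0)
  writeLines(c(recs, "TER", "END"), path)
  invisible(path)
}
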