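# Shared geometric constructions and oracles for the test suite.

# chain of n collinear points with the given spacing (Angstrom)
collinear_chain <- function(n, spacing) {
  chain_structure(cbind(spacing * (0:(n - 1)), 0, 0))
}

# two ideal 10-residue helices laid side by side 9 A apart; the second either
# runs back anti-parallel or repeats the first helix's direction
two_helix_pair <- function(antiparallel) {
  h1 <- build_helix(helix_spec(10))
  top <- (10 - 1) * 1.5
  h2 <- if (antiparallel) {
    build_helix(helix_spec(10, origin = c(9, 0, top), direction = c(0, 0, -1)))
  } else {
    build_helix(helix_spec(10, origin = c(9, 0, 0)))
  }
  chain <- chain_structure(rbind(h1, h2))
  pair <- data.frame(h1 = 1L, h2 = 2L, s1 = 1L, e1 = 10L, s2 = 11L, e2 = 20L,
                     peak1 = NA_integer_, peak2 = NA_integer_)
  list(chain = chain, pair = pair)
}

# single chain holding two parallel helices joined by a loop that returns to
# the base of the second helix (both helices run +z)
parallel_bundle_chain <- function() {
  h1 <- build_helix(helix_spec(12))
  h2 <- build_helix(helix_spec(12, origin = c(9, 0, 0)))
  way <- rbind(h1[12, ], c(14, 0, h1[12, 3] - 2), c(14, 0, -4),
               c(9 + 2.3, 0, -4), h2[1, ])
  chain_structure(rbind(h1, polyline_points(way, 8), h2))
}

# manual secondary-structure segment table from run-length pairs
seg_df <- function(classes, lengths, source = "manual") {
  end <- cumsum(lengths)
  data.frame(ss_class = classes, start = end - lengths + 1L, end = end,
             source = source, stringsAsFactors = FALSE)
}

# minimal stand-in for an eigen_profile (detector code reads $levc and $n)
fake_profile <- function(levc) list(levc = levc, n = length(levc))

# uniformly random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rmsd_under <- function(a, b, rot) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  sqrt(mean(rowSums((a - b %*% rot)^2)))
}

rot_zyz <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
  rz(a) %*% ry(b) %*% rz(c)
}

# independent superposition oracle: Euler-angle grid search followed by
# shrinking local refinement around the incumbent best
grid_search_rmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  eval_rot <- function(al, be, ga)
    sqrt(mean(rowSums((ac - bc %*% rot_zyz(al, be, ga))^2)))
  best <- Inf; arg <- c(0, 0, 0)
  step <- pi / 18
  for (al in seq(0, 2 * pi, by = step))
    for (be in seq(0, pi, by = step))
      for (ga in seq(0, 2 * pi, by = step)) {
        r <- eval_rot(al, be, ga)
        if (r < best) { best <- r; arg <- c(al, be, ga) }
      }
  for (iter in 1:10) {
    step <- step / 2
    offs <- seq(-3, 3) * step
    for (da in offs) for (db in offs) for (dg in offs) {
      r <- eval_rot(arg[1] + da, arg[2] + db, arg[3] + dg)
      if (r < best) { best <- r; arg <- arg + c(da, db, dg) }
    }
  }
  best
}
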