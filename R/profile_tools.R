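# Per-repeat profile slices, peak normalization for overlaying repeat copies,
# and rigid-body superposition RMSD for validating predicted motifs against a
# reference motif.

#' Extract the profile slice of one repeat
#'
#' @param profile an `eigen_profile`.
#' @param start,end internal indices (inclusive), e.g. one row of an
#'   `ank_result$repeats` frame.
#' @return object of class `repeat_profile` with `values`, `start`, `end`,
#'   `normalized`.
#' @export
repeat_profile <- function(profile, start, end) {
  stopifnot(start >= 1L, end <= profile$n, start <= end)
  structure(list(values = profile$levc[start:end],
                 start = as.integer(start), end = as.integer(end),
                 normalized = FALSE),
            class = "repeat_profile")
}

#' Normalize a repeat profile by its largest peak
#'
#' Divides every value by the slice maximum so that repeat copies can be
#' overlaid on a common 0-1 scale; idempotent.
#'
#' @param p a `repeat_profile`.
#' @return the normalized `repeat_profile` (max value exactly 1).
#' @export
normalize_profile <- function(p) {
  stopifnot(inherits(p, "repeat_profile"), length(p$values) > 0L)
  mx <- max(p$values)
  if (mx <= 0) stop("degenerate profile: all values are zero or negative")
  p$values <- p$values / mx
  p$normalized <- TRUE
  p
}

# Kabsch: optimal proper rotation (no reflection) minimizing the RMSD of two
# centred equal-length point sets.
kabsch_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(b, a))          # 3x3 covariance t(B) %*% A
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((a - b %*% rot)^2)))
}

#' Minimum RMSD after rigid-body superposition
#'
#' Least-squares Kabsch superposition over all rotations and translations
#' with a positional (i-to-i) correspondence; reflections are disallowed.
#' When the two sets differ in length the shorter is superposed on every
#' contiguous window of the longer and the minimum RMSD is returned — ANK
#' motifs are near-constant in length, so a sliding window stands in for a
#' full fragment alignment.
#'
#' @param coords_a,coords_b numeric matrices (n x 3) of ordered C-alpha
#'   coordinates, each with at least 3 points.
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (nrow(a) < 3L || nrow(b) < 3L)
    stop("superposition needs at least 3 points in each set")
  stopifnot(ncol(a) == 3L, ncol(b) == 3L)
  if (nrow(a) > nrow(b)) { tmp <- a; a <- b; b <- tmp }
  k <- nrow(a)
  offs <- 0:(nrow(b) - k)
  min(vapply(offs, function(o) kabsch_rmsd(a, b[(o + 1):(o + k), , drop = FALSE]),
             numeric(1)))
}

#' C-alpha coordinates of one predicted repeat
#'
#' Convenience accessor for superposing predicted repeats.
#'
#' @param chain a [chain_structure].
#' @param start,end internal indices (inclusive).
#' @return numeric matrix, (end - start + 1) x 3.
#' @export
repeat_coords <- function(chain, start, end) {
  stopifnot(start >= 1L, end <= chain$n, start <= end)
  chain$xyz[start:end, , drop = FALSE]
}

#' Export repeat profiles as a long table
#'
#' @param profiles list of `repeat_profile` objects.
#' @return data.frame with `copy`, `offset` (position within the repeat,
#'   0-based) and `value` columns, suitable for overlay plotting or TSV export.
#' @export
profiles_table <- function(profiles) {
  do.call(rbind, lapply(seq_along(profiles), function(k) {
    p <- profiles[[k]]
    data.frame(copy = k, offset = seq_along(p$values) - 1L, value = p$values)
  }))
}
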