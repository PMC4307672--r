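# The ANK repeat detector: rule set over the centrality profile and the
# secondary-structure architecture.
#
# An ANK motif is recognised as a helix-turn-helix (H1-T-H2) whose
#  (i)  helices are anti-parallel:  d(S1,E2) < d(E1,E2), strict;
#  (ii) first helix is buried:      mean profile over H1 > mean over H2;
#  (iii) profile peaks of the two helices are 5-15 residues apart;
#  (iv) H1-T-H2 core spans at least 13 residues.
# The repeat starts 4 residues before H1 and ends at the profile minimum of
# the beta-turn following H2; at least two motifs within 17 residues of each
# other form a reportable tandem region.

#' Detection parameters
#'
#' Defaults encode the ANK rule set; every threshold can be overridden.
#'
#' @param r_c contact-network distance cutoff, Angstrom.
#' @param peak_dist_min,peak_dist_max allowed separation (residues) between
#'   the profile peak of the first and second helix.
#' @param min_core_len minimum helix-turn-helix core length, residues.
#' @param start_offset residues before the first helix where the repeat
#'   starts (the "-4" rule).
#' @param turn_window how far past the second helix to search for the
#'   boundary beta-turn, residues.
#' @param tandem_gap_max largest gap (residues strictly between consecutive
#'   repeats) still counted as tandem; half a typical ANK motif.
#' @param min_chain_len batch-mode filter: chains shorter than this are
#'   skipped (never applied in single-structure mode).
#' @return object of class `detection_params`.
#' @export
detection_params <- function(r_c = 7.0, peak_dist_min = 5L, peak_dist_max = 15L,
                             min_core_len = 13L, start_offset = 4L,
                             turn_window = 15L, tandem_gap_max = 17L,
                             min_chain_len = 50L) {
  p <- list(r_c = r_c, peak_dist_min = as.integer(peak_dist_min),
            peak_dist_max = as.integer(peak_dist_max),
            min_core_len = as.integer(min_core_len),
            start_offset = as.integer(start_offset),
            turn_window = as.integer(turn_window),
            tandem_gap_max = as.integer(tandem_gap_max),
            min_chain_len = as.integer(min_chain_len))
  if (any(unlist(p) <= 0)) stop("all detection parameters must be positive")
  if (p$peak_dist_min > p$peak_dist_max)
    stop("peak_dist_min must not exceed peak_dist_max")
  class(p) <- "detection_params"
  p
}

# argmax/argmin with lowest-index tie-breaking (which.max/min already do).
peak_in <- function(levc, from, to) from - 1L + which.max(levc[from:to])

#' Enumerate helix-turn-helix candidates
#'
#' Every ordered pair of consecutive HELIX segments separated only by TURN or
#' COIL segments, annotated with the position of the profile maximum inside
#' each helix (ties broken toward the lower index).
#'
#' @param segments segment data.frame from one of the assigners.
#' @param profile the matching `eigen_profile`.
#' @return data.frame with one row per candidate: `h1`, `h2` (row indices in
#'   `segments`), `s1`, `e1`, `s2`, `e2` (internal indices of helix starts and
#'   ends), `peak1`, `peak2`. Zero rows when fewer than two helices.
#' @export
find_hth_candidates <- function(segments, profile) {
  hel <- which(segments$ss_class == "HELIX")
  out <- data.frame(h1 = integer(0), h2 = integer(0), s1 = integer(0),
                    e1 = integer(0), s2 = integer(0), e2 = integer(0),
                    peak1 = integer(0), peak2 = integer(0))
  if (length(hel) < 2L) return(out)
  for (k in seq_len(length(hel) - 1L)) {
    a <- hel[k]; b <- hel[k + 1L]
    between <- if (b > a + 1L) segments$ss_class[(a + 1L):(b - 1L)] else character(0)
    if (!all(between %in% c("TURN", "COIL"))) next
    out[nrow(out) + 1L, ] <- list(
      a, b, segments$start[a], segments$end[a],
      segments$start[b], segments$end[b],
      peak_in(profile$levc, segments$start[a], segments$end[a]),
      peak_in(profile$levc, segments$start[b], segments$end[b]))
  }
  out
}

#' Anti-parallel helix test (criterion i)
#'
#' The two helices of a candidate are anti-parallel when the C-alpha distance
#' from the start of the first helix to the end of the second is strictly
#' smaller than the distance between the two helix ends.
#'
#' @param chain the [chain_structure].
#' @param pair one candidate row from [find_hth_candidates()].
#' @return logical.
#' @export
is_antiparallel <- function(chain, pair) {
  d <- function(i, j) sqrt(sum((chain$xyz[i, ] - chain$xyz[j, ])^2))
  d(pair$s1, pair$e2) < d(pair$e1, pair$e2)
}

#' Buried-first-helix test (criterion ii)
#'
#' True when the mean profile value over the first helix strictly exceeds the
#' mean over the second: the inner helix of an ANK motif packs against the
#' stack core and carries higher centrality.
#'
#' @param profile an `eigen_profile`.
#' @param pair one candidate row.
#' @return logical.
#' @export
eigen_dominance <- function(profile, pair) {
  mean(profile$levc[pair$s1:pair$e1]) > mean(profile$levc[pair$s2:pair$e2])
}

#' Peak-separation test (criterion iii)
#'
#' @param pair one candidate row.
#' @param params a `detection_params`.
#' @return logical; true when `peak2 - peak1` lies in
#'   `[peak_dist_min, peak_dist_max]` (inclusive).
#' @export
peak_distance_ok <- function(pair, params = detection_params()) {
  dd <- pair$peak2 - pair$peak1
  dd >= params$peak_dist_min && dd <= params$peak_dist_max
}

#' Core-length test (criterion iv)
#'
#' @inheritParams peak_distance_ok
#' @return logical; true when the H1-T-H2 core `e2 - s1 + 1` has at least
#'   `min_core_len` residues.
#' @export
core_length_ok <- function(pair, params = detection_params()) {
  (pair$e2 - pair$s1 + 1L) >= params$min_core_len
}

#' Repeat start position (the "-4" rule)
#'
#' The repeat begins `start_offset` residues before the first helix; clamped
#' at the chain start, in which case the repeat is flagged terminal.
#'
#' @inheritParams peak_distance_ok
#' @return list with `start` (internal index) and `terminal` (logical).
#' @export
repeat_start <- function(pair, params = detection_params()) {
  raw <- pair$s1 - params$start_offset
  list(start = max(1L, raw), terminal = raw < 1L)
}

#' Repeat end position (beta-turn profile minimum)
#'
#' Searches the window after the second helix — up to `turn_window` residues,
#' truncated at the start of the next repeat when one follows — for the TURN
#' residue of lowest profile value (ties toward the lower index). If the
#' window holds no TURN, its COIL residues are used. A window that is empty
#' or runs past the chain terminus ends the repeat at the last residue
#' (`chain_end`); an end at or beyond the next repeat's start is pulled back
#' to just before it (`clipped`).
#'
#' @param profile an `eigen_profile`.
#' @param segments the segment data.frame.
#' @param pair one candidate row.
#' @param next_start internal start index of the following repeat, or `NA`.
#' @param params a `detection_params`.
#' @return list with `end` (internal index) and
#'   `end_rule` (`"turn_min"`, `"chain_end"` or `"clipped"`).
#' @export
repeat_end <- function(profile, segments, pair, next_start = NA,
                       params = detection_params()) {
  n <- profile$n
  e2 <- pair$e2
  w <- params$turn_window
  if (!is.na(next_start)) w <- min(w, next_start - e2 - 1L)
  upper_raw <- e2 + w
  window <- if (upper_raw > e2 && e2 < n) (e2 + 1L):min(upper_raw, n)
            else integer(0)
  classes <- residue_classes(segments, n)
  res <- NULL
  cand <- window[classes[window] == "TURN"]
  if (length(cand)) {
    res <- list(end = cand[which.min(profile$levc[cand])], end_rule = "turn_min")
  } else if (length(window) == 0L || upper_raw > n) {
    res <- list(end = n, end_rule = "chain_end")
  } else {
    cand <- window[classes[window] == "COIL"]
    if (!length(cand)) cand <- window
    res <- list(end = cand[which.min(profile$levc[cand])], end_rule = "turn_min")
  }
  if (!is.na(next_start) && res$end >= next_start) {
    res <- list(end = next_start - 1L, end_rule = "clipped")
  }
  res
}

#' Detect tandem ANK repeats in one chain
#'
#' Runs the full rule set: a greedy left-to-right scan over helix-turn-helix
#' candidates accepts every pair passing all four criteria and resumes after
#' its second helix (repeats never share a helix); a failing pair advances by
#' one helix. Boundaries are then assigned (start by the "-4" rule, end by
#' the beta-turn profile minimum, computed once all starts are known), repeats
#' are grouped into tandem regions wherever consecutive gaps stay within
#' `tandem_gap_max`, and isolated single repeats are discarded.
#'
#' @param chain a [chain_structure].
#' @param segments secondary-structure segments for the chain.
#' @param profile the chain's `eigen_profile`.
#' @param params a `detection_params`.
#' @return object of class `ank_result`: `repeats` (data.frame: `copy`,
#'   `region`, `start`, `end`, `start_resno`, `end_resno` in author numbering,
#'   `s1`, `e1`, `s2`, `e2`, `peak1`, `peak2`, `end_rule`, `terminal`),
#'   `regions` (data.frame: `region`, `n_repeats`, `region_start`,
#'   `region_end`), plus `n` and `params`. Both frames have zero rows when no
#'   tandem region is found.
#' @export
detect_ank <- function(chain, segments, profile, params = detection_params()) {
  stopifnot(inherits(chain, "chain_structure"),
            profile$n == chain$n,
            max(segments$end) == chain$n)
  validate_segments(segments, chain$n)
  cand <- find_hth_candidates(segments, profile)
  accepted <- cand[0, ]
  k <- 1L
  while (k <= nrow(cand)) {
    pair <- cand[k, ]
    ok <- is_antiparallel(chain, pair) &&
      eigen_dominance(profile, pair) &&
      peak_distance_ok(pair, params) &&
      core_length_ok(pair, params)
    if (ok) {
      accepted <- rbind(accepted, pair)
      # skip every candidate whose first helix precedes the end of this H2:
      # repeats never share a helix
      k <- k + 1L
      while (k <= nrow(cand) && cand$h1[k] <= pair$h2[1]) k <- k + 1L
    } else {
      k <- k + 1L
    }
  }
  m <- nrow(accepted)
  empty <- list(
    repeats = data.frame(copy = integer(0), region = integer(0),
                         start = integer(0), end = integer(0),
                         start_resno = integer(0), end_resno = integer(0),
                         s1 = integer(0), e1 = integer(0), s2 = integer(0),
                         e2 = integer(0), peak1 = integer(0),
                         peak2 = integer(0), end_rule = character(0),
                         terminal = logical(0)),
    regions = data.frame(region = integer(0), n_repeats = integer(0),
                         region_start = integer(0), region_end = integer(0)),
    n = chain$n, params = params)
  if (m == 0L) return(structure(empty, class = "ank_result"))

  starts <- integer(m); terminal <- logical(m)
  for (k in seq_len(m)) {
    st <- repeat_start(accepted[k, ], params)
    starts[k] <- st$start; terminal[k] <- st$terminal
  }
  ends <- integer(m); end_rule <- character(m)
  for (k in seq_len(m)) {
    nx <- if (k < m) starts[k + 1L] else NA
    en <- repeat_end(profile, segments, accepted[k, ], nx, params)
    ends[k] <- en$end; end_rule[k] <- en$end_rule
  }
  terminal <- terminal | end_rule == "chain_end"

  # tandem grouping: gap = residues strictly between consecutive repeats
  region <- integer(m)
  region[1] <- 1L
  if (m > 1L) for (k in 2L:m) {
    gap <- starts[k] - ends[k - 1L] - 1L
    region[k] <- if (gap <= params$tandem_gap_max) region[k - 1L]
                 else region[k - 1L] + 1L
  }
  keep <- region %in% as.integer(names(which(table(region) >= 2L)))
  if (!any(keep)) return(structure(empty, class = "ank_result"))

  rep_df <- data.frame(
    copy = seq_len(sum(keep)),
    region = match(region[keep], unique(region[keep])),
    start = starts[keep], end = ends[keep],
    start_resno = chain$resno[starts[keep]],
    end_resno = chain$resno[ends[keep]],
    s1 = accepted$s1[keep], e1 = accepted$e1[keep],
    s2 = accepted$s2[keep], e2 = accepted$e2[keep],
    peak1 = accepted$peak1[keep], peak2 = accepted$peak2[keep],
    end_rule = end_rule[keep], terminal = terminal[keep],
    stringsAsFactors = FALSE)
  reg_df <- do.call(rbind, lapply(split(rep_df, rep_df$region), function(g)
    data.frame(region = g$region[1], n_repeats = nrow(g),
               region_start = min(g$start), region_end = max(g$end))))
  rownames(reg_df) <- rownames(rep_df) <- NULL
  structure(list(repeats = rep_df, regions = reg_df, n = chain$n,
                 params = params), class = "ank_result")
}

#' @export
print.ank_result <- function(x, ...) {
  if (nrow(x$repeats) == 0L) {
    cat("<ank_result> no tandem ANK repeat region\n")
  } else {
    cat(sprintf("<ank_result> %d repeat(s) in %d region(s)\n",
                nrow(x$repeats), nrow(x$regions)))
    print(x$repeats[, c("copy", "region", "start_resno", "end_resno",
                        "end_rule", "terminal")], row.names = FALSE)
  }
  invisible(x)
}

#' Independently re-check every reported repeat against the rule set
#'
#' Post-hoc verifier: recomputes criteria (i)-(iv) for each reported repeat
#' from the raw inputs, plus the non-overlap and tandem-gap invariants.
#'
#' @param result an `ank_result`.
#' @param chain,segments,profile the inputs `detect_ank` was called with.
#' @return TRUE, or a character vector of violations.
#' @export
verify_detection <- function(result, chain, segments, profile) {
  bad <- character(0)
  rp <- result$repeats
  p <- result$params
  for (k in seq_len(nrow(rp))) {
    pair <- rp[k, ]
    if (!is_antiparallel(chain, pair)) bad <- c(bad, paste("copy", k, "not anti-parallel"))
    if (!eigen_dominance(profile, pair)) bad <- c(bad, paste("copy", k, "H1 not dominant"))
    if (!peak_distance_ok(pair, p)) bad <- c(bad, paste("copy", k, "peak distance out of range"))
    if (!core_length_ok(pair, p)) bad <- c(bad, paste("copy", k, "core too short"))
    if (!(pair$start <= pair$s1 && pair$s1 < pair$e2 && pair$e2 <= pair$end))
      bad <- c(bad, paste("copy", k, "boundaries do not bracket the core"))
  }
  if (nrow(rp) > 1L) for (k in 2L:nrow(rp)) {
    if (rp$start[k] <= rp$end[k - 1L])
      bad <- c(bad, paste("copies", k - 1L, "and", k, "overlap"))
    if (rp$region[k] == rp$region[k - 1L] &&
        rp$start[k] - rp$end[k - 1L] - 1L > p$tandem_gap_max)
      bad <- c(bad, paste("gap before copy", k, "exceeds tandem threshold"))
  }
  if (any(table(result$repeats$region) < 2L))
    bad <- c(bad, "region with fewer than 2 repeats reported")
  if (length(bad)) bad else TRUE
}

#' Batch-mode chain length filter
#'
#' Short fragments are unlikely to hold two contiguous ANK motifs and are
#' skipped in batch scans; never applied in single-structure mode.
#'
#' @param chain a [chain_structure].
#' @param params a `detection_params`.
#' @return logical.
#' @export
chain_passes_batch_filter <- function(chain, params = detection_params()) {
  chain$n >= params$min_chain_len
}
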