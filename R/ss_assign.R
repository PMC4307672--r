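# Per-residue secondary structure: STRIDE / DSSP output parsers and a
# C-alpha-only geometric fallback assigner.
#
# Classes are pooled into four states. Helix pools alpha (H), 3-10 (G) and
# pi (I): observed first helices of the ANK motif can be as short as 3-4
# residues, so short 3-10 runs must count as helix. STRAND pools E/B(/b),
# TURN is the assigner's turn state, everything else is COIL.

.SS_CLASSES <- c("HELIX", "STRAND", "TURN", "COIL")

map_ss_code <- function(code, dialect = c("stride", "dssp")) {
  dialect <- match.arg(dialect)
  strand <- if (dialect == "stride") c("E", "B", "b") else c("E", "B")
  out <- rep("COIL", length(code))
  out[code %in% c("H", "G", "I")] <- "HELIX"
  out[code %in% strand] <- "STRAND"
  out[code == "T"] <- "TURN"
  out
}

# Collapse a per-residue class vector into maximal-run segments.
segments_from_classes <- function(classes, source) {
  r <- rle(classes)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(ss_class = r$values, start = start, end = end,
             source = source, stringsAsFactors = FALSE)
}

# Expand segments back to a per-residue class vector.
residue_classes <- function(segments, n) {
  out <- rep(NA_character_, n)
  for (k in seq_len(nrow(segments)))
    out[segments$start[k]:segments$end[k]] <- segments$ss_class[k]
  out
}

validate_segments <- function(segments, n) {
  stopifnot(nrow(segments) >= 1L)
  if (segments$start[1] != 1L || segments$end[nrow(segments)] != n ||
      any(segments$start > segments$end) ||
      (nrow(segments) > 1L &&
         any(segments$start[-1] != segments$end[-nrow(segments)] + 1L)))
    stop("secondary-structure segments do not partition the chain")
  if (nrow(segments) > 1L &&
      any(segments$ss_class[-1] == segments$ss_class[-nrow(segments)]))
    stop("adjacent segments share a class: runs are not maximal")
  invisible(segments)
}

# Split an author "residue number + optional insertion code" token, e.g.
# "60A" -> (60, "A"), "-3" -> (-3, "").
split_resnum_token <- function(tok) {
  m <- regmatches(tok, regexec("^(-?[0-9]+)([A-Za-z]?)$", tok))[[1]]
  if (length(m) == 0L) return(NULL)
  list(resno = as.integer(m[2]), insert = m[3])
}

# Map assignment records (author numbering) onto chain positions; records for
# residues absent from the chain are dropped with a warning, chain residues
# without a record default to COIL.
reconcile_assignment <- function(chain, resno, insert, classes, source) {
  chain_key <- paste(chain$resno, chain$insert, sep = "\r")
  rec_key <- paste(resno, insert, sep = "\r")
  pos <- match(rec_key, chain_key)
  if (anyNA(pos)) {
    warning(sum(is.na(pos)), " ", source, " record(s) did not match chain ",
            chain$chain_id, " residues and were dropped")
  }
  per_res <- rep("COIL", chain$n)
  per_res[pos[!is.na(pos)]] <- classes[!is.na(pos)]
  validate_segments(segments_from_classes(per_res, source), chain$n)
}

#' Parse STRIDE output into secondary-structure segments
#'
#' Reads the ASG records of a STRIDE output file, maps the one-letter codes
#' to the four pooled classes (H/G/I to HELIX, E/B/b to STRAND, T to TURN,
#' else COIL), matches records to the chain by author residue number plus
#' insertion code, and emits maximal runs.
#'
#' @param path STRIDE output file.
#' @param chain the [chain_structure] the assignment belongs to.
#' @return data.frame of segments: `ss_class`, `start`, `end` (1-based
#'   internal indices, inclusive), `source = "stride"`. Segments are sorted,
#'   non-overlapping and cover the whole chain.
#' @export
parse_stride <- function(path, chain) {
  lines <- readLines(path, warn = FALSE)
  asg <- lines[startsWith(lines, "ASG")]
  resno <- integer(0); insert <- character(0); code <- character(0)
  for (ln in asg) {
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(f) < 6L || f[3] != chain$chain_id) next
    tok <- split_resnum_token(f[4])
    if (is.null(tok)) next
    resno <- c(resno, tok$resno)
    insert <- c(insert, tok$insert)
    code <- c(code, f[6])
  }
  if (length(code) == 0L)
    stop("no STRIDE ASG records for chain ", chain$chain_id, " in ", path)
  reconcile_assignment(chain, resno, insert,
                       map_ss_code(code, "stride"), "stride")
}

#' Parse classic DSSP output into secondary-structure segments
#'
#' @inheritParams parse_stride
#' @return as [parse_stride()], with `source = "dssp"`.
#' @export
parse_dssp <- function(path, chain) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) stop("not a classic DSSP file: ", path)
  body <- lines[(hdr[1] + 1L):length(lines)]
  body <- body[nchar(body) >= 17L]
  ch <- substr(body, 12L, 12L)
  aa <- substr(body, 14L, 14L)
  body <- body[ch == chain$chain_id & aa != "!"]
  if (length(body) == 0L)
    stop("no DSSP records for chain ", chain$chain_id, " in ", path)
  resno <- as.integer(substr(body, 6L, 10L))
  insert <- trimws(substr(body, 11L, 11L))
  code <- substr(body, 17L, 17L)
  reconcile_assignment(chain, resno, insert,
                       map_ss_code(code, "dssp"), "dssp")
}

#' C-alpha-only geometric secondary-structure assignment
#'
#' Fallback assigner needing no external program. Residue i is flagged
#' helical when the i to i+3 C-alpha distance lies in [4.5, 6.5] Angstrom and
#' the i to i+4 distance in [5.0, 7.0]; runs of at least 4 flagged residues
#' become HELIX. Residue i is flagged extended when the i to i+2 distance
#' lies in [6.4, 7.4]; non-helix runs of at least 3 become STRAND. Up to 4
#' unassigned residues immediately following a helix are labelled TURN;
#' everything else is COIL.
#'
#' @param chain a [chain_structure] with at least 5 residues.
#' @return segment data.frame as [parse_stride()], `source = "internal"`.
#' @export
assign_internal <- function(chain) {
  n <- chain$n
  if (n < 5L) stop("chain too short for secondary-structure assignment (n < 5)")
  xyz <- chain$xyz
  dk <- function(k) {
    i <- seq_len(n - k)
    sqrt(rowSums((xyz[i + k, , drop = FALSE] - xyz[i, , drop = FALSE])^2))
  }
  d2 <- dk(2L); d3 <- dk(3L); d4 <- dk(4L)
  hel_flag <- logical(n)
  i <- seq_len(n - 4L)
  hel_flag[i] <- d3[i] >= 4.5 & d3[i] <= 6.5 & d4[i] >= 5.0 & d4[i] <= 7.0
  str_flag <- logical(n)
  i <- seq_len(n - 2L)
  str_flag[i] <- d2[i] >= 6.4 & d2[i] <= 7.4

  per_res <- rep("COIL", n)
  mark_runs <- function(flag, min_len, label) {
    r <- rle(flag)
    end <- cumsum(r$lengths); start <- end - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len))
      per_res[start[k]:end[k]] <<- label
  }
  mark_runs(str_flag, 3L, "STRAND")
  mark_runs(hel_flag, 4L, "HELIX")
  # turn window after each helix
  r <- rle(per_res)
  end <- cumsum(r$lengths)
  for (k in which(r$values == "HELIX")) {
    j <- end[k] + 1L
    taken <- 0L
    while (j <= n && taken < 4L && per_res[j] == "COIL") {
      per_res[j] <- "TURN"
      j <- j + 1L; taken <- taken + 1L
    }
  }
  validate_segments(segments_from_classes(per_res, "internal"), n)
}
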