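# Reading PDB coordinate files into per-chain C-alpha records.
#
# Only C-alpha atoms are ever used downstream: the contact network, the
# secondary-structure fallback and the superposition all operate on the
# C-alpha trace.

# HETATM residue names treated as modified standard amino acids when they
# carry a CA atom (mapped to the parent residue for the one-letter code).
.modres_parent <- c(
  MSE = "MET", MLY = "LYS", M3L = "LYS", MLZ = "LYS", KCX = "LYS",
  SEP = "SER", TPO = "THR", PTR = "TYR", CSO = "CYS", CSD = "CYS",
  CME = "CYS", OCS = "CYS", SEC = "CYS", HYP = "PRO", PCA = "GLU"
)

#' Construct a chain of ordered C-alpha records
#'
#' Low-level constructor for the per-chain container used throughout the
#' package: an ordered set of C-alpha coordinates with author numbering kept
#' for reporting. Internal indices are purely positional (1..n, file order);
#' all user-facing boundary reports use the author residue numbers.
#'
#' @param xyz numeric matrix, n x 3, C-alpha coordinates in Angstrom.
#' @param chain_id one-character chain label.
#' @param resno integer author residue numbers (defaults to 1..n).
#' @param insert insertion codes, `""` when absent.
#' @param resid three-letter residue names (defaults to poly-alanine).
#' @return an object of class `chain_structure` with fields `chain_id`,
#'   `n`, `resno`, `insert`, `resid`, `seq` (one-letter string) and `xyz`.
#' @export
chain_structure <- function(xyz, chain_id = "A", resno = NULL,
                            insert = NULL, resid = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L || !all(is.finite(xyz)))
    stop("xyz must be an n x 3 matrix of finite coordinates")
  n <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(insert)) insert <- rep("", n)
  if (is.null(resid)) resid <- rep("ALA", n)
  stopifnot(length(resno) == n, length(insert) == n, length(resid) == n)
  key <- paste(resno, insert)
  if (anyDuplicated(key))
    stop("duplicate (residue number, insertion code) within chain ", chain_id)
  aa1 <- three_to_one(resid)
  structure(
    list(chain_id = chain_id, n = n, resno = as.integer(resno),
         insert = as.character(insert), resid = as.character(resid),
         seq = paste(aa1, collapse = ""), xyz = unname(xyz)),
    class = "chain_structure"
  )
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure> chain %s: %d C-alpha residues (%d-%d)\n",
              x$chain_id, x$n, x$resno[1], x$resno[x$n]))
  invisible(x)
}

# Standard 3->1 letter mapping; modified residues mapped to their parent,
# anything unknown to 'X'.
three_to_one <- function(resid) {
  resid <- toupper(resid)
  parent <- .modres_parent[resid]
  resid[!is.na(parent)] <- parent[!is.na(parent)]
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !out %in% LETTERS] <- "X"
  out
}

#' Read a PDB file into per-chain C-alpha records
#'
#' Parses ATOM (and modified-residue HETATM) records of one model and returns
#' one [chain_structure] per chain that has at least one C-alpha atom.
#' Residues lacking a C-alpha are skipped; for alternate locations the
#' highest-occupancy conformer is kept (ties broken by altLoc label order,
#' blank before 'A' before 'B'); nucleic-acid chains carry no C-alpha and are
#' skipped silently.
#'
#' @param path path to a PDB-format file.
#' @param model model number to read for multi-model (NMR) entries; default
#'   the first model.
#' @return named list of [chain_structure] objects, in file order.
#' @export
read_structure <- function(path, model = 1L) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (model > 1L) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model)
      stop("model ", model, " not present in ", path)
    co <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
    at$x <- co[, 1]; at$y <- co[, 2]; at$z <- co[, 3]
  }
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  keep <- at$elety == "CA" &
    (at$type == "ATOM" |
       (at$type == "HETATM" & toupper(at$resid) %in% names(.modres_parent)))
  ca <- at[keep, , drop = FALSE]
  if (nrow(ca) == 0L)
    stop("no C-alpha atoms found in ", path)
  # altLoc: keep highest occupancy per residue; ties -> lowest altLoc label
  # ('' sorts before 'A').
  ca$o[is.na(ca$o)] <- 1
  key <- paste(ca$chain, ca$resno, ca$insert, sep = "\r")
  ord <- order(match(key, unique(key)), -ca$o, ca$alt)
  ca <- ca[ord, , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno, ca$insert, sep = "\r")), ,
           drop = FALSE]
  chains <- list()
  for (cid in unique(ca$chain)) {
    cc <- ca[ca$chain == cid, , drop = FALSE]
    chains[[cid]] <- chain_structure(
      cbind(cc$x, cc$y, cc$z), chain_id = cid,
      resno = cc$resno, insert = cc$insert, resid = cc$resid
    )
  }
  chains
}

#' Select one chain from a parsed structure
#'
#' @param chains list returned by [read_structure()].
#' @param chain_id chain label; default `"A"`.
#' @return the matching [chain_structure].
#' @export
select_chain <- function(chains, chain_id = "A") {
  if (length(chains) == 0L) stop("empty chain list")
  ids <- vapply(chains, function(ch) ch$chain_id, character(1))
  hit <- which(ids == chain_id)
  if (length(hit) == 0L)
    stop("chain '", chain_id, "' not found; available chains: ",
         paste(ids, collapse = ", "))
  chains[[hit[1]]]
}
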