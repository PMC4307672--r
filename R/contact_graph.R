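# Protein contact network over the C-alpha trace, and its principal
# eigenvector (the per-residue centrality profile the detector reads).

#' Build a C-alpha protein contact network
#'
#' Nodes are the C-alpha atoms of one chain; an undirected edge joins residues
#' i and j (i != j) whenever their Euclidean distance is at most the cutoff
#' `r_c`. The comparison is inclusive: a pair at exactly `r_c` Angstrom is an
#' edge.
#'
#' @param chain a [chain_structure].
#' @param r_c distance cutoff in Angstrom; default 7.0.
#' @return object of class `contact_network`: `n`, binary symmetric
#'   `adjacency` matrix with zero diagonal, `r_c`, and `chain` (the source).
#' @export
build_contact_network <- function(chain, r_c = 7.0) {
  stopifnot(inherits(chain, "chain_structure"))
  if (chain$n < 2L) stop("degenerate structure: need at least 2 residues")
  if (r_c <= 0) stop("r_c must be positive")
  d <- as.matrix(stats::dist(chain$xyz))
  a <- (d <= r_c) * 1L
  diag(a) <- 0L
  dimnames(a) <- NULL
  structure(list(n = chain$n, adjacency = a, r_c = r_c, chain = chain),
            class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("<contact_network> %d nodes, %d edges, r_c = %.2f A\n",
              x$n, sum(x$adjacency) / 2L, x$r_c))
  invisible(x)
}

#' Degree of a node in the contact network
#'
#' @param net a `contact_network`.
#' @param i node index (1-based); if missing, the full degree vector.
#' @return number of adjacent nodes.
#' @export
node_degree <- function(net, i) {
  if (missing(i)) return(as.integer(rowSums(net$adjacency)))
  if (any(i < 1L | i > net$n)) stop("node index out of range")
  as.integer(rowSums(net$adjacency[i, , drop = FALSE]))
}

#' Principal eigenvector profile of the contact network
#'
#' Computes the dominant eigenpair of the adjacency matrix (AX = lambda X).
#' The eigenvector is the per-residue centrality profile: components peak
#' inside densely packed secondary-structure elements. The vector is unit
#' Euclidean norm with sign fixed so the component sum is positive (for a
#' connected network this makes all components nonnegative, by
#' Perron-Frobenius); if the sum is numerically zero the entry of largest
#' magnitude is made positive.
#'
#' @param net a `contact_network`.
#' @return object of class `eigen_profile`: `lam` (principal eigenvalue),
#'   `levc` (length-n component vector), `n`, and `connected` (whether the
#'   network has a single connected component).
#' @export
principal_eigenvector <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  e <- eigen(net$adjacency, symmetric = TRUE)
  lam <- e$values[1]
  v <- e$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  s <- sum(v)
  if (abs(s) > 1e-12) {
    if (s < 0) v <- -v
  } else if (v[which.max(abs(v))] < 0) {
    v <- -v
  }
  resid <- max(abs(net$adjacency %*% v - lam * v))
  if (resid > 1e-8 * max(1, abs(lam)))
    stop(sprintf("eigenpair did not converge: residual %.3e", resid))
  structure(list(lam = lam, levc = as.numeric(v), n = net$n,
                 connected = is_connected_adjacency(net$adjacency)),
            class = "eigen_profile")
}

#' @export
print.eigen_profile <- function(x, ...) {
  cat(sprintf("<eigen_profile> n = %d, lambda = %.4f%s\n", x$n, x$lam,
              if (x$connected) "" else " (disconnected network)"))
  invisible(x)
}

# Breadth-first reachability from node 1.
is_connected_adjacency <- function(a) {
  n <- nrow(a)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    nb <- which(a[i, ] != 0L & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Export the contact network as an edge list
#'
#' @param net a `contact_network`.
#' @return data.frame with columns `i`, `j` (1-based node indices, i < j) and
#'   `distance` (Angstrom).
#' @export
network_edge_list <- function(net) {
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
  d <- sqrt(rowSums((net$chain$xyz[idx[, 1], , drop = FALSE] -
                       net$chain$xyz[idx[, 2], , drop = FALSE])^2))
  ord <- order(idx[, 1], idx[, 2])
  data.frame(i = idx[ord, 1], j = idx[ord, 2], distance = d[ord],
             row.names = NULL)
}

#' Tabulate the centrality profile for plotting or export
#'
#' @param profile an `eigen_profile`.
#' @param chain the matching [chain_structure].
#' @return data.frame with `index` (internal), `resno` (author numbering),
#'   `insert` and `levc` columns.
#' @export
levc_table <- function(profile, chain) {
  stopifnot(profile$n == chain$n)
  data.frame(index = seq_len(chain$n), resno = chain$resno,
             insert = chain$insert, levc = profile$levc)
}
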