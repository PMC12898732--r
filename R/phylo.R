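## phylo_validate: distances, neighbor-joining, bootstrap, monophyly

.char_matrix <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 2L, !is.null(names(seqs)))
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("sequences are not aligned (unequal lengths)")
  m <- t(vapply(seqs, function(s)
    strsplit(toupper(s), "", fixed = TRUE)[[1]], character(L)))
  rownames(m) <- names(seqs)
  m
}

.dist_from_chars <- function(xa, xb, model) {
  valid <- xa %in% c("A", "C", "G", "T") & xb %in% c("A", "C", "G", "T")
  nv <- sum(valid)
  if (nv == 0L) stop("no valid (ungapped, unambiguous) columns shared")
  a <- xa[valid]; b <- xb[valid]
  diffs <- a != b
  if (model == "p") return(sum(diffs) / nv)
  purine <- c("A", "G")
  transition <- diffs & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / nv
  Q <- sum(diffs & !transition) / nv
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0)
    stop("K2P distance undefined (saturation): 1-2P-Q = ", signif(arg1, 4),
         ", 1-2Q = ", signif(arg2, 4))
  -0.5 * log(arg1 * sqrt(arg2))
}

#' Pairwise evolutionary distance between aligned sequences
#'
#' Columns where either sequence has a gap or an ambiguity code are
#' excluded pairwise. The p-distance is the proportion of mismatching
#' valid columns; the Kimura two-parameter (K2P) distance, the barcoding
#' convention, is \eqn{-\frac12 \ln((1-2P-Q)\sqrt{1-2Q})} with transition
#' proportion P and transversion proportion Q.
#'
#' @param a,b equal-length aligned DNA strings.
#' @param model \code{"K2P"} (default) or \code{"p"}.
#' @return the distance (substitutions per site).
#' @export
pairwise_distance <- function(a, b, model = c("K2P", "p")) {
  model <- match.arg(model)
  a <- .check_dna(a, "sequence a"); b <- .check_dna(b, "sequence b")
  if (nchar(a) != nchar(b))
    stop("sequences must be aligned to equal length")
  .dist_from_chars(strsplit(a, "", fixed = TRUE)[[1]],
                   strsplit(b, "", fixed = TRUE)[[1]], model)
}

#' Distance matrix for a set of aligned sequences
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @param model distance model, as in [pairwise_distance()].
#' @return symmetric matrix with zero diagonal, dimnames = sequence names.
#' @export
dist_matrix <- function(seqs, model = c("K2P", "p")) {
  model <- match.arg(model)
  m <- .char_matrix(seqs)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- .dist_from_chars(m[i, ], m[j, ], model)
  d
}

.check_dist <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm),
            !is.null(rownames(dm)))
  if (any(!is.finite(dm))) stop("non-finite distances")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix not symmetric")
  if (max(abs(diag(dm))) > 1e-12) stop("distance matrix diagonal not zero")
  invisible(dm)
}

#' Neighbor-joining tree with negative-branch clamping
#'
#' Saitou-Nei neighbor joining (via \code{ape::nj}) followed by the
#' clamp-and-transfer policy common in barcoding software: any negative
#' branch length is set to zero and its deficit added to the sister
#' branch, preserving total tree length and all leaf-to-leaf path sums
#' through the affected node pair.
#'
#' @param dm symmetric distance matrix with zero diagonal (n >= 3 taxa).
#' @return an unrooted \code{ape::phylo} tree with non-negative branch
#'   lengths.
#' @export
nj_tree <- function(dm) {
  .check_dist(dm)
  if (nrow(dm) < 3L) stop("neighbor joining needs >= 3 taxa")
  tr <- ape::nj(stats::as.dist(dm))
  ## clamp-and-transfer: add the negative value to the sister branch so the
  ## path length through the shared node (and the total tree length) is
  ## preserved, then zero the offending branch
  for (iter in seq_len(10L * length(tr$edge.length))) {
    neg <- which(tr$edge.length < -1e-12)
    if (!length(neg)) break
    e <- neg[1]
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sibs)) {
      ## deterministic: transfer to the sister with the smallest child index
      sib <- sibs[order(tr$edge[sibs, 2])][1]
      tr$edge.length[sib] <- tr$edge.length[sib] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and annotates each internal node of the original tree with
#' the percentage of replicates containing its bipartition. Seeded and
#' reproducible.
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (>= 4 taxa).
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param model distance model, as in [pairwise_distance()].
#' @return the NJ tree of the full alignment with integer percent supports
#'   in \code{$node.label}.
#' @export
bootstrap_support <- function(seqs, n_reps = 1000L, seed = 1L,
                              model = c("K2P", "p")) {
  model <- match.arg(model)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  m <- .char_matrix(seqs)
  if (nrow(m) < 4L) stop("bootstrap supports need >= 4 taxa")
  L <- ncol(m)
  dist_of <- function(cm) {
    n <- nrow(cm)
    d <- matrix(0, n, n, dimnames = list(rownames(cm), rownames(cm)))
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n)
        d[i, j] <- d[j, i] <- .dist_from_chars(cm[i, ], cm[j, ], model)
    d
  }
  tr <- nj_tree(dist_of(m))
  set.seed(as.integer(seed))
  boots <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    boots[[b]] <- nj_tree(dist_of(m[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(tr, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tr$node.label <- as.integer(round(100 * counts / n_reps))
  tr
}

#' Monophyly check against tree bipartitions
#'
#' A taxon group is monophyletic on an unrooted tree iff some edge
#' bipartition separates exactly that group from the rest; singleton
#' groups (and the full leaf set) are monophyletic by convention.
#'
#' @param tree an \code{ape::phylo} tree.
#' @param group_map named list label -> character vector of tip labels.
#' @return named logical vector, one entry per group.
#' @export
clade_check <- function(tree, group_map) {
  stopifnot(inherits(tree, "phylo"), is.list(group_map),
            !is.null(names(group_map)))
  tips <- tree$tip.label
  unknown <- setdiff(unlist(group_map), tips)
  if (length(unknown))
    stop("unknown taxon/taxa: ", paste(unknown, collapse = ", "))
  parts <- lapply(ape::prop.part(tree), function(p) sort(tips[p]))
  vapply(group_map, function(g) {
    g <- sort(unique(g))
    if (length(g) <= 1L || length(g) >= length(tips) - 1L) return(TRUE)
    comp <- sort(setdiff(tips, g))
    any(vapply(parts, function(p)
      identical(p, g) || identical(p, comp), logical(1)))
  }, logical(1))
}
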