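# Distance-based phylogeny of the paralog family: p / JC69 distances with
# pairwise gap deletion, Saitou-Nei neighbor joining with a deterministic
# tie rule, and column-resampling bootstrap support.  ape supplies the tree
# container and newick I/O; the NJ agglomeration itself is implemented here
# so the tie-break (lexicographically smallest taxon pair) is guaranteed.

#' Pairwise evolutionary distance between two aligned sequences
#'
#' Columns where either sequence has a gap are excluded (pairwise deletion).
#' \code{p} is the mismatch proportion; \code{jc69} is the Jukes-Cantor
#' correction \code{-(3/4) ln(1 - 4p/3)} (substitutions per site).
#'
#' @param a,b Equal-length aligned sequences (gaps as \code{"-"}).
#' @param model \code{"p"} or \code{"jc69"}.
#' @return Distance (substitutions per site).
#' @export
pairwise_distance <- function(a, b, model = c("p", "jc69")) {
  model <- match.arg(model)
  ac <- strsplit(as_seq_string(a), "", fixed = TRUE)[[1L]]
  bc <- strsplit(as_seq_string(b), "", fixed = TRUE)[[1L]]
  if (length(ac) != length(bc))
    stop("pairwise_distance: sequences must be aligned to equal length")
  keep <- ac != "-" & bc != "-"
  if (!any(keep)) stop("pairwise_distance: no comparable columns")
  p <- mean(ac[keep] != bc[keep])
  if (model == "p") return(p)
  if (p >= 0.75)
    stop("pairwise_distance: distance undefined under jc69 (p >= 0.75)")
  -0.75 * log(1 - 4 * p / 3)
}

#' Distance matrix for a set of aligned sequences
#'
#' @param alignment Named character vector (or list of [seq_record]s) of
#'   equal-length gapped sequences.
#' @param model See [pairwise_distance()].
#' @return Symmetric numeric matrix with zero diagonal, taxon ids as
#'   dimnames.
#' @export
distance_matrix <- function(alignment, model = c("p", "jc69")) {
  model <- match.arg(model)
  if (is.list(alignment)) {
    nm <- vapply(alignment, record_id, "")
    alignment <- stats::setNames(vapply(alignment, as_seq_string, ""), nm)
  }
  n <- length(alignment)
  ids <- names(alignment)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("distance_matrix: alignment must be named")
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      D[i, j] <- D[j, i] <-
        pairwise_distance(alignment[[i]], alignment[[j]], model = model)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration minimizing the Q criterion; ties are broken by
#' the lexicographically smallest pair of clade representatives (the
#' smallest leaf name in each clade), so the result is deterministic.
#' Negative branch lengths are clamped to zero with a warning.
#'
#' @param D Symmetric distance matrix with taxon ids as dimnames (>= 3 taxa).
#' @return An unrooted \code{ape::phylo} tree with branch lengths.
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D) || nrow(D) < 3L)
    stop("nj_tree: need a square matrix over >= 3 taxa")
  if (max(abs(D - t(D))) > 1e-9) stop("nj_tree: non-symmetric matrix")
  ids <- rownames(D)
  if (is.null(ids)) stop("nj_tree: matrix must have taxon ids as dimnames")
  frag <- ids           # newick fragment per active node
  rep_leaf <- ids       # smallest leaf name per active node (tie rule)
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  while (length(frag) > 3L) {
    n <- length(frag)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key1 <- pmin(rep_leaf[cand[, 1L]], rep_leaf[cand[, 2L]])
    key2 <- pmax(rep_leaf[cand[, 1L]], rep_leaf[cand[, 2L]])
    pick <- order(key1, key2)[[1L]]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    li <- clamp(D[i, j] / 2 + (r[[i]] - r[[j]]) / (2 * (n - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (r[[i]] - r[[j]]) / (2 * (n - 2))))
    newfrag <- sprintf("(%s:%.12g,%s:%.12g)", frag[[i]], li, frag[[j]], lj)
    newrep <- min(rep_leaf[[i]], rep_leaf[[j]])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], newrep)
    D <- D2
    frag <- c(frag[keep], newfrag)
    rep_leaf <- c(rep_leaf[keep], newrep)
  }
  d12 <- D[1L, 2L]; d13 <- D[1L, 3L]; d23 <- D[2L, 3L]
  l1 <- clamp((d12 + d13 - d23) / 2)
  l2 <- clamp((d12 + d23 - d13) / 2)
  l3 <- clamp((d13 + d23 - d12) / 2)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[[1L]], l1, frag[[2L]], l2, frag[[3L]], l3)
  if (clamped)
    warning("nj_tree: negative branch length(s) clamped to zero")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "newick") <- nwk
  tree
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement \code{n_replicates} times,
#' rebuilds the NJ tree per replicate, and reports the percentage of
#' replicates containing each internal bipartition of the full-alignment
#' tree. Fully reproducible given the seed.
#'
#' @param alignment Named character vector of equal-length gapped sequences.
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param model Distance model, see [pairwise_distance()].
#' @return The NJ tree with node labels set to percent support (the root
#'   label stays empty); supports are also in \code{attr(, "support")}.
#' @export
bootstrap_support <- function(alignment, n_replicates, seed,
                              model = c("p", "jc69")) {
  model <- match.arg(model)
  if (is.list(alignment)) {
    nm <- vapply(alignment, record_id, "")
    alignment <- stats::setNames(vapply(alignment, as_seq_string, ""), nm)
  }
  ncol <- unique(nchar(alignment))
  if (length(ncol) != 1L)
    stop("bootstrap_support: sequences must be aligned to equal length")
  if (ncol < 1L || n_replicates < 1L)
    stop("bootstrap_support: need >= 1 column and >= 1 replicate")
  main <- nj_tree(distance_matrix(alignment, model = model))
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  boots <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol, ncol, replace = TRUE)
    res <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
    boots[[b]] <- nj_tree(distance_matrix(stats::setNames(res, names(alignment)),
                                          model = model))
  }
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  support <- round(100 * counts / n_replicates)
  lab <- as.character(support)
  lab[is.na(lab)] <- ""
  main$node.label <- lab
  attr(main, "support") <- support
  main
}

#' Write a tree to a newick file
#' @param tree An \code{ape::phylo} tree (e.g. from [nj_tree()]).
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
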