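# Distance-based family phylogeny with bootstrap support, class assignment
# by edge cutting, and exon-intron structure statistics.

#' Poisson-corrected protein distance matrix
#'
#' Pairwise p-distances over shared non-gap columns, corrected as
#' `d = -ln(1 - p)` (Poisson model of amino-acid substitution).
#'
#' @param alignment named character vector of equal-length gap-aligned
#'   protein strings, at least 3 sequences.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(alignment) {
  stopifnot(!is.null(names(alignment)), length(alignment) >= 3L)
  L <- unique(nchar(alignment))
  if (length(L) != 1L) stop("alignment rows have unequal lengths")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(mat) <- names(alignment)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      shared <- mat[i, ] != "-" & mat[j, ] != "-"
      ns <- sum(shared)
      if (ns == 0L) {
        stop("sequences '", names(alignment)[i], "' and '",
             names(alignment)[j], "' share no aligned columns")
      }
      p <- sum(mat[i, shared] != mat[j, shared]) / ns
      if (p >= 1) {
        stop("saturated distance between '", names(alignment)[i], "' and '",
             names(alignment)[j], "' (p = 1)")
      }
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining via [ape::nj()]; negative branch lengths are
#' clamped to zero.
#'
#' @param d symmetric non-negative distance matrix, >= 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  if (any(d < 0)) stop("distance matrix must be non-negative")
  tree <- ape::nj(d)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# canonical bipartition key: the side not containing the reference taxon
split_key <- function(tips, all_tips) {
  ref <- sort(all_tips)[1L]
  side <- if (ref %in% tips) setdiff(all_tips, tips) else tips
  paste(sort(side), collapse = "|")
}

tree_split_keys <- function(tree) {
  parts <- ape::prop.part(tree)
  labels <- attr(parts, "labels")
  vapply(parts, function(idx) split_key(labels[idx], labels), character(1))
}

#' Bootstrap support for a neighbor-joining protein tree
#'
#' Resamples alignment columns with replacement `n` times, rebuilds the
#' Poisson-distance NJ tree for each replicate, and reports per-bipartition
#' support (percent of replicates containing the same split) as node labels
#' on the reference tree.
#'
#' @param alignment named character vector of gap-aligned proteins.
#' @param n number of bootstrap replicates (default 1000, the conventional
#'   choice for family trees).
#' @param seed RNG seed; fixed seed gives identical supports across runs.
#' @return object of class `bootstrap_phylo`: a list with `tree` (reference
#'   NJ tree, `node.label` = support in percent, `NA` at the root), `n`,
#'   and the replicate split counts used by [split_support()].
#' @export
bootstrap_tree <- function(alignment, n = 1000L, seed = 1L) {
  set.seed(as.integer(seed))
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(mat) <- names(alignment)
  L <- ncol(mat)
  ref <- nj_tree(distance_matrix(alignment))
  counts <- new.env(parent = emptyenv())
  for (b in seq_len(n)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- setNames(apply(mat[, cols, drop = FALSE], 1L, paste, collapse = ""),
                        rownames(mat))
    keys <- tree_split_keys(nj_tree(distance_matrix(rep_aln)))
    for (k in keys) {
      if (!nzchar(k)) next  # root part (all tips): trivial
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
    }
  }
  ref_keys <- tree_split_keys(ref)
  support <- vapply(ref_keys, function(k) {
    if (!nzchar(k)) return(NA_real_)
    100 * (counts[[k]] %||% 0L) / n
  }, numeric(1))
  # the part containing all tips (the root "split") is trivial
  parts <- ape::prop.part(ref)
  trivial <- vapply(parts, length, integer(1)) == length(ref$tip.label)
  support[trivial] <- NA_real_
  ref$node.label <- unname(support)
  structure(list(tree = ref, n = n,
                 counts = as.list(counts), tips = sort(ref$tip.label)),
            class = "bootstrap_phylo")
}

#' @export
print.bootstrap_phylo <- function(x, ...) {
  cat(sprintf("<bootstrap_phylo> %d tips, %d replicates; min support %.1f%%\n",
              length(x$tree$tip.label), x$n,
              suppressWarnings(min(x$tree$node.label, na.rm = TRUE))))
  invisible(x)
}

#' Bootstrap support of a given tip bipartition
#'
#' @param bs a `bootstrap_phylo` from [bootstrap_tree()].
#' @param tips character vector of tip labels forming one side of the split.
#' @return support in percent (0 if the split never occurred).
#' @export
split_support <- function(bs, tips) {
  stopifnot(all(tips %in% bs$tips))
  key <- split_key(tips, bs$tips)
  if (!nzchar(key)) return(100)  # trivial split (all tips on one side)
  100 * (bs$counts[[key]] %||% 0L) / bs$n
}

#' Assign family classes by cutting long tree edges
#'
#' Cuts the `k - 1` longest eligible edges of the tree (longest first, ties
#' broken by the smallest tip label below the edge); an edge is eligible
#' when removing it separates two parts that each still contain at least
#' one tip, so every cut increases the class count by exactly one. For
#' well-separated clades this reduces to cutting the longest internal
#' edges. Classes are numbered by decreasing size (ties by smallest member
#' label).
#'
#' @param tree a `phylo` tree (a `bootstrap_phylo` is also accepted).
#' @param k number of classes, `1 <= k <= ` leaf count.
#' @return named integer vector: tip label -> class in `1..k`.
#' @export
assign_classes <- function(tree, k = 3L) {
  if (inherits(tree, "bootstrap_phylo")) tree <- tree$tree
  ntip <- length(tree$tip.label)
  if (k < 1L || k > ntip) stop("k must be between 1 and the leaf count (", ntip, ")")
  edges <- tree$edge
  lens <- tree$edge.length
  nnode <- max(edges)
  cut <- rep(FALSE, nrow(edges))

  components <- function() {
    parent <- seq_len(nnode)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (e in which(!cut)) {
      ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
      if (ra != rb) parent[rb] <- ra
    }
    vapply(seq_len(nnode), find, integer(1))
  }

  # deterministic edge order: longest first, ties by the smallest tip label
  # below the edge's child node
  tips_below <- lapply(seq_len(nrow(edges)), function(e) {
    node <- edges[e, 2]
    if (node <= ntip) tree$tip.label[node]
    else tree$tip.label[unlist(ape::prop.part(tree)[[node - ntip]])]
  })
  ord <- order(-lens, vapply(tips_below, function(t) sort(t)[1L], character(1)))

  for (cut_i in seq_len(k - 1L)) {
    done <- FALSE
    for (e in ord) {
      if (cut[e]) next
      cut[e] <- TRUE
      comp2 <- components()
      sides <- comp2[c(edges[e, 1], edges[e, 2])]
      tip_comp <- comp2[seq_len(ntip)]
      if (sides[1] != sides[2] && all(sides %in% tip_comp)) {
        done <- TRUE
        break
      }
      cut[e] <- FALSE
    }
    if (!done) stop("cannot split the tree into ", k, " leaf-bearing classes")
  }
  comp <- components()
  tip_comp <- comp[seq_len(ntip)]
  groups <- split(tree$tip.label, tip_comp)
  ord_g <- order(-vapply(groups, length, integer(1)),
                 vapply(groups, function(g) sort(g)[1L], character(1)))
  out <- integer(ntip)
  names(out) <- tree$tip.label
  for (ci in seq_along(ord_g)) out[groups[[ord_g[ci]]]] <- ci
  out
}

#' Exon-intron structure statistics
#'
#' @param models list of [gene_model] objects.
#' @return data.frame with `gene_id`, `exon_count`, `intron_count`
#'   (`exon_count - 1`) and `cds_length` in bp.
#' @export
exon_intron_stats <- function(models) {
  if (length(models) == 0L) {
    return(data.frame(gene_id = character(0), exon_count = integer(0),
                      intron_count = integer(0), cds_length = integer(0)))
  }
  rows <- lapply(models, function(m) {
    ne <- nrow(m$exon_intervals)
    data.frame(gene_id = m$gene_id, exon_count = ne,
               intron_count = ne - 1L,
               cds_length = sum(m$cds_intervals[, 2] - m$cds_intervals[, 1] + 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
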