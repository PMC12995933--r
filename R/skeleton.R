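# Morphological thinning and skeleton branch decomposition.
# EBImage provides no thinning, so Guo-Hall two-subiteration thinning is
# implemented here, vectorised over the whole image per sub-iteration.

# 8-neighbourhood values (clockwise from north) as matrices.
neighbour_stack <- function(x) {
  list(p2 = shift_mat(x, 1, 0),  p3 = shift_mat(x, 1, -1),
       p4 = shift_mat(x, 0, -1), p5 = shift_mat(x, -1, -1),
       p6 = shift_mat(x, -1, 0), p7 = shift_mat(x, -1, 1),
       p8 = shift_mat(x, 0, 1),  p9 = shift_mat(x, 1, 1))
}

#' Skeletonize a binary mask by morphological thinning
#'
#' Guo-Hall two-subiteration thinning: iteratively peels boundary pixels
#' until a 1-pixel-wide, topology-preserving centerline remains.  Free
#' ends of straight bars are preserved to within about one pixel.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical matrix of the same shape (the skeleton, a subset of the
#'   mask).
#' @export
thin_skeleton <- function(mask) {
  x <- (mask > 0) * 1
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # x1..x8 clockwise from east (Lam-Lee-Suen convention)
      x1 <- shift_mat(x, 0, -1);  x2 <- shift_mat(x, 1, -1)
      x3 <- shift_mat(x, 1, 0);   x4 <- shift_mat(x, 1, 1)
      x5 <- shift_mat(x, 0, 1);   x6 <- shift_mat(x, -1, 1)
      x7 <- shift_mat(x, -1, 0);  x8 <- shift_mat(x, -1, -1)
      XH <- (1 - x1) * pmax(x2, x3) + (1 - x3) * pmax(x4, x5) +
            (1 - x5) * pmax(x6, x7) + (1 - x7) * pmax(x8, x1)
      n1 <- pmax(x1, x2) + pmax(x3, x4) + pmax(x5, x6) + pmax(x7, x8)
      n2 <- pmax(x2, x3) + pmax(x4, x5) + pmax(x6, x7) + pmax(x8, x1)
      nmin <- pmin(n1, n2)
      g3 <- if (step == 1L) pmax(x2, x3, 1 - x8) * x1 else
        pmax(x6, x7, 1 - x4) * x5
      del <- x == 1 & XH == 1 & nmin >= 2 & nmin <= 3 & g3 == 0
      if (any(del)) {
        x[del] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  x > 0
}

# 8-connected component labelling via igraph (EBImage::bwlabel is
# 4-connected, which would split diagonal skeleton chains).
label_components_8 <- function(mask) {
  idx <- which(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(out)
  h <- nrow(mask)
  pos <- integer(length(mask)); pos[idx] <- seq_along(idx)
  edges <- NULL
  row_of <- function(i) ((i - 1L) %% h) + 1L
  for (off in c(1L, h, h + 1L, h - 1L)) {   # S, E, SE, NE neighbours
    a <- idx
    if (off %in% c(1L, h + 1L)) a <- a[row_of(a) < h]
    if (off == h - 1L) a <- a[row_of(a) > 1L]
    a <- a[a + off <= length(mask)]
    b <- a + off
    keep <- mask[b]
    edges <- rbind(edges, cbind(pos[a[keep]], pos[b[keep]]))
  }
  if (is.null(edges) || nrow(edges) == 0L) {
    out[idx] <- seq_along(idx)
    return(out)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  out[idx] <- as.integer(memb)
  out
}

# Euclidean path length of one set of chain pixels: orthogonal adjacencies
# count 1, diagonal adjacencies sqrt(2) unless they shortcut an orthogonal
# step, plus 1 so an n-pixel straight chain measures n.
chain_length <- function(bin) {
  h <- nrow(bin)
  n_o <- sum(bin & shift_mat(bin, 1, 0)) + sum(bin & shift_mat(bin, 0, 1))
  dg1 <- bin & shift_mat(bin, 1, 1)    # pixel and its NW neighbour
  dg2 <- bin & shift_mat(bin, 1, -1)   # pixel and its NE neighbour
  # drop diagonals with a shared orthogonal neighbour inside the chain
  dg1 <- dg1 & !(shift_mat(bin, 1, 0) & shift_mat(bin, 0, 1))
  dg2 <- dg2 & !(shift_mat(bin, 1, 0) & shift_mat(bin, 0, -1))
  max(1, n_o + sqrt(2) * (sum(dg1) + sum(dg2)) + 1)
}

#' Decompose a skeleton into branches
#'
#' Splits a skeleton at its branch points (pixels with three or more
#' skeleton neighbours) and labels the remaining chains as individual
#' branches; each branch gets a Euclidean path length (orthogonal steps
#' count 1 px, diagonal steps `sqrt(2)` px).
#'
#' @param skeleton logical matrix from [thin_skeleton()].
#' @return list with `labels` (integer matrix, 0 = background/branch
#'   point) and `lengths` (numeric vector, one per branch, >= 1 px).
#' @export
skeleton_branches <- function(skeleton) {
  sk <- skeleton > 0
  if (!any(sk)) return(list(labels = matrix(0L, nrow(sk), ncol(sk)),
                            lengths = numeric(0)))
  nb <- neighbour_stack(sk * 1)
  ncount <- Reduce(`+`, nb)
  branchpt <- sk & ncount >= 3
  labels <- label_components_8(sk & !branchpt)
  nb_lab <- max(labels)
  if (nb_lab == 0L) {           # skeleton is all branch points (tiny blob)
    labels <- label_components_8(sk)
    nb_lab <- max(labels)
  }
  lengths <- vapply(seq_len(nb_lab), function(b) chain_length(labels == b), 0)
  list(labels = labels, lengths = lengths)
}
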