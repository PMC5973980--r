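# Independent re-implementation of the (26, 6) medial-axis thinning used for
# centreline extraction: same directional sub-iterations and raster order,
# but the simple-point tests are done with igraph component counts instead of
# hand-rolled flood fills. Slow; only for small oracle masks.

thin3d_oracle <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  d <- dim(mask)
  pos27 <- as.matrix(expand.grid(x = 1:3, y = 1:3, z = 1:3))
  man <- abs(pos27[, 1] - 2) + abs(pos27[, 2] - 2) + abs(pos27[, 3] - 2)
  in18 <- man >= 1 & man <= 2
  is_face <- man == 1

  deletable <- function(a, x, y, z) {
    nb <- a[(x - 1):(x + 1), (y - 1):(y + 1), (z - 1):(z + 1)]
    fg <- nb[cbind(pos27[, 1], pos27[, 2], pos27[, 3])]
    fg[14] <- FALSE  # centre excluded
    n <- sum(fg)
    if (n <= 1) return(FALSE)  # end-point or isolated
    # exactly one 26-connected foreground component in the neighbourhood
    p <- pos27[fg, , drop = FALSE]
    if (nrow(p) > 1) {
      adj <- as.matrix(stats::dist(p, method = "maximum")) <= 1
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
      if (igraph::components(g)$no != 1) return(FALSE)
    }
    # exactly one 6-connected background component in the 18-neighbourhood
    # that touches a face neighbour
    bgsel <- which(!fg & in18 & man > 0)
    bgsel <- setdiff(bgsel, 14L)
    if (!length(bgsel)) return(FALSE)
    p <- pos27[bgsel, , drop = FALSE]
    if (nrow(p) == 1) {
      comp <- 1L
    } else {
      adj <- as.matrix(stats::dist(p, method = "manhattan")) == 1
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
      comp <- igraph::components(g)$membership
    }
    face_comps <- unique(comp[is_face[bgsel]])
    length(face_comps) == 1
  }

  dirs <- rbind(c(0, 0, 1), c(0, 0, -1), c(0, 1, 0), c(0, -1, 0),
                c(1, 0, 0), c(-1, 0, 0))
  a <- mask
  repeat {
    changed <- FALSE
    for (di in 1:6) {
      dv <- dirs[di, ]
      cand <- matrix(integer(0), 0, 3)
      for (z in 2:(d[3] - 1)) for (y in 2:(d[2] - 1)) for (x in 2:(d[1] - 1)) {
        if (!a[x, y, z]) next
        if (a[x + dv[1], y + dv[2], z + dv[3]]) next
        if (deletable(a, x, y, z)) cand <- rbind(cand, c(x, y, z))
      }
      for (r in seq_len(nrow(cand))) {
        x <- cand[r, 1]; y <- cand[r, 2]; z <- cand[r, 3]
        if (deletable(a, x, y, z)) {
          a[x, y, z] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  a
}
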