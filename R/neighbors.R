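# Internal fixed-radius neighbor search via grid binning. All inputs in a
# common length unit (nm throughout the package).

# All index pairs (i, j) with distance <= eps, including self pairs
# (i, i). Fully vectorized: points are binned into eps-sized cells and
# candidate pairs come from the 3x3 cell neighborhood.
radius_pairs <- function(x, y, eps) {
  n <- length(x)
  if (n == 0) {
    return(list(i = integer(0), j = integer(0)))
  }
  cx <- as.integer(floor(x / eps)); cy <- as.integer(floor(y / eps))
  cx <- cx - min(cx); cy <- cy - min(cy)
  ncx <- max(cx) + 1L; ncy <- max(cy) + 1L
  cid <- cx + cy * ncx + 1L
  ncell <- ncx * ncy
  ord <- order(cid)
  counts <- tabulate(cid, nbins = ncell)
  cell_end <- cumsum(counts)
  cell_start <- cell_end - counts + 1L
  res_i <- vector("list", 9L); res_j <- vector("list", 9L)
  k <- 0L
  for (ox in -1:1) {
    for (oy in -1:1) {
      k <- k + 1L
      tx <- cx + ox; ty <- cy + oy
      ok <- which(tx >= 0L & tx < ncx & ty >= 0L & ty < ncy)
      if (!length(ok)) next
      tid <- tx[ok] + ty[ok] * ncx + 1L
      cnt <- counts[tid]
      has <- cnt > 0L
      if (!any(has)) next
      ok <- ok[has]; tid <- tid[has]; cnt <- cnt[has]
      ii <- rep.int(ok, cnt)
      jj <- ord[sequence(cnt, from = cell_start[tid])]
      d2 <- (x[ii] - x[jj])^2 + (y[ii] - y[jj])^2
      keep <- d2 <= eps * eps
      res_i[[k]] <- ii[keep]; res_j[[k]] <- jj[keep]
    }
  }
  list(i = unlist(res_i, use.names = FALSE),
       j = unlist(res_j, use.names = FALSE))
}

# For each query point, the nearest reference point within max_dist.
# Returns list(index, dist) with NA where nothing lies within range.
nearest_within <- function(qx, qy, rx, ry, max_dist) {
  nq <- length(qx); nr <- length(rx)
  idx <- rep(NA_integer_, nq); dst <- rep(NA_real_, nq)
  if (nq == 0 || nr == 0) return(list(index = idx, dist = dst))
  eps <- max_dist
  x0 <- min(qx, rx); y0 <- min(qy, ry)
  cxq <- as.integer(floor((qx - x0) / eps))
  cyq <- as.integer(floor((qy - y0) / eps))
  cxr <- as.integer(floor((rx - x0) / eps))
  cyr <- as.integer(floor((ry - y0) / eps))
  ncx <- max(cxq, cxr) + 1L; ncy <- max(cyq, cyr) + 1L
  cidr <- cxr + cyr * ncx + 1L
  ncell <- ncx * ncy
  ord <- order(cidr)
  counts <- tabulate(cidr, nbins = ncell)
  cell_end <- cumsum(counts)
  cell_start <- cell_end - counts + 1L
  best_d2 <- rep(Inf, nq)
  for (ox in -1:1) {
    for (oy in -1:1) {
      tx <- cxq + ox; ty <- cyq + oy
      ok <- which(tx >= 0L & tx < ncx & ty >= 0L & ty < ncy)
      if (!length(ok)) next
      tid <- tx[ok] + ty[ok] * ncx + 1L
      cnt <- counts[tid]
      has <- cnt > 0L
      if (!any(has)) next
      ok <- ok[has]; tid <- tid[has]; cnt <- cnt[has]
      ii <- rep.int(ok, cnt)
      jj <- ord[sequence(cnt, from = cell_start[tid])]
      d2 <- (qx[ii] - rx[jj])^2 + (qy[ii] - ry[jj])^2
      upd <- which(d2 < best_d2[ii])
      if (length(upd)) {
        # Within one offset block a query can meet several candidates;
        # resolve with a per-query min.
        o <- order(ii[upd], d2[upd])
        u <- upd[o][!duplicated(ii[upd][o])]
        better <- d2[u] < best_d2[ii[u]]
        u <- u[better]
        best_d2[ii[u]] <- d2[u]
        idx[ii[u]] <- jj[u]
      }
    }
  }
  inrange <- best_d2 <= max_dist^2
  idx[!inrange] <- NA_integer_
  dst[inrange] <- sqrt(best_d2[inrange])
  list(index = idx, dist = dst)
}

# Connected components over an undirected edge list (list(i, j));
# delegated to igraph, which handles the multi-million-edge graphs that
# dense clusters produce.
connected_components <- function(n, links) {
  if (length(links$i) == 0) return(seq_len(n))
  g <- igraph::make_graph(rbind(links$i, links$j), n = n, directed = FALSE)
  as.integer(igraph::components(g)$membership)
}
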