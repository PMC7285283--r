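# Morphological thinning (Zhang-Suen) of a logical matrix to a one-pixel
# skeleton. The two sub-iterations are applied in a fixed order over the
# whole image (vectorised raster passes), so the result is deterministic
# and platform-independent.
thin_binary <- function(B, max_iter = 1000L) {
  stopifnot(is.logical(B))
  P <- B * 1L
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours p2..p9: N, NE, E, SE, S, SW, W, NW
      nb <- lapply(seq_len(8L), function(i)
        shift_mat(P, NBR8[i, 1L], NBR8[i, 2L], 0L))
      Bsum <- Reduce(`+`, nb)
      A <- matrix(0L, nrow(P), ncol(P))
      for (i in seq_len(8L)) {
        j <- if (i == 8L) 1L else i + 1L
        A <- A + (nb[[i]] == 0L & nb[[j]] == 1L)
      }
      if (sub == 1L) {
        c1 <- nb[[1L]] * nb[[3L]] * nb[[5L]] == 0L  # p2*p4*p6
        c2 <- nb[[3L]] * nb[[5L]] * nb[[7L]] == 0L  # p4*p6*p8
      } else {
        c1 <- nb[[1L]] * nb[[3L]] * nb[[7L]] == 0L  # p2*p4*p8
        c2 <- nb[[1L]] * nb[[5L]] * nb[[7L]] == 0L  # p2*p6*p8
      }
      del <- P == 1L & Bsum >= 2L & Bsum <= 6L & A == 1L & c1 & c2
      if (any(del)) {
        P[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # Zhang-Suen can leave solid 2x2 blocks where branches meet; remove
  # simple pixels (deletable without breaking local connectivity) from such
  # blocks in raster order until none remain
  repeat {
    solid <- P[-nrow(P), -ncol(P), drop = FALSE] &
             P[-1, -ncol(P), drop = FALSE] &
             P[-nrow(P), -1, drop = FALSE] & P[-1, -1, drop = FALSE]
    blk <- which(solid == 1L, arr.ind = TRUE)
    if (nrow(blk) == 0L) break
    removed <- FALSE
    cand <- unique(rbind(blk, blk + rep(c(1L, 0L), each = nrow(blk)),
                         blk + rep(c(0L, 1L), each = nrow(blk)),
                         blk + 1L))
    cand <- cand[order(cand[, 2L], cand[, 1L]), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1L]; c <- cand[i, 2L]
      if (P[r, c] == 0L) next
      # still part of a solid block?
      in_block <- FALSE
      for (dr in c(-1L, 0L)) for (dc in c(-1L, 0L)) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1L && cc >= 1L && rr + 1L <= nrow(P) && cc + 1L <= ncol(P) &&
            P[rr, cc] && P[rr + 1L, cc] && P[rr, cc + 1L] && P[rr + 1L, cc + 1L])
          in_block <- TRUE
      }
      if (!in_block) next
      nbv <- integer(8L)
      for (k in seq_len(8L)) {
        rr <- r + NBR8[k, 1L]; cc <- c + NBR8[k, 2L]
        nbv[k] <- if (rr >= 1L && rr <= nrow(P) && cc >= 1L && cc <= ncol(P))
          P[rr, cc] else 0L
      }
      # deletable iff the set neighbours form one 8-connected component
      # (true adjacency among the ring cells, not just ring order) and a
      # 4-neighbour is background
      on <- which(nbv == 1L)
      if (length(on) >= 2L && length(on) <= 7L &&
          any(nbv[c(1L, 3L, 5L, 7L)] == 0L)) {
        pos <- NBR8[on, , drop = FALSE]
        comp <- seq_along(on)
        for (a1 in seq_along(on)) for (a2 in seq_along(on)) {
          if (a1 < a2 &&
              max(abs(pos[a1, ] - pos[a2, ])) <= 1L &&
              comp[a1] != comp[a2])
            comp[comp == comp[a2]] <- comp[a1]
        }
        if (length(unique(comp)) == 1L) {
          P[r, c] <- 0L
          removed <- TRUE
        }
      }
    }
    if (!removed) break
  }
  P == 1L
}

# 8-connected component labels for the TRUE pixels of a logical matrix.
# Returns an integer matrix (0 = background).
label_components8 <- function(B) {
  lab <- matrix(0L, nrow(B), ncol(B))
  idx <- which(B)
  if (length(idx) == 0L) return(lab)
  nr <- nrow(B)
  pos <- integer(length(B)); pos[idx] <- seq_along(idx)
  edges <- list(); k <- 0L
  # scan 4 of the 8 directions; the symmetric ones are implied
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    r2 <- r + off[1L]; c2 <- c + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(B)
    idx2 <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- B[idx2]
    if (any(hit)) {
      k <- k + 1L
      edges[[k]] <- cbind(pos[idx[ok][hit]], pos[idx2[hit]])
    }
  }
  el <- if (k > 0L) do.call(rbind, edges) else matrix(integer(0), 0L, 2L)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp[seq_along(idx)]
  lab
}

# Neighbouring TRUE pixels of (r, c) in B, as an n x 2 matrix.
nbrs_of <- function(B, r, c) {
  rs <- r + NBR8[, 1L]; cs <- c + NBR8[, 2L]
  ok <- rs >= 1L & rs <= nrow(B) & cs >= 1L & cs <= ncol(B)
  rs <- rs[ok]; cs <- cs[ok]
  on <- B[cbind(rs, cs)]
  cbind(rs[on], cs[on])
}

# Remove terminal branches shorter than shave_len: the path from an endpoint
# up to and including the pixel that attaches to the main body (>= 2
# neighbours outside the path), iterating to a fixed point; then delete
# 8-connected components with fewer than del_len pixels.
prune_binary <- function(B, shave_len, del_len, max_rounds = 100L) {
  if (shave_len > 0) {
    for (round in seq_len(max_rounds)) {
      nc <- neighbor_count(B)
      eps <- which(B & nc == 1L, arr.ind = TRUE)
      if (nrow(eps) == 0L) break
      remove <- matrix(integer(0), 0L, 2L)
      for (e in seq_len(nrow(eps))) {
        path <- eps[e, , drop = FALSE]
        cur <- eps[e, ]
        is_branch <- FALSE
        repeat {
          nb <- nbrs_of(B, cur[1L], cur[2L])
          in_path <- logical(nrow(nb))
          for (q in seq_len(nrow(nb)))
            in_path[q] <- any(path[, 1L] == nb[q, 1L] &
                              path[, 2L] == nb[q, 2L])
          nb <- nb[!in_path, , drop = FALSE]
          if (nrow(nb) == 0L) break            # pure path: del stage
          if (nrow(nb) >= 2L) { is_branch <- TRUE; break }  # attachment
          if (nrow(path) >= shave_len) break   # long enough, keep
          cur <- nb[1L, ]
          path <- rbind(path, cur)
        }
        if (is_branch && nrow(path) < shave_len)
          remove <- rbind(remove, path)
      }
      if (nrow(remove) == 0L) break
      B[remove] <- FALSE
    }
  }
  if (del_len > 0) {
    lab <- label_components8(B)
    if (max(lab) > 0L) {
      sizes <- tabulate(lab[lab > 0L])
      drop <- which(sizes < del_len)
      if (length(drop) > 0L) B[lab %in% drop] <- FALSE
    }
  }
  B
}

# Fill background holes of at most `max_area` pixels (4-connected holes of
# an 8-connected foreground). Border-touching background is never a hole.
fill_small_holes <- function(B, max_area = 9L) {
  lab <- EBImage::bwlabel((!B) * 1)
  lab <- as.matrix(lab)
  if (max(lab) == 0L) return(B)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0L])
  fill <- setdiff(which(sizes <= max_area), border)
  if (length(fill) > 0L) B[lab %in% fill] <- TRUE
  B
}
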