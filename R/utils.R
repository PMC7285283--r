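# Internal helpers shared across the pipeline.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state; seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

stop_cwrq <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cwrq_error")))
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_cwrq(sprintf("`%s` must be a single finite number", name),
              "cwrq_config_error")
  ok <- if (strict) x > min else x >= min
  if (!ok)
    stop_cwrq(sprintf("`%s` must be %s %g", name,
                      if (strict) ">" else ">=", min),
              "cwrq_config_error")
  invisible(x)
}

# Shift a matrix by (dr, dc), padding with `fill`; used to vectorise
# neighbourhood operations (Hessian stencils, NMS, thinning).
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Offsets of the 8-neighbourhood in (dr, dc) order N, NE, E, SE, S, SW, W, NW
# with rows increasing downwards.
NBR8 <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
              dc = c(0, 1, 1, 1, 0, -1, -1, -1))

# Count of 8-neighbours that are TRUE, for a logical matrix.
neighbor_count <- function(B) {
  num <- matrix(0L, nrow(B), ncol(B))
  Bm <- B * 1L
  for (i in seq_len(8L))
    num <- num + shift_mat(Bm, NBR8[i, 1L], NBR8[i, 2L], 0L)
  num
}

# Arc length of an n x 2 polyline (row, col coordinates), in pixels.
polyline_length <- function(pts) {
  if (is.null(pts) || nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}
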