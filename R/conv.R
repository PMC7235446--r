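# Convolutional plumbing for spiking layers. Feature maps are 4-d arrays
# (batch, channel, height, width). Convolutions are evaluated by unrolling
# input patches into a matrix (im2col) and multiplying by the kernel matrix,
# which makes the kernel gradient literally the dense three-factor gradient
# applied to the unrolled patch matrix.

# Precomputed patch-gather plan for im2col on maps of fixed geometry and
# batch size: a single linear-index matrix turns patch unrolling into one
# vector gather instead of C*k*k strided array slices. Two map layouts are
# supported: "cf" (batch, channel, height, width), used by the exported
# array API, and "cl" (batch, height, width, channel), used by the training
# fast path because it lets pooled maps reinterpret as flat unit matrices
# without transposition. Patch-matrix column order is (channel, ky, kx)
# with channel fastest in both layouts, so the same kernel matrix applies.
make_im2col_plan <- function(B, C, H, W, k, pad, layout = c("cf", "cl")) {
  layout <- match.arg(layout)
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  Ho <- Hp - k + 1L
  Wo <- Wp - k + 1L
  if (Ho < 1L || Wo < 1L) abort("kernel larger than (padded) input map")
  # the linear index of an element decomposes into a row part (b, oy, ox)
  # plus a column part (ch, dy, dx)
  oy <- rep(rep(0:(Ho - 1L), each = B), times = Wo)
  ox <- rep(0:(Wo - 1L), each = B * Ho)
  ch <- rep(0:(C - 1L), times = k * k)
  dy <- rep(rep(0:(k - 1L), each = C), times = k)
  dx <- rep(0:(k - 1L), each = C * k)
  if (layout == "cf") {
    row0 <- rep.int(seq_len(B), Ho * Wo) + B * C * oy + B * C * Hp * ox
    col0 <- B * ch + B * C * dy + B * C * Hp * dx
  } else {
    row0 <- rep.int(seq_len(B), Ho * Wo) + B * oy + B * Hp * ox
    col0 <- B * dy + B * Hp * dx + B * Hp * Wp * ch
  }
  # keep the gather index as a bare vector: a matrix subscript whose column
  # count equals the array's dimensionality would be treated as coordinates
  idx <- as.vector(outer(row0, col0, "+"))
  list(
    idx = idx, n_rows = length(row0), n_cols = length(col0),
    B = B, C = C, H = H, W = W, k = k, pad = pad, layout = layout,
    Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, out_dim = c(B, Ho, Wo)
  )
}

# Row indices of the four 2x2-window positions of a pre-pool (B, Ho, Wo)
# row grid, for each pooled cell (b, py, px): position order top-left,
# bottom-left, top-right, bottom-right (matching max_pool_idx codes).
make_pool_plan <- function(B, Ho, Wo) {
  Hp <- Ho %/% 2L
  Wp <- Wo %/% 2L
  py <- rep(rep(0:(Hp - 1L), each = B), times = Wp)
  px <- rep(0:(Wp - 1L), each = B * Hp)
  base <- rep.int(seq_len(B), Hp * Wp)
  at <- function(dy, dx) base + B * (2L * py + dy) + B * Ho * (2L * px + dx)
  list(rows = list(at(0L, 0L), at(1L, 0L), at(0L, 1L), at(1L, 1L)),
       Hp = Hp, Wp = Wp)
}

# Unroll k x k patches (stride 1) of X (B, C, H, W) into a matrix of shape
# (B * Ho * Wo, C * k * k). Row order: batch fastest, then output row, then
# output column. Column order: channel fastest, then kernel row, then kernel
# column. A precomputed plan (same geometry) avoids repeated index work.
im2col <- function(X, k, pad = 0, plan = NULL) {
  d <- dim(X)
  if (length(d) != 4L) abort("feature maps must be 4-d (batch, channel, height, width)")
  if (is.null(plan)) plan <- make_im2col_plan(d[1], d[2], d[3], d[4], k, pad)
  if (plan$pad > 0L) {
    if (plan$layout == "cf") {
      Xp <- array(0, c(plan$B, plan$C, plan$Hp, plan$Wp))
      Xp[, , plan$pad + seq_len(plan$H), plan$pad + seq_len(plan$W)] <- X
    } else {
      Xp <- array(0, c(plan$B, plan$Hp, plan$Wp, plan$C))
      Xp[, plan$pad + seq_len(plan$H), plan$pad + seq_len(plan$W), ] <- X
    }
  } else {
    Xp <- X
  }
  M <- Xp[plan$idx]
  dim(M) <- c(plan$n_rows, plan$n_cols)
  attr(M, "out_dim") <- plan$out_dim
  M
}

# Dense (rows = B*Ho*Wo, cols = F) -> map array (B, F, Ho, Wo)
cols_to_map <- function(V, out_dim) {
  B <- out_dim[1]; Ho <- out_dim[2]; Wo <- out_dim[3]
  aperm(array(V, c(B, Ho, Wo, ncol(V))), c(1L, 4L, 2L, 3L))
}

# Map array (B, F, Ho, Wo) -> matrix (B*Ho*Wo, F) matching im2col row order.
map_to_cols <- function(A) {
  d <- dim(A)
  matrix(aperm(A, c(1L, 3L, 4L, 2L)), d[1] * d[3] * d[4], d[2])
}

# Flatten a map array (B, F, H, W) to a (B, units) matrix; unit order is
# channel fastest, then row, then column. The inverse is mat_to_map().
map_to_mat <- function(A) matrix(A, nrow = dim(A)[1])
mat_to_map <- function(m, d) array(m, d)

# Convolution of X with kernel matrix Wk (F x C*k*k), stride 1.
# Returns the output map (B, F, Ho, Wo) with bias added, plus the unrolled
# patch matrix (reused by the gradient).
conv_forward <- function(X, Wk, b, k, pad = 0, plan = NULL) {
  M <- im2col(X, k, pad, plan)
  V <- M %*% t(Wk)
  V <- sweep(V, 2L, b, "+")
  list(V = cols_to_map(V, attr(M, "out_dim")), M = M, out_dim = attr(M, "out_dim"))
}

#' Non-overlapping 2x2 max pooling
#'
#' Applied to membrane-potential maps before thresholding. Accepts a plain
#' 2-d matrix or a 4-d (batch, channel, height, width) array; odd trailing
#' rows/columns are truncated.
#'
#' @param U_map numeric matrix or 4-d array.
#' @param window pooling window (only 2 supported).
#' @return the pooled map, same structure at half resolution.
#' @examples
#' max_pool(matrix(1:4, 2, 2, byrow = TRUE)) # 4
#' @export
max_pool <- function(U_map, window = 2) {
  if (window != 2) abort("only 2x2 pooling is supported")
  if (is.matrix(U_map)) {
    A <- array(U_map, c(1L, 1L, nrow(U_map), ncol(U_map)))
    return(max_pool_idx(A)$pooled[1, 1, , , drop = TRUE])
  }
  max_pool_idx(U_map)$pooled
}

# 2x2 max pooling with argmax bookkeeping for gradient routing.
# idx codes the within-window argmax: 1 = top-left, 2 = bottom-left,
# 3 = top-right, 4 = bottom-right (ties broken in that order).
max_pool_idx <- function(A) {
  d <- dim(A)
  Hp <- d[3] %/% 2L
  Wp <- d[4] %/% 2L
  ry <- seq_len(2L * Hp)
  rx <- seq_len(2L * Wp)
  a11 <- A[, , ry[ry %% 2L == 1L], rx[rx %% 2L == 1L], drop = FALSE]
  a21 <- A[, , ry[ry %% 2L == 0L], rx[rx %% 2L == 1L], drop = FALSE]
  a12 <- A[, , ry[ry %% 2L == 1L], rx[rx %% 2L == 0L], drop = FALSE]
  a22 <- A[, , ry[ry %% 2L == 0L], rx[rx %% 2L == 0L], drop = FALSE]
  pooled <- pmax(a11, a21, a12, a22)
  i1 <- a11 == pooled
  i2 <- !i1 & (a21 == pooled)
  i3 <- !i1 & !i2 & (a12 == pooled)
  idx <- 4L - 3L * i1 - 2L * i2 - 1L * i3
  dim(idx) <- dim(pooled)
  list(pooled = pooled, idx = idx)
}

# Scatter pooled-level values back onto the pre-pool grid at the argmax
# positions (zeros elsewhere). dp and idx have pooled shape (B, F, Hp, Wp);
# the result has pre-pool shape (B, F, Ho, Wo).
pool_scatter <- function(dp, idx, Ho, Wo) {
  d <- dim(dp)
  B <- d[1]; Fn <- d[2]; Hp <- d[3]; Wp <- d[4]
  D <- array(0, c(B, Fn, Ho, Wo))
  ys <- list(seq(1L, 2L * Hp, 2L), seq(2L, 2L * Hp, 2L), seq(1L, 2L * Hp, 2L), seq(2L, 2L * Hp, 2L))
  xs <- list(seq(1L, 2L * Wp, 2L), seq(1L, 2L * Wp, 2L), seq(2L, 2L * Wp, 2L), seq(2L, 2L * Wp, 2L))
  for (pos in 1:4) {
    contrib <- dp * (idx == pos)
    D[, , ys[[pos]], xs[[pos]]] <- D[, , ys[[pos]], xs[[pos]], drop = FALSE] + contrib
  }
  D
}

#' Three-factor gradient for a convolutional layer
#'
#' The kernel gradient is the dense rule applied to the unrolled patch
#' matrix of the presynaptic traces: at every output position the gated
#' error `error * boxcar(U)` multiplies the corresponding input patch of
#' `P`; contributions are summed over spatial positions and averaged over
#' the batch. The bias gradient sums the gated error over positions.
#'
#' @param error_map backprojected error at the conv output (B, F, Ho, Wo).
#' @param U_map membrane potential at the conv output, same shape.
#' @param P_map presynaptic trace map (B, C, H, W).
#' @param kernel kernel size k (square kernels, stride 1).
#' @param pad zero padding applied to `P_map`.
#' @return list with `gW` (F x C*k*k kernel-matrix gradient) and `gb`
#'   (length F).
#' @export
conv_decolle_gradient <- function(error_map, U_map, P_map, kernel, pad = 0) {
  if (!identical(dim(error_map), dim(U_map))) abort("`error_map` and `U_map` shapes differ")
  M <- im2col(P_map, kernel, pad)
  od <- attr(M, "out_dim")
  if (!all(dim(error_map)[c(1L, 3L, 4L)] == od)) {
    abort("output-map geometry does not match the patch geometry of `P_map`")
  }
  d <- error_map * surrogate_derivative(U_map)
  Dm <- map_to_cols(d)
  B <- od[1]
  list(gW = crossprod(Dm, M) / B, gb = colSums(Dm) / B)
}

# Convert between the kernel matrix (F x C*k*k, im2col column order) and the
# 4-d kernel array (F, C, k, k). Used for checkpoint inspection.
kernel_matrix_to_array <- function(Wk, C, k) {
  array(Wk, c(nrow(Wk), C, k, k))
}
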