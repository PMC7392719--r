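#' @importFrom stats rnorm sd var cor quantile approx
#' @importFrom utils write.csv read.csv head
NULL

# trapezoidal integral; thin wrapper so the integrator is named once
trapz_int <- function(x, y) pracma::trapz(x, y)

# cumulative trapezoidal integral, same length as x (first element 0)
cumtrapz_int <- function(x, y) {
  c(0, cumsum(diff(x) * (head(y, -1) + y[-1]) / 2))
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid("'%s' must be a single positive finite number", name)
  invisible(x)
}

# largest 4-connected component of a logical matrix; returns logical matrix.
# Flood fill with an integer queue; matrices here are small (<= a few hundred
# columns) so plain R is adequate.
largest_component <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  nlab <- 0L
  best_size <- 0L; best_lab <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    nlab <- nlab + 1L
    queue <- integer(length(idx_all)); qh <- 1L; qt <- 1L
    queue[1L] <- start; labels[start] <- nlab
    size <- 0L
    while (qh <= qt) {
      p <- queue[qh]; qh <- qh + 1L; size <- size + 1L
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      if (r > 1L) { q <- p - 1L; if (mask[q] && labels[q] == 0L) { labels[q] <- nlab; qt <- qt + 1L; queue[qt] <- q } }
      if (r < nr) { q <- p + 1L; if (mask[q] && labels[q] == 0L) { labels[q] <- nlab; qt <- qt + 1L; queue[qt] <- q } }
      if (cc > 1L) { q <- p - nr; if (mask[q] && labels[q] == 0L) { labels[q] <- nlab; qt <- qt + 1L; queue[qt] <- q } }
      if (cc < nc) { q <- p + nr; if (mask[q] && labels[q] == 0L) { labels[q] <- nlab; qt <- qt + 1L; queue[qt] <- q } }
    }
    if (size > best_size) { best_size <- size; best_lab <- nlab }
  }
  labels == best_lab & best_lab > 0L
}

# binary dilation by `k` pixels (Chebyshev / square structuring element),
# implemented as iterated shift-OR
dilate_mask <- function(mask, k) {
  if (k <= 0) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(k)) {
    m <- mask
    m[-1, ] <- m[-1, ] | mask[-nr, ]
    m[-nr, ] <- m[-nr, ] | mask[-1, ]
    m[, -1] <- m[, -1] | mask[, -nc]
    m[, -nc] <- m[, -nc] | mask[, -1]
    # diagonal neighbours
    m[-1, -1] <- m[-1, -1] | mask[-nr, -nc]
    m[-nr, -nc] <- m[-nr, -nc] | mask[-1, -1]
    m[-1, -nc] <- m[-1, -nc] | mask[-nr, -1]
    m[-nr, -1] <- m[-nr, -1] | mask[-1, -nc]
    mask <- m
  }
  mask
}

# 3x3 boxcar mean filter with zero padding outside the grid
smooth3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    src_r <- max(1, 1 - dr):min(nr, nr - dr)
    dst_r <- src_r + dr
    src_c <- max(1, 1 - dc):min(nc, nc - dc)
    dst_c <- src_c + dc
    acc[dst_r, dst_c] <- acc[dst_r, dst_c] + m[src_r, src_c]
  }
  acc / 9
}

# longest contiguous run of TRUE; returns integer indices (empty if none)
longest_run <- function(flag) {
  if (!any(flag)) return(integer(0))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_runs <- which(r$values)
  best <- true_runs[which.max(r$lengths[true_runs])]
  seq.int(starts[best], ends[best])
}
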