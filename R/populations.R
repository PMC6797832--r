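## Virtual-drug population generators: Saltelli low-discrepancy sampling
## (Population I) and kernel-density resampling around drug-derived
## parameter points (Population II).

#' Input parameter ranges for virtual-drug sampling
#'
#' The sampling bounds of the nine drug-action inputs: percent block of the
#' six non-hERG currents in `[0, 80]`, static hERG binding strength `sbIKr`
#' in `[0, 4]`, trapping half-voltage `Vhalf` in `[-200, -1]` mV, unbinding
#' rate `Ku` in `[0, 1]` 1/ms.
#'
#' @return 9 x 2 matrix with rownames the block-vector components and
#'   columns `min`, `max`.
#' @export
parameter_ranges <- function() {
  m <- rbind(bINa = c(0, 80), bINaL = c(0, 80), bIto = c(0, 80),
             bIKs = c(0, 80), bICaL = c(0, 80), bIK1 = c(0, 80),
             sbIKr = c(0, 4), Vhalf = c(-200, -1), Ku = c(0, 1))
  colnames(m) <- c("min", "max")
  m
}

## Sobol direction numbers (standard Joe-Kuo table, first 21 dimensions):
## full primitive-polynomial encodings and initial m values.
.sobol_poly <- c(3, 7, 11, 13, 19, 25, 37, 41, 47, 55, 59, 61, 67, 91, 97,
                 103, 109, 115, 131, 137)
.sobol_minit <- list(
  c(1), c(1, 3), c(1, 3, 1), c(1, 1, 1), c(1, 1, 3, 3), c(1, 3, 5, 13),
  c(1, 1, 5, 5, 17), c(1, 1, 5, 5, 5), c(1, 1, 7, 11, 19),
  c(1, 1, 5, 1, 1), c(1, 1, 1, 3, 11), c(1, 3, 5, 5, 31),
  c(1, 3, 3, 9, 7, 49), c(1, 1, 1, 15, 21, 21), c(1, 3, 1, 13, 27, 49),
  c(1, 1, 1, 15, 7, 5), c(1, 3, 1, 15, 13, 25), c(1, 1, 5, 5, 19, 61),
  c(1, 3, 7, 11, 23, 15, 103), c(1, 3, 7, 13, 13, 15, 69))
.sobol_maxbit <- 30L

## direction-number table for one dimension (integer v_k, k = 1..maxbit)
.sobol_directions <- function(dim) {
  mb <- .sobol_maxbit
  v <- integer(mb)
  if (dim == 1) {
    for (k in seq_len(mb)) v[k] <- bitwShiftL(1L, mb - k)
    return(v)
  }
  poly <- .sobol_poly[dim - 1]
  s <- floor(log2(poly))
  m <- .sobol_minit[[dim - 1]]
  for (k in seq_len(s)) v[k] <- bitwShiftL(m[k], mb - k)
  for (k in seq(s + 1, mb)) {
    vk <- bitwXor(v[k - s], bitwShiftR(v[k - s], s))
    for (i in seq_len(s - 1)) {
      if (bitwAnd(bitwShiftR(poly, s - i), 1L) == 1L)
        vk <- bitwXor(vk, v[k - i])
    }
    v[k] <- vk
  }
  v
}

#' Sobol low-discrepancy sequence
#'
#' Gray-code Sobol sequence on the unit hypercube with a seeded random
#' digital shift (XOR scrambling), so different seeds give different but
#' equally uniform point sets and a fixed seed is fully reproducible.
#'
#' @param n Number of points.
#' @param d Dimension (up to 21).
#' @param seed Integer seed for the digital shift; `NULL` for the
#'   unscrambled sequence.
#' @return n x d matrix in `[0, 1)`.
#' @export
sobol_sequence <- function(n, d, seed = NULL) {
  if (d > 21) stop("Sobol direction numbers embedded up to dimension 21")
  mb <- .sobol_maxbit
  vmat <- vapply(seq_len(d), .sobol_directions, integer(mb))
  shift <- integer(d)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    shift <- as.integer(floor(stats::runif(d) * 2^mb))
  }
  x <- matrix(0L, n, d)
  state <- integer(d)
  for (i in seq_len(n)) {
    if (i > 1) {
      ## lowest zero bit of i - 2 (Gray-code ordering)
      j <- i - 2
      c_ <- 1L
      while (bitwAnd(j, 1L) == 1L) {
        j <- bitwShiftR(j, 1)
        c_ <- c_ + 1L
      }
      state <- bitwXor(state, vmat[c_, ])
    }
    x[i, ] <- bitwXor(state, shift)
  }
  x / 2^mb
}

#' Saltelli cross-sampling population (Virtual Drug Population I)
#'
#' Sobol-sequence-based A/B/AB (and BA for second-order) arrangement scaled
#' to the sampling ranges.  Row count is `n * (2k + 2)` with the
#' second-order layout and `n * (k + 2)` without.  Rows are grouped per
#' base sample: A, the k AB_i rows (column i taken from B), the k BA_i rows
#' when `second_order`, then B — the layout [sobol_indices()] expects.
#'
#' @param ranges Sampling bounds, as [parameter_ranges()].
#' @param n Base sample size (a power of 2 is recommended; anything else
#'   draws a warning).
#' @param k Number of input parameters; must match `nrow(ranges)`.
#' @param second_order Include the BA blocks needed for S2 estimates.
#' @param seed Seed for the digital shift.
#' @return Object of class `sample_matrix`: `samples` (data.frame, one
#'   block vector per row), `scheme`, `n`, `k`, `second_order`, `seed`,
#'   `ranges`.
#' @export
saltelli_population <- function(ranges = parameter_ranges(), n = 500,
                                k = nrow(ranges), second_order = TRUE,
                                seed = 1) {
  if (k != nrow(ranges))
    stop("k (", k, ") does not match nrow(ranges) (", nrow(ranges), ")")
  if (n < 1 || n != round(n)) stop("n must be a positive integer")
  if (bitwAnd(n, n - 1) != 0)
    warning("n = ", n, " is not a power of 2; the Sobol sequence is most ",
            "uniform at powers of 2")
  base <- sobol_sequence(n, 2 * k, seed = seed)
  A <- base[, seq_len(k), drop = FALSE]
  B <- base[, k + seq_len(k), drop = FALSE]
  per <- if (second_order) 2 * k + 2 else k + 2
  out <- matrix(NA_real_, n * per, k)
  for (i in seq_len(n)) {
    off <- (i - 1) * per
    out[off + 1, ] <- A[i, ]
    for (j in seq_len(k)) {
      ab <- A[i, ]; ab[j] <- B[i, j]
      out[off + 1 + j, ] <- ab
    }
    if (second_order) {
      for (j in seq_len(k)) {
        ba <- B[i, ]; ba[j] <- A[i, j]
        out[off + 1 + k + j, ] <- ba
      }
    }
    out[off + per, ] <- B[i, ]
  }
  scaled <- sweep(sweep(out, 2, ranges[, "max"] - ranges[, "min"], "*"),
                  2, ranges[, "min"], "+")
  colnames(scaled) <- rownames(ranges)
  structure(list(samples = as.data.frame(scaled), scheme = "saltelli",
                 n = n, k = k, second_order = second_order, seed = seed,
                 ranges = ranges),
            class = "sample_matrix")
}

#' Kernel-density resampled population (Virtual Drug Population II)
#'
#' Draws virtual drugs from a product-Gaussian kernel density estimate
#' built on MinMax-normalized seed points (the drug-derived parameter
#' vectors): a seed point is drawn uniformly, each component is perturbed
#' independently with Gaussian noise of standard deviation `bandwidth` on
#' the normalized scale, and rows falling outside the rejection hull are
#' discarded until `n_out` rows are accepted.
#'
#' @param seed_points Matrix or data.frame of parameter rows in original
#'   units (columns ordered as [parameter_ranges()]).
#' @param n_out Number of accepted samples.
#' @param bandwidth Kernel standard deviation on the normalized scale.
#' @param ranges Parameter ranges (used when `hull = "ranges"`).
#' @param seed RNG seed.
#' @param hull `"seed"` rejects outside the componentwise min/max of the
#'   seed points (the default reading of "the range prescribed by the
#'   reference drugs"); `"ranges"` rejects outside `ranges`.
#' @return A `sample_matrix` with `scheme = "kde"`.
#' @export
kde_population <- function(seed_points, n_out, bandwidth = 0.08,
                           ranges = parameter_ranges(), seed = 1,
                           hull = c("seed", "ranges")) {
  hull <- match.arg(hull)
  pts <- as.matrix(seed_points)
  k <- ncol(pts)
  lo <- if (hull == "seed") apply(pts, 2, min) else ranges[, "min"]
  hi <- if (hull == "seed") apply(pts, 2, max) else ranges[, "max"]
  span <- hi - lo
  span[span == 0] <- 1
  norm <- sweep(sweep(pts, 2, lo, "-"), 2, span, "/")
  set.seed(seed)
  acc <- matrix(NA_real_, 0, k)
  tried <- 0
  while (nrow(acc) < n_out) {
    m <- max(1000, 2 * (n_out - nrow(acc)))
    tried <- tried + m
    idx <- sample.int(nrow(norm), m, replace = TRUE)
    cand <- norm[idx, , drop = FALSE] +
      matrix(stats::rnorm(m * k, sd = bandwidth), m, k)
    ok <- rowSums(cand < 0 | cand > 1) == 0
    acc <- rbind(acc, cand[ok, , drop = FALSE])
    if (tried >= 100 * n_out && nrow(acc) / tried < 0.01)
      stop("KDE acceptance rate below 1%; review bandwidth or hull")
  }
  acc <- acc[seq_len(n_out), , drop = FALSE]
  out <- sweep(sweep(acc, 2, span, "*"), 2, lo, "+")
  colnames(out) <- colnames(pts)
  structure(list(samples = as.data.frame(out), scheme = "kde", n = n_out,
                 k = k, second_order = FALSE, seed = seed, ranges = ranges,
                 bandwidth = bandwidth, hull = hull),
            class = "sample_matrix")
}

#' Write / read a population as CSV
#' @param pop A `sample_matrix`.
#' @param path CSV path.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(pop$samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @param scheme Sampling scheme recorded on the reloaded object.
#' @param ... Metadata fields (`n`, `k`, `second_order`, `seed`) to restore.
#' @export
read_population <- function(path, scheme = "saltelli", ...) {
  df <- utils::read.csv(path)
  meta <- list(...)
  structure(c(list(samples = df, scheme = scheme,
                   k = ncol(df)), meta),
            class = "sample_matrix")
}
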