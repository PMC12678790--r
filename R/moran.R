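#' Inverse-distance weights over a matrix grid
#'
#' One observation per matrix cell at integer (row, col) coordinates;
#' \code{w[i, j] = 1 / dist(coords_i, coords_j)} with a zero diagonal. Cell
#' order matches \code{as.vector()} on the matrix (column-major), so the
#' weights can be applied directly to a vectorised 7x7 significance matrix.
#'
#' @param rows,cols grid dimensions (default 7x7).
#' @param metric \code{"euclidean"} or \code{"manhattan"}.
#' @return An object of class \code{grid_weights}: \code{w} (n x n),
#'   \code{coords} (n x 2), \code{n}.
#' @export
inverse_distance_weights <- function(rows = 7, cols = 7,
                                     metric = c("euclidean", "manhattan")) {
  stopifnot(rows >= 2, cols >= 2)
  metric <- match.arg(metric)
  coords <- cbind(row = rep(seq_len(rows), times = cols),
                  col = rep(seq_len(cols), each = rows))
  d <- as.matrix(stats::dist(coords, method = metric))
  w <- ifelse(d > 0, 1 / d, 0)
  structure(list(w = w, coords = coords, n = rows * cols, metric = metric),
            class = "grid_weights")
}

#' Moran's I spatial autocorrelation
#'
#' Evaluates
#' \deqn{I = \frac{\sum_{i} \sum_{j \ne i} w_{ij} (x_i - \bar x)(x_j - \bar x)}
#'            {S^2 \sum_{i} \sum_{j \ne i} w_{ij}}, \quad
#'       S^2 = \frac{1}{n} \sum_i (x_i - \bar x)^2}
#' exactly as written, with no weight normalisation by default. Setting
#' \code{normalize = "row"} row-standardises the weights first (the
#' convention \code{ape::Moran.I} applies), which changes I unless weights
#' are already row-stochastic.
#'
#' @param x numeric observations, one per grid cell (e.g.
#'   \code{as.vector(m$sig)} for a significance matrix).
#' @param weights a \code{\link{inverse_distance_weights}} object or a plain
#'   weight matrix with zero diagonal.
#' @param normalize \code{"none"} (the displayed formula) or \code{"row"}.
#' @return An object of class \code{moran_result}: \code{I}, \code{x_bar},
#'   \code{S2}, \code{n}, \code{expected} (\code{-1/(n-1)}).
#' @export
morans_i <- function(x, weights = inverse_distance_weights(),
                     normalize = c("none", "row")) {
  normalize <- match.arg(normalize)
  w <- if (inherits(weights, "grid_weights")) weights$w else weights
  stopifnot(is.matrix(w), length(x) == nrow(w), nrow(w) == ncol(w),
            all(diag(w) == 0))
  n <- length(x)
  x_bar <- mean(x)
  S2 <- mean((x - x_bar)^2)
  if (S2 == 0) stop("Moran's I undefined for constant observations (S^2 = 0)")
  if (normalize == "row") {
    rs <- rowSums(w)
    w <- w / ifelse(rs > 0, rs, 1)
  }
  xc <- x - x_bar
  I <- as.numeric(crossprod(xc, w %*% xc)) / (S2 * sum(w))
  structure(list(I = I, x_bar = x_bar, S2 = S2, n = n,
                 expected = -1 / (n - 1), normalize = normalize),
            class = "moran_result")
}

#' Moran's I of a significance matrix
#'
#' Convenience wrapper: vectorises all 49 cells of the 7x7 matrix (zero
#' diagonal included) in column-major order and scores them against
#' inverse-distance grid weights.
#'
#' @param m a \code{sig_matrix} or plain 7x7 numeric/logical matrix.
#' @param weights grid weights (default Euclidean inverse distance on 7x7).
#' @param ... passed to \code{\link{morans_i}}.
#' @return A \code{moran_result}.
#' @export
morans_i_matrix <- function(m, weights = inverse_distance_weights(), ...) {
  s <- if (inherits(m, "sig_matrix")) m$sig else m
  stopifnot(is.matrix(s))
  morans_i(as.numeric(s), weights, ...)
}

#' Shuffle null distribution of Moran's I
#'
#' Permutes the cell values of the matrix uniformly at random across all
#' cell positions (diagonal included, matching the vectorised observation
#' set) and recomputes I after each shuffle.
#'
#' @param m a \code{sig_matrix} or plain 7x7 matrix with at least one
#'   nonconstant cell.
#' @param weights grid weights.
#' @param n_shuffles number of shuffles (default 10).
#' @param seed optional integer seed for reproducibility.
#' @return Numeric vector of null I values, in shuffle order.
#' @export
shuffle_null <- function(m, weights = inverse_distance_weights(),
                         n_shuffles = 10, seed = NULL) {
  s <- if (inherits(m, "sig_matrix")) m$sig else m
  x <- as.numeric(s)
  if (stats::var(x) == 0) stop("constant matrix: null undefined")
  if (!is.null(seed)) set.seed(seed)
  if (n_shuffles == 0) return(numeric(0))
  w <- if (inherits(weights, "grid_weights")) weights$w else weights
  sumw <- sum(w)
  x_bar <- mean(x)
  S2 <- mean((x - x_bar)^2)
  vapply(seq_len(n_shuffles), function(k) {
    xs <- sample(x) - x_bar
    as.numeric(crossprod(xs, w %*% xs)) / (S2 * sumw)
  }, numeric(1))
}
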