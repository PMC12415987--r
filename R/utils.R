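#' @importFrom methods is
#' @importFrom stats rlnorm rnorm rpois runif median mad sd aov t.test TukeyHSD
#' @importFrom utils modifyList write.csv read.csv
NULL

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0) stopf("'%s' must be > 0", name)
  if (nonneg && x < 0) stopf("'%s' must be >= 0", name)
  if (integer && x != round(x)) stopf("'%s' must be an integer", name)
  invisible(x)
}

check_fraction <- function(x, name) {
  check_scalar(x, name)
  if (x < 0 || x > 1) stopf("'%s' must lie in [0, 1]", name)
  invisible(x)
}

# Coerce EBImage return values back to a plain matrix.
as_mat <- function(x) {
  if (methods::is(x, "Image")) x <- EBImage::imageData(x)
  m <- as.matrix(x)
  dimnames(m) <- NULL
  m
}

# Ramanujan's second approximation to the perimeter of an ellipse with
# semi-axes a, b; accurate to O(h^10), far below measurement error here.
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# Linear indices of pixels whose (0-based) centers fall inside the ellipse
# centered at (cy, cx) with semi-axes (a, b) and rotation theta.
ellipse_pixels <- function(cy, cx, a, b, theta, nrow, ncol) {
  r <- max(a, b) + 1
  rows <- max(1L, floor(cy + 1 - r)):min(nrow, ceiling(cy + 1 + r))
  cols <- max(1L, floor(cx + 1 - r)):min(ncol, ceiling(cx + 1 + r))
  if (!length(rows) || !length(cols)) return(integer(0))
  dy <- (rows - 1) - cy
  dx <- (cols - 1) - cx
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy, dx, function(y, x) x * ct + y * st)
  v <- outer(dy, dx, function(y, x) -x * st + y * ct)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  ij <- which(inside, arr.ind = TRUE)
  if (!nrow(ij)) return(integer(0))
  (cols[ij[, 2L]] - 1L) * nrow + rows[ij[, 1L]]
}

# Row/column (1-based) coordinates of linear matrix indices.
idx_rc <- function(idx, nrow) {
  cbind(row = ((idx - 1L) %% nrow) + 1L, col = ((idx - 1L) %/% nrow) + 1L)
}
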