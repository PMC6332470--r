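#' Deterministic test signals
#'
#' Generates the analog signals used to exercise spike-based encoding:
#' a step (zero until a third of the window, then `amplitude`), a linear
#' ramp from 0 to `amplitude`, or a sine of the given period centred on 0.
#'
#' @param kind one of `"step"`, `"ramp"`, `"sine"`.
#' @param amplitude signal amplitude.
#' @param duration window length (ms).
#' @param dt sampling step (ms).
#' @param onset step onset time (ms), for `kind = "step"`.
#' @param period sine period (ms), for `kind = "sine"`.
#' @return numeric vector sampled at `dt`, length `duration / dt`.
#' @examples
#' s <- make_signal("step", amplitude = 1, duration = 300)
#' range(s)
#' @export
make_signal <- function(kind = c("step", "ramp", "sine"), amplitude = 1,
                        duration = 500, dt = 1, onset = duration / 3,
                        period = 100) {
  kind <- match.arg(kind)
  if (duration <= 0) stop("'duration' must be > 0", call. = FALSE)
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  switch(kind,
         step = ifelse(t >= onset, amplitude, 0),
         ramp = amplitude * t / ((n - 1) * dt),
         sine = amplitude * sin(2 * pi * t / period))
}

#' Seeded Gaussian-blob classification data
#'
#' `K` spherical Gaussian clusters (unit variance per dimension) whose
#' centres sit at the vertices of a regular simplex scaled so that every
#' pair of centres is `separation` standard deviations apart. Labels are
#' balanced up to rounding; a train/test split is drawn stratified by class.
#' Everything is a pure function of `seed`.
#'
#' @param n total number of samples.
#' @param d feature dimension (requires `K <= d + 1` for the simplex).
#' @param K number of classes.
#' @param separation pairwise centre distance in units of the cluster
#'   standard deviation.
#' @param seed integer seed.
#' @param test_fraction fraction of samples held out as the test split.
#' @return object of class `toy_dataset`: list with `features` (n x d
#'   matrix), `labels` (integers in `0..K-1`), `train`, `test` (index
#'   vectors), `K`, and `seed`.
#' @examples
#' ds <- make_blobs(n = 90, d = 4, K = 3, separation = 10, seed = 1)
#' table(ds$labels)
#' @export
make_blobs <- function(n, d, K, separation, seed, test_fraction = 1 / 3) {
  if (n < K) stop("'n' must be >= K", call. = FALSE)
  if (separation <= 0) stop("'separation' must be > 0", call. = FALSE)
  if (K < 2) stop("'K' must be >= 2", call. = FALSE)
  if (K > d + 1) stop("simplex placement requires K <= d + 1", call. = FALSE)

  centers <- simplex_vertices(K, d) * separation
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  labels <- rep_len(seq_len(K) - 1L, n)
  x <- matrix(stats::rnorm(n * d), n, d) + centers[labels + 1L, , drop = FALSE]
  perm <- sample.int(n)
  x <- x[perm, , drop = FALSE]
  labels <- labels[perm]

  test <- unlist(lapply(split(seq_len(n), labels), function(idx) {
    idx[seq_len(max(1L, round(length(idx) * test_fraction)))]
  }), use.names = FALSE)
  train <- setdiff(seq_len(n), test)

  structure(list(features = x, labels = labels, train = sort(train),
                 test = sort(test), K = K, seed = seed),
            class = "toy_dataset")
}

# K vertices of a regular simplex embedded in R^d, unit pairwise distance.
simplex_vertices <- function(K, d) {
  v <- diag(1, K, K)
  v <- v - matrix(colMeans(v), K, K, byrow = TRUE)
  # rows of v have pairwise distance sqrt(2); project to K-1 dims via QR
  q <- qr.Q(qr(t(v)))[, seq_len(K - 1), drop = FALSE]
  coords <- v %*% q / sqrt(2)
  out <- matrix(0, K, d)
  out[, seq_len(K - 1)] <- coords
  out
}

#' @export
print.toy_dataset <- function(x, ...) {
  cat(sprintf("Toy dataset: %d samples, %d features, %d classes (seed %s)\n",
              nrow(x$features), ncol(x$features), x$K, format(x$seed)))
  cat(sprintf("  split: %d train / %d test\n", length(x$train), length(x$test)))
  invisible(x)
}

# Preserve caller's RNG state so generators are pure functions of their seed.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
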