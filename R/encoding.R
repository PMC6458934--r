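#' Assemble a classification dataset
#'
#' Lightweight container for a numeric feature matrix plus class labels.
#' Labels are remapped to contiguous integer ids `0..K-1` in first
#' appearance order of the class names, which also fixes the class ordering
#' used for target firing times.
#'
#' @param x Numeric matrix or data frame of features (samples in rows).
#' @param labels Vector of class labels (factor, character or integer).
#' @return An object of class `"snn_dataset"` with fields `x` (numeric
#'   matrix), `y` (integer ids 0..K-1) and `class_names`.
#' @examples
#' ds <- snn_dataset(matrix(rnorm(20), 10), rep(c("a", "b"), 5))
#' table(ds$y)
#' @export
snn_dataset <- function(x, labels) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  if (nrow(x) != length(labels))
    stop("labels length does not match number of rows", call. = FALSE)
  class_names <- as.character(unique(labels))
  if (length(class_names) < 2L)
    stop("a dataset needs at least 2 classes", call. = FALSE)
  y <- match(as.character(labels), class_names) - 1L
  if (any(table(y) < 2L))
    stop("every class needs at least 2 samples", call. = FALSE)
  structure(list(x = x, y = y, class_names = class_names),
            class = "snn_dataset")
}

#' @export
print.snn_dataset <- function(x, ...) {
  cat("SNN dataset:", nrow(x$x), "samples,", ncol(x$x), "features,",
      length(x$class_names), "classes\n")
  print(stats::setNames(as.integer(table(x$y)), x$class_names))
  invisible(x)
}

#' Read a CSV classification dataset
#'
#' Reads a UCI-style numeric table. The label column may be named or given
#' by (1-based) index; all remaining columns must be numeric features.
#'
#' @param path Path to a comma-separated file.
#' @param label Label column: a column name or a 1-based column index.
#'   Defaults to the last column.
#' @param header Does the file have a header row?
#' @return An [snn_dataset()] object.
#' @export
read_dataset <- function(path, label = NULL, header = TRUE) {
  df <- read.csv(path, header = header, stringsAsFactors = FALSE)
  if (is.null(label)) label <- ncol(df)
  if (is.character(label)) {
    label <- match(label, names(df))
    if (is.na(label)) stop("label column not found", call. = FALSE)
  }
  snn_dataset(df[, -label, drop = FALSE], df[[label]])
}

#' Encode one feature value as a spike time
#'
#' The one-dimensional temporal encoding: a linear map sending the feature
#' range `[m, M]` onto the time window `[a, b]`,
#' \deqn{Y(f) = \frac{b-a}{r} f + \frac{aM - bm}{r}, \quad r = M - m,}
#' so that `Y(m) = a` and `Y(M) = b`. Values outside `[m, M]` are clamped to
#' the nearest endpoint before encoding; a degenerate range (`r = 0`) maps
#' every value to the window midpoint `(a+b)/2`.
#'
#' @param f Feature value(s); vectorized.
#' @param a,b Lower and upper temporal limits in ms (`a < b`); the study
#'   window is `[0.01, 9]` ms.
#' @param m,M Feature minimum and maximum learned from the design subset.
#' @return Spike time(s) in ms, inside `[a, b]`.
#' @examples
#' encode_feature(0.5, a = 0.01, b = 9, m = 0, M = 1)  # midpoint -> 4.505
#' @export
encode_feature <- function(f, a = 0.01, b = 9, m, M) {
  stopifnot(a < b, M >= m)
  r <- M - m
  if (r == 0) return(rep((a + b) / 2, length(f)))
  f <- pmin(pmax(f, m), M)
  ((b - a) / r) * f + (a * M - b * m) / r
}

#' Fit the temporal encoding on the design subset
#'
#' Learns per-feature minima and maxima from the design subset only, so the
#' held-out test half never influences the encoding (no leakage). Features
#' that are constant on the design subset are flagged degenerate and later
#' encode to the window midpoint, with a warning.
#'
#' @param design An [snn_dataset()] (the design half).
#' @param a,b Temporal window limits in ms.
#' @return An object of class `"snn_encoding"` with per-feature `m`, `M`,
#'   `r` and the window `[a, b]`.
#' @export
fit_encoding <- function(design, a = 0.01, b = 9) {
  stopifnot(inherits(design, "snn_dataset"), a < b)
  if (nrow(design$x) == 0L) stop("empty design set", call. = FALSE)
  m <- apply(design$x, 2, min)
  M <- apply(design$x, 2, max)
  degen <- (M - m) == 0
  if (any(degen))
    warning(sum(degen), " degenerate feature(s) (constant on design set) ",
            "will encode to the window midpoint", call. = FALSE)
  structure(list(a = a, b = b, m = m, M = M, r = M - m, degenerate = degen),
            class = "snn_encoding")
}

#' Encode a whole dataset as spike-time patterns
#'
#' Applies [encode_feature()] column-wise using an encoding fitted on the
#' design subset; dimension preserving.
#'
#' @param ds An [snn_dataset()].
#' @param spec An `"snn_encoding"` from [fit_encoding()].
#' @return A list with `spikes` (numeric matrix of input spike times, same
#'   shape as `ds$x`) and `y` (integer labels).
#' @export
encode_dataset <- function(ds, spec) {
  stopifnot(inherits(ds, "snn_dataset"), inherits(spec, "snn_encoding"))
  if (ncol(ds$x) != length(spec$m))
    stop("dataset and encoding dimensions do not match", call. = FALSE)
  spikes <- ds$x
  for (j in seq_len(ncol(spikes)))
    spikes[, j] <- encode_feature(ds$x[, j], spec$a, spec$b,
                                  spec$m[j], spec$M[j])
  list(spikes = spikes, y = ds$y)
}

#' Stratified half split into design and test subsets
#'
#' Randomly halves the dataset so that each class is evenly distributed
#' between the two subsets. Odd per-class counts send the extra sample to
#' the design subset. Deterministic for a fixed seed.
#'
#' @param ds An [snn_dataset()]; every class must have at least 2 samples.
#' @param seed Integer seed controlling the partition.
#' @return A list with `design` and `test` ([snn_dataset()] objects) and the
#'   integer row indices `design_idx`, `test_idx` into `ds`.
#' @export
stratified_split <- function(ds, seed = 1L) {
  stopifnot(inherits(ds, "snn_dataset"))
  design_idx <- with_seed(seed, {
    unlist(lapply(sort(unique(ds$y)), function(k) {
      rows <- which(ds$y == k)
      sample(rows, ceiling(length(rows) / 2))
    }), use.names = FALSE)
  })
  design_idx <- sort(design_idx)
  test_idx <- setdiff(seq_along(ds$y), design_idx)
  subset_ds <- function(idx)
    structure(list(x = ds$x[idx, , drop = FALSE], y = ds$y[idx],
                   class_names = ds$class_names),
              class = "snn_dataset")
  list(design = subset_ds(design_idx), test = subset_ds(test_idx),
       design_idx = design_idx, test_idx = test_idx)
}

#' Generate a synthetic Gaussian-blob dataset
#'
#' Test fixture generator: balanced isotropic Gaussian blobs with unit
#' noise, one centroid per class, centroids spaced `separation` apart along
#' a random direction arrangement. With large `separation` the classes are
#' linearly separable; with `separation = 0` all class-conditional means
#' coincide.
#'
#' @param n_samples Total sample count (balanced across classes; must be at
#'   least `2 * n_classes`).
#' @param n_features Feature-space dimension.
#' @param n_classes Number of classes.
#' @param separation Distance between consecutive class centroids.
#' @param seed Integer seed; the same seed reproduces the same dataset.
#' @return An [snn_dataset()].
#' @examples
#' ds <- make_blobs(40, 2, 2, separation = 8, seed = 1)
#' @export
make_blobs <- function(n_samples, n_features = 2, n_classes = 2,
                       separation = 8, seed = 1L) {
  stopifnot(n_samples >= 2 * n_classes, n_features >= 1, n_classes >= 2,
            separation >= 0)
  with_seed(seed, {
    centers <- matrix(0, n_classes, n_features)
    # place centroids separation apart along a random unit direction each
    for (k in seq_len(n_classes)[-1]) {
      dir <- rnorm(n_features)
      dir <- dir / sqrt(sum(dir^2))
      centers[k, ] <- centers[k - 1, ] + separation * dir
    }
    per <- rep(n_samples %/% n_classes, n_classes)
    extra <- n_samples - sum(per)
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    x <- do.call(rbind, lapply(seq_len(n_classes), function(k) {
      matrix(rnorm(per[k] * n_features), per[k]) +
        matrix(centers[k, ], per[k], n_features, byrow = TRUE)
    }))
    y <- rep(seq_len(n_classes) - 1L, per)
    snn_dataset(x, paste0("class", y))
  })
}
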